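# Scenario configurations: the base model and the five parameter-variation
# experiment families (pericapillary resistance, CSF outflow resistance,
# capillary-filtration mode, perivascular transfer coefficients, extracellular
# permeability).

#' Scenario names understood by [build_scenario()]
#' @export
scenario_names <- function() {
  c("base",
    "var1_base", "var1_pizzo", "var1_high",
    "var2_high", "var2_low",
    "var3_constant",
    "var4_case1", "var4_case2", "var4_case3", "var4_case4",
    "var5_high", "var5_veryhigh")
}

#' Base scenario configuration
#'
#' Bundles compartment parameters, transfer coefficients, lumped-model
#' overrides and the capillary-filtration mode into one configuration object.
#'
#' @param params See [default_compartment_params()].
#' @param omega See [default_transfer_coefficients()].
#' @export
base_scenario <- function(params = default_compartment_params(),
                          omega = default_transfer_coefficients()) {
  validate_compartment_params(params)
  validate_transfer_coefficients(omega)
  structure(list(
    name = "base",
    params = params,
    omega = omega,
    # lumped-model constants before the alpha scaling; NULL means default
    R_DS_const = NULL,
    R_crib_const = NULL,
    # capillary filtration: "pressure" (omega_c,pc exchange) or "constant"
    # (fixed ventricular influx into the pericapillary network)
    filtration = list(mode = "pressure", rate_ml_min = NULL)
  ), class = "scenario_config")
}

set_kappa <- function(scenario, comp, kappa_m2) {
  scenario$params$kappa[scenario$params$compartment == comp] <- kappa_m2
  scenario
}

set_omega <- function(scenario, i, j, value) {
  scenario$omega[i, j] <- scenario$omega[j, i] <- value
  scenario
}

#' Build a named scenario from the base configuration
#'
#' Applies exactly the parameter overrides of the study design:
#' * `var1_*`: pericapillary permeability recomputed from a pericapillary
#'   resistance R_pc of 9.2e-3 (base: kept at the tabulated kappa_pc),
#'   3.32e-4 ("pizzo") or 32.24 ("high") mmHg/(ml/min) via
#'   [permeability_from_resistance()] with L/A = 1.21e-4 /m.
#' * `var2_high` / `var2_low`: dural-sinus resistance constant doubled
#'   (21.62) or halved (5.41) mmHg/(ml/min); cribriform unchanged (67).
#' * `var3_constant`: omega_c,pc = 0 with a constant ventricular filtration of
#'   0.16 ml/min into the pericapillary network.
#' * `var4_case1..4`: perivascular transfer coefficient permutations
#'   (case1: omega_pc,e = 5e-7; case2: omega_pa,e = 1.86e-6,
#'   omega_pv,e = 1.65e-6, omega_pc,e = 1e-8; case3: omega_pa,e = 1e-10,
#'   omega_pc,e = 1.86e-7; case4: omega_pa,e and omega_pv,e halved).
#' * `var5_high` / `var5_veryhigh`: kappa_e = 200 / 2000 nm^2.
#'
#' @param name One of [scenario_names()].
#' @param base Starting configuration, by default [base_scenario()].
#' @export
build_scenario <- function(name, base = base_scenario()) {
  stopifnot(inherits(base, "scenario_config"))
  if (!name %in% scenario_names()) {
    stop("unknown scenario name: ", name)
  }
  sc <- base
  sc$name <- name
  mu_csf <- sc$params$mu[sc$params$compartment == "pc"]
  switch(name,
    base = sc,
    # Variation 1: kappa_pc from R_pc; the tabulated base kappa_pc stands in
    # for the R_pc = 9.2e-3 scenario (see the methods vignette).
    var1_base = sc,
    var1_pizzo = set_kappa(sc, "pc", permeability_from_resistance(3.32e-4, mu_csf)),
    var1_high  = set_kappa(sc, "pc", permeability_from_resistance(32.24, mu_csf)),
    var2_high = { sc$R_DS_const <- 21.62; sc$R_crib_const <- 67; sc },
    var2_low  = { sc$R_DS_const <- 5.41;  sc$R_crib_const <- 67; sc },
    var3_constant = {
      sc <- set_omega(sc, "c", "pc", 0)
      sc$filtration <- list(mode = "constant", rate_ml_min = 0.16)
      sc
    },
    var4_case1 = set_omega(sc, "pc", "e", 5e-7),
    var4_case2 = {
      sc <- set_omega(sc, "pa", "e", 1.86e-6)
      sc <- set_omega(sc, "pv", "e", 1.65e-6)
      set_omega(sc, "pc", "e", 1e-8)
    },
    var4_case3 = {
      sc <- set_omega(sc, "pa", "e", 1e-10)
      set_omega(sc, "pc", "e", 1.86e-7)
    },
    var4_case4 = {
      sc <- set_omega(sc, "pa", "e", base$omega["pa", "e"] / 2)
      set_omega(sc, "pv", "e", base$omega["pv", "e"] / 2)
    },
    var5_high     = set_kappa(sc, "e", 200e-18),
    var5_veryhigh = set_kappa(sc, "e", 2000e-18)
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>", x$name, "\n")
  cat("  kappa (nm^2):",
      paste(sprintf("%s=%.3g", x$params$compartment, x$params$kappa * 1e18),
            collapse = " "), "\n")
  nz <- which(upper.tri(x$omega) & x$omega != 0, arr.ind = TRUE)
  cat("  omega (1/(Pa s)):",
      paste(sprintf("%s-%s=%.3g", rownames(x$omega)[nz[, 1]],
                    colnames(x$omega)[nz[, 2]], x$omega[nz]), collapse = " "), "\n")
  if (!is.null(x$R_DS_const)) cat("  R_DS const:", x$R_DS_const, "mmHg/(ml/min)\n")
  cat("  filtration:", x$filtration$mode,
      if (identical(x$filtration$mode, "constant"))
        paste0("(", x$filtration$rate_ml_min, " ml/min at ventricles)"), "\n")
  invisible(x)
}

# ---- flat key-value configuration files ------------------------------------

#' Write a scenario to a flat key-value configuration file
#'
#' The file format is YAML-style `key: value` lines. Permeabilities are stored
#' in nm^2, transfer coefficients in 1/(Pa*s) and resistances in
#' mmHg/(ml/min), matching the units of the literature tables.
#'
#' @param scenario A [base_scenario()]-style object.
#' @param path Output path.
#' @export
write_scenario_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario_config"))
  p <- scenario$params
  lines <- c(
    paste0("name: ", scenario$name),
    sprintf("kappa_%s_nm2: %.17g", p$compartment, p$kappa * 1e18),
    sprintf("mu_%s_Pa_s: %.17g", p$compartment, p$mu),
    sprintf("phi_%s: %.17g", p$compartment, p$phi),
    sprintf("C_%s_per_Pa: %.17g", p$compartment, p$C)
  )
  prs <- .transfer_pairs()
  lines <- c(lines, sprintf("omega_%s_%s: %.17g", prs[, 1], prs[, 2],
                            scenario$omega[prs]))
  if (!is.null(scenario$R_DS_const))
    lines <- c(lines, sprintf("R_DS_mmHg_ml_min: %.17g", scenario$R_DS_const))
  if (!is.null(scenario$R_crib_const))
    lines <- c(lines, sprintf("R_crib_mmHg_ml_min: %.17g", scenario$R_crib_const))
  lines <- c(lines,
             paste0("filtration_mode: ", scenario$filtration$mode),
             if (identical(scenario$filtration$mode, "constant"))
               sprintf("filtration_rate_ml_min: %.17g", scenario$filtration$rate_ml_min))
  writeLines(lines, path)
  invisible(path)
}

#' Read a scenario from a flat key-value configuration file
#'
#' Every key is validated against the compartment/pair legend; unknown keys
#' are an error, as are values violating the type invariants (positivity,
#' porosity < 1, symmetric connectivity).
#'
#' @param path Path written by [write_scenario_config()].
#' @export
read_scenario_config <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw)) & !startsWith(trimws(raw), "#")]
  kv <- regmatches(raw, regexec("^([A-Za-z0-9_]+):\\s*(.*)$", raw))
  if (any(lengths(kv) != 3L)) stop("malformed config line(s): ",
                                   paste(raw[lengths(kv) != 3L], collapse = "; "))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  if (anyDuplicated(keys)) stop("duplicate config keys: ",
                                paste(unique(keys[duplicated(keys)]), collapse = ", "))
  sc <- base_scenario()
  prs <- .transfer_pairs()
  known <- c("name", "filtration_mode", "filtration_rate_ml_min",
             "R_DS_mmHg_ml_min", "R_crib_mmHg_ml_min",
             paste0("kappa_", compartments(), "_nm2"),
             paste0("mu_", compartments(), "_Pa_s"),
             paste0("phi_", compartments()),
             paste0("C_", compartments(), "_per_Pa"),
             sprintf("omega_%s_%s", prs[, 1], prs[, 2]))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  num <- function(v) {
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) stop("non-numeric config value: ", v)
    x
  }
  for (k in seq_along(keys)) {
    key <- keys[k]; val <- vals[k]
    if (key == "name") {
      sc$name <- val
    } else if (key == "filtration_mode") {
      sc$filtration$mode <- match.arg(val, c("pressure", "constant"))
    } else if (key == "filtration_rate_ml_min") {
      sc$filtration$rate_ml_min <- num(val)
    } else if (key == "R_DS_mmHg_ml_min") {
      sc$R_DS_const <- num(val)
    } else if (key == "R_crib_mmHg_ml_min") {
      sc$R_crib_const <- num(val)
    } else if (grepl("^kappa_", key)) {
      comp <- sub("^kappa_([a-z]+)_nm2$", "\\1", key)
      sc$params$kappa[sc$params$compartment == comp] <- num(val) * 1e-18
    } else if (grepl("^mu_", key)) {
      comp <- sub("^mu_([a-z]+)_Pa_s$", "\\1", key)
      sc$params$mu[sc$params$compartment == comp] <- num(val)
    } else if (grepl("^phi_", key)) {
      comp <- sub("^phi_([a-z]+)$", "\\1", key)
      sc$params$phi[sc$params$compartment == comp] <- num(val)
    } else if (grepl("^C_", key)) {
      comp <- sub("^C_([a-z]+)_per_Pa$", "\\1", key)
      sc$params$C[sc$params$compartment == comp] <- num(val)
    } else if (grepl("^omega_", key)) {
      ij <- strsplit(sub("^omega_", "", key), "_")[[1]]
      sc$omega[ij[1], ij[2]] <- sc$omega[ij[2], ij[1]] <- num(val)
    }
  }
  validate_compartment_params(sc$params)
  validate_transfer_coefficients(sc$omega)
  if (identical(sc$filtration$mode, "constant") &&
      (is.null(sc$filtration$rate_ml_min) || sc$filtration$rate_ml_min <= 0)) {
    stop("constant filtration mode requires a positive filtration_rate_ml_min")
  }
  sc
}
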