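# Material parameters of the seven-network porous-medium brain model and the
# derivation formulas tying them to lumped (0D) resistances and flows.
#
# Compartments: arterial (a), capillary (c), venous (v) blood; their perivascular
# spaces (pa, pc, pv); extracellular space (e).

#' The seven compartment labels
#'
#' @return Character vector `c("a","c","v","pa","pc","pv","e")`.
#' @export
compartments <- function() c("a", "c", "v", "pa", "pc", "pv", "e")

#' Blood and CSF/ISF compartment subsets
#' @rdname compartments
#' @export
blood_compartments <- function() c("a", "c", "v")

#' @rdname compartments
#' @export
csf_compartments <- function() c("pa", "pc", "pv", "e")

# viscosities: water at 37 C for CSF/ISF; blood modelled as 3x that
MU_CSF <- 0.75e-3   # Pa*s
MU_BLOOD <- 3 * MU_CSF

#' Default compartmental material parameters
#'
#' Permeability `kappa` (m^2), dynamic viscosity `mu` (Pa*s), porosity `phi`
#' (dimensionless) and compliance `C` (1/Pa) for each of the seven networks.
#' Blood viscosity is three times the CSF/ISF viscosity (0.75 mPa*s, water at
#' 37 C). Large vessels (a, v) have compliance 1e-4 /Pa, all other networks
#' 1e-8 /Pa.
#'
#' @return A data.frame with one row per compartment and attributes in SI units.
#' @export
default_compartment_params <- function() {
  kappa_nm2 <- c(a = 3.63e4, c = 1.44e3, v = 1.13e6,
                 pa = 30, pc = 1.44e3, pv = 1.95e4, e = 20)
  phi <- c(a = 1.09e-2, c = 2.31e-3, v = 1.98e-2,
           pa = 1.52e-2, pc = 2.31e-3, pv = 2.77e-2, e = 1.40e-1)
  comp <- compartments()
  mu <- ifelse(comp %in% blood_compartments(), MU_BLOOD, MU_CSF)
  C <- ifelse(comp %in% c("a", "v"), 1e-4, 1e-8)
  out <- data.frame(
    compartment = comp,
    kappa = unname(kappa_nm2[comp]) * 1e-18,  # m^2
    mu = mu,                                   # Pa*s
    phi = unname(phi[comp]),
    C = C,
    stringsAsFactors = FALSE
  )
  validate_compartment_params(out)
  out
}

validate_compartment_params <- function(p) {
  stopifnot(is.data.frame(p),
            identical(p$compartment, compartments()),
            all(p$kappa > 0), all(p$mu > 0), all(p$C > 0),
            all(p$phi > 0), all(p$phi < 1))
  invisible(p)
}

# connectivity of the network graph: which pairs exchange fluid
.transfer_pairs <- function() {
  rbind(
    c("a", "c"), c("c", "v"), c("c", "pc"),
    c("pa", "pc"), c("pc", "pv"),
    c("pa", "e"), c("pv", "e"), c("pc", "e")
  )
}

#' Default intercompartmental transfer coefficients
#'
#' Symmetric 7x7 matrix of transfer coefficients `omega_{i,j}` (1/(Pa*s)),
#' nonzero exactly on the connected pairs a-c, c-v, c-pc, pa-pc, pc-pv, pa-e,
#' pv-e and pc-e. The blood coefficients correspond to a canonical brain of
#' 1000 ml with arterial inflow 700 ml/min and fixed pressure drops of 60 mmHg
#' (a to c) and 10 mmHg (c to v); [blood_transfer_coefficients()] recomputes
#' them for other subjects/domains.
#'
#' @return Numeric matrix with dimnames equal to [compartments()].
#' @export
default_transfer_coefficients <- function() {
  comp <- compartments()
  om <- matrix(0, 7, 7, dimnames = list(comp, comp))
  vals <- c("a.c" = 1.45e-6, "c.v" = 8.75e-6, "c.pc" = 8.48e-10,
            "pa.pc" = 1e-6, "pc.pv" = 1e-6,
            "pa.e" = 1.86e-7, "pv.e" = 1.65e-7, "pc.e" = 1e-10)
  prs <- .transfer_pairs()
  for (k in seq_len(nrow(prs))) {
    i <- prs[k, 1]; j <- prs[k, 2]
    om[i, j] <- om[j, i] <- vals[[paste(i, j, sep = ".")]]
  }
  om
}

validate_transfer_coefficients <- function(om) {
  comp <- compartments()
  stopifnot(is.matrix(om), identical(dimnames(om), list(comp, comp)),
            isTRUE(all.equal(om, t(om))), all(om >= 0))
  allowed <- matrix(FALSE, 7, 7, dimnames = list(comp, comp))
  prs <- .transfer_pairs()
  for (k in seq_len(nrow(prs))) {
    allowed[prs[k, 1], prs[k, 2]] <- allowed[prs[k, 2], prs[k, 1]] <- TRUE
  }
  if (any(om[!allowed] != 0)) stop("transfer coefficients outside the network connectivity")
  invisible(om)
}

#' Subject boundary data for an infusion simulation
#'
#' Arterial inflow `B_in` (ml/min), CSF outflow resistance `R_out`
#' (mmHg/(ml/min)) and reference pressure `p_ref` (mmHg). Defaults are the
#' control-cohort means; `cohort = "inph"` gives the iNPH-cohort means.
#'
#' @param cohort `"control"` or `"inph"`, or `NULL` when giving values directly.
#' @param B_in,R_out,p_ref Optional overrides.
#' @export
subject_boundary_data <- function(cohort = "control",
                                  B_in = NULL, R_out = NULL, p_ref = NULL) {
  base <- switch(match.arg(cohort, c("control", "inph")),
    control = list(B_in = 712.5, R_out = 10.03, p_ref = 8.92),
    inph    = list(B_in = 653.4, R_out = 18.06, p_ref = 9.26)
  )
  if (!is.null(B_in)) base$B_in <- B_in
  if (!is.null(R_out)) base$R_out <- R_out
  if (!is.null(p_ref)) base$p_ref <- p_ref
  stopifnot(base$B_in > 0, base$R_out > 0, base$p_ref > 0)
  structure(base, class = "subject_boundary_data")
}

#' Tracer transport constants for Peclet numbers
#'
#' @param D Tracer diffusivity (m^2/s); default is gadobutrol, 1.3e-10.
#' @param L Transport length scale (m); default 0.1 (approximate brain length).
#' @export
transport_constants <- function(D = 1.3e-10, L = 0.1) {
  stopifnot(D > 0, L > 0)
  list(D = D, L = L)
}

#' Transfer coefficient from a lumped flow resistance
#'
#' Volume-averaging the exchange term relates the 3D transfer coefficient to a
#' lumped resistance by `omega = 1/(V * R)`.
#'
#' @param R Resistance in mmHg/(ml/min).
#' @param V_domain Domain volume in m^3.
#' @return omega in 1/(Pa*s).
#' @export
omega_from_resistance <- function(R, V_domain) {
  stopifnot(R > 0, V_domain > 0)
  1 / (V_domain * rclin_to_si(R))
}

#' Blood-network transfer coefficients from arterial inflow
#'
#' The arterial-capillary and capillary-venous coefficients are fixed by
#' requiring the exchange to carry the full arterial inflow `B_in` at the
#' assumed mean pressure drops: `omega = B_in / (dp * V)`.
#'
#' @param B_in Arterial inflow (ml/min).
#' @param dp_ac Mean arterial-to-capillary pressure drop (mmHg), default 60.
#' @param dp_cv Mean capillary-to-venous pressure drop (mmHg), default 10.
#' @param V_domain Domain volume (m^3).
#' @return Named vector `c(omega_ac=, omega_cv=)` in 1/(Pa*s).
#' @export
blood_transfer_coefficients <- function(B_in, dp_ac = 60, dp_cv = 10, V_domain) {
  stopifnot(B_in > 0, V_domain > 0)
  if (dp_ac <= 0 || dp_cv <= 0) stop("pressure drops must be positive")
  B <- mlmin_to_m3s(B_in)
  c(omega_ac = B / (mmhg_to_pa(dp_ac) * V_domain),
    omega_cv = B / (mmhg_to_pa(dp_cv) * V_domain))
}

#' Length-over-area constant relating resistance and permeability
#'
#' For a homogeneous porous channel, `R * kappa / mu = L/A` is a geometric
#' constant shared by all compartments.
#'
#' @param R Compartment resistance (mmHg/(ml/min)).
#' @param kappa Permeability (m^2).
#' @param mu Viscosity (Pa*s).
#' @return L/A in 1/m.
#' @export
length_area_constant <- function(R, kappa, mu) {
  stopifnot(R > 0, kappa > 0, mu > 0)
  rclin_to_si(R) * kappa / mu
}

#' Permeability from a lumped compartment resistance
#'
#' Inverts [length_area_constant()]: `kappa = mu * (L/A) / R`.
#'
#' @param R Resistance (mmHg/(ml/min)).
#' @param mu Viscosity (Pa*s).
#' @param L_over_A Geometric constant (1/m), default 1.21e-4 as implied by the
#'   extracellular network (kappa_e = 20 nm^2, mu = 0.75 mPa*s).
#' @return kappa in m^2.
#' @export
permeability_from_resistance <- function(R, mu, L_over_A = 1.21e-4) {
  stopifnot(R > 0, mu > 0, L_over_A > 0)
  mu * L_over_A / rclin_to_si(R)
}

#' Peclet number of a superficial speed
#'
#' `Pe = speed * L / D` with the tracer constants of [transport_constants()].
#'
#' @param speed Superficial speed in m/s (>= 0).
#' @param constants See [transport_constants()].
#' @export
peclet_number <- function(speed, constants = transport_constants()) {
  stopifnot(all(speed >= 0))
  speed * constants$L / constants$D
}
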