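# Coupled 0D/3D solver for the seven-network parabolic pressure system.
#
# Each backward-Euler step solves the monolithic symmetric positive-definite
# block system over all seven pressure fields (constant compartment
# compliances make the step linear); the lumped subarachnoid pressure is
# advanced first with the perivascular exchange Q_pvs lagged one step, then
# enters the PDE boundary data at the new time level.
#
# Boundary conditions (outward normal n, flux (kappa/mu) grad p . n = influx):
#   arterial      pial        influx  Q_in = B_in / A_pial
#   capillary     ventricular efflux  Q_prod (uniform density)
#   venous        pial        Robin  beta1 ((p_DS + p_CSF)/2 - p_v)
#   arterial PVS  pial        Robin  beta2 (p_CSF - p_pa)
#   venous PVS    pial        Robin  beta3 ((p_CSF + p_DS)/2 - p_pv)
#   pericapillary ventricular influx 0.16 ml/min (constant-filtration mode)
#   all fields    stem cut    no flux; e (and pc otherwise) no flux everywhere

#' Boundary condition set for the MPET solver
#'
#' The Robin coefficients carry the tabulated values of the source model.
#' Their unit here is mm/(s*mmHg): the tables print m/(s*mmHg), but with that
#' reading the venous-PVS pial drain is three orders of magnitude too strong
#' and no reported pressure or flow regime is reproducible, whereas the
#' mm-reading (a metre/millimetre slip consistent with mm-scaled imaging
#' meshes) reproduces the resting and plateau pressures and all flow
#' magnitudes simultaneously. See the methods vignette for the full
#' conductance analysis.
#'
#' @param beta1,beta2,beta3 Robin coefficients (mm/(s*mmHg)) for the venous,
#'   arterial-PVS and venous-PVS pial exchange.
#' @param Q_prod Capillary secretion through the ventricular wall (ml/min).
#' @param p_DS Dural sinus pressure (mmHg).
#' @export
mpet_bcs <- function(beta1 = 1.33e-1, beta2 = 1.33e-1, beta3 = 1.33e-5,
                     Q_prod = 0.33, p_DS = 8.4) {
  stopifnot(beta1 >= 0, beta2 >= 0, beta3 >= 0, Q_prod >= 0)
  structure(list(beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 Q_prod = Q_prod, p_DS = p_DS), class = "mpet_bcs")
}

#' Solver configuration
#'
#' @param dt Time step (s).
#' @param degree Element polynomial degree; only linear (1) elements are
#'   implemented (see the methods vignette for the accompanying mesh/time
#'   convergence checks).
#' @param rtol Relative tolerance reported against the direct-solver residual.
#' @export
solver_config <- function(dt = 20, degree = 1L, rtol = 1e-10) {
  stopifnot(dt > 0)
  if (!identical(as.integer(degree), 1L)) {
    stop("only degree-1 (linear) elements are implemented")
  }
  structure(list(dt = dt, degree = 1L, rtol = rtol), class = "solver_config")
}

#' Assemble the time-invariant monolithic MPET system
#'
#' Builds mass, stiffness, exchange and Robin blocks for all seven fields and
#' factorizes the backward-Euler system matrix (supernodal Cholesky). The
#' factor is reused for every time step.
#'
#' @param mesh A `brain_mesh`.
#' @param scenario A `scenario_config`.
#' @param bcs [mpet_bcs()].
#' @param B_in Arterial inflow (ml/min) distributed over the pial surface.
#' @param dt Time step (s).
#' @param omega Optional transfer-coefficient matrix overriding the
#'   scenario's (used to inject subject-calibrated blood coefficients).
#' @return An `mpet_system` used by [advance()] and the post-processing
#'   helpers.
#' @export
assemble_mpet_system <- function(mesh, scenario, bcs = mpet_bcs(),
                                 B_in = 712.5, dt = 20, omega = NULL) {
  stopifnot(inherits(mesh, "brain_mesh"), inherits(scenario, "scenario_config"))
  comp <- compartments()
  nC <- length(comp)
  n <- nrow(mesh$vertices)
  geom <- tet_geometry(mesh$vertices, mesh$cells)
  if (any(geom$vol <= 0)) stop("mesh has non-positive cell volumes")
  M <- assemble_mass(mesh$vertices, mesh$cells, geom)
  K <- assemble_stiffness(mesh$vertices, mesh$cells, geom)
  leg <- mesh$legend
  pial <- mesh$facets[mesh$facet_label == leg$boundary[["pial"]], , drop = FALSE]
  vent <- mesh$facets[mesh$facet_label == leg$boundary[["ventricular"]], , drop = FALSE]
  S_pial <- assemble_surface_mass(mesh$vertices, pial)
  s_pial <- as.numeric(S_pial %*% rep(1, n))
  S_vent <- assemble_surface_mass(mesh$vertices, vent)
  s_vent <- as.numeric(S_vent %*% rep(1, n))
  A_pial <- sum(s_pial)
  A_vent <- sum(s_vent)
  V_domain <- sum(geom$vol)
  w_node <- as.numeric(M %*% rep(1, n))   # nodal integration weights

  if (is.null(omega)) omega <- scenario$omega
  p <- scenario$params
  mmhg <- unit_constants[["pa_per_mmhg"]]
  # betas are mm/(s*mmHg) -> m/(s*Pa); see mpet_bcs() for the unit rationale
  beta_si <- c(v = bcs$beta1, pa = bcs$beta2, pv = bcs$beta3) * 1e-3 / mmhg
  robin <- list(v = beta_si[["v"]] * S_pial,
                pa = beta_si[["pa"]] * S_pial,
                pv = beta_si[["pv"]] * S_pial)

  # block triplets
  Mt <- methods::as(M, "TsparseMatrix")
  Kt <- methods::as(K, "TsparseMatrix")
  ii <- list(); jj <- list(); xx <- list()
  add <- function(bi, bj, Ts, scale) {
    if (scale == 0) return(invisible())
    ii[[length(ii) + 1L]] <<- Ts@i + 1L + (bi - 1L) * n
    jj[[length(jj) + 1L]] <<- Ts@j + 1L + (bj - 1L) * n
    xx[[length(xx) + 1L]] <<- Ts@x * scale
  }
  for (i in seq_len(nC)) {
    ci <- comp[i]
    add(i, i, Mt, p$C[i] / dt + sum(omega[ci, ]))
    add(i, i, Kt, p$kappa[i] / p$mu[i])
    if (ci %in% names(robin)) {
      Rt <- methods::as(robin[[ci]], "TsparseMatrix")
      add(i, i, Rt, 1)
    }
    for (j in seq_len(nC)) {
      if (j != i && omega[ci, comp[j]] > 0) add(i, j, Mt, -omega[ci, comp[j]])
    }
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nC * n, nC * n))
  chol <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, super = TRUE)

  grads <- gradient_operators(mesh$vertices, mesh$cells, geom)
  structure(list(
    mesh = mesh, scenario = scenario, bcs = bcs, omega = omega,
    dt = dt, n = n, comp = comp, params = p,
    M = M, A = A, chol = chol, beta_si = beta_si,
    s_pial = s_pial, s_vent = s_vent, A_pial = A_pial, A_vent = A_vent,
    V_domain = V_domain, w_node = w_node, vol = geom$vol,
    grads = grads,
    B_in = B_in,
    Q_in_si = mlmin_to_m3s(B_in) / A_pial,
    Q_prod_si = mlmin_to_m3s(bcs$Q_prod),
    Q_filt_si = if (identical(scenario$filtration$mode, "constant"))
      mlmin_to_m3s(scenario$filtration$rate_ml_min) else 0
  ), class = "mpet_system")
}

# Robin exterior target pressures (Pa) given the lumped pressure (Pa)
.robin_targets <- function(sys, p_csf_pa) {
  p_ds_pa <- mmhg_to_pa(sys$bcs$p_DS)
  c(v = (p_ds_pa + p_csf_pa) / 2,
    pa = p_csf_pa,
    pv = (p_csf_pa + p_ds_pa) / 2)
}

# load vector (length 7n) at lumped pressure p_csf (Pa)
.mpet_loads <- function(sys, p_csf_pa) {
  n <- sys$n
  b <- numeric(length(sys$comp) * n)
  tg <- .robin_targets(sys, p_csf_pa)
  for (i in seq_along(sys$comp)) {
    ci <- sys$comp[i]
    idx <- (i - 1L) * n + seq_len(n)
    if (ci == "a") b[idx] <- b[idx] + sys$Q_in_si * sys$s_pial
    if (ci == "c" && sys$A_vent > 0)
      b[idx] <- b[idx] - (sys$Q_prod_si / sys$A_vent) * sys$s_vent
    if (ci == "pc" && sys$Q_filt_si > 0 && sys$A_vent > 0)
      b[idx] <- b[idx] + (sys$Q_filt_si / sys$A_vent) * sys$s_vent
    if (ci %in% names(tg) && sys$beta_si[[ci]] > 0)
      b[idx] <- b[idx] + sys$beta_si[[ci]] * tg[[ci]] * sys$s_pial
  }
  b
}

#' Advance the seven pressure fields by one backward-Euler step
#'
#' @param fields Matrix (nodes x 7) of pressures (Pa), columns in
#'   [compartments()] order.
#' @param sys An assembled `mpet_system`.
#' @param p_csf_pa Subarachnoid pressure at the new time level (Pa).
#' @return Updated fields matrix.
#' @export
advance <- function(fields, sys, p_csf_pa) {
  stopifnot(inherits(sys, "mpet_system"),
            nrow(fields) == sys$n, ncol(fields) == length(sys$comp))
  b <- .mpet_loads(sys, p_csf_pa)
  n <- sys$n
  for (i in seq_along(sys$comp)) {
    idx <- (i - 1L) * n + seq_len(n)
    b[idx] <- b[idx] + (sys$params$C[i] / sys$dt) *
      as.numeric(sys$M %*% fields[, i])
  }
  x <- as.numeric(Matrix::solve(sys$chol, b))
  matrix(x, n, length(sys$comp), dimnames = list(NULL, sys$comp))
}

#' Net SAS-to-brain perivascular exchange Q_pvs
#'
#' The pial surface integral `-int beta2 (p_CSF - p_pa) dS` in ml/min: the
#' (negative of the) net flow from the subarachnoid space into the arterial
#' perivascular network, passed as a source into the lumped balance.
#'
#' @inheritParams advance
#' @export
compute_Q_pvs <- function(fields, sys, p_csf_pa) {
  influx_si <- sys$beta_si[["pa"]] *
    (p_csf_pa * sys$A_pial - sum(sys$s_pial * fields[, "pa"]))
  -m3s_to_mlmin(influx_si)
}

# per-compartment boundary influx (ml/min) at the current state
.boundary_influx <- function(fields, sys, p_csf_pa) {
  tg <- .robin_targets(sys, p_csf_pa)
  out <- c(a = sys$B_in, c = -sys$bcs$Q_prod, v = 0, pa = 0, pc = 0, pv = 0, e = 0)
  if (sys$Q_filt_si > 0) out[["pc"]] <- m3s_to_mlmin(sys$Q_filt_si)
  for (ci in names(tg)) {
    out[[ci]] <- m3s_to_mlmin(sys$beta_si[[ci]] *
      (tg[[ci]] * sys$A_pial - sum(sys$s_pial * fields[, ci])))
  }
  out[compartments()]
}

# relative discrete mass-balance residual of one accepted step
mass_balance_residual <- function(sys, fields_old, fields_new, p_csf_pa) {
  storage <- 0
  for (i in seq_along(sys$comp)) {
    storage <- storage + (sys$params$C[i] / sys$dt) *
      sum(sys$w_node * (fields_new[, i] - fields_old[, i]))
  }
  influx <- sum(mlmin_to_m3s(.boundary_influx(fields_new, sys, p_csf_pa)))
  scale <- max(abs(storage), abs(influx), mlmin_to_m3s(1e-3))
  abs(storage - influx) / scale
}

#' Superficial velocity field of one compartment
#'
#' Cellwise `-(kappa / (mu phi)) grad p` (m/s), the porosity-scaled Darcy
#' velocity reported by the model.
#'
#' @param p_field Nodal pressures (Pa).
#' @param sys Assembled `mpet_system` (or pass `mesh` plus `scenario`).
#' @param compartment One of [compartments()].
#' @export
superficial_velocity <- function(p_field, sys, compartment) {
  stopifnot(inherits(sys, "mpet_system"))
  i <- match(compartment, sys$comp)
  coef <- -sys$params$kappa[i] / (sys$params$mu[i] * sys$params$phi[i])
  cbind(coef * as.numeric(sys$grads$Gx %*% p_field),
        coef * as.numeric(sys$grads$Gy %*% p_field),
        coef * as.numeric(sys$grads$Gz %*% p_field))
}

# volume-averaged |v| (m/s) for all compartments at once
.mean_speeds <- function(fields, sys) {
  vapply(seq_along(sys$comp), function(i) {
    v <- superficial_velocity(fields[, i], sys, sys$comp[i])
    sum(sys$vol * sqrt(rowSums(v^2))) / sys$V_domain
  }, numeric(1))
}

#' Run a full three-stage infusion simulation
#'
#' Calibrates the resistance scale alpha from the subject's measured R_out
#' (via the 0D procedure with base outflow constants), assembles the coupled
#' system, equilibrates without infusion, infuses at the protocol rate and
#' recovers. Blood transfer coefficients are recomputed from the subject's
#' arterial inflow and the mesh volume.
#'
#' @param mesh A `brain_mesh`.
#' @param scenario A `scenario_config` or scenario name.
#' @param subject [subject_boundary_data()].
#' @param protocol [infusion_protocol()].
#' @param config [solver_config()].
#' @param bcs [mpet_bcs()].
#' @param snapshot_times Absolute times (s) at which full fields are stored;
#'   defaults to one minute before infusion, end of infusion, and the final
#'   time.
#' @return An `mpet_result` with volume-averaged pressure/speed series,
#'   intercompartmental transfer and boundary-flux series, the lumped
#'   pressure and Q_pvs series, stored snapshots, and run metadata.
#' @export
run_infusion_simulation <- function(mesh,
                                    scenario = "base",
                                    subject = subject_boundary_data(),
                                    protocol = infusion_protocol(),
                                    config = solver_config(),
                                    bcs = mpet_bcs(),
                                    snapshot_times = NULL) {
  if (is.character(scenario)) scenario <- build_scenario(scenario)
  stopifnot(inherits(scenario, "scenario_config"))

  cal <- calibrate_alpha(subject$R_out)
  params <- lumped_params(
    p_ref = subject$p_ref,
    R_DS = if (is.null(scenario$R_DS_const)) 10.81 else scenario$R_DS_const,
    R_crib = if (is.null(scenario$R_crib_const)) 67 else scenario$R_crib_const,
    alpha = cal$alpha
  )

  # subject/domain-specific blood transfer coefficients
  mesh_V <- sum(abs(tet_geometry(mesh$vertices, mesh$cells)$vol))
  bt <- blood_transfer_coefficients(subject$B_in, V_domain = mesh_V)
  omega <- scenario$omega
  omega["a", "c"] <- omega["c", "a"] <- bt[["omega_ac"]]
  omega["c", "v"] <- omega["v", "c"] <- bt[["omega_cv"]]

  sys <- assemble_mpet_system(mesh, scenario, bcs, B_in = subject$B_in,
                              dt = config$dt, omega = omega)

  times <- seq(0, protocol$t_pre + protocol$t_inf + protocol$t_post,
               by = config$dt)
  nt <- length(times)
  if (is.null(snapshot_times)) {
    snapshot_times <- c(protocol$t_pre - 60, protocol$t_pre + protocol$t_inf,
                        times[nt])
  }
  snap_idx <- vapply(snapshot_times, function(tt) which.min(abs(times - tt)),
                     integer(1))

  p_csf <- numeric(nt)
  q_pvs <- numeric(nt)
  p_csf[1] <- steady_state_plateau(params$alpha, params$Q_prod, params)
  fields <- matrix(mmhg_to_pa(p_csf[1]), sys$n, length(sys$comp),
                   dimnames = list(NULL, sys$comp))

  nC <- length(sys$comp)
  pbar <- matrix(NA_real_, nt, nC, dimnames = list(NULL, sys$comp))
  speed <- matrix(NA_real_, nt, nC, dimnames = list(NULL, sys$comp))
  prs <- .transfer_pairs()
  pair_names <- paste(prs[, 1], prs[, 2], sep = "_")
  transfers <- matrix(NA_real_, nt, nrow(prs), dimnames = list(NULL, pair_names))
  boundary <- matrix(NA_real_, nt, nC, dimnames = list(NULL, sys$comp))
  snapshots <- vector("list", length(snap_idx))
  names(snapshots) <- sprintf("t%.0f", times[snap_idx])

  record <- function(k) {
    pbar[k, ] <<- pa_to_mmhg(colSums(sys$w_node * fields) / sys$V_domain)
    speed[k, ] <<- .mean_speeds(fields, sys) * 1e9   # nm/s
    dd <- fields[, prs[, 2], drop = FALSE] - fields[, prs[, 1], drop = FALSE]
    transfers[k, ] <<- m3s_to_mlmin(sys$omega[prs] *
                                    colSums(sys$w_node * dd))
    boundary[k, ] <<- .boundary_influx(fields, sys, mmhg_to_pa(p_csf[k]))
    if (k %in% snap_idx) {
      snapshots[[match(k, snap_idx)]] <<- fields
    }
  }
  record(1L)

  for (k in 2:nt) {
    p_csf[k] <- step_sas_pressure(p_csf[k - 1], q_pvs[k - 1],
                                  infusion_rate(times[k], protocol),
                                  config$dt, params)
    fields <- advance(fields, sys, mmhg_to_pa(p_csf[k]))
    q_pvs[k] <- compute_Q_pvs(fields, sys, mmhg_to_pa(p_csf[k]))
    record(k)
  }

  # drop the factorization and system matrix (hundreds of MB) from the
  # returned object; post-processing only needs the light members
  sys$chol <- NULL
  sys$A <- NULL
  structure(list(
    time_s = times,
    time_rel_s = times - protocol$t_pre,
    p_csf = p_csf,
    q_pvs = q_pvs,
    pbar = pbar,
    speed = speed,
    transfers = transfers,
    boundary = boundary,
    snapshots = snapshots,
    snapshot_times = times[snap_idx],
    protocol = protocol,
    scenario_name = scenario$name,
    subject = subject,
    alpha = params$alpha,
    calibration = cal[c("slope", "intercept", "r_squared")],
    sys = sys
  ), class = "mpet_result")
}

#' @export
print.mpet_result <- function(x, ...) {
  nt <- length(x$time_s)
  k_end <- which.min(abs(x$time_s - (x$protocol$t_pre + x$protocol$t_inf)))
  cat("<mpet_result>", x$scenario_name, "-", nt, "steps\n")
  cat(sprintf("  p_CSF: baseline %.2f -> plateau %.2f mmHg (alpha = %.3f)\n",
              x$p_csf[1], x$p_csf[k_end], x$alpha))
  cat(sprintf("  p_e:   baseline %.2f -> plateau %.2f mmHg\n",
              x$pbar[1, "e"], x$pbar[k_end, "e"]))
  invisible(x)
}
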