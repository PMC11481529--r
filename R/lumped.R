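# Lumped (0D) subarachnoid CSF pressure model with nonlinear elastance-type
# compliance, the infusion protocol, Davson-form outflow resistance, and the
# calibration mapping measured R_out to the resistance scale alpha.
#
# The pressure balance is
#   C(p) dp/dt = Q_prod + Q_inf(t) + Q_pvs(t)
#                - (p - p_DS)/R_DS - (p - p_crib)/R_crib
# with R_DS = R_DS_const * alpha, R_crib = R_crib_const * alpha, and the
# piecewise compliance C(p) = 1/(E (p_lim - p_ref)) below the threshold
# p_lim and 1/(E (p - p_ref)) above it. Units: mmHg, ml/min; time kept in
# seconds at the interface.

#' Parameters of the lumped subarachnoid CSF model
#'
#' @param E Elastance (1/ml).
#' @param p_ref Reference pressure (mmHg).
#' @param p_lim Threshold pressure (mmHg) below which compliance is constant.
#' @param p_DS,R_DS Dural-sinus pressure (mmHg) and outflow resistance
#'   constant (mmHg/(ml/min)) before the alpha scaling.
#' @param p_crib,R_crib Cribriform-plate pressure and resistance constant.
#' @param Q_prod CSF production rate (ml/min).
#' @param alpha Outflow-resistance scale factor multiplying both R_DS and
#'   R_crib.
#' @export
lumped_params <- function(E = 0.2, p_ref = 9, p_lim = 13,
                          p_DS = 8.4, R_DS = 10.81,
                          p_crib = 0, R_crib = 67,
                          Q_prod = 0.33, alpha = 1) {
  stopifnot(E > 0, R_DS > 0, R_crib > 0, alpha > 0, Q_prod >= 0)
  structure(list(E = E, p_ref = p_ref, p_lim = p_lim, p_DS = p_DS,
                 R_DS = R_DS, p_crib = p_crib, R_crib = R_crib,
                 Q_prod = Q_prod, alpha = alpha),
            class = "lumped_params")
}

#' Infusion test protocol
#'
#' Three stages: pre-infusion equilibration, constant-rate infusion, and
#' post-infusion recovery. Defaults: 1000 s / 2000 s / 1200 s (16:40 pre,
#' 33:20 infusion ending at absolute t = 50 min, 20 min recovery) at
#' Q_inf = 1.5 ml/min with a 20 s step.
#'
#' @param t_pre,t_inf,t_post Stage durations (s).
#' @param Q_inf Infusion rate (ml/min).
#' @param dt Time step (s).
#' @export
infusion_protocol <- function(t_pre = 1000, t_inf = 2000, t_post = 1200,
                              Q_inf = 1.5, dt = 20) {
  stopifnot(t_pre > 0, t_inf > 0, t_post > 0, dt > 0, Q_inf >= 0)
  structure(list(t_pre = t_pre, t_inf = t_inf, t_post = t_post,
                 Q_inf = Q_inf, dt = dt),
            class = "infusion_protocol")
}

# infusion rate at absolute time t (backward-Euler evaluation at step end)
infusion_rate <- function(t, protocol) {
  ifelse(t > protocol$t_pre & t <= protocol$t_pre + protocol$t_inf,
         protocol$Q_inf, 0)
}

#' Subarachnoid compliance (ml/mmHg)
#'
#' Piecewise compliance with the singular-point floor rule: if the threshold
#' does not exceed the reference pressure, the effective reference is lowered
#' to `p_lim - 1`; in the supra-threshold branch a pressure at or below the
#' reference uses `p - 1` (giving C = 1/E).
#'
#' @param p CSF pressure (mmHg), vectorized.
#' @param params [lumped_params()].
#' @export
compliance_sas <- function(p, params = lumped_params()) {
  E <- params$E; p_lim <- params$p_lim; p_ref <- params$p_ref
  ref_lo <- if (p_lim <= p_ref) p_lim - 1 else p_ref
  ref_hi <- ifelse(p <= p_ref, p - 1, p_ref)
  ifelse(p < p_lim, 1 / (E * (p_lim - ref_lo)), 1 / (E * (p - ref_hi)))
}

# net source into the SAS (ml/min) at pressure p
.sas_rhs_terms <- function(params) {
  list(R_DS = params$R_DS * params$alpha,
       R_crib = params$R_crib * params$alpha)
}

#' One backward-Euler step of the SAS pressure
#'
#' Solves the implicit step with the compliance lagged through fixed-point
#' iteration (tolerance 1e-9 mmHg, at most 100 iterations).
#'
#' @param p Current pressure (mmHg).
#' @param Q_pvs Net perivascular exchange source (ml/min; negative while the
#'   SAS loses fluid to the brain).
#' @param Q_inf Infusion rate over the step (ml/min).
#' @param dt Step length (s).
#' @param params [lumped_params()].
#' @export
step_sas_pressure <- function(p, Q_pvs, Q_inf, dt, params = lumped_params()) {
  stopifnot(dt > 0)
  R <- .sas_rhs_terms(params)
  gsum <- 1 / R$R_DS + 1 / R$R_crib
  src <- params$Q_prod + Q_inf + Q_pvs +
    params$p_DS / R$R_DS + params$p_crib / R$R_crib
  dtm <- dt / 60  # minutes, matching ml/min
  p_new <- p
  for (it in seq_len(100L)) {
    Ck <- compliance_sas(p_new, params)
    # (C/dt)(p_new - p) = src - gsum * p_new
    p_next <- (Ck / dtm * p + src) / (Ck / dtm + gsum)
    if (abs(p_next - p_new) < 1e-9) return(p_next)
    p_new <- p_next
  }
  stop("compliance fixed-point iteration did not converge in 100 iterations")
}

#' Analytic steady state of the SAS balance
#'
#' Closed form of the resting/plateau pressure for a constant total source
#' `Q_total` (ml/min): `p* = R_par * (Q_total * alpha + p_DS/R_DS + p_crib/R_crib)`
#' where `R_par` is the parallel combination of the unscaled resistances.
#'
#' @param alpha Resistance scale.
#' @param Q_total Constant source (ml/min), e.g. `Q_prod` or `Q_prod + Q_inf`.
#' @param params [lumped_params()] (its `alpha` is ignored in favour of the
#'   argument).
#' @export
steady_state_plateau <- function(alpha, Q_total, params = lumped_params()) {
  stopifnot(alpha > 0)
  R_par <- 1 / (1 / params$R_DS + 1 / params$R_crib)
  R_par * (Q_total * alpha + params$p_DS / params$R_DS +
           params$p_crib / params$R_crib)
}

#' Simulate the 0D infusion test
#'
#' Integrates the SAS balance over the three protocol stages with backward
#' Euler. The initial pressure is the analytic resting steady state. `Q_pvs`
#' is zero unless a sampled series (one value per grid point) is supplied.
#'
#' @param protocol [infusion_protocol()].
#' @param params [lumped_params()].
#' @param Q_pvs_series Optional numeric series on the protocol grid (ml/min).
#' @param relative_time If `TRUE`, the returned time column is relative to
#'   infusion start (infusion spans 0..t_inf); default is absolute simulation
#'   time (infusion spans t_pre..t_pre+t_inf).
#' @return A `pressure_trace` data.frame with `time_s`, `p_csf_mmHg`,
#'   `q_pvs_ml_min`.
#' @export
simulate_0d <- function(protocol = infusion_protocol(),
                        params = lumped_params(),
                        Q_pvs_series = NULL,
                        relative_time = FALSE) {
  stopifnot(inherits(protocol, "infusion_protocol"))
  times <- seq(0, protocol$t_pre + protocol$t_inf + protocol$t_post,
               by = protocol$dt)
  nt <- length(times)
  qpvs <- if (is.null(Q_pvs_series)) numeric(nt) else {
    stopifnot(length(Q_pvs_series) == nt)
    Q_pvs_series
  }
  p <- numeric(nt)
  p[1] <- steady_state_plateau(params$alpha, params$Q_prod + qpvs[1], params)
  for (k in 2:nt) {
    p[k] <- step_sas_pressure(p[k - 1], qpvs[k],
                              infusion_rate(times[k], protocol),
                              protocol$dt, params)
  }
  out <- data.frame(time_s = if (relative_time) times - protocol$t_pre else times,
                    p_csf_mmHg = p, q_pvs_ml_min = qpvs)
  attr(out, "protocol") <- protocol
  class(out) <- c("pressure_trace", "data.frame")
  out
}

#' Outflow resistance from a pressure trace (Davson form)
#'
#' `R_out = (p at end of infusion - p_ref) / Q_inf`.
#'
#' @param trace A [simulate_0d()] trace (absolute time).
#' @param protocol The protocol used.
#' @param p_ref Reference pressure (mmHg).
#' @export
rout_from_trace <- function(trace, protocol = attr(trace, "protocol"),
                            p_ref = 9) {
  if (protocol$Q_inf <= 0) stop("R_out is undefined without infusion (Q_inf = 0)")
  t_end <- protocol$t_pre + protocol$t_inf
  if (max(trace$time_s) < t_end) stop("trace does not cover the end of infusion")
  p_end <- trace$p_csf_mmHg[which.min(abs(trace$time_s - t_end))]
  (p_end - p_ref) / protocol$Q_inf
}

#' Calibrate the resistance scale alpha against a measured R_out
#'
#' Simulates the 0D infusion test over a fixed grid of alpha values (0.25 to
#' 4, 16 points), computes the Davson R_out for each (against p_ref = 9 mmHg),
#' fits the affine relation `R_out = a * alpha + b` by least squares, and
#' inverts it at the target.
#'
#' @param R_out_target Measured outflow resistance (mmHg/(ml/min)).
#' @param params,protocol Model and protocol for the calibration runs.
#' @return List with `alpha`, `slope`, `intercept`, `r_squared` and the grid
#'   data frame.
#' @export
calibrate_alpha <- function(R_out_target, params = lumped_params(),
                            protocol = infusion_protocol()) {
  grid <- seq(0.25, 4, length.out = 16L)
  rout <- vapply(grid, function(a) {
    pa <- params; pa$alpha <- a
    rout_from_trace(simulate_0d(protocol, pa), protocol, p_ref = 9)
  }, numeric(1))
  fit <- stats::lm(rout ~ grid)
  b <- unname(stats::coef(fit)[1]); a <- unname(stats::coef(fit)[2])
  alpha <- (R_out_target - b) / a
  if (R_out_target < min(rout) || R_out_target > max(rout)) {
    warning(sprintf("R_out target %.3g outside the fitted range [%.3g, %.3g]; extrapolating",
                    R_out_target, min(rout), max(rout)))
  }
  list(alpha = alpha, slope = a, intercept = b,
       r_squared = summary(fit)$r.squared,
       grid = data.frame(alpha = grid, R_out = rout))
}
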