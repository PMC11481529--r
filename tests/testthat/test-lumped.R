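test_that("compliance follows the piecewise law with the floor rules", {
  expect_equal(compliance_sas(10), 1.25)                  # 1/(0.2*(13-9))
  expect_equal(compliance_sas(19), 0.5)                   # 1/(0.2*(19-9))
  # monotone decay to zero above the threshold
  ps <- seq(14, 200, by = 1)
  expect_true(all(diff(compliance_sas(ps)) < 0))
  expect_lt(compliance_sas(1e6), 1e-5)
  # floor rule: p_lim <= p_ref lowers the effective reference to p_lim - 1
  pars <- lumped_params(p_ref = 20, p_lim = 13)
  expect_equal(compliance_sas(10, pars), 1 / (0.2 * 1))
  # floor rule: supra-threshold p at/below p_ref gives C = 1/E
  pars2 <- lumped_params(p_ref = 30, p_lim = 13)
  expect_equal(compliance_sas(14, pars2), 1 / 0.2)
})

test_that("backward-Euler step has the analytic fixed point and slope", {
  pars <- lumped_params()
  p_star <- steady_state_plateau(1, pars$Q_prod, pars)
  expect_equal(step_sas_pressure(p_star, 0, 0, 20, pars), p_star,
               tolerance = 1e-9)
  # dt -> 0 limit matches the explicit derivative
  p0 <- 15
  dd <- (step_sas_pressure(p0, 0, 1.5, 1e-4, pars) - p0) / (1e-4 / 60)
  rhs <- (pars$Q_prod + 1.5 - (p0 - pars$p_DS) / pars$R_DS -
          p0 / pars$R_crib) / compliance_sas(p0, pars)
  expect_equal(dd, rhs, tolerance = 1e-4)
  # a large infusion raises the pressure within the step
  expect_gt(step_sas_pressure(p0, 0, 100, 20, pars), p0)
})

test_that("steady_state_plateau matches hand evaluation", {
  expect_equal(steady_state_plateau(1, 1.83), 24.27, tolerance = 1e-3)
  expect_equal(steady_state_plateau(1, 0.33), 10.31, tolerance = 1e-3)
  # source-free balance is the resistance-weighted average of the sinks,
  # independent of alpha
  expect_equal(steady_state_plateau(1, 0), steady_state_plateau(3.7, 0))
  pars <- lumped_params()
  wavg <- (pars$p_DS / pars$R_DS + pars$p_crib / pars$R_crib) /
    (1 / pars$R_DS + 1 / pars$R_crib)
  expect_equal(steady_state_plateau(2, 0), wavg)
})

test_that("simulate_0d reaches the closed-form plateau and baseline", {
  tr <- simulate_0d()
  expect_equal(tr$p_csf_mmHg[1], 10.31, tolerance = 1e-3)
  k_end <- which.min(abs(tr$time_s - 3000))
  expect_equal(tr$p_csf_mmHg[k_end], 24.3, tolerance = 0.2 / 24.3)
  # no infusion: stays at baseline
  tr0 <- simulate_0d(infusion_protocol(Q_inf = 0))
  expect_lt(max(abs(tr0$p_csf_mmHg - tr0$p_csf_mmHg[1])), 1e-6)
  # relative-time option shifts the clock so infusion starts at 0
  trr <- simulate_0d(relative_time = TRUE)
  expect_equal(trr$time_s[1], -1000)
})

test_that("plateau matches the analytic steady state over the alpha range", {
  for (a in c(0.25, 1, 2.5, 4)) {
    pars <- lumped_params(alpha = a)
    tr <- simulate_0d(params = pars)
    k_end <- which.min(abs(tr$time_s - 3000))
    expect_lt(abs(tr$p_csf_mmHg[k_end] - steady_state_plateau(a, 1.83, pars)),
              0.3)
  }
})

test_that("backward Euler converges with first order against an RK4 oracle", {
  pars <- lumped_params()
  proto <- function(dt) infusion_protocol(dt = dt)
  ref_times <- seq(0, 4200, by = 40)
  ref <- rk4_sas_reference(ref_times,
                           steady_state_plateau(1, pars$Q_prod, pars),
                           pars, proto(40))
  errs <- vapply(c(40, 20, 10, 5), function(dt) {
    tr <- simulate_0d(proto(dt), pars)
    idx <- match(ref_times, tr$time_s)
    max(abs(tr$p_csf_mmHg[idx] - ref))
  }, numeric(1))
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders > 0.9 & orders < 1.1))
})

test_that("Davson R_out extraction and its edge cases", {
  tr <- simulate_0d()
  expect_equal(rout_from_trace(tr, p_ref = 9), (24.27 - 9) / 1.5,
               tolerance = 1e-3)
  # plateau exactly at p_ref gives zero
  expect_equal(rout_from_trace(tr, p_ref = tail(
    tr$p_csf_mmHg[which.min(abs(tr$time_s - 3000))], 1)), 0)
  expect_error(rout_from_trace(tr, infusion_protocol(Q_inf = 0)), "Q_inf")
  # monotone in alpha
  tr2 <- simulate_0d(params = lumped_params(alpha = 2))
  expect_gt(rout_from_trace(tr2), rout_from_trace(tr))
})

test_that("alpha calibration reproduces the affine outflow relation", {
  cal <- calibrate_alpha(10.03)
  pars <- lumped_params()
  R_par <- 1 / (1 / pars$R_DS + 1 / pars$R_crib)
  slope_analytic <- R_par * (pars$Q_prod + 1.5) / 1.5
  expect_equal(cal$slope, slope_analytic, tolerance = 5e-3)
  expect_equal(cal$slope, 11.3, tolerance = 0.02)
  expect_gt(cal$r_squared, 0.999)
  # inversion identity: target a + b maps to alpha = 1
  cal1 <- calibrate_alpha(cal$slope + cal$intercept)
  expect_equal(cal1$alpha, 1, tolerance = 1e-6)
  expect_warning(calibrate_alpha(200), "extrapolating")
})
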