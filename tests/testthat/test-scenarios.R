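# Every scenario must change exactly the parameters of its experiment design.

scenario_diff <- function(sc, base = base_scenario()) {
  out <- list()
  kd <- which(sc$params$kappa != base$params$kappa)
  if (length(kd)) out$kappa <- sc$params$compartment[kd]
  od <- which(sc$omega != base$omega & upper.tri(sc$omega) |
              sc$omega != base$omega & lower.tri(sc$omega))
  om_pairs <- unique(apply(which(sc$omega != base$omega, arr.ind = TRUE), 1,
                           function(ij) paste(sort(rownames(sc$omega)[ij]),
                                              collapse = "-")))
  if (length(om_pairs)) out$omega <- sort(om_pairs)
  if (!identical(sc$R_DS_const, base$R_DS_const)) out$R_DS <- sc$R_DS_const
  if (!identical(sc$filtration, base$filtration)) out$filtration <- sc$filtration$mode
  expect_true(all(sc$params$mu == base$params$mu))
  expect_true(all(sc$params$phi == base$params$phi))
  expect_true(all(sc$params$C == base$params$C))
  out
}

test_that("build_scenario applies exactly the stated overrides", {
  expect_error(build_scenario("nope"), "unknown scenario")
  expect_identical(build_scenario("base"), base_scenario())
  expect_identical(build_scenario("var1_base"),
                   { b <- base_scenario(); b$name <- "var1_base"; b })

  d <- scenario_diff(build_scenario("var1_pizzo"))
  expect_identical(d, list(kappa = "pc"))
  expect_equal(build_scenario("var1_pizzo")$params$kappa[5] * 1e18, 3.42e4,
               tolerance = 1e-2)
  d <- scenario_diff(build_scenario("var1_high"))
  expect_identical(d, list(kappa = "pc"))
  expect_equal(build_scenario("var1_high")$params$kappa[5] * 1e18, 0.352,
               tolerance = 1e-2)

  expect_identical(scenario_diff(build_scenario("var2_high")),
                   list(R_DS = 21.62))
  expect_identical(scenario_diff(build_scenario("var2_low")),
                   list(R_DS = 5.41))

  d <- scenario_diff(build_scenario("var3_constant"))
  expect_identical(d, list(omega = "c-pc", filtration = "constant"))
  expect_identical(build_scenario("var3_constant")$omega["c", "pc"], 0)
  expect_identical(build_scenario("var3_constant")$filtration$rate_ml_min, 0.16)

  expect_identical(scenario_diff(build_scenario("var4_case1")),
                   list(omega = "e-pc"))
  expect_identical(scenario_diff(build_scenario("var4_case2")),
                   list(omega = c("e-pa", "e-pc", "e-pv")))
  sc <- build_scenario("var4_case2")
  expect_equal(sc$omega["pa", "e"], 1.86e-6)
  expect_equal(sc$omega["pv", "e"], 1.65e-6)
  expect_equal(sc$omega["pc", "e"], 1e-8)
  expect_identical(scenario_diff(build_scenario("var4_case3")),
                   list(omega = c("e-pa", "e-pc")))
  sc <- build_scenario("var4_case4")
  expect_identical(scenario_diff(sc), list(omega = c("e-pa", "e-pv")))
  expect_equal(sc$omega["pa", "e"], 1.86e-7 / 2)

  expect_equal(build_scenario("var5_high")$params$kappa[7], 200e-18)
  expect_equal(build_scenario("var5_veryhigh")$params$kappa[7], 2000e-18)
  expect_identical(scenario_diff(build_scenario("var5_high")),
                   list(kappa = "e"))
})

test_that("scenario config files round trip and are validated", {
  path <- withr::local_tempfile(fileext = ".conf")
  sc0 <- build_scenario("var3_constant")
  write_scenario_config(sc0, path)
  sc1 <- read_scenario_config(path)
  expect_equal(sc1$params, sc0$params, tolerance = 1e-12)
  expect_equal(sc1$omega, sc0$omega, tolerance = 1e-12)
  expect_identical(sc1$filtration, sc0$filtration)

  shipped <- system.file("extdata", "base_parameters.conf", package = "mpetcsf")
  expect_equal(read_scenario_config(shipped)$omega,
               default_transfer_coefficients(), tolerance = 1e-12)

  writeLines(c("name: x", "bogus_key: 1"), path)
  expect_error(read_scenario_config(path), "unknown config key")
  writeLines(c("phi_e: 1.5"), path)
  expect_error(read_scenario_config(path))
})
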