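test_that("volume averages: constants, symmetry, subdomain weighting", {
  cube <- unit_cube_mesh()
  expect_equal(volume_average(rep(3.7, 8), cube), 3.7)
  # linear field on a symmetric region equals the centroid value
  expect_equal(volume_average(cube$vertices[, 1], cube), 0.5)
  expect_error(volume_average(rep(1, 8), cube, region = "bogus"), "unknown")
  expect_error(volume_average(rep(1, 8), cube, region = "white"), "no cells")

  # piecewise nodal indicator on the spherical shell: 1 inside the gray/white
  # interface radius, 0 outside. The white region is then exactly 1; the
  # region averages recombine exactly into the volume-weighted global mean
  mesh <- sym_mesh()
  m <- compute_metrics(mesh)
  r <- sqrt(rowSums(mesh$vertices^2))
  leg <- mesh$legend$subdomain
  white_nodes <- unique(as.vector(mesh$cells[mesh$cell_label == leg[["white"]], ]))
  r_if <- max(r[white_nodes])
  f <- as.numeric(r <= r_if + 1e-9)
  expect_equal(volume_average(f, mesh, "white"), 1)
  g <- volume_average(f, mesh, "gray")
  expect_gt(g, 0); expect_lt(g, 0.5)
  recombined <- (m$V_subdomain[["white"]] * 1 + m$V_subdomain[["gray"]] * g) /
    (m$V_subdomain[["white"]] + m$V_subdomain[["gray"]])
  expect_equal(volume_average(f, mesh), recombined, tolerance = 1e-12)
})

test_that("mean speed: zero, uniform, and an analytic radial field", {
  cube <- unit_cube_mesh()
  z <- matrix(0, 6, 3)
  expect_equal(mean_speed(z, cube), 0)
  u <- matrix(rep(c(3e-9, 4e-9, 0), each = 6), 6, 3)
  expect_equal(mean_speed(u, cube), 5)           # |(3,4,0)| nm/s
  # radial 1/r^2 flux field on a spherical shell: mean = c 4 pi (r2-r1) / V
  mesh <- sym_mesh()
  geom <- mpetcsf:::tet_geometry(mesh$vertices, mesh$cells)
  cen <- (mesh$vertices[mesh$cells[, 1], ] + mesh$vertices[mesh$cells[, 2], ] +
          mesh$vertices[mesh$cells[, 3], ] + mesh$vertices[mesh$cells[, 4], ]) / 4
  r <- sqrt(rowSums(cen^2))
  cc <- 1e-12
  vel <- cc / r^2 / r * cen                      # magnitude c/r^2, radial
  r1 <- min(sqrt(rowSums(mesh$vertices^2))); r2 <- max(sqrt(rowSums(mesh$vertices^2)))
  analytic <- cc * 4 * pi * (r2 - r1) / sum(geom$vol) * 1e9
  expect_equal(mean_speed(vel, mesh), analytic, tolerance = 0.05)
})

test_that("intercompartment totals: constant integrand and antisymmetry", {
  mesh <- small_mesh()
  sys <- assemble_mpet_system(mesh, base_scenario(), mpet_bcs(), B_in = 0)
  f <- matrix(mmhg_to_pa(10), sys$n, 7, dimnames = list(NULL, compartments()))
  f[, "pa"] <- mmhg_to_pa(12)                    # pa 2 mmHg above the rest
  fc <- intercompartment_totals(f, sys, 10)
  pa_e <- fc$pairs$rate_ml_min[fc$pairs$from == "pa" & fc$pairs$to == "e"]
  expected <- m3s_to_mlmin(1.86e-7 * mmhg_to_pa(2) * sys$V_domain)
  expect_equal(pa_e, expected, tolerance = 1e-10)
  # antisymmetry: recompute with the pair orientation flipped
  flip <- vapply(seq_len(nrow(fc$pairs)), function(k) {
    i <- fc$pairs$from[k]; j <- fc$pairs$to[k]
    m3s_to_mlmin(sys$omega[i, j] * sum(sys$w_node * (f[, j] - f[, i])))
  }, numeric(1))
  expect_equal(flip, -fc$pairs$rate_ml_min)
})

test_that("transmantle pressure difference on constructed fields", {
  mesh <- small_mesh()
  expect_equal(transmantle_dp(rep(1234, nrow(mesh$vertices)), mesh), 0)
  # radially linear field on the spherical shell: inner minus outer value
  sph <- sym_mesh()
  r <- sqrt(rowSums(sph$vertices^2))
  slope <- -mmhg_to_pa(1) / diff(range(r))       # 1 mmHg higher inside
  p <- slope * (r - max(r))
  expect_equal(transmantle_dp(p, sph), 1, tolerance = 1e-9)
  cube <- unit_cube_mesh()                       # flat faces: exact
  expect_equal(transmantle_dp(mmhg_to_pa(cube$vertices[, 3]), cube), 1,
               tolerance = 1e-12)
})

test_that("experiment suite collects rows and records failures", {
  mesh <- small_mesh()
  proto <- infusion_protocol(t_pre = 400, t_inf = 600, t_post = 200)
  outdir <- withr::local_tempdir()
  suppressMessages(
    suite <- run_experiment_suite(c("base", "not_a_scenario"), mesh,
                                  protocol = proto, outdir = outdir)
  )
  expect_identical(nrow(suite$summary), 1L)
  expect_identical(suite$summary$scenario, "base")
  expect_named(suite$failures, "not_a_scenario")
  expect_true(file.exists(file.path(outdir, "summary.csv")))
  expect_true(file.exists(file.path(outdir, "trace_base.csv")))
  expect_true(file.exists(file.path(outdir, "flowchart_base_end.csv")))
  # flowchart totals are antisymmetric pairwise by construction; check the
  # summary carries the documented clocks
  expect_true(all(c("p_e_pre", "p_e_end", "v_e_end", "Pe_e_end",
                    "transmantle_dp_end") %in% names(suite$summary)))
})
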