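test_that("unfolded unit ball hits the analytic sphere metrics", {
  mesh <- generate_synthetic_brain(geometry_spec(
    volume_l = 1, pial_area_dm2 = NULL, vent_area_dm2 = NULL,
    stem_angle_deg = 0, n = 8, layers = 4, grading = 1,
    outer_aspect = c(1, 1, 1)))
  m <- compute_metrics(mesh)
  expect_equal(m$V_domain, 1e-3, tolerance = 1e-6)      # exact by calibration
  # faceted sphere of calibrated volume: area near 4 pi r^2 = 4.836 dm^2
  expect_equal(m$A_pial * 1e2, 4.836, tolerance = 0.03)
  expect_identical(m$A_vent, 0)
  # all of the boundary is pial here
  expect_equal(m$A_pial, m$A_boundary, tolerance = 1e-10)
})

test_that("raw discretized ball volume converges monotonically from below", {
  vols <- vapply(c(4, 6, 8), function(n) {
    cs <- mpetcsf:::cube_sphere(n)
    tris <- mpetcsf:::split_quads(cs$quads)$tris
    mpetcsf:::enclosed_volume(cs$dirs, tris)
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
  expect_true(all(vols < 4 * pi / 3))
  expect_equal(vols[3], 4 * pi / 3, tolerance = 0.02)
})

test_that("default cohort-average spec meets its morphometric targets", {
  mesh <- fixture("default_mesh", function() {
    generate_synthetic_brain(geometry_spec())
  })
  m <- attr(mesh, "metrics")
  expect_equal(m$V_domain * 1e3, 1.04, tolerance = 0.05)
  expect_equal(m$A_pial * 1e2, 20.5, tolerance = 0.15)
  expect_equal(m$A_vent * 1e2, 1.89, tolerance = 0.02)
  expect_gt(m$quality_min, 0)
  # subdomains all populated
  expect_true(all(m$V_subdomain > 0))
  # facet labels partition the boundary (checked internally) and sum exactly
  expect_equal(m$A_pial + m$A_vent + m$A_stem_cut, m$A_boundary,
               tolerance = 1e-10)
})

test_that("same spec and seed give bit-identical meshes; seeds differ", {
  s <- geometry_spec(n = 5, layers = 3, pial_area_dm2 = 12)
  m1 <- generate_synthetic_brain(s)
  m2 <- generate_synthetic_brain(s)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$cells, m2$cells)
  m3 <- generate_synthetic_brain(geometry_spec(n = 5, layers = 3, pial_area_dm2 = 12, seed = 99L))
  expect_false(identical(m1$vertices, m3$vertices))
})

test_that("unattainable pial area errors with achieved vs target", {
  expect_error(
    generate_synthetic_brain(geometry_spec(pial_area_dm2 = 500, n = 5,
                                           layers = 3, fold_amp_max = 0.2)),
    "unattainable.*achieved.*target")
})

test_that("compute_metrics on hand-built cube and scaling laws", {
  cube <- unit_cube_mesh()
  m <- compute_metrics(cube)
  expect_equal(m$V_domain, 1)
  expect_equal(m$A_pial, 1)
  expect_equal(m$A_vent, 1)
  expect_equal(m$A_stem_cut, 4)
  big <- compute_metrics(unit_cube_mesh(scale = 2))
  expect_equal(big$V_domain, 8 * m$V_domain)
  expect_equal(big$A_pial, 4 * m$A_pial)
  # unlabeled boundary facets are an error
  broken <- cube
  broken$facets <- broken$facets[-1, ]
  broken$facet_label <- broken$facet_label[-1]
  expect_error(compute_metrics(broken), "not labelled exactly once")
})
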