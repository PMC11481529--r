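# Shared fixtures, memoized so expensive meshes/runs are built once per suite.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- fn()
  fixture_env[[name]]
}

# coarse brain-like mesh for solver tests (~10k cells)
small_mesh <- function() fixture("small_mesh", function() {
  generate_synthetic_brain(geometry_spec(n = 6, layers = 4, seed = 3L))
})

# spherically symmetric shell (no folding, spherical aspects, no stem)
sym_mesh <- function(n = 6) fixture(paste0("sym_mesh_", n), function() {
  generate_synthetic_brain(geometry_spec(
    pial_area_dm2 = NULL, stem_angle_deg = 0, n = n, layers = 4,
    grading = 1, outer_aspect = c(1, 1, 1), vent_aspect = c(1, 1, 1)))
})

# hand-built unit cube: 6 Kuhn tetrahedra around the 1-7 diagonal, boundary
# labelled pial (z=0), ventricular (z=1), stem_cut (sides)
unit_cube_mesh <- function(scale = 1) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)) * scale
  cells <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                 c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  g <- mpetcsf:::tet_geometry(v, cells)
  neg <- g$vol < 0
  cells[neg, c(2, 3)] <- cells[neg, c(3, 2)]
  facets <- rbind(c(1, 2, 3), c(1, 3, 4),            # z = 0
                  c(5, 6, 7), c(5, 7, 8),            # z = 1
                  c(1, 4, 8), c(1, 8, 5), c(2, 3, 7), c(2, 7, 6),
                  c(1, 2, 6), c(1, 6, 5), c(3, 4, 7), c(4, 8, 7))
  storage.mode(cells) <- "integer"
  storage.mode(facets) <- "integer"
  leg <- mesh_legend()
  structure(list(vertices = v, cells = cells,
                 cell_label = rep(leg$subdomain[["gray"]], 6L),
                 facets = facets,
                 facet_label = c(rep(leg$boundary[["pial"]], 2L),
                                 rep(leg$boundary[["ventricular"]], 2L),
                                 rep(leg$boundary[["stem_cut"]], 8L)),
                 legend = leg, spec = NULL),
            class = "brain_mesh")
}

# boundary set with everything switched off (pure interior dynamics)
zero_bcs <- function() mpet_bcs(beta1 = 0, beta2 = 0, beta3 = 0, Q_prod = 0)

# Independent 0D reference: classical RK4 on the SAS balance with the
# compliance formula written out here (not calling the package), dt = 0.05 s.
rk4_sas_reference <- function(times, p0, params, protocol, dt_fine = 0.05) {
  E <- params$E; p_lim <- params$p_lim; p_ref <- params$p_ref
  R_DS <- params$R_DS * params$alpha
  R_crib <- params$R_crib * params$alpha
  comp <- function(p) {
    ref_lo <- if (p_lim <= p_ref) p_lim - 1 else p_ref
    if (p < p_lim) 1 / (E * (p_lim - ref_lo))
    else 1 / (E * (p - if (p <= p_ref) p - 1 else p_ref))
  }
  qinf <- function(t) if (t > protocol$t_pre && t <= protocol$t_pre + protocol$t_inf)
    protocol$Q_inf else 0
  rhs <- function(t, p) {
    (params$Q_prod + qinf(t) - (p - params$p_DS) / R_DS -
       (p - params$p_crib) / R_crib) / comp(p) / 60  # per second
  }
  out <- numeric(length(times)); out[1] <- p0
  p <- p0; t <- times[1]
  for (k in 2:length(times)) {
    while (t < times[k] - 1e-9) {
      h <- min(dt_fine, times[k] - t)
      k1 <- rhs(t, p); k2 <- rhs(t + h / 2, p + h / 2 * k1)
      k3 <- rhs(t + h / 2, p + h / 2 * k2); k4 <- rhs(t + h, p + h * k3)
      p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[k] <- p
  }
  out
}
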