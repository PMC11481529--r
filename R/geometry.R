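# Synthetic brain-like tetrahedral meshes.
#
# The domain is a shell between an inner "ventricle" ellipsoid cavity and an
# outer "pial" ellipsoid whose radius is perturbed by a band-limited real
# spherical-harmonic field emulating cortical folding. Angular structure comes
# from a cube-sphere grid (no pole degeneracy); radial structure from graded
# layers, finest (about 1.5-2 mm, the reference discretization scale) at the
# pial surface where the exchange boundary layers live. Radial quad columns
# are split into triangle
# prisms and then into tetrahedra via face min-vertex-id diagonals, which is
# conforming by construction. Subdomains: gray (outer rind), white (interior),
# stem (a radial cone sector around the inferior pole whose outer cap is the
# no-flux stem_cut surface).

#' Specification for the synthetic brain mesh generator
#'
#' Defaults target the control-cohort average morphometrics: parenchyma volume
#' 1.04 L, pial surface area 20.5 dm^2 and ventricular surface area 1.89 dm^2.
#'
#' @param volume_l Target parenchyma (domain) volume in litres.
#' @param pial_area_dm2 Target pial area in dm^2, or `NULL` for an unfolded
#'   (smooth ellipsoid) surface.
#' @param vent_area_dm2 Target ventricular cavity area in dm^2, or `NULL`/0 for
#'   a solid domain without cavity.
#' @param gray_thickness_mm Thickness of the gray-matter rind (mm, measured
#'   radially from the outer surface).
#' @param stem_angle_deg Half-angle of the brain-stem cone around the inferior
#'   (-z) pole; 0 disables the stem subdomain.
#' @param n Angular resolution: grid cells per cube-sphere face edge.
#' @param layers Number of radial layers.
#' @param grading Radial grading ratio in (0, 1]; successive layer thicknesses
#'   shrink by this factor toward the pial surface (1 = uniform).
#' @param fold_degrees Spherical-harmonic degrees of the folding field.
#' @param fold_amp_max Upper bound for the relative folding amplitude used in
#'   the area calibration bisection.
#' @param outer_aspect,vent_aspect Ellipsoid semi-axis ratios (x, y, z) of the
#'   outer surface and of the ventricular cavity.
#' @param quality_floor Minimum accepted cell quality (regular tet = 1).
#' @param seed Integer seed fixing the folding field (and hence the mesh).
#' @export
geometry_spec <- function(volume_l = 1.04,
                          pial_area_dm2 = 20.5,
                          vent_area_dm2 = 1.89,
                          gray_thickness_mm = 10,
                          stem_angle_deg = 15,
                          n = 10,
                          layers = 7,
                          grading = 0.8,
                          fold_degrees = 8:16,
                          fold_amp_max = 2.0,
                          outer_aspect = c(1.2, 1.0, 0.87),
                          vent_aspect = c(1.4, 1.1, 0.65),
                          quality_floor = 1e-8,
                          seed = 1L) {
  stopifnot(volume_l > 0, n >= 2, layers >= 2, grading > 0, grading <= 1,
            is.null(pial_area_dm2) || pial_area_dm2 > 0,
            length(outer_aspect) == 3, all(outer_aspect > 0),
            length(vent_aspect) == 3, all(vent_aspect > 0),
            fold_amp_max > 0, stem_angle_deg >= 0)
  structure(list(volume_l = volume_l, pial_area_dm2 = pial_area_dm2,
                 vent_area_dm2 = vent_area_dm2,
                 gray_thickness_mm = gray_thickness_mm,
                 stem_angle_deg = stem_angle_deg, n = as.integer(n),
                 layers = as.integer(layers), grading = grading,
                 fold_degrees = fold_degrees, fold_amp_max = fold_amp_max,
                 outer_aspect = outer_aspect, vent_aspect = vent_aspect,
                 quality_floor = quality_floor, seed = as.integer(seed)),
            class = "geometry_spec")
}

#' Subdomain and boundary label legend
#' @export
mesh_legend <- function() {
  list(subdomain = c(gray = 1L, white = 2L, stem = 3L),
       boundary = c(pial = 1L, ventricular = 2L, stem_cut = 3L))
}

# ---- spherical harmonics ----------------------------------------------------

# Associated Legendre P_l^m(x) (unnormalized, no Condon-Shortley sign) for all
# l in `degrees`, fixed m, vector x. Stable for the moderate degrees used here.
.assoc_legendre <- function(x, lmax, m) {
  out <- matrix(0, length(x), lmax + 1L)  # columns l = 0..lmax
  if (m > lmax) return(out)
  s <- sqrt(pmax(0, 1 - x^2))
  pmm <- rep(1, length(x))
  if (m > 0) {
    for (i in seq_len(m)) pmm <- pmm * (2 * i - 1) * s
  }
  out[, m + 1L] <- pmm
  if (m < lmax) {
    pm1 <- x * (2 * m + 1) * pmm
    out[, m + 2L] <- pm1
    if (m + 2L <= lmax) {
      for (l in (m + 2L):lmax) {
        p <- (x * (2 * l - 1) * pm1 - (l + m - 1) * pmm) / (l - m)
        out[, l + 1L] <- p
        pmm <- pm1; pm1 <- p
      }
    }
  }
  out
}

# Band-limited random field on the unit sphere: sum of real spherical
# harmonics over `degrees` with iid standard normal coefficients, normalized to
# zero mean / unit sd over the supplied directions.
harmonic_field <- function(dirs, degrees, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  ct <- dirs[, 3]
  phi <- atan2(dirs[, 2], dirs[, 1])
  lmax <- max(degrees)
  f <- numeric(nrow(dirs))
  for (m in 0:lmax) {
    P <- .assoc_legendre(ct, lmax, m)
    for (l in degrees) {
      if (m > l) next
      # full normalization; sqrt(2) for the two real harmonics when m > 0
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      if (m == 0) {
        f <- f + rnorm(1) * nrm * P[, l + 1L]
      } else {
        f <- f + sqrt(2) * nrm * P[, l + 1L] *
          (rnorm(1) * cos(m * phi) + rnorm(1) * sin(m * phi))
      }
    }
  }
  f <- f - mean(f)
  sdf <- stats::sd(f)
  if (sdf > 0) f <- f / sdf
  f
}

# ---- cube-sphere angular grid ----------------------------------------------

# Unit-sphere direction grid from an n x n x 6 cube-sphere, with quad
# connectivity. Returns list(dirs = D x 3, quads = Q x 4 vertex rows).
cube_sphere <- function(n) {
  u <- seq(-1, 1, length.out = n + 1L)
  key_env <- new.env(hash = TRUE, size = 8L * n * n)
  pts <- list(); npts <- 0L
  get_id <- function(p) {
    key <- paste(signif(p, 12), collapse = ",")
    id <- key_env[[key]]
    if (is.null(id)) {
      npts <<- npts + 1L
      pts[[npts]] <<- p
      key_env[[key]] <- npts
      id <- npts
    }
    id
  }
  faces <- list(
    function(a, b) c(1, a, b), function(a, b) c(-1, a, b),
    function(a, b) c(a, 1, b), function(a, b) c(a, -1, b),
    function(a, b) c(a, b, 1), function(a, b) c(a, b, -1)
  )
  quads <- vector("list", 6L)
  for (fidx in seq_along(faces)) {
    ids <- matrix(0L, n + 1L, n + 1L)
    for (i in seq_len(n + 1L)) for (j in seq_len(n + 1L)) {
      ids[i, j] <- get_id(faces[[fidx]](u[i], u[j]))
    }
    q <- cbind(as.vector(ids[-(n + 1L), -(n + 1L)]),
               as.vector(ids[-1L, -(n + 1L)]),
               as.vector(ids[-1L, -1L]),
               as.vector(ids[-(n + 1L), -1L]))
    quads[[fidx]] <- q
  }
  quads <- do.call(rbind, quads)
  cube <- do.call(rbind, pts)
  dirs <- cube / sqrt(rowSums(cube^2))
  # orient all quads outward (normal along the radial direction)
  c1 <- dirs[quads[, 1], ]; c2 <- dirs[quads[, 2], ]; c3 <- dirs[quads[, 3], ]
  cen <- (c1 + c2 + c3 + dirs[quads[, 4], ]) / 4
  e1 <- c2 - c1; e2 <- c3 - c1
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  flip <- (nx * cen[, 1] + ny * cen[, 2] + nz * cen[, 3]) < 0
  quads[flip, ] <- quads[flip, c(1, 4, 3, 2)]
  list(dirs = dirs, quads = quads)
}

# Split quads (Q x 4 of vertex ids) into triangles along the diagonal through
# the quad's minimum vertex id; identical ids across shared quads give
# identical triangulations (conformity). Degenerate triangles are dropped.
# Returns 2Q x 3 (with NA rows removed); `aux` rows are replicated alongside.
split_quads <- function(quads, aux = NULL) {
  amin <- max.col(-quads, ties.method = "first")
  thru13 <- amin == 1L | amin == 3L
  t1 <- ifelse(thru13, quads[, 1], quads[, 2])
  t2 <- ifelse(thru13, quads[, 2], quads[, 3])
  t3 <- ifelse(thru13, quads[, 3], quads[, 4])
  s1 <- ifelse(thru13, quads[, 1], quads[, 2])
  s2 <- ifelse(thru13, quads[, 3], quads[, 4])
  s3 <- ifelse(thru13, quads[, 4], quads[, 1])
  tris <- rbind(cbind(t1, t2, t3), cbind(s1, s2, s3))
  aux2 <- if (!is.null(aux)) c(aux, aux) else NULL
  ok <- tris[, 1] != tris[, 2] & tris[, 2] != tris[, 3] & tris[, 1] != tris[, 3]
  list(tris = tris[ok, , drop = FALSE],
       aux = if (!is.null(aux2)) aux2[ok] else NULL)
}

# Split prisms (np x 6 ids: bottom b1,b2,b3 outward-oriented, top t1,t2,t3
# radially above) into 3 tets each, with quad-face diagonals through the
# face's minimum global vertex id (conforming across shared faces, and never
# the unrealizable cyclic pattern). Tets with repeated ids (collapsed center
# of a solid ball) are dropped; `keep` indexes the surviving rows of the
# 3-per-prism layout.
split_prisms <- function(prisms) {
  perms <- rbind(
    c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4), c(3, 1, 2, 6, 4, 5),
    c(4, 6, 5, 1, 3, 2), c(5, 4, 6, 2, 1, 3), c(6, 5, 4, 3, 2, 1)
  )
  np <- nrow(prisms)
  argm <- max.col(-prisms, ties.method = "first")
  P <- matrix(0L, np, 6L)
  for (k in 1:6) P[, k] <- prisms[cbind(seq_len(np), perms[argm, k])]
  # face (v2,v3,v6,v5): diagonal through its min id
  faceB <- P[, c(2L, 3L, 6L, 5L), drop = FALSE]
  bmin <- max.col(-faceB, ties.method = "first")
  thru26 <- bmin == 1L | bmin == 3L    # min is v2 or v6
  t1 <- cbind(P[, 1], P[, 2], P[, 3], ifelse(thru26, P[, 6], P[, 5]))
  t2 <- ifelse(matrix(thru26, np, 4L),
               cbind(P[, 1], P[, 2], P[, 6], P[, 5]),
               cbind(P[, 1], P[, 3], P[, 6], P[, 5]))
  t3 <- ifelse(matrix(thru26, np, 4L),
               cbind(P[, 1], P[, 5], P[, 6], P[, 4]),
               cbind(P[, 1], P[, 6], P[, 4], P[, 5]))
  tets <- matrix(0L, 3L * np, 4L)
  tets[seq(1L, 3L * np, by = 3L), ] <- t1
  tets[seq(2L, 3L * np, by = 3L), ] <- t2
  tets[seq(3L, 3L * np, by = 3L), ] <- t3
  dup <- tets[, 1] == tets[, 2] | tets[, 1] == tets[, 3] | tets[, 1] == tets[, 4] |
         tets[, 2] == tets[, 3] | tets[, 2] == tets[, 4] | tets[, 3] == tets[, 4]
  list(tets = tets[!dup, , drop = FALSE], keep = which(!dup))
}

# radius of an ellipsoid with semi-axes `semi` along unit directions `dirs`
ellipsoid_radius <- function(dirs, semi) {
  1 / sqrt((dirs[, 1] / semi[1])^2 + (dirs[, 2] / semi[2])^2 +
           (dirs[, 3] / semi[3])^2)
}

# area and enclosed volume of a closed, outward-oriented triangulated surface
surface_area <- function(coords, tris) sum(tri_areas(coords, tris))
enclosed_volume <- function(coords, tris) {
  p1 <- coords[tris[, 1], , drop = FALSE]
  p2 <- coords[tris[, 2], , drop = FALSE]
  p3 <- coords[tris[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

# ---- generator --------------------------------------------------------------

#' Generate a synthetic brain-like tetrahedral mesh
#'
#' Builds the labelled shell mesh described in [geometry_spec()], calibrating
#' the outer scale exactly to the volume target and the folding amplitude by
#' bisection to the pial-area target (achieved volume within 5% and pial area
#' within 15% are enforced; the ventricular area is matched exactly up to
#' discretization by radial scaling of the cavity).
#'
#' @param spec A [geometry_spec()].
#' @return A `brain_mesh`: vertices (m), 4-column `cells`, `cell_label`,
#'   3-column boundary `facets`, `facet_label`, the label `legend`, and the
#'   achieved [compute_metrics()] as attribute `"metrics"`.
#' @export
generate_synthetic_brain <- function(spec = geometry_spec()) {
  stopifnot(inherits(spec, "geometry_spec"))
  cs <- cube_sphere(spec$n)
  dirs <- cs$dirs; quads <- cs$quads
  ndir <- nrow(dirs)
  surf_tris <- split_quads(quads)$tris

  V_target <- spec$volume_l * 1e-3
  A_pial_target <- if (is.null(spec$pial_area_dm2)) NULL else spec$pial_area_dm2 * 1e-2
  A_vent_target <- if (is.null(spec$vent_area_dm2) || spec$vent_area_dm2 <= 0) NULL
                   else spec$vent_area_dm2 * 1e-2

  # cavity: radial scaling matches the discrete area target exactly
  if (!is.null(A_vent_target)) {
    semi_v <- spec$vent_aspect / prod(spec$vent_aspect)^(1 / 3)
    r_vent <- ellipsoid_radius(dirs, semi_v)
    A1 <- surface_area(dirs * r_vent, surf_tris)
    r_vent <- r_vent * sqrt(A_vent_target / A1)
    V_cav <- enclosed_volume(dirs * r_vent, surf_tris)
  } else {
    r_vent <- numeric(ndir)  # solid ball: cavity collapses to the origin
    V_cav <- 0
  }

  # outer surface: shape = ellipsoid * (1 + eps * folding field)
  semi_o <- spec$outer_aspect / prod(spec$outer_aspect)^(1 / 3)
  e_out <- ellipsoid_radius(dirs, semi_o)
  f <- if (!is.null(A_pial_target)) harmonic_field(dirs, spec$fold_degrees, spec$seed)
       else numeric(ndir)

  # The folding modulates the shell thickness above the cavity, so the outer
  # surface stays strictly outside the ventricles at any amplitude; the radial
  # factor is floored to keep the surface star-shaped. The overall ellipsoid
  # scale s is solved (monotone bisection) so the enclosed volume matches.
  fold_fac <- function(eps) pmax(1 + eps * f, 0.1)
  radius_at <- function(s, fac) r_vent + fac * pmax(s * e_out - r_vent, 1e-4)
  outer_radius <- function(eps) {
    fac <- fold_fac(eps)
    vol_of <- function(s) enclosed_volume(dirs * radius_at(s, fac), surf_tris) - V_cav
    s_lo <- max(r_vent / e_out) + 1e-6
    s_hi <- max(1.05 * s_lo, ((V_target + V_cav) * 3 / (4 * pi))^(1 / 3) /
                               min(e_out) * 2)
    while (vol_of(s_hi) < V_target) s_hi <- s_hi * 1.5
    for (it in 1:80) {
      s_mid <- (s_lo + s_hi) / 2
      if (vol_of(s_mid) < V_target) s_lo <- s_mid else s_hi <- s_mid
    }
    radius_at((s_lo + s_hi) / 2, fac)
  }
  achieved_area <- function(eps) {
    surface_area(dirs * outer_radius(eps), surf_tris)
  }

  if (is.null(A_pial_target)) {
    eps <- 0
  } else {
    a_hi <- achieved_area(spec$fold_amp_max)
    if (is.na(a_hi) || a_hi < A_pial_target) {
      stop(sprintf(paste0("pial area target unattainable at amplitude bound %.3g: ",
                          "achieved %.4g dm^2 vs target %.4g dm^2"),
                   spec$fold_amp_max,
                   ifelse(is.na(a_hi), NA, a_hi * 1e2), A_pial_target * 1e2))
    }
    lo <- 0; hi <- spec$fold_amp_max
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (achieved_area(mid) < A_pial_target) lo <- mid else hi <- mid
    }
    eps <- hi
  }
  R_out <- outer_radius(eps)
  if (any(R_out <= r_vent + 1e-3)) {
    stop("outer surface intersects the ventricular cavity; reduce folding or cavity size")
  }

  # radial layer positions: geometric grading, finest at the pial surface
  L <- spec$layers
  w <- spec$grading^(seq_len(L))
  t_l <- c(0, cumsum(w) / sum(w))

  # vertices: (direction, layer); solid-ball case collapses layer 0 to a point
  solid <- is.null(A_vent_target)
  nvert_shell <- ndir * (L + 1L)
  vid <- matrix(0L, ndir, L + 1L)
  if (solid) {
    vid[, 1L] <- 1L
    vid[, 2:(L + 1L)] <- 1L + seq_len(ndir * L)
    nvert <- 1L + ndir * L
  } else {
    vid[] <- seq_len(nvert_shell)
    nvert <- nvert_shell
  }
  verts <- matrix(0, nvert, 3L)
  for (l in 0:L) {
    r <- r_vent + t_l[l + 1L] * (R_out - r_vent)
    if (solid && l == 0L) { verts[1L, ] <- 0; next }
    verts[vid[, l + 1L], ] <- dirs * r
  }

  # triangle columns: split direction quads once (min-direction-id diagonal,
  # monotone in the per-layer global ids, so boundary facet splits agree)
  nq <- nrow(quads)
  spq <- split_quads(quads, aux = seq_len(nq))
  dir_tris <- spq$tris          # outward oriented
  tri_quad <- spq$aux
  ntri <- nrow(dir_tris)

  # prisms: one per (direction triangle, layer); t_i radially above b_i
  prisms <- matrix(0L, ntri * L, 6L)
  prism_layer <- rep(seq_len(L), each = ntri)
  prism_tri <- rep(seq_len(ntri), L)
  for (l in seq_len(L)) {
    rows <- (l - 1L) * ntri + seq_len(ntri)
    prisms[rows, 1:3] <- cbind(vid[dir_tris[, 1], l], vid[dir_tris[, 2], l],
                               vid[dir_tris[, 3], l])
    prisms[rows, 4:6] <- cbind(vid[dir_tris[, 1], l + 1L], vid[dir_tris[, 2], l + 1L],
                               vid[dir_tris[, 3], l + 1L])
  }

  # subdomain labels per prism column
  leg <- mesh_legend()
  qdir <- dirs[quads[, 1], ] + dirs[quads[, 2], ] + dirs[quads[, 3], ] + dirs[quads[, 4], ]
  qdir <- qdir / sqrt(rowSums(qdir^2))
  stem_quad <- if (spec$stem_angle_deg > 0) {
    acos(pmax(-1, pmin(1, -qdir[, 3]))) <= spec$stem_angle_deg * pi / 180
  } else rep(FALSE, nq)
  depth <- rowMeans(matrix((1 - (t_l[prism_layer] + t_l[prism_layer + 1L]) / 2) *
                           (R_out[dir_tris[prism_tri, ]] - r_vent[dir_tris[prism_tri, ]]),
                           nrow(prisms), 3L))
  prism_label <- ifelse(stem_quad[tri_quad[prism_tri]], leg$subdomain[["stem"]],
                        ifelse(depth < spec$gray_thickness_mm * 1e-3,
                               leg$subdomain[["gray"]], leg$subdomain[["white"]]))

  split <- split_prisms(prisms)
  cells <- split$tets
  cell_label <- rep(prism_label, each = 3L)[split$keep]

  geom <- tet_geometry(verts, cells)
  vol <- geom$vol
  if (any(vol <= 0)) {
    stop(sprintf("prism split produced %d non-positive tetrahedra; reduce folding amplitude",
                 sum(vol <= 0)))
  }

  # cell quality: 6*sqrt(2)*V / longest_edge^3 (regular tet = 1)
  edge_pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  lmax2 <- 0
  for (k in seq_len(6)) {
    d <- verts[cells[, edge_pairs[k, 1]], ] - verts[cells[, edge_pairs[k, 2]], ]
    lmax2 <- pmax(lmax2, rowSums(d^2))
  }
  quality <- 6 * sqrt(2) * vol / lmax2^1.5
  if (min(quality) < spec$quality_floor) {
    stop(sprintf("mesh quality %.3g below floor %.3g; coarsen folding or raise resolution",
                 min(quality), spec$quality_floor))
  }

  # boundary facets: outer (pial / stem_cut) and cavity (ventricular); these
  # are exactly the top/bottom prism triangles, so the mesh conforms
  facet <- cbind(vid[dir_tris[, 1], L + 1L], vid[dir_tris[, 2], L + 1L],
                 vid[dir_tris[, 3], L + 1L])
  facet_label <- ifelse(stem_quad[tri_quad], leg$boundary[["stem_cut"]],
                        leg$boundary[["pial"]])
  if (!solid) {
    facet <- rbind(facet, cbind(vid[dir_tris[, 1], 1L], vid[dir_tris[, 2], 1L],
                                vid[dir_tris[, 3], 1L]))
    facet_label <- c(facet_label, rep(leg$boundary[["ventricular"]], ntri))
  }

  mesh <- structure(list(
    vertices = verts,
    cells = cells,
    cell_label = as.integer(cell_label),
    facets = facet,
    facet_label = as.integer(facet_label),
    legend = leg,
    spec = spec
  ), class = "brain_mesh")
  metrics <- compute_metrics(mesh)
  # enforce the generator's own accuracy contract
  if (abs(metrics$V_domain - V_target) > 0.05 * V_target) {
    stop(sprintf("achieved volume %.4g L vs target %.4g L (>5%% off)",
                 metrics$V_domain * 1e3, V_target * 1e3))
  }
  if (!is.null(A_pial_target) &&
      abs(metrics$A_pial - A_pial_target) > 0.15 * A_pial_target) {
    stop(sprintf("achieved pial area %.4g dm^2 vs target %.4g dm^2 (>15%% off)",
                 metrics$A_pial * 1e2, A_pial_target * 1e2))
  }
  attr(mesh, "metrics") <- metrics
  mesh
}

#' @export
print.brain_mesh <- function(x, ...) {
  m <- attr(x, "metrics")
  if (is.null(m)) m <- compute_metrics(x)
  cat("<brain_mesh>", nrow(x$cells), "tets,", nrow(x$vertices), "vertices\n")
  cat(sprintf("  V = %.3f L, A_pial = %.2f dm^2, A_vent = %.2f dm^2\n",
              m$V_domain * 1e3, m$A_pial * 1e2, m$A_vent * 1e2))
  invisible(x)
}

# ---- metrics ----------------------------------------------------------------

# sorted-triple keys for face matching
.face_keys <- function(tris) {
  r1 <- pmin(tris[, 1], tris[, 2], tris[, 3])
  r3 <- pmax(tris[, 1], tris[, 2], tris[, 3])
  r2 <- tris[, 1] + tris[, 2] + tris[, 3] - r1 - r3
  paste(r1, r2, r3)
}

#' Compute mesh metrics
#'
#' Domain and per-subdomain volumes (summed cell volumes), labelled surface
#' areas (summed facet areas), cell count and min/max cell quality. Errors if
#' the labelled facets do not exactly cover the mesh boundary or any cell has
#' non-positive volume.
#'
#' @param mesh A `brain_mesh`.
#' @return A list of class `mesh_metrics`.
#' @export
compute_metrics <- function(mesh) {
  stopifnot(inherits(mesh, "brain_mesh"))
  geom <- tet_geometry(mesh$vertices, mesh$cells)
  if (any(geom$vol <= 0)) stop("mesh contains inverted or degenerate cells")
  # boundary faces = faces of exactly one cell; must equal labelled facets
  fc <- rbind(mesh$cells[, c(1, 2, 3)], mesh$cells[, c(1, 2, 4)],
              mesh$cells[, c(1, 3, 4)], mesh$cells[, c(2, 3, 4)])
  keys <- .face_keys(fc)
  tab <- table(keys)
  boundary_keys <- names(tab)[tab == 1L]
  labelled_keys <- .face_keys(mesh$facets)
  if (!setequal(boundary_keys, labelled_keys) ||
      anyDuplicated(labelled_keys) > 0L) {
    stop("boundary facets are not labelled exactly once (",
         length(boundary_keys), " boundary faces vs ",
         length(labelled_keys), " labelled facets)")
  }
  leg <- mesh$legend
  areas <- tri_areas(mesh$vertices, mesh$facets)
  area_by <- vapply(leg$boundary, function(lbl)
    sum(areas[mesh$facet_label == lbl]), numeric(1))
  vol_by <- vapply(leg$subdomain, function(lbl)
    sum(geom$vol[mesh$cell_label == lbl]), numeric(1))
  edge_pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  lmax2 <- 0
  for (k in seq_len(6)) {
    d <- mesh$vertices[mesh$cells[, edge_pairs[k, 1]], ] -
         mesh$vertices[mesh$cells[, edge_pairs[k, 2]], ]
    lmax2 <- pmax(lmax2, rowSums(d^2))
  }
  quality <- 6 * sqrt(2) * geom$vol / lmax2^1.5
  structure(list(
    V_domain = sum(geom$vol),
    V_subdomain = vol_by,
    A_pial = area_by[["pial"]],
    A_vent = area_by[["ventricular"]],
    A_stem_cut = area_by[["stem_cut"]],
    A_boundary = sum(areas),
    n_cells = nrow(mesh$cells),
    n_vertices = nrow(mesh$vertices),
    quality_min = min(quality),
    quality_max = max(quality)
  ), class = "mesh_metrics")
}

#' @export
print.mesh_metrics <- function(x, ...) {
  cat("<mesh_metrics>\n")
  cat(sprintf("  V = %.4f L (gray %.3f / white %.3f / stem %.3f)\n",
              x$V_domain * 1e3, x$V_subdomain[["gray"]] * 1e3,
              x$V_subdomain[["white"]] * 1e3, x$V_subdomain[["stem"]] * 1e3))
  cat(sprintf("  A_pial = %.2f dm^2, A_vent = %.2f dm^2, A_stem_cut = %.3f dm^2\n",
              x$A_pial * 1e2, x$A_vent * 1e2, x$A_stem_cut * 1e2))
  cat(sprintf("  %d cells / %d vertices, quality [%.3g, %.3g]\n",
              x$n_cells, x$n_vertices, x$quality_min, x$quality_max))
  invisible(x)
}
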