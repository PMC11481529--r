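# Linear (P1) tetrahedral finite element primitives: cell geometry, stiffness,
# consistent mass, boundary (surface) mass on labelled facets, and cellwise
# gradient operators. All fully vectorized over cells.

# Signed volumes and P1 basis gradients for all tets.
# Returns list(vol, gx, gy, gz) with gx/gy/gz of dim (ncell x 4):
# gradient of basis function of local vertex k in cell c.
tet_geometry <- function(vertices, cells) {
  v1 <- vertices[cells[, 1], , drop = FALSE]
  v2 <- vertices[cells[, 2], , drop = FALSE]
  v3 <- vertices[cells[, 3], , drop = FALSE]
  v4 <- vertices[cells[, 4], , drop = FALSE]
  a <- v2 - v1; b <- v3 - v1; c3 <- v4 - v1
  # det of J = [a; b; c] (rows)
  det <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
         a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
         a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  vol <- det / 6
  # rows of inv(J)^T = grad(lambda_2..4); cofactor formulas
  inv <- 1 / det
  g2x <- (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) * inv
  g2y <- (b[, 3] * c3[, 1] - b[, 1] * c3[, 3]) * inv
  g2z <- (b[, 1] * c3[, 2] - b[, 2] * c3[, 1]) * inv
  g3x <- (c3[, 2] * a[, 3] - c3[, 3] * a[, 2]) * inv
  g3y <- (c3[, 3] * a[, 1] - c3[, 1] * a[, 3]) * inv
  g3z <- (c3[, 1] * a[, 2] - c3[, 2] * a[, 1]) * inv
  g4x <- (a[, 2] * b[, 3] - a[, 3] * b[, 2]) * inv
  g4y <- (a[, 3] * b[, 1] - a[, 1] * b[, 3]) * inv
  g4z <- (a[, 1] * b[, 2] - a[, 2] * b[, 1]) * inv
  list(
    vol = vol,
    gx = cbind(-(g2x + g3x + g4x), g2x, g3x, g4x),
    gy = cbind(-(g2y + g3y + g4y), g2y, g3y, g4y),
    gz = cbind(-(g2z + g3z + g4z), g2z, g3z, g4z)
  )
}

# Areas of triangles (facets) given vertex coordinates.
tri_areas <- function(vertices, facets) {
  a <- vertices[facets[, 2], , drop = FALSE] - vertices[facets[, 1], , drop = FALSE]
  b <- vertices[facets[, 3], , drop = FALSE] - vertices[facets[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Stiffness matrix  sum_cells coef_c * V_c * G G^T  (coef: scalar or per cell).
assemble_stiffness <- function(vertices, cells, geom = NULL, coef = 1) {
  if (is.null(geom)) geom <- tet_geometry(vertices, cells)
  n <- nrow(vertices)
  w <- geom$vol * coef
  ii <- jj <- xx <- vector("list", 16L)
  k <- 0L
  for (p in 1:4) for (q in 1:4) {
    k <- k + 1L
    ii[[k]] <- cells[, p]
    jj[[k]] <- cells[, q]
    xx[[k]] <- w * (geom$gx[, p] * geom$gx[, q] +
                    geom$gy[, p] * geom$gy[, q] +
                    geom$gz[, p] * geom$gz[, q])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

# Consistent P1 mass matrix: V/20 * (1 + delta_pq).
assemble_mass <- function(vertices, cells, geom = NULL) {
  if (is.null(geom)) geom <- tet_geometry(vertices, cells)
  n <- nrow(vertices)
  ii <- jj <- xx <- vector("list", 16L)
  k <- 0L
  for (p in 1:4) for (q in 1:4) {
    k <- k + 1L
    ii[[k]] <- cells[, p]
    jj[[k]] <- cells[, q]
    xx[[k]] <- geom$vol / 20 * (1 + (p == q))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

# Surface mass matrix over a set of boundary triangles: A/12 * (1 + delta_pq).
assemble_surface_mass <- function(vertices, facets) {
  n <- nrow(vertices)
  if (is.null(facets) || nrow(facets) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  }
  area <- tri_areas(vertices, facets)
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (p in 1:3) for (q in 1:3) {
    k <- k + 1L
    ii[[k]] <- facets[, p]
    jj[[k]] <- facets[, q]
    xx[[k]] <- area / 12 * (1 + (p == q))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

# Sparse cellwise gradient operators Gx, Gy, Gz (ncell x nnode):
# (Gx %*% p)[c] = d/dx of the P1 interpolant of p on cell c.
gradient_operators <- function(vertices, cells, geom = NULL) {
  if (is.null(geom)) geom <- tet_geometry(vertices, cells)
  m <- nrow(cells); n <- nrow(vertices)
  ci <- rep.int(seq_len(m), 4L)
  cj <- as.vector(cells)
  list(
    Gx = Matrix::sparseMatrix(i = ci, j = cj, x = as.vector(geom$gx), dims = c(m, n)),
    Gy = Matrix::sparseMatrix(i = ci, j = cj, x = as.vector(geom$gy), dims = c(m, n)),
    Gz = Matrix::sparseMatrix(i = ci, j = cj, x = as.vector(geom$gz), dims = c(m, n))
  )
}
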