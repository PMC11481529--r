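# Mesh readers/writers: Gmsh MSH 4.1, VTU (XML unstructured grid) and XDMF,
# all as plain ASCII. Subdomain labels travel as the cell-data array
# "subdomain" (on tetrahedra) and boundary labels as "boundary" (on
# triangles); in MSH files the entity tag of each element block carries the
# label. Round trips are bit-exact (coordinates written with %.17g).

.fmt_coord <- function(x) sprintf("%.17g", x)

.mesh_format_of <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("msh", "vtu", "xdmf")))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("msh", "vtu", "xdmf")) {
    stop("cannot infer mesh format from extension '", ext,
         "'; pass format = \"msh\", \"vtu\" or \"xdmf\"")
  }
  ext
}

#' Write a brain mesh to MSH 4.1, VTU or XDMF
#'
#' @param mesh A `brain_mesh`.
#' @param path Output file path.
#' @param format `"msh"`, `"vtu"` or `"xdmf"`; inferred from the extension if
#'   omitted.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "brain_mesh"))
  format <- .mesh_format_of(path, format)
  switch(format,
         msh = .write_msh(mesh, path),
         vtu = .write_vtu(mesh, path),
         xdmf = .write_xdmf(mesh, path))
  invisible(path)
}

#' Read a brain mesh written by [write_mesh()]
#'
#' Readers parse the package's documented ASCII dialects. Files without both
#' label sets (cell array `subdomain`, facet array `boundary`) are rejected.
#'
#' @param path Input file path.
#' @param format As in [write_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  format <- .mesh_format_of(path, format)
  out <- switch(format,
                msh = .read_msh(path),
                vtu = .read_vtu(path),
                xdmf = .read_xdmf(path))
  .as_brain_mesh(out)
}

.as_brain_mesh <- function(parts) {
  missing <- character(0)
  if (is.null(parts$cell_label)) missing <- c(missing, "subdomain")
  if (is.null(parts$facet_label) || is.null(parts$facets) ||
      nrow(parts$facets) == 0L) missing <- c(missing, "boundary")
  if (length(missing)) {
    stop("mesh file lacks required label array(s): ",
         paste(missing, collapse = ", "))
  }
  structure(list(vertices = parts$vertices,
                 cells = parts$cells,
                 cell_label = as.integer(parts$cell_label),
                 facets = parts$facets,
                 facet_label = as.integer(parts$facet_label),
                 legend = mesh_legend(),
                 spec = NULL),
            class = "brain_mesh")
}

# ---- MSH 4.1 ----------------------------------------------------------------

.write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices)
  writeLines(c("$MeshFormat", "4.1 0 8", "$EndMeshFormat"), con)
  # single 3D node entity block
  writeLines(c("$Nodes", paste(1, nv, 1, nv), paste(3, 1, 0, nv)), con)
  writeLines(format(seq_len(nv)), con)
  writeLines(paste(.fmt_coord(mesh$vertices[, 1]),
                   .fmt_coord(mesh$vertices[, 2]),
                   .fmt_coord(mesh$vertices[, 3])), con)
  writeLines("$EndNodes", con)
  # one element block per (dim, label); entity tag = label
  blocks <- list()
  for (lbl in sort(unique(mesh$facet_label))) {
    idx <- which(mesh$facet_label == lbl)
    blocks[[length(blocks) + 1L]] <- list(dim = 2L, tag = lbl, type = 2L,
                                          conn = mesh$facets[idx, , drop = FALSE])
  }
  for (lbl in sort(unique(mesh$cell_label))) {
    idx <- which(mesh$cell_label == lbl)
    blocks[[length(blocks) + 1L]] <- list(dim = 3L, tag = lbl, type = 4L,
                                          conn = mesh$cells[idx, , drop = FALSE])
  }
  nelem <- sum(vapply(blocks, function(b) nrow(b$conn), integer(1)))
  writeLines(c("$Elements", paste(length(blocks), nelem, 1, nelem)), con)
  eid <- 0L
  for (b in blocks) {
    writeLines(paste(b$dim, b$tag, b$type, nrow(b$conn)), con)
    ids <- eid + seq_len(nrow(b$conn))
    eid <- eid + nrow(b$conn)
    writeLines(paste(ids, apply(b$conn, 1L, paste, collapse = " ")), con)
  }
  writeLines("$EndElements", con)
}

.read_msh <- function(path) {
  lines <- readLines(path)
  sect <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) stop("MSH file lacks section $", name)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  nd <- sect("Nodes")
  hdr <- scan(text = nd[1], quiet = TRUE)
  nblocks <- hdr[1]; nnodes <- hdr[2]
  verts <- matrix(NA_real_, nnodes, 3L)
  pos <- 2L
  for (b in seq_len(nblocks)) {
    bh <- scan(text = nd[pos], quiet = TRUE)
    nn <- bh[4]
    ids <- as.integer(nd[pos + seq_len(nn)])
    coords <- do.call(rbind, lapply(nd[pos + nn + seq_len(nn)],
                                    function(s) scan(text = s, quiet = TRUE)))
    verts[ids, ] <- coords[, 1:3]
    pos <- pos + 2L * nn + 1L
  }
  el <- sect("Elements")
  hdr <- scan(text = el[1], quiet = TRUE)
  nblocks <- hdr[1]
  pos <- 2L
  cells <- list(); clab <- list(); facets <- list(); flab <- list()
  for (b in seq_len(nblocks)) {
    bh <- scan(text = el[pos], quiet = TRUE)
    dim <- bh[1]; tag <- bh[2]; type <- bh[3]; ne <- bh[4]
    rows <- do.call(rbind, lapply(el[pos + seq_len(ne)],
                                  function(s) scan(text = s, quiet = TRUE)))
    conn <- matrix(as.integer(rows[, -1L]), nrow = ne)
    if (type == 4L) {            # tetrahedra
      cells[[length(cells) + 1L]] <- conn
      clab[[length(clab) + 1L]] <- rep(as.integer(tag), ne)
    } else if (type == 2L) {     # triangles
      facets[[length(facets) + 1L]] <- conn
      flab[[length(flab) + 1L]] <- rep(as.integer(tag), ne)
    }
    pos <- pos + ne + 1L
  }
  list(vertices = verts,
       cells = if (length(cells)) do.call(rbind, cells) else NULL,
       cell_label = if (length(clab)) unlist(clab) else NULL,
       facets = if (length(facets)) do.call(rbind, facets) else
         matrix(integer(0), 0, 3),
       facet_label = if (length(flab)) unlist(flab) else NULL)
}

# ---- VTU --------------------------------------------------------------------

# Tets and boundary triangles are stored as one cell list (VTK types 10 and 5)
# with two Int32 cell-data arrays: "subdomain" (label on tets, -1 on
# triangles) and "boundary" (label on triangles, -1 on tets).
.write_vtu <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$cells); nf <- nrow(mesh$facets)
  conn0 <- c(t(mesh$cells) - 1L, t(mesh$facets) - 1L)
  offsets <- c(seq_len(nt) * 4L, nt * 4L + seq_len(nf) * 3L)
  types <- c(rep(10L, nt), rep(5L, nf))
  subdomain <- c(mesh$cell_label, rep(-1L, nf))
  boundary <- c(rep(-1L, nt), mesh$facet_label)
  pts <- paste(.fmt_coord(mesh$vertices[, 1]), .fmt_coord(mesh$vertices[, 2]),
               .fmt_coord(mesh$vertices[, 3]))
  xml <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '  <UnstructuredGrid>',
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', nv, nt + nf),
    '      <Points>',
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    paste0("          ", pts),
    '        </DataArray>',
    '      </Points>',
    '      <Cells>',
    '        <DataArray type="Int32" Name="connectivity" format="ascii">',
    paste0("          ", paste(conn0, collapse = " ")),
    '        </DataArray>',
    '        <DataArray type="Int32" Name="offsets" format="ascii">',
    paste0("          ", paste(offsets, collapse = " ")),
    '        </DataArray>',
    '        <DataArray type="UInt8" Name="types" format="ascii">',
    paste0("          ", paste(types, collapse = " ")),
    '        </DataArray>',
    '      </Cells>',
    '      <CellData>',
    '        <DataArray type="Int32" Name="subdomain" format="ascii">',
    paste0("          ", paste(subdomain, collapse = " ")),
    '        </DataArray>',
    '        <DataArray type="Int32" Name="boundary" format="ascii">',
    paste0("          ", paste(boundary, collapse = " ")),
    '        </DataArray>',
    '      </CellData>',
    '    </Piece>',
    '  </UnstructuredGrid>',
    '</VTKFile>')
  writeLines(xml, path)
}

.read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  num <- function(node) scan(text = xml2::xml_text(node), quiet = TRUE)
  arr <- function(xpath) {
    node <- xml2::xml_find_first(piece, xpath)
    if (inherits(node, "xml_missing")) NULL else num(node)
  }
  pts <- arr(".//Points/DataArray")
  verts <- matrix(pts, ncol = 3L, byrow = TRUE)
  conn <- as.integer(arr(".//Cells/DataArray[@Name='connectivity']")) + 1L
  offsets <- as.integer(arr(".//Cells/DataArray[@Name='offsets']"))
  types <- as.integer(arr(".//Cells/DataArray[@Name='types']"))
  subdomain <- arr(".//CellData/DataArray[@Name='subdomain']")
  boundary <- arr(".//CellData/DataArray[@Name='boundary']")
  starts <- c(1L, head(offsets, -1L) + 1L)
  is_tet <- types == 10L
  is_tri <- types == 5L
  cells <- if (any(is_tet))
    matrix(conn[as.vector(t(cbind(starts[is_tet], starts[is_tet] + 1L,
                                  starts[is_tet] + 2L, starts[is_tet] + 3L)))],
           ncol = 4L, byrow = TRUE) else NULL
  facets <- if (any(is_tri))
    matrix(conn[as.vector(t(cbind(starts[is_tri], starts[is_tri] + 1L,
                                  starts[is_tri] + 2L)))],
           ncol = 3L, byrow = TRUE) else matrix(integer(0), 0, 3)
  list(vertices = verts, cells = cells,
       cell_label = if (!is.null(subdomain)) as.integer(subdomain[is_tet]) else NULL,
       facets = facets,
       facet_label = if (!is.null(boundary) && any(is_tri))
         as.integer(boundary[is_tri]) else NULL)
}

# ---- XDMF -------------------------------------------------------------------

# Single-file XDMF with inline (XML) data items: a volume grid with the
# "subdomain" cell attribute and a boundary grid with the "boundary" cell
# attribute, sharing one XYZ geometry.
.write_xdmf <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$cells); nf <- nrow(mesh$facets)
  geom <- paste(.fmt_coord(mesh$vertices[, 1]), .fmt_coord(mesh$vertices[, 2]),
                .fmt_coord(mesh$vertices[, 3]))
  geom_block <- c(
    sprintf('      <Geometry GeometryType="XYZ"><DataItem Dimensions="%d 3" Format="XML">', nv),
    paste0("        ", geom),
    '      </DataItem></Geometry>')
  xml <- c(
    '<?xml version="1.0"?>',
    '<Xdmf Version="3.0">',
    '  <Domain>',
    '    <Grid Name="volume">',
    sprintf('      <Topology TopologyType="Tetrahedron" NumberOfElements="%d"><DataItem Dimensions="%d 4" Format="XML">', nt, nt),
    paste0("        ", apply(mesh$cells - 1L, 1L, paste, collapse = " ")),
    '      </DataItem></Topology>',
    geom_block,
    sprintf('      <Attribute Name="subdomain" Center="Cell"><DataItem Dimensions="%d" Format="XML">', nt),
    paste0("        ", paste(mesh$cell_label, collapse = " ")),
    '      </DataItem></Attribute>',
    '    </Grid>',
    '    <Grid Name="boundary">',
    sprintf('      <Topology TopologyType="Triangle" NumberOfElements="%d"><DataItem Dimensions="%d 3" Format="XML">', nf, nf),
    paste0("        ", apply(mesh$facets - 1L, 1L, paste, collapse = " ")),
    '      </DataItem></Topology>',
    geom_block,
    sprintf('      <Attribute Name="boundary" Center="Cell"><DataItem Dimensions="%d" Format="XML">', nf),
    paste0("        ", paste(mesh$facet_label, collapse = " ")),
    '      </DataItem></Attribute>',
    '    </Grid>',
    '  </Domain>',
    '</Xdmf>')
  writeLines(xml, path)
}

.read_xdmf <- function(path) {
  doc <- xml2::read_xml(path)
  num <- function(node) scan(text = xml2::xml_text(node), quiet = TRUE)
  vol <- xml2::xml_find_first(doc, ".//Grid[@Name='volume']")
  bnd <- xml2::xml_find_first(doc, ".//Grid[@Name='boundary']")
  if (inherits(vol, "xml_missing")) stop("XDMF file lacks the 'volume' grid")
  verts <- matrix(num(xml2::xml_find_first(vol, ".//Geometry/DataItem")),
                  ncol = 3L, byrow = TRUE)
  cells <- matrix(as.integer(num(xml2::xml_find_first(vol, ".//Topology/DataItem"))),
                  ncol = 4L, byrow = TRUE) + 1L
  sub_node <- xml2::xml_find_first(vol, ".//Attribute[@Name='subdomain']/DataItem")
  cell_label <- if (inherits(sub_node, "xml_missing")) NULL else as.integer(num(sub_node))
  facets <- matrix(integer(0), 0, 3); facet_label <- NULL
  if (!inherits(bnd, "xml_missing")) {
    facets <- matrix(as.integer(num(xml2::xml_find_first(bnd, ".//Topology/DataItem"))),
                     ncol = 3L, byrow = TRUE) + 1L
    lab_node <- xml2::xml_find_first(bnd, ".//Attribute[@Name='boundary']/DataItem")
    facet_label <- if (inherits(lab_node, "xml_missing")) NULL else as.integer(num(lab_node))
  }
  list(vertices = verts, cells = cells, cell_label = cell_label,
       facets = facets, facet_label = facet_label)
}
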