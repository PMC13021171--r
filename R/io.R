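# Model and state serialization: legacy-VTK unstructured grids for states,
# JSON run files for configurations, and a minimal FEBio-format export of an
# assembled model for cross-validation in an external solver (write-only).

#' Write a tetrahedral state snapshot as a legacy VTK unstructured grid
#'
#' ASCII legacy VTK with point displacement vectors and cell arrays for
#' region id, Jacobian and equivalent strain (when a state is given).
#'
#' @param model an `fe_model` or `tet_model`.
#' @param path output file (.vtk).
#' @param state optional converged `sim_state`.
#' @return the path, invisibly.
#' @export
write_vtk <- function(model, path, state = NULL) {
  if (inherits(model, "fe_model")) {
    nodes <- model$mesh$nodes
    elems <- model$mesh$elements
    region <- model$mesh$region
  } else {
    nodes <- model$nodes; elems <- model$elements; region <- model$region
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "neotongue state snapshot", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(nodes))), con)
  writeLines(apply(nodes, 1, function(r) paste(format(r, digits = 10),
                                               collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", nrow(elems), 5 * nrow(elems)), con)
  writeLines(apply(elems - 1L, 1, function(r)
    paste(c(4L, r), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(elems)), con)
  writeLines(rep("10", nrow(elems)), con)
  if (!is.null(state)) {
    u <- matrix(state$u, ncol = 3, byrow = TRUE)[seq_len(nrow(nodes)), ,
                                                 drop = FALSE]
    writeLines(sprintf("POINT_DATA %d", nrow(nodes)), con)
    writeLines("VECTORS displacement double", con)
    writeLines(apply(u, 1, function(r) paste(format(r, digits = 10),
                                             collapse = " ")), con)
    if (!is.null(state$fields)) {
      writeLines(sprintf("CELL_DATA %d", nrow(elems)), con)
      writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
      writeLines(as.character(as.integer(factor(region))), con)
      writeLines(c("SCALARS jacobian double 1", "LOOKUP_TABLE default"), con)
      writeLines(format(state$fields[, 7], digits = 8), con)
      eq <- vapply(seq_len(nrow(state$fields)), function(e) {
        v <- state$fields[e, 1:6]
        equivalent_strain(matrix(v[c(1, 4, 5, 4, 2, 6, 5, 6, 3)], 3, 3))
      }, numeric(1))
      writeLines(c("SCALARS eq_strain double 1", "LOOKUP_TABLE default"), con)
      writeLines(format(eq, digits = 8), con)
    }
  }
  invisible(path)
}

#' Write a surface mesh as ASCII STL
#'
#' @param mesh a `surface_mesh`.
#' @param path output file (.stl).
#' @param name solid name.
#' @return the path, invisibly.
#' @export
write_stl <- function(mesh, path, name = "surface") {
  V <- mesh$vertices; Tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  for (t in seq_len(nrow(Tr))) {
    a <- V[Tr[t, 1], ]; b <- V[Tr[t, 2], ]; d <- V[Tr[t, 3], ]
    n <- c((b[2] - a[2]) * (d[3] - a[3]) - (b[3] - a[3]) * (d[2] - a[2]),
           (b[3] - a[3]) * (d[1] - a[1]) - (b[1] - a[1]) * (d[3] - a[3]),
           (b[1] - a[1]) * (d[2] - a[2]) - (b[2] - a[2]) * (d[1] - a[1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(sprintf("  facet normal %g %g %g", n[1], n[2], n[3]), con)
    writeLines("    outer loop", con)
    for (p in list(a, b, d))
      writeLines(sprintf("      vertex %g %g %g", p[1], p[2], p[3]), con)
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Read an ASCII STL surface
#'
#' @param path .stl file path.
#' @param tol vertex-merge tolerance (mm).
#' @return a `surface_mesh`.
#' @export
read_stl <- function(path, tol = 1e-8) {
  ln <- readLines(path)
  vl <- grep("^\\s*vertex", ln, value = TRUE)
  pts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  key <- apply(round(pts / max(tol, 1e-12)) * tol, 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  verts <- pts[!duplicated(key), , drop = FALSE]
  tris <- matrix(uid, ncol = 3, byrow = TRUE)
  surface_mesh(verts, tris)
}

#' Serialize / restore a run configuration as JSON
#'
#' @param cfg a [run_config].
#' @param path JSON file path.
#' @return `write_run_config` returns the path; `read_run_config` a
#'   [run_config].
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Export an assembled model in FEBio input format
#'
#' Minimal write-only `.feb` (FEBio 3 spec layout) export of the mesh,
#' materials and fixed boundary for cross-checking the assembled model in
#' an external solver; discrete suture elements are exported as comments.
#'
#' @param model an `fe_model`.
#' @param path output file (.feb).
#' @return the path, invisibly.
#' @export
write_febio <- function(model, path) {
  nodes <- model$mesh$nodes
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="ISO-8859-1"?>')
  w('<febio_spec version="3.0">')
  w('  <Material>')
  for (i in seq_along(model$materials)) {
    m <- model$materials[[i]]; he <- m$hyperelastic
    if (he$model == "yeoh") {
      w('    <material id="%d" name="%s" type="uncoupled solid mixture">',
        i, m$label)
      w('      <!-- Yeoh c = (%s) kPa, k = %g kPa -->',
        paste(he$c, collapse = ", "), he$k)
    } else {
      w('    <material id="%d" name="%s" type="Ogden">', i, m$label)
      w('      <!-- c = (%s) kPa, m = (%s), k = %g kPa -->',
        paste(he$c, collapse = ", "), paste(he$m, collapse = ", "), he$k)
      for (t in seq_along(he$c)) {
        w('      <c%d>%g</c%d>', t, he$c[t], t)
        w('      <m%d>%g</m%d>', t, he$m[t], t)
      }
      w('      <k>%g</k>', he$k)
    }
    w('    </material>')
  }
  w('  </Material>')
  w('  <Mesh>')
  w('    <Nodes name="all">')
  for (i in seq_len(nrow(nodes)))
    w('      <node id="%d">%g,%g,%g</node>', i, nodes[i, 1], nodes[i, 2],
      nodes[i, 3])
  w('    </Nodes>')
  regs <- unique(model$mesh$region)
  for (r in regs) {
    w('    <Elements type="tet4" name="%s">', r)
    idx <- which(model$mesh$region == r)
    for (e in idx)
      w('      <elem id="%d">%s</elem>', e,
        paste(model$mesh$elements[e, ], collapse = ","))
    w('    </Elements>')
  }
  if (length(model$fixed)) {
    w('    <NodeSet name="fixed">')
    w('      %s', paste(model$fixed, collapse = ","))
    w('    </NodeSet>')
  }
  w('  </Mesh>')
  w('  <Boundary>')
  w('    <bc type="fix" node_set="fixed"><dofs>x,y,z</dofs></bc>')
  w('  </Boundary>')
  w('</febio_spec>')
  invisible(path)
}

#' Write node and element sets as a JSON sidecar
#'
#' Companion file for mesh exports (STL / VTK carry no set information):
#' records the named node sets and per-element region tags.
#'
#' @param model a `tet_model`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_sets_json <- function(model, path) {
  jsonlite::write_json(
    list(node_sets = model$node_sets,
         region = model$region),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
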