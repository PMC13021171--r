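#' Triangulated surface mesh
#'
#' @param vertices n x 3 numeric matrix of points (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex triplets.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(triangles) == 3L)
  if (nrow(triangles))
    stopifnot(min(triangles) >= 1L, max(triangles) <= nrow(vertices))
  structure(list(vertices = vertices, triangles = triangles),
            class = "surface_mesh")
}

#' Labeled tetrahedral model
#'
#' Four-node tetrahedra with per-element region tags and named node sets.
#' All elements must be positively oriented.
#'
#' @param nodes n x 3 numeric matrix (mm).
#' @param elements m x 4 integer connectivity (1-based).
#' @param region character vector of per-element region tags
#'   (`native`, `skin`, `adipose`, ...).
#' @param node_sets named list of integer node-index vectors.
#' @param validate check element orientation (default TRUE).
#' @return An object of class `tet_model`.
#' @export
tet_model <- function(nodes, elements, region = rep("native", nrow(elements)),
                      node_sets = list(), validate = TRUE) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  elements <- as.matrix(elements); storage.mode(elements) <- "integer"
  stopifnot(ncol(nodes) == 3L, ncol(elements) == 4L,
            length(region) == nrow(elements),
            min(elements) >= 1L, max(elements) <= nrow(nodes))
  if (length(node_sets))
    stopifnot(all(unlist(node_sets) >= 1L),
              all(unlist(node_sets) <= nrow(nodes)))
  m <- structure(list(nodes = nodes, elements = elements,
                      region = as.character(region), node_sets = node_sets),
                 class = "tet_model")
  if (validate) {
    v <- tet4_volumes(nodes, elements)
    if (any(v <= 0))
      stop("inverted elements: ", paste(head(which(v <= 0), 10), collapse = ", "))
  }
  m
}

#' @export
print.tet_model <- function(x, ...) {
  cat(sprintf("<tet_model> %d nodes, %d tet4 elements\n",
              nrow(x$nodes), nrow(x$elements)))
  cat("  regions:", paste(sprintf("%s (%d)", names(table(x$region)),
                                  table(x$region)), collapse = ", "), "\n")
  if (length(x$node_sets))
    cat("  node sets:", paste(sprintf("%s (%d)", names(x$node_sets),
                                      lengths(x$node_sets)), collapse = ", "),
        "\n")
  invisible(x)
}

# Signed tet4 volumes, vectorized.
tet4_volumes <- function(nodes, elements) {
  a <- nodes[elements[, 1], , drop = FALSE]
  v1 <- nodes[elements[, 2], , drop = FALSE] - a
  v2 <- nodes[elements[, 3], , drop = FALSE] - a
  v3 <- nodes[elements[, 4], , drop = FALSE] - a
  (v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
   v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
   v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}

#' Mesh volume
#'
#' Signed-volume sum: over tetrahedra for a `tet_model` (error on inverted
#' elements), over origin-cones for a closed `surface_mesh`.
#'
#' @param x a `tet_model` or `surface_mesh`.
#' @return Volume (mm^3).
#' @export
mesh_volume <- function(x) UseMethod("mesh_volume")

#' @export
mesh_volume.tet_model <- function(x) {
  v <- tet4_volumes(x$nodes, x$elements)
  if (any(v <= 0))
    stop("inverted elements: ", paste(head(which(v <= 0), 10), collapse = ", "))
  sum(v)
}

#' @export
mesh_volume.surface_mesh <- function(x) {
  a <- x$vertices[x$triangles[, 1], , drop = FALSE]
  b <- x$vertices[x$triangles[, 2], , drop = FALSE]
  d <- x$vertices[x$triangles[, 3], , drop = FALSE]
  v <- sum(a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
           a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
           a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
  if (v <= 0) stop("non-positive enclosed volume: check surface orientation")
  v
}

# Boundary faces of a tet mesh with outward orientation (for positive tets).
boundary_faces <- function(elements) {
  f <- rbind(elements[, c(2, 3, 4)], elements[, c(1, 4, 3)],
             elements[, c(1, 2, 4)], elements[, c(1, 3, 2)])
  key <- apply(f, 1, function(r) paste(sort(r), collapse = "-"))
  tab <- table(key)
  bnd <- names(tab)[tab == 1L]
  f[key %in% bnd, , drop = FALSE]
}

#' Extract the boundary surface of a tetrahedral model
#'
#' @param model a `tet_model`.
#' @param drop_nodes optional integer vector: faces whose three corners all
#'   lie in this set are excluded (used to strip interface patches).
#' @return A `surface_mesh` using the model's node coordinates (re-indexed to
#'   the referenced vertices), with attribute `node_map` giving the original
#'   node index of each surface vertex.
#' @export
extract_surface <- function(model, drop_nodes = NULL) {
  f <- boundary_faces(model$elements)
  if (!is.null(drop_nodes) && length(drop_nodes)) {
    keep <- !(f[, 1] %in% drop_nodes & f[, 2] %in% drop_nodes &
              f[, 3] %in% drop_nodes)
    f <- f[keep, , drop = FALSE]
  }
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(model$nodes))
  remap[used] <- seq_along(used)
  sm <- surface_mesh(model$nodes[used, , drop = FALSE],
                     matrix(remap[f], ncol = 3))
  attr(sm, "node_map") <- used
  sm
}

#' Deterministic quasi-uniform surface sampling
#'
#' Allocates sample counts to triangles proportionally to area (largest
#' remainder) and fills each triangle with a low-discrepancy barycentric
#' pattern; fully deterministic.
#'
#' @param mesh a `surface_mesh`.
#' @param n total number of samples (at least one per triangle is not
#'   guaranteed; tiny triangles may receive none).
#' @return n x 3 matrix of points.
#' @export
sample_surface <- function(mesh, n = 10000L) {
  V <- mesh$vertices; Tr <- mesh$triangles
  a <- V[Tr[, 1], , drop = FALSE]
  ab <- V[Tr[, 2], , drop = FALSE] - a
  ac <- V[Tr[, 3], , drop = FALSE] - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  quota <- n * area / sum(area)
  ni <- floor(quota)
  rem <- n - sum(ni)
  if (rem > 0) {
    extra <- order(quota - ni, decreasing = TRUE)[seq_len(rem)]
    ni[extra] <- ni[extra] + 1
  }
  phi <- (sqrt(5) - 1) / 2
  out <- matrix(0, n, 3)
  pos <- 0L
  for (t in which(ni > 0)) {
    k <- seq_len(ni[t])
    u <- (k - 0.5) / ni[t]
    v <- (k * phi) %% 1
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
    pts <- a[rep(t, ni[t]), , drop = FALSE] + u * ab[rep(t, ni[t]), ] +
      v * ac[rep(t, ni[t]), ]
    out[pos + k, ] <- pts
    pos <- pos + ni[t]
  }
  out[seq_len(pos), , drop = FALSE]
}

#' Percentile Hausdorff distance between two surfaces
#'
#' Samples both surfaces quasi-uniformly, computes the point-to-surface
#' distance distribution in each direction, takes the `q`-quantile of each,
#' and (for the symmetric variant) returns the larger of the two. `q = 1`
#' recovers the classic (sampled) Hausdorff distance. The 99th percentile is
#' the robust anatomical-deviation metric: it discards isolated spikes from
#' mesh irregularities while retaining the largest regional deviation.
#'
#' @param a,b `surface_mesh` objects in a common coordinate frame.
#' @param q percentile in (0, 1].
#' @param n_samples samples per surface (default 10000).
#' @param direction `"symmetric"` (default), `"a_to_b"`, or `"b_to_a"`.
#' @return Distance (mm).
#' @export
hausdorff_percentile <- function(a, b, q = 0.99, n_samples = 10000L,
                                 direction = c("symmetric", "a_to_b",
                                               "b_to_a")) {
  direction <- match.arg(direction)
  stopifnot(inherits(a, "surface_mesh"), inherits(b, "surface_mesh"),
            q > 0, q <= 1)
  if (nrow(a$triangles) == 0L || nrow(b$triangles) == 0L)
    stop("empty surface mesh")
  d_ab <- function() {
    p <- sample_surface(a, n_samples)
    quantile(.point_surface_dist(p, b$vertices, b$triangles), q, names = FALSE)
  }
  d_ba <- function() {
    p <- sample_surface(b, n_samples)
    quantile(.point_surface_dist(p, a$vertices, a$triangles), q, names = FALSE)
  }
  switch(direction,
         symmetric = max(d_ab(), d_ba()),
         a_to_b = d_ab(),
         b_to_a = d_ba())
}

#' Place equally spaced suture points on a closed polyline
#'
#' Targets a clinically motivated inter-suture spacing: the count is the
#' perimeter divided by the spacing, rounded to the nearest integer (minimum
#' three), and the points are then re-spaced exactly equally by arc length
#' starting at the polyline start.
#'
#' @param polyline k x 3 matrix whose last row repeats the first (closed).
#' @param spacing target spacing (mm), default 5.
#' @return Matrix of suture points with attribute `arc_spacing`.
#' @export
place_suture_points <- function(polyline, spacing = 5) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 4 ||
      max(abs(polyline[1, ] - polyline[nrow(polyline), ])) > 1e-9)
    stop("polyline must be closed (first point repeated at the end)")
  seg <- sqrt(rowSums(diff(polyline)^2))
  L <- sum(seg)
  if (L <= spacing) stop("polyline shorter than one spacing interval")
  n <- max(3L, as.integer(round(L / spacing)))
  s_target <- (seq_len(n) - 1) * L / n
  s_cum <- c(0, cumsum(seg))
  pts <- t(vapply(s_target, function(s) {
    i <- findInterval(s, s_cum, rightmost.closed = TRUE)
    i <- min(i, length(seg))
    f <- (s - s_cum[i]) / seg[i]
    polyline[i, ] + f * (polyline[i + 1, ] - polyline[i, ])
  }, numeric(3)))
  attr(pts, "arc_spacing") <- L / n
  pts
}

#' Surface nodes within a radius of a suture point
#'
#' All boundary-surface nodes of the model within Euclidean distance
#' `radius` of `center`. Distributing each suture force over such a cluster
#' (rather than a single node) avoids artificial stress concentrations.
#'
#' @param model a `tet_model`.
#' @param center length-3 point (mm).
#' @param radius cluster radius (mm), default 2.
#' @param surface_nodes optional precomputed surface node indices.
#' @return Integer vector of node indices.
#' @export
cluster_nodes <- function(model, center, radius = 2, surface_nodes = NULL) {
  stopifnot(radius > 0, length(center) == 3)
  if (is.null(surface_nodes))
    surface_nodes <- sort(unique(as.vector(boundary_faces(model$elements))))
  d2 <- colSums((t(model$nodes[surface_nodes, , drop = FALSE]) -
                   as.numeric(center))^2)
  hit <- surface_nodes[d2 <= radius^2]
  if (!length(hit))
    stop(sprintf(paste("empty suture cluster at (%.2f, %.2f, %.2f):",
                       "mesh too coarse for radius %g mm"),
                 center[1], center[2], center[3], radius))
  hit
}

# --- structured toy anatomy -------------------------------------------------

# Smooth cube-to-ellipsoid map on [-1,1]^3 (identity for shape = "box").
param_to_space <- function(p, semi, shape) {
  if (shape == "box") return(sweep(p, 2, semi, `*`))
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  q <- cbind(
    x * sqrt(pmax(1 - y^2 / 2 - z^2 / 2 + y^2 * z^2 / 3, 0.02)),
    y * sqrt(pmax(1 - x^2 / 2 - z^2 / 2 + x^2 * z^2 / 3, 0.02)),
    z * sqrt(pmax(1 - x^2 / 2 - y^2 / 2 + x^2 * y^2 / 3, 0.02)))
  sweep(q, 2, semi, `*`)
}

# Kuhn 6-tet subdivision of the unit hex (corner bits x fastest); conforming
# under translation.
kuhn_tets <- matrix(c(
  1, 2, 4, 8,
  1, 4, 3, 8,
  1, 3, 7, 8,
  1, 7, 5, 8,
  1, 5, 6, 8,
  1, 6, 2, 8), ncol = 4, byrow = TRUE)

# Resection score per case style; higher = removed first. u anterior(-) to
# posterior(+), v lateral, w inferior(-) to superior(+), all in [-1,1].
case_score <- function(style, u, v, w) {
  switch(style,
         A = v - 1.5 * pmax(0, -u - 0.45),       # tip-sparing lateral
         B = v,                                   # full lateral
         C = v + 0.45 * u,                        # posteriorly extended
         D = 0.75 * v - 0.45 * u + 0.12,          # midline-crossing anterior
         stop("unknown case style: ", style))
}

#' Generate a toy tongue anatomy with a planned resection
#'
#' Builds a convex tongue-like solid (a smoothly mapped structured
#' tetrahedral grid), selects a case-style-dependent contiguous element set
#' as the resection, and returns the resected tongue, the resection solid,
#' both surfaces, and the fixed attachment node set on the inferior face
#' (mimicking the mandible / hyoid muscular attachments). Because the
#' resection is an exact element partition, resected + resection volumes add
#' up to the tongue volume to machine precision.
#'
#' Case styles qualitatively mirror common glossectomy patterns: `A`
#' tip-sparing lateral, `B` full lateral, `C` posteriorly extended lateral,
#' `D` asymmetric midline-crossing; no anatomical fidelity is claimed.
#'
#' @param case_style one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param fraction resection volume fraction in (0, 0.6].
#' @param dims tongue bounding dimensions (mm), length/width/height.
#' @param divisions grid divisions per axis (elements = 6 * prod(divisions)).
#' @param shape `"ellipsoid"` (smooth convex solid) or `"box"` (prismatic,
#'   exact slab arithmetic; used by volume-bookkeeping checks).
#' @param seed integer; the generator is deterministic, the seed is recorded
#'   in the output for provenance.
#' @param skin_layer thickness (mm) of the graded outermost lateral grid
#'   layer (the flap's skin shell).
#' @param refine nested-refinement factor: each coarse cell is subdivided
#'   `refine` times per axis while the resection is still selected at the
#'   coarse level, so all refinements mesh the same parametric geometry
#'   (used by mesh-convergence studies).
#' @return List of class `toy_anatomy`.
#' @export
generate_toy_anatomy <- function(case_style = "A", fraction = 0.25,
                                 dims = c(60, 50, 40),
                                 divisions = c(8, 7, 6),
                                 shape = c("ellipsoid", "box"),
                                 seed = 1L, skin_layer = 2.5,
                                 refine = 1L) {
  shape <- match.arg(shape)
  refine <- as.integer(refine)
  stopifnot(fraction > 0, fraction <= 0.6, all(divisions >= 3), refine >= 1)
  # coarse knot vectors; graded lateral (+y) spacing so the outermost layer
  # is one skin thickness and the flap's skin is a genuinely thin shell
  y_last <- 1 - min(0.5, skin_layer / (dims[2] / 2))
  gx_c <- seq(-1, 1, length.out = divisions[1] + 1L)
  gy_c <- c(seq(-1, y_last, length.out = divisions[2]), 1)
  gz_c <- seq(-1, 1, length.out = divisions[3] + 1L)
  # nested refinement subdivides each coarse interval; the resection is
  # always selected at the coarse level, so every refinement meshes the
  # same parametric geometry
  subdivide <- function(g) {
    if (refine == 1L) return(g)
    out <- unlist(lapply(seq_len(length(g) - 1), function(i)
      seq(g[i], g[i + 1], length.out = refine + 1L)[-(refine + 1L)]))
    c(out, g[length(g)])
  }
  gx <- subdivide(gx_c); gy <- subdivide(gy_c); gz <- subdivide(gz_c)
  divisions_f <- divisions * refine
  nd <- divisions_f + 1L
  ijk <- as.matrix(expand.grid(i = seq_len(nd[1]), j = seq_len(nd[2]),
                               k = seq_len(nd[3]), KEEP.OUT.ATTRS = FALSE))
  param <- cbind(gx[ijk[, 1]], gy[ijk[, 2]], gz[ijk[, 3]])
  nid <- function(i, j, k) (k - 1L) * nd[1] * nd[2] + (j - 1L) * nd[1] + i
  nodes <- param_to_space(param, dims / 2, shape)

  hexes <- as.matrix(expand.grid(i = seq_len(divisions_f[1]),
                                 j = seq_len(divisions_f[2]),
                                 k = seq_len(divisions_f[3]),
                                 KEEP.OUT.ATTRS = FALSE))
  corner <- function(h, bx, by, bz) nid(h[, 1] + bx, h[, 2] + by, h[, 3] + bz)
  hx <- cbind(corner(hexes, 0, 0, 0), corner(hexes, 1, 0, 0),
              corner(hexes, 0, 1, 0), corner(hexes, 1, 1, 0),
              corner(hexes, 0, 0, 1), corner(hexes, 1, 0, 1),
              corner(hexes, 0, 1, 1), corner(hexes, 1, 1, 1))
  elems <- do.call(rbind, lapply(seq_len(nrow(kuhn_tets)), function(t)
    hx[, kuhn_tets[t, ], drop = FALSE]))
  v <- tet4_volumes(nodes, elems)
  flip <- v < 0
  if (any(flip))
    elems[flip, c(3, 4)] <- elems[flip, c(4, 3)]
  v <- abs(v)
  elem_hex <- rep(seq_len(nrow(hexes)), times = nrow(kuhn_tets))

  # resection selection on COARSE hex centroids (all children of a coarse
  # cell, and all 6 tets of each fine hex, move together)
  parent <- cbind((hexes[, 1] - 1L) %/% refine + 1L,
                  (hexes[, 2] - 1L) %/% refine + 1L,
                  (hexes[, 3] - 1L) %/% refine + 1L)
  pid <- (parent[, 3] - 1L) * divisions[1] * divisions[2] +
    (parent[, 2] - 1L) * divisions[1] + parent[, 1]
  coarse <- as.matrix(expand.grid(i = seq_len(divisions[1]),
                                  j = seq_len(divisions[2]),
                                  k = seq_len(divisions[3]),
                                  KEEP.OUT.ATTRS = FALSE))
  hc <- cbind((gx_c[coarse[, 1]] + gx_c[coarse[, 1] + 1]) / 2,
              (gy_c[coarse[, 2]] + gy_c[coarse[, 2] + 1]) / 2,
              (gz_c[coarse[, 3]] + gz_c[coarse[, 3] + 1]) / 2)
  score <- case_score(case_style, hc[, 1], hc[, 2], hc[, 3])
  elem_coarse <- pid[elem_hex]
  coarse_vol <- vapply(seq_len(nrow(coarse)), function(h)
    sum(v[elem_coarse == h]), numeric(1))
  ord <- order(score, decreasing = TRUE)
  cum <- cumsum(coarse_vol[ord])
  target <- fraction * sum(coarse_vol)
  ncut <- which.min(abs(cum - target))
  cut_hex <- ord[seq_len(ncut)]
  removed <- elem_coarse %in% cut_hex

  sub_model <- function(keep, region) {
    el <- elems[keep, , drop = FALSE]
    used <- sort(unique(as.vector(el)))
    remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
    list(model = tet_model(nodes[used, , drop = FALSE],
                           matrix(remap[el], ncol = 4),
                           region = rep(region, sum(keep))),
         orig_nodes = used)
  }
  kept <- sub_model(!removed, "native")
  cut <- sub_model(removed, "adipose")

  # interface: nodes shared by kept and removed elements
  iface_orig <- intersect(kept$orig_nodes[unique(as.vector(
    kept$model$elements))], cut$orig_nodes)
  iface_orig <- intersect(unique(as.vector(elems[!removed, ])),
                          unique(as.vector(elems[removed, ])))
  resected <- kept$model
  resected$node_sets$interface <-
    match(iface_orig, kept$orig_nodes)
  # attachment: inferior-face nodes of the resected tongue
  att <- which(param[kept$orig_nodes, 3] <= -1 + 1e-9)
  if (!length(att)) stop("meshing failure: empty attachment set")
  resected$node_sets$attachment <- att

  resection_model <- cut$model
  resection_model$node_sets$interface <- match(iface_orig, cut$orig_nodes)

  tongue_surface <- extract_surface(
    tet_model(nodes, elems, validate = FALSE))
  resection_surface <- extract_surface(resection_model)

  dir_raw <- colMeans(nodes[cut$orig_nodes, , drop = FALSE]) -
    colMeans(nodes)
  thick_dir <- dir_raw / sqrt(sum(dir_raw^2))

  structure(list(
    resected = resected, resection_model = resection_model,
    tongue_surface = tongue_surface, resection_surface = resection_surface,
    resected_orig_nodes = kept$orig_nodes,
    resection_orig_nodes = cut$orig_nodes,
    interface_orig = iface_orig,
    param = param, node_ijk = ijk, grid = list(gx = gx, gy = gy, gz = gz),
    dims = dims, divisions = divisions, refine = refine, shape = shape,
    case_style = case_style, fraction = fraction, seed = as.integer(seed),
    thickness_dir = thick_dir,
    tongue_volume = sum(v), resection_volume = sum(v[removed])),
    class = "toy_anatomy")
}

#' @export
print.toy_anatomy <- function(x, ...) {
  cat(sprintf(
    "<toy_anatomy> case %s, %s, resection %.1f%% of %.0f mm^3 tongue\n",
    x$case_style, x$shape, 100 * x$resection_volume / x$tongue_volume,
    x$tongue_volume))
  invisible(x)
}

#' Build a two-layer flap congruent with the resection cavity
#'
#' Copies the resection solid as an independent body, splits it into an
#' outer skin layer (elements within `skin_thickness` of the original tongue
#' exterior) and an inner adipose core, and applies overbulking by scaling
#' the adipose layer along the flap's thickness direction. The scaling
#' factor is solved so the adipose volume increases by exactly
#' `(1 + overbulk_level)`; skin is shifted rigidly outward so its volume is
#' (near-)unchanged and the interface with the recipient site remains
#' node-congruent.
#'
#' Overbulking is the enlargement of the flap's stress-free adipose
#' configuration; two equivalent realizations are offered. The default
#' (`realize = "growth"`) keeps the mesh congruent with the resection and
#' records the overbulk level as a kinematic growth prestretch along the
#' flap thickness direction, applied by the simulation pipeline; the skin
#' paddle dimensions are untouched, mirroring the clinical practice of
#' thickening only the subcutaneous layer. With `realize = "geometry"` the
#' enlargement is materialized geometrically: the standalone flap, pinned
#' at its interface, is inflated by the same thickness-direction growth and
#' relaxed to equilibrium with a soft surrogate material, and the deformed
#' mesh is returned (growth stretch calibrated so the adipose volume
#' increases by exactly `1 + overbulk_level`).
#'
#' @param anatomy a `toy_anatomy`.
#' @param skin_thickness skin layer thickness (mm), default 2.5.
#' @param overbulk_level adipose bulk-increase fraction, >= 0
#'   (the factorial levels are 0, 0.222, 0.444, 0.667, 0.889).
#' @param realize `"growth"` (congruent mesh + recorded prestretch) or
#'   `"geometry"` (inflated mesh).
#' @return A `tet_model` with regions `skin` / `adipose`, node sets
#'   `interface` (congruent with the recipient cut surface) and attributes
#'   `recipient_interface_orig` (original grid ids of interface nodes),
#'   `overbulk_level`, `thickness_dir` and `adipose_volume0`.
#' @export
build_flap <- function(anatomy, skin_thickness = 2.5, overbulk_level = 0,
                       realize = c("growth", "geometry")) {
  realize <- match.arg(realize)
  stopifnot(inherits(anatomy, "toy_anatomy"), skin_thickness > 0)
  if (overbulk_level < 0) stop("overbulk_level must be non-negative")
  fl <- anatomy$resection_model
  orig <- anatomy$resection_orig_nodes
  iface <- fl$node_sets$interface

  # skin = elements near the original tongue exterior
  outer_faces_all <- boundary_faces(fl$elements)
  on_iface <- outer_faces_all[, 1] %in% iface &
    outer_faces_all[, 2] %in% iface & outer_faces_all[, 3] %in% iface
  outer <- outer_faces_all[!on_iface, , drop = FALSE]
  if (!nrow(outer)) stop("resection has no exterior patch")
  used <- sort(unique(as.vector(outer)))
  remap <- integer(nrow(fl$nodes)); remap[used] <- seq_along(used)
  outer_surf <- surface_mesh(fl$nodes[used, , drop = FALSE],
                             matrix(remap[outer], ncol = 3))
  cent <- (fl$nodes[fl$elements[, 1], ] + fl$nodes[fl$elements[, 2], ] +
           fl$nodes[fl$elements[, 3], ] + fl$nodes[fl$elements[, 4], ]) / 4
  dist_out <- .point_surface_dist(cent, outer_surf$vertices,
                                  outer_surf$triangles)
  region <- ifelse(dist_out <= skin_thickness, "skin", "adipose")
  if (!any(region == "adipose"))
    stop("skin_thickness consumes the whole flap; no adipose core left")
  fl$region <- region

  # Overbulking is realized mechanically: the standalone flap, pinned at its
  # (future) interface, is inflated by positive isotropic kinematic growth
  # of the adipose core and relaxed to hyperelastic equilibrium, so the
  # extra bulk distributes along the local thickness direction and no
  # element can invert. The growth stretch is calibrated so the adipose
  # volume increases by exactly (1 + overbulk_level).
  v0 <- tet4_volumes(fl$nodes, fl$elements)
  v_adip0 <- sum(v0[fl$region == "adipose"])
  if (overbulk_level > 0 && realize == "geometry") {
    # soft surrogate materials for the morph: the inflation is a geometric
    # step, not a mechanical prediction, and must not be locked by the donor
    # skin's strong strain stiffening. The skin surrogate is nearly
    # incompressible so the skin layer carries its volume along unchanged;
    # the adipose surrogate is compliant and compressible so the growth can
    # realize freely.
    fl$node_sets$interface <- iface
    mats <- list(adipose = nt_material(yeoh_params(0.3, 3), NULL, "morph"),
                 skin = nt_material(yeoh_params(1.0, 500), NULL, "morph"))
    mod <- fe_model(fl, mats, fixed_sets = "interface",
                    gravity = c(0, 0, 0))
    setts <- solver_settings(tol_rel = 1e-6, max_iter = 40L)
    targ <- (1 + overbulk_level) * v_adip0
    solve_at <- function(lg, state, n_ramp) {
      lg_seq <- if (n_ramp > 1) seq(1, lg, length.out = n_ramp + 1)[-1] else lg
      for (l in lg_seq) {
        mod_l <- apply_growth(mod, "adipose", 1,
                              direction = anatomy$thickness_dir, axial = l)
        state <- solve_static(mod_l, setts, state)
        if (!isTRUE(state$converged))
          stop("overbulk inflation failed at growth stretch ", l)
      }
      list(state = state, model = mod_l)
    }
    lg <- 1 + overbulk_level
    res <- solve_at(lg, NULL, n_ramp = 3L)
    for (it in 1:4) {
      v_ad <- deformed_volume(res$model, res$state, "adipose")
      if (abs(v_ad / targ - 1) < 2e-3) break
      lg <- lg * (targ / v_ad)
      res <- solve_at(lg, res$state, n_ramp = 1L)
    }
    u <- matrix(res$state$u, ncol = 3, byrow = TRUE)
    fl$nodes <- fl$nodes + u[seq_len(nrow(fl$nodes)), , drop = FALSE]
    attr(fl, "thickness_scale") <- lg
  } else {
    attr(fl, "thickness_scale") <- 1
  }
  v <- tet4_volumes(fl$nodes, fl$elements)
  if (any(v <= 0))
    stop("overbulk scaling inverted elements: ",
         paste(head(which(v <= 0), 5), collapse = ", "))
  attr(fl, "adipose_volume0") <- v_adip0
  attr(fl, "recipient_interface_orig") <- anatomy$interface_orig
  attr(fl, "overbulk_level") <- overbulk_level
  attr(fl, "thickness_dir") <- anatomy$thickness_dir
  fl
}

#' Structured tetrahedral box mesh
#'
#' A box meshed with the same conforming 6-tet subdivision used by the toy
#' anatomy generator; face node sets are provided for boundary conditions.
#' Optional interior-node jitter (deterministic given `seed`) produces
#' irregular meshes for patch-type verification tests.
#'
#' @param dims box edge lengths (mm).
#' @param divisions grid divisions per axis.
#' @param jitter interior-node jitter as a fraction of the local cell size.
#' @param seed jitter seed.
#' @param region region tag for all elements.
#' @return A `tet_model` with node sets `xmin`, `xmax`, `ymin`, `ymax`,
#'   `zmin`, `zmax` and `boundary`.
#' @export
box_tet_mesh <- function(dims = c(1, 1, 1), divisions = c(2, 2, 2),
                         jitter = 0, seed = 1L, region = "native") {
  nd <- divisions + 1L
  gx <- seq(0, dims[1], length.out = nd[1])
  gy <- seq(0, dims[2], length.out = nd[2])
  gz <- seq(0, dims[3], length.out = nd[3])
  ijk <- as.matrix(expand.grid(i = seq_len(nd[1]), j = seq_len(nd[2]),
                               k = seq_len(nd[3]), KEEP.OUT.ATTRS = FALSE))
  nodes <- cbind(gx[ijk[, 1]], gy[ijk[, 2]], gz[ijk[, 3]])
  on_bnd <- ijk[, 1] %in% c(1L, nd[1]) | ijk[, 2] %in% c(1L, nd[2]) |
    ijk[, 3] %in% c(1L, nd[3])
  if (jitter > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
    h <- dims / divisions
    J <- matrix(runif(3 * nrow(nodes), -jitter, jitter), ncol = 3)
    J <- sweep(J, 2, h, `*`)
    J[on_bnd, ] <- 0
    nodes <- nodes + J
  }
  nid <- function(i, j, k) (k - 1L) * nd[1] * nd[2] + (j - 1L) * nd[1] + i
  hexes <- as.matrix(expand.grid(i = seq_len(divisions[1]),
                                 j = seq_len(divisions[2]),
                                 k = seq_len(divisions[3]),
                                 KEEP.OUT.ATTRS = FALSE))
  corner <- function(h, bx, by, bz) nid(h[, 1] + bx, h[, 2] + by, h[, 3] + bz)
  hx <- cbind(corner(hexes, 0, 0, 0), corner(hexes, 1, 0, 0),
              corner(hexes, 0, 1, 0), corner(hexes, 1, 1, 0),
              corner(hexes, 0, 0, 1), corner(hexes, 1, 0, 1),
              corner(hexes, 0, 1, 1), corner(hexes, 1, 1, 1))
  elems <- do.call(rbind, lapply(seq_len(nrow(kuhn_tets)), function(t)
    hx[, kuhn_tets[t, ], drop = FALSE]))
  v <- tet4_volumes(nodes, elems)
  flip <- v < 0
  if (any(flip)) elems[flip, c(3, 4)] <- elems[flip, c(4, 3)]
  tet_model(nodes, elems, region = rep(region, nrow(elems)),
            node_sets = list(
              xmin = which(ijk[, 1] == 1L), xmax = which(ijk[, 1] == nd[1]),
              ymin = which(ijk[, 2] == 1L), ymax = which(ijk[, 2] == nd[2]),
              zmin = which(ijk[, 3] == 1L), zmax = which(ijk[, 3] == nd[3]),
              boundary = which(on_bnd)))
}

#' Suture line of a toy anatomy
#'
#' The closed rim where the resection cavity meets the tongue exterior on
#' the resected model, ordered into a closed polyline.
#'
#' @param anatomy a `toy_anatomy`.
#' @return k x 3 matrix, first row repeated at the end; attribute
#'   `node_ids` gives the resected-model node index of each polyline vertex.
#' @export
suture_line <- function(anatomy) {
  m <- anatomy$resected
  iface <- m$node_sets$interface
  f <- boundary_faces(m$elements)
  is_cut <- f[, 1] %in% iface & f[, 2] %in% iface & f[, 3] %in% iface
  cutf <- f[is_cut, , drop = FALSE]
  if (!nrow(cutf)) stop("no cut faces found")
  ed <- rbind(cutf[, 1:2], cutf[, 2:3], cutf[, c(3, 1)])
  ekey <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  rim <- ed[ekey %in% names(which(table(ekey) == 1L)), , drop = FALSE]
  # walk the rim into an ordered loop
  nxt <- split(c(rim[, 2], rim[, 1]), c(rim[, 1], rim[, 2]))
  start <- rim[1, 1]
  loop <- c(start, rim[1, 2])
  while (tail(loop, 1) != start) {
    cand <- nxt[[as.character(tail(loop, 1))]]
    step <- cand[cand != loop[length(loop) - 1]][1]
    if (is.na(step)) stop("suture rim is not a single closed loop")
    loop <- c(loop, step)
    if (length(loop) > nrow(rim) + 1) stop("suture rim walk did not close")
  }
  pts <- m$nodes[loop, , drop = FALSE]
  attr(pts, "node_ids") <- loop
  pts
}
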