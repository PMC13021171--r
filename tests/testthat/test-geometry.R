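# Toy anatomy generation, flap assembly, suture layout and surface metrics.

test_that("resection partitions the tongue volume exactly", {
  for (cs in c("A", "B", "C", "D")) {
    an <- generate_toy_anatomy(cs, 0.25, divisions = c(6, 5, 4))
    expect_equal(mesh_volume(an$resected) + mesh_volume(an$resection_model),
                 an$tongue_volume, tolerance = 1e-9)
    expect_equal(an$resection_volume / an$tongue_volume, 0.25,
                 tolerance = 0.05)
    expect_gt(length(an$resected$node_sets$attachment), 0)
    expect_gt(length(an$resected$node_sets$interface), 0)
  }
})

test_that("a vanishing resection leaves the tongue nearly intact", {
  an <- generate_toy_anatomy("B", 0.02, divisions = c(6, 5, 4))
  expect_lt(an$resection_volume / an$tongue_volume, 0.06)
  res_surf <- extract_surface(an$resected)
  d <- hausdorff_percentile(res_surf, an$tongue_surface, q = 0.9,
                            n_samples = 3000)
  expect_lt(d, 2)
})

test_that("anatomy generation is deterministic", {
  a1 <- generate_toy_anatomy("C", 0.3, seed = 5)
  a2 <- generate_toy_anatomy("C", 0.3, seed = 5)
  expect_identical(a1$resected$nodes, a2$resected$nodes)
  expect_identical(a1$resected$elements, a2$resected$elements)
})

test_that("surface extraction closes the volume", {
  an <- generate_toy_anatomy("A", 0.25, divisions = c(6, 5, 4))
  expect_equal(mesh_volume(an$tongue_surface), an$tongue_volume,
               tolerance = 1e-9)
  expect_equal(mesh_volume(an$resection_surface),
               an$resection_volume, tolerance = 1e-9)
})

test_that("mesh_volume matches analytic volumes and is additive", {
  box <- box_tet_mesh(c(1, 1, 1), c(2, 2, 2))
  expect_equal(mesh_volume(box), 1, tolerance = 1e-12)

  # fine ellipsoid mapping of a 10 mm sphere
  an <- generate_toy_anatomy("B", 0.3, dims = c(20, 20, 20),
                             divisions = c(18, 18, 18), skin_layer = 1)
  expect_equal(an$tongue_volume, 4 / 3 * pi * 1000, tolerance = 5e-3)

  # disjoint union of two unit cubes
  b2 <- box_tet_mesh(c(1, 1, 1), c(1, 1, 1))
  nodes <- rbind(box_tet_mesh(c(1, 1, 1), c(1, 1, 1))$nodes,
                 sweep(b2$nodes, 2, c(3, 0, 0), `+`))
  elems <- rbind(b2$elements, b2$elements + nrow(b2$nodes))
  two <- tet_model(nodes, elems, rep("native", nrow(elems)))
  expect_equal(mesh_volume(two), 2, tolerance = 1e-12)

  # inverted elements are reported
  bad <- b2
  bad$elements[3, c(3, 4)] <- bad$elements[3, c(4, 3)]
  expect_error(mesh_volume(bad), "inverted")
})

test_that("suture points are equally spaced with the rounding rule", {
  # perimeter 50 mm at 5 mm spacing: exactly 10 points
  th <- seq(0, 2 * pi, length.out = 401)
  r <- 50 / (2 * pi)
  circle <- cbind(r * cos(th), r * sin(th), 0)
  p <- place_suture_points(circle, 5)
  expect_equal(nrow(p), 10)

  # 20 x 20 square, perimeter 80: 16 points
  sq <- rbind(c(0, 0, 0), c(20, 0, 0), c(20, 20, 0), c(0, 20, 0), c(0, 0, 0))
  p2 <- place_suture_points(sq, 5)
  expect_equal(nrow(p2), 16)
  seg <- sqrt(rowSums(diff(rbind(p2, p2[1, ]))^2))
  # re-measured arc spacing is uniform (chord lengths equal on each edge)
  expect_equal(attr(p2, "arc_spacing"), 5)

  # perimeter 52: rounds to 10 points at 5.2 mm arc spacing
  r2 <- 52 / (2 * pi)
  circ2 <- cbind(r2 * cos(th), r2 * sin(th), 0)
  p3 <- place_suture_points(circ2, 5)
  expect_equal(nrow(p3), 10)
  expect_equal(attr(p3, "arc_spacing"), 5.2, tolerance = 1e-4)

  # open polyline is rejected; minimum of three points enforced
  expect_error(place_suture_points(sq[1:4, ], 5), "closed")
  tri <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 0))
  expect_equal(nrow(place_suture_points(tri, 6)), 3)
})

test_that("cluster_nodes equals the brute-force ball and errors when empty", {
  m <- box_tet_mesh(c(6, 6, 2), c(6, 6, 2))   # 1 mm surface grid
  center <- c(3, 3, 2)
  cl <- cluster_nodes(m, center, 2)
  surf <- sort(unique(as.vector(neotongue:::boundary_faces(m$elements))))
  brute <- surf[sqrt(colSums((t(m$nodes[surf, ]) - center)^2)) <= 2]
  expect_setequal(cl, brute)
  # node exactly at the center is included
  expect_true(which(colSums(abs(t(m$nodes) - center)) < 1e-12) %in% cl)
  # radius smaller than half the grid around an off-node center: empty
  expect_error(cluster_nodes(m, c(3.5, 3.5, 2), 0.099), "too coarse")
})

test_that("percentile Hausdorff distance behaves like a metric diagnostic", {
  an <- generate_toy_anatomy("B", 0.3, dims = c(1, 1, 1),
                             divisions = c(3, 3, 3), shape = "box")
  cube <- an$tongue_surface
  shifted <- cube
  shifted$vertices <- sweep(cube$vertices, 2, c(1, 0, 0), `+`)

  expect_equal(hausdorff_percentile(cube, cube, 0.99, 2000), 0,
               tolerance = 1e-10)
  expect_equal(hausdorff_percentile(cube, shifted, 1, 4000), 1,
               tolerance = 1e-9)
  # symmetry
  expect_equal(hausdorff_percentile(cube, shifted, 0.97, 4000),
               hausdorff_percentile(shifted, cube, 0.97, 4000))
  # monotone in q
  qs <- c(0.5, 0.8, 0.95, 1)
  ds <- vapply(qs, function(q)
    hausdorff_percentile(cube, shifted, q, 4000), numeric(1))
  expect_true(all(diff(ds) >= -1e-12))

  # a spiked vertex region is discarded once the percentile excludes its
  # share of the sampled surface area
  an6 <- generate_toy_anatomy("B", 0.3, dims = c(1, 1, 1),
                              divisions = c(6, 6, 6), shape = "box",
                              skin_layer = 0.17)
  fine <- an6$tongue_surface
  spiked <- fine
  spk <- which.min(rowSums(fine$vertices))
  spiked$vertices[spk, ] <- spiked$vertices[spk, ] - 0.5 / sqrt(3)
  d90 <- hausdorff_percentile(spiked, fine, 0.90, 10000)
  d100 <- hausdorff_percentile(spiked, fine, 1, 10000)
  expect_gt(d100, 0.3)
  expect_lt(d90, d100 / 4)

  expect_error(hausdorff_percentile(cube, surface_mesh(cube$vertices,
    matrix(integer(0), 0, 3)), 0.99), "empty")
})

test_that("geometric flap realization honors the slab volume arithmetic", {
  # prismatic (box) toy with thin skin: adipose scales by 1 + level
  an <- generate_toy_anatomy("B", 0.3, dims = c(40, 30, 24),
                             divisions = c(5, 5, 4), shape = "box")
  fl0 <- build_flap(an, 2.0, 0, realize = "geometry")
  expect_equal(mesh_volume(fl0), an$resection_volume, tolerance = 1e-6)

  fl <- build_flap(an, 2.0, 2 / 3, realize = "geometry")
  v <- neotongue:::tet4_volumes(fl$nodes, fl$elements)
  expect_equal(sum(v[fl$region == "adipose"]),
               (1 + 2 / 3) * attr(fl, "adipose_volume0"),
               tolerance = 0.01)
  # skin volume unchanged within 1%
  expect_equal(sum(v[fl$region == "skin"]),
               sum(neotongue:::tet4_volumes(fl0$nodes, fl0$elements)[
                 fl0$region == "skin"]), tolerance = 0.01)
  # interface nodes stay congruent with the recipient cut surface
  iface <- fl$node_sets$interface
  expect_equal(fl$nodes[iface, ], fl0$nodes[iface, ], tolerance = 1e-9)

  # total volume is affine in the level
  lv <- c(0, 0.222, 0.444)
  vols <- vapply(lv, function(l)
    mesh_volume(build_flap(an, 2.0, l, realize = "geometry")), numeric(1))
  expect_true(all(diff(vols) > 0))
  pred <- vols[1] + lv * attr(fl, "adipose_volume0")
  expect_equal(vols, pred, tolerance = 0.01)

  expect_error(build_flap(an, 2.0, -0.1), "non-negative")
  expect_error(build_flap(an, 50, 0), "adipose")
})

test_that("growth realization keeps the mesh congruent and tags the level", {
  an <- generate_toy_anatomy("A", 0.25, divisions = c(6, 5, 4))
  fl <- build_flap(an, 2.5, 0.667, realize = "growth")
  expect_equal(mesh_volume(fl), an$resection_volume, tolerance = 1e-9)
  expect_equal(attr(fl, "overbulk_level"), 0.667)
  expect_true(all(c("skin", "adipose") %in% fl$region))
})

test_that("the suture line is a closed rim on the resected tongue", {
  an <- generate_toy_anatomy("A", 0.25, divisions = c(6, 5, 4))
  loop <- suture_line(an)
  expect_equal(loop[1, ], loop[nrow(loop), ])
  expect_gt(nrow(loop), 6)
  ids <- attr(loop, "node_ids")
  expect_true(all(ids %in% an$resected$node_sets$interface))
})
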