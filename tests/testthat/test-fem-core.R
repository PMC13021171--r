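# Verification of the implicit tetrahedral solver: closed-form uniaxial
# oracles, patch test, kinematic growth, viscoelastic relaxation, discrete
# suturing and global equilibrium.

test_that("zero load produces zero displacement and zero residual", {
  m <- box_tet_mesh(c(2, 2, 2), c(2, 2, 2))
  mod <- fe_model(m, list(native = nt_material(lib$tongue$hyperelastic)),
                  fixed_sets = character(0), gravity = c(0, 0, 0),
                  prescribed = data.frame(node = m$node_sets$zmin,
                                          dof = rep(1:3,
                                            each = length(m$node_sets$zmin)),
                                          value = 0))
  st <- solve_static(mod)
  expect_true(st$converged)
  expect_equal(max(abs(st$u)), 0)
  expect_equal(st$iterations, 0L)
})

test_that("single-element uniaxial stress matches the closed form", {
  # linear elements, all packaged materials at lambda suited to their range
  lams <- c(tongue = 1.2, adipose = 1.15, `forearm-skin-L1` = 1.1,
            `forearm-skin-L2` = 1.08, `forearm-skin-L3` = 1.08,
            `thigh-skin-L1` = 1.06, `thigh-skin-L2` = 1.05,
            `thigh-skin-L3` = 1.05)
  for (nm in names(lams)) {
    r <- fe_uniaxial(lib[[nm]], lams[[nm]], order = 1L, div = c(1, 1, 1))
    expect_equal(r$sigma, r$closed, tolerance = 0.01, label = nm)
  }
})

test_that("quadratic (tet10) elements reproduce the uniaxial oracle", {
  r <- fe_uniaxial(lib$tongue, 1.2, order = 2L, div = c(1, 1, 1))
  expect_equal(r$sigma, r$closed, tolerance = 0.01)
  r2 <- fe_uniaxial(lib$adipose, 1.1, order = 2L, div = c(1, 1, 1))
  expect_equal(r2$sigma, r2$closed, tolerance = 0.01)
})

test_that("patch test: linear boundary field gives constant interior strain", {
  m <- box_tet_mesh(c(1, 1, 1), c(2, 2, 2), jitter = 0.25, seed = 3)
  A <- matrix(c(0.05, 0.02, -0.01,
                0.01, -0.03, 0.02,
                0.00, 0.01, 0.04), 3, 3, byrow = TRUE)
  mod <- fe_model(m, list(native = nt_material(lib$tongue$hyperelastic)),
                  fixed_sets = character(0), gravity = c(0, 0, 0), order = 2L,
                  prescribed = data.frame(node = 1L, dof = 1L, value = 0))
  bnd <- expand_node_set(mod, m$node_sets$boundary)
  UA <- mod$nodes[bnd, , drop = FALSE] %*% t(A)
  mod$prescribed <- data.frame(node = rep(bnd, 3),
                               dof = rep(1:3, each = length(bnd)),
                               value = as.numeric(UA))
  st <- solve_static(mod, solver_settings(tol_rel = 1e-10, tol_abs = 1e-10))
  expect_true(st$converged)
  Fg <- diag(3) + A
  Eex <- 0.5 * (t(Fg) %*% Fg - diag(3))
  Eex_v <- c(Eex[1, 1], Eex[2, 2], Eex[3, 3], Eex[1, 2], Eex[1, 3], Eex[2, 3])
  dev <- sweep(st$fields[, 1:6, drop = FALSE], 2, Eex_v)
  expect_lt(max(abs(dev)), 1e-8)
})

test_that("free isotropic negative growth follows the determinant law", {
  m <- box_tet_mesh(c(10, 10, 10), c(2, 2, 2), region = "adipose")
  n_org <- which(rowSums(abs(m$nodes)) < 1e-9)
  n_x <- which(abs(m$nodes[, 1] - 10) < 1e-9 & m$nodes[, 2] < 1e-9 &
                 m$nodes[, 3] < 1e-9)
  n_y <- which(abs(m$nodes[, 2] - 10) < 1e-9 & m$nodes[, 1] < 1e-9 &
                 m$nodes[, 3] < 1e-9)
  pres <- rbind(data.frame(node = n_org, dof = 1:3, value = 0),
                data.frame(node = n_x, dof = 2:3, value = 0),
                data.frame(node = n_y, dof = 3, value = 0))
  mod <- fe_model(m, list(adipose = nt_material(lib$adipose$hyperelastic)),
                  fixed_sets = character(0), gravity = c(0, 0, 0),
                  prescribed = pres)
  mod <- apply_growth(mod, "adipose", 0.6^(1 / 3))
  st <- solve_static(mod)
  expect_true(st$converged)
  expect_equal(deformed_volume(mod, st) / 1000, 0.6, tolerance = 0.005)
  expect_lt(max(element_fields(mod, st)$eq_strain), 1e-6)

  # growth stretch of one is a no-op
  mod1 <- apply_growth(mod, "adipose", 1)
  st1 <- solve_static(mod1)
  expect_equal(max(abs(st1$u)), 0, tolerance = 1e-12)

  expect_error(apply_growth(mod, "adipose", -0.2), "positive")
})

test_that("fully encastred growth preserves volume but stores stress", {
  m <- box_tet_mesh(c(5, 5, 5), c(2, 2, 2), region = "adipose")
  pres <- data.frame(node = rep(m$node_sets$boundary, 3),
                     dof = rep(1:3, each = length(m$node_sets$boundary)),
                     value = 0)
  mod <- fe_model(m, list(adipose = nt_material(lib$adipose$hyperelastic)),
                  fixed_sets = character(0), gravity = c(0, 0, 0),
                  prescribed = pres)
  mod <- apply_growth(mod, "adipose", 0.9)
  st <- solve_static(mod)
  expect_true(st$converged)
  # with every node clamped the volume cannot change at all, while the
  # shrunken stress-free configuration leaves a nonzero tensile reaction
  # field on the boundary
  expect_equal(deformed_volume(mod, st) / 125, 1, tolerance = 1e-10)
  expect_gt(max(abs(st$reactions)), 1)
})

test_that("transversely isotropic growth stretches only the axis", {
  m <- box_tet_mesh(c(4, 4, 4), c(2, 2, 2), region = "adipose")
  n_org <- which(rowSums(abs(m$nodes)) < 1e-9)
  n_x <- which(abs(m$nodes[, 1] - 4) < 1e-9 & m$nodes[, 2] < 1e-9 &
                 m$nodes[, 3] < 1e-9)
  n_y <- which(abs(m$nodes[, 2] - 4) < 1e-9 & m$nodes[, 1] < 1e-9 &
                 m$nodes[, 3] < 1e-9)
  pres <- rbind(data.frame(node = n_org, dof = 1:3, value = 0),
                data.frame(node = n_x, dof = 2:3, value = 0),
                data.frame(node = n_y, dof = 3, value = 0))
  mod <- fe_model(m, list(adipose = nt_material(lib$adipose$hyperelastic)),
                  fixed_sets = character(0), gravity = c(0, 0, 0),
                  prescribed = pres)
  mod <- apply_growth(mod, "adipose", 1, direction = c(0, 0, 1), axial = 1.5)
  st <- solve_static(mod)
  expect_true(st$converged)
  expect_equal(deformed_volume(mod, st) / 64, 1.5, tolerance = 0.005)
  u <- matrix(st$u, ncol = 3, byrow = TRUE)
  # top face rises by ~50% of the height, x/y extents unchanged
  expect_equal(max(u[m$node_sets$zmax, 3]), 2, tolerance = 0.01)
  expect_lt(max(abs(u[m$node_sets$xmax, 1])), 0.01)
})

test_that("held-stretch relaxation follows G(t) and equilibrium is balanced", {
  m <- box_tet_mesh(c(5, 5, 5), c(2, 2, 2))
  he <- lib$tongue$hyperelastic
  he$k <- 2e4
  mat <- nt_material(he, lib$tongue$viscoelastic, "tongue")
  lam <- 1.15
  pres <- rbind(
    data.frame(node = m$node_sets$xmin, dof = 1, value = 0),
    data.frame(node = m$node_sets$xmax, dof = 1, value = 5 * (lam - 1)),
    data.frame(node = m$node_sets$ymin, dof = 2, value = 0),
    data.frame(node = m$node_sets$zmin, dof = 3, value = 0))
  mod <- fe_model(m, list(native = mat), fixed_sets = character(0),
                  gravity = c(0, 0, 0), prescribed = pres)
  st0 <- solve_static(mod, solver_settings(), dt = 1e-6)  # instantaneous
  expect_true(st0$converged)
  fx0 <- sum(st0$reactions[3 * (m$node_sets$xmax - 1) + 1])
  st1 <- relaxation_step(mod, st0, solver_settings(), duration = 300,
                         n_steps = 14)
  fx1 <- sum(st1$reactions[3 * (m$node_sets$xmax - 1) + 1])
  p <- lib$tongue$viscoelastic
  expect_equal(fx1 / fx0,
               relaxation_function(p, 300) / relaxation_function(p, 0),
               tolerance = 0.05)
  # peak force is non-increasing over the hold
  expect_lt(fx1, fx0)

  # global equilibrium: residual vanishes on free dofs and the end-face
  # reactions balance each other
  fixed_idx <- 3 * (mod$prescribed$node - 1) + mod$prescribed$dof
  free_idx <- setdiff(seq_along(st1$reactions), fixed_idx)
  expect_lt(sqrt(sum(st1$reactions[free_idx]^2)) / abs(fx1), 1e-4)
  expect_equal(sum(st1$reactions[3 * (m$node_sets$xmin - 1) + 1]), -fx1,
               tolerance = 1e-4)

  # a purely elastic model is returned unchanged by the relaxation stage
  mod_el <- fe_model(m, list(native = nt_material(he)),
                     fixed_sets = character(0), gravity = c(0, 0, 0),
                     prescribed = pres)
  st_el <- solve_static(mod_el)
  st_el2 <- relaxation_step(mod_el, st_el, solver_settings(), duration = 300)
  expect_identical(st_el2$u, st_el$u)
  # zero duration is the identity
  expect_identical(relaxation_step(mod, st1, duration = 0), st1)
})

test_that("re-solving a converged model reproduces nodal positions", {
  r1 <- fe_uniaxial(lib$tongue, 1.15, div = c(2, 2, 2))
  r2 <- fe_uniaxial(lib$tongue, 1.15, div = c(2, 2, 2))
  expect_lt(max(abs(r1$state$u - r2$state$u)), 1e-8)
})

test_that("a suture pair draws two cubes together symmetrically", {
  b <- box_tet_mesh(c(4, 4, 4), c(2, 2, 2))
  n1 <- nrow(b$nodes)
  nodes <- rbind(b$nodes, sweep(b$nodes, 2, c(6, 0, 0), `+`))  # 2 mm gap
  elems <- rbind(b$elements, b$elements + n1)
  mesh <- tet_model(nodes, elems, rep("native", nrow(elems)))
  mat <- nt_material(lib$tongue$hyperelastic, NULL, "t")
  mod <- fe_model(mesh, list(native = mat), fixed_sets = character(0),
                  gravity = c(0, 0, 0),
                  prescribed = data.frame(node = 1L, dof = 1L, value = 0))
  mod$prescribed <- NULL
  # one suture pair: cluster centers on the facing faces
  fa <- which(abs(nodes[, 1] - 4) < 1e-9 & nodes[, 2] > 1 & nodes[, 2] < 3 &
                nodes[, 3] > 1 & nodes[, 3] < 3)
  fb <- which(abs(nodes[, 1] - 6) < 1e-9 & nodes[, 2] > 1 & nodes[, 2] < 3 &
                nodes[, 3] > 1 & nodes[, 3] < 3)
  plan <- structure(list(pairs = list(list(point = c(4, 2, 2),
                                           recipient = fa, flap = fb)),
                         spacing = 5, cluster_radius = 2, mesh_h = 2),
                    class = "suture_plan")
  mod <- neotongue:::add_suture_elements(mod, plan, k_cluster = 100)
  out <- suture_step(mod, solver_settings(reg_k = 1e-3))
  expect_lt(max(out$gaps), 0.1)
  u <- matrix(out$state$u, ncol = 3, byrow = TRUE)
  # symmetric approach: both free cubes move ~1 mm toward each other
  expect_equal(mean(u[fa, 1]), 1, tolerance = 0.15)
  expect_equal(mean(u[fb, 1]), -1, tolerance = 0.15)

  # with one cube fully fixed only the free cube translates
  mod2 <- mod
  mod2$prescribed <- data.frame(node = rep(seq_len(n1), 3),
                                dof = rep(1:3, each = n1), value = 0)
  out2 <- suture_step(mod2, solver_settings(reg_k = 1e-3))
  expect_lt(max(out2$gaps), 0.1)
  u2 <- matrix(out2$state$u, ncol = 3, byrow = TRUE)
  expect_equal(max(abs(u2[seq_len(n1), ])), 0)
  expect_lt(mean(u2[fb, 1]), -1.5)
})
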