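# Shared fixtures: packaged material library and small deterministic helpers.

lib <- material_library()

# random admissible deformation gradients near identity (fixed seed)
random_F <- function(n, scale = 0.15, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      F <- diag(3) + scale * matrix(rnorm(9), 3, 3)
      if (det(F) > 0.4) return(F)
    }
  })
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# uniaxial FE fixture: symmetric one-octant cube stretched along x with
# near-incompressible bulk modulus, returns measured vs closed-form Cauchy
# stress
fe_uniaxial <- function(mat, lam, order = 1L, div = c(2, 2, 2), k = 2e4) {
  m <- box_tet_mesh(c(1, 1, 1), div)
  he <- mat$hyperelastic
  he$k <- k
  mat2 <- nt_material(he, NULL, mat$label)
  pres <- rbind(
    data.frame(node = m$node_sets$xmin, dof = 1, value = 0),
    data.frame(node = m$node_sets$xmax, dof = 1, value = lam - 1),
    data.frame(node = m$node_sets$ymin, dof = 2, value = 0),
    data.frame(node = m$node_sets$zmin, dof = 3, value = 0))
  mod <- fe_model(m, list(native = mat2), fixed_sets = character(0),
                  gravity = c(0, 0, 0), order = order, prescribed = pres)
  mod$prescribed <- expand_prescribed(mod, pres)
  st <- solve_static(mod, solver_settings())
  stopifnot(isTRUE(st$converged))
  xm <- expand_node_set(mod, m$node_sets$xmax)
  fx <- sum(st$reactions[3 * (xm - 1) + 1])
  u <- matrix(st$u, ncol = 3, byrow = TRUE)
  lat <- 1 + max(u[m$node_sets$ymax, 2])
  list(sigma = fx / lat^2,
       closed = uniaxial_stress_incompressible(mat, lam),
       state = st, model = mod, mesh = m)
}

# quick low-resolution run configuration for pipeline tests
toy_cfg <- function(...) {
  run_config(divisions = c(6, 5, 4), offset_dist = 4, ...)
}
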