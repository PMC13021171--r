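#' Solver settings
#'
#' @param tol_rel relative residual tolerance (vs. the load scale).
#' @param tol_abs absolute residual tolerance (mN); the default 1e-3 mN is
#'   physically negligible against the mN-to-N forces of the simulations and
#'   keeps small load steps from demanding precision below the
#'   finite-difference tangent noise floor.
#' @param max_iter Newton iterations per step.
#' @param max_halvings line-search / step halvings before failure.
#' @param reg_k small grounding-spring stiffness (mN/mm) applied to every
#'   node as dynamic regularization of floating bodies; 0 disables.
#' @param min_dt_factor smallest fraction of a step the auto time stepper
#'   may retreat to before declaring non-convergence.
#' @return list of class `solver_settings`.
#' @export
solver_settings <- function(tol_rel = 1e-6, tol_abs = 1e-3, max_iter = 50L,
                            max_halvings = 8L, reg_k = 0,
                            min_dt_factor = 1 / 64) {
  stopifnot(tol_rel > 0, tol_abs > 0, max_iter >= 1)
  structure(list(tol_rel = tol_rel, tol_abs = tol_abs,
                 max_iter = as.integer(max_iter),
                 max_halvings = as.integer(max_halvings),
                 reg_k = reg_k, min_dt_factor = min_dt_factor),
            class = "solver_settings")
}

# Convert a tet4 model to tet10 connectivity: global edge midpoints appended.
# Edge order per element: (12, 13, 14, 23, 24, 34).
tet10_convert <- function(nodes, elements) {
  ep <- rbind(elements[, c(1, 2)], elements[, c(1, 3)], elements[, c(1, 4)],
              elements[, c(2, 3)], elements[, c(2, 4)], elements[, c(3, 4)])
  key <- paste(pmin(ep[, 1], ep[, 2]), pmax(ep[, 1], ep[, 2]))
  uk <- !duplicated(key)
  edge_id <- match(key, key[uk])
  mid <- (nodes[ep[uk, 1], , drop = FALSE] + nodes[ep[uk, 2], , drop = FALSE]) / 2
  nel <- nrow(elements)
  el10 <- cbind(elements,
                matrix(nrow(nodes) + edge_id, nrow = nel, ncol = 6))
  edges_unique <- ep[uk, , drop = FALSE]
  list(nodes = rbind(nodes, mid), elements = el10,
       edge_nodes = edges_unique,
       midside_of = function(a, b) {
         # midside node id for corner pair (a, b), NA if absent
         k <- paste(pmin(a, b), pmax(a, b))
         nrow(nodes) + match(k, key[uk])
       })
}

#' Define a finite element model
#'
#' Collects the mesh, per-region materials, boundary conditions, gravity,
#' discrete spring elements and growth into a single definition consumed by
#' [solve_static] and the stage drivers. With `order = 2` the tet4 mesh is
#' promoted to quadratic tet10 elements (edge midpoints added), the
#' anti-locking default for production runs; `order = 1` keeps linear tets
#' for fast toy studies.
#'
#' @param mesh a `tet_model`.
#' @param materials named list of [nt_material], one per region tag.
#' @param fixed_sets character vector of node-set names to fix fully
#'   (must be nonempty in total: rigid-body modes are removed here).
#' @param gravity gravity vector (mm/s^2), default c(0, 0, -9810); applied
#'   as a body force through each material's density.
#' @param order 1 (tet4) or 2 (tet10).
#' @param prescribed optional data.frame (node, dof, value) of prescribed
#'   displacement components (in addition to `fixed_sets`).
#' @return list of class `fe_model`.
#' @export
fe_model <- function(mesh, materials, fixed_sets = "attachment",
                     gravity = c(0, 0, -9810), order = 1L,
                     prescribed = NULL) {
  stopifnot(inherits(mesh, "tet_model"))
  regs <- unique(mesh$region)
  if (!all(regs %in% names(materials)))
    stop("missing material for region(s): ",
         paste(setdiff(regs, names(materials)), collapse = ", "))
  fixed <- unique(unlist(mesh$node_sets[fixed_sets]))
  if (!length(fixed) && is.null(prescribed))
    stop("no fixed nodes: rigid-body modes unconstrained")
  nodes <- mesh$nodes
  elements <- mesh$elements
  m10 <- NULL
  if (order == 2L) {
    m10 <- tet10_convert(nodes, elements)
    nodes <- m10$nodes
    elements <- m10$elements
  }
  if (order == 2L && length(fixed)) {
    en <- m10$edge_nodes
    both <- en[, 1] %in% fixed & en[, 2] %in% fixed
    fixed <- c(fixed, nrow(mesh$nodes) + which(both))
  }
  mat_names <- names(materials)
  mat_id <- match(mesh$region, mat_names)
  structure(list(
    mesh = mesh, nodes = nodes, elements = elements, order = order,
    tet10 = m10,
    materials = materials, mat_id = mat_id,
    fixed = fixed, prescribed = prescribed,
    gravity = as.numeric(gravity),
    virtual_nodes = matrix(numeric(0), 0, 3),
    springs = data.frame(a = integer(0), b = integer(0),
                         k = numeric(0), L0 = numeric(0),
                         type = character(0)),
    tie_pairs = NULL, ties_active = FALSE, tie_k = 500,
    planes = NULL,   # unilateral plane constraints (nx, ny, nz, offset, k)
    growth_lambda_region = NULL,   # named per-region growth stretch
    n_mesh_nodes = nrow(nodes)),
    class = "fe_model")
}

n_total_nodes <- function(model) model$n_mesh_nodes + nrow(model$virtual_nodes)

#' Expand a corner node set to tet10 midside nodes
#'
#' For quadratic models, returns the set augmented with every midside node
#' whose two corner nodes are both members. For linear models the set is
#' returned unchanged.
#'
#' @param model an `fe_model`.
#' @param nodes integer corner-node set.
#' @return integer node set in the model's (possibly tet10) numbering.
#' @export
expand_node_set <- function(model, nodes) {
  if (model$order != 2L || is.null(model$tet10)) return(nodes)
  en <- model$tet10$edge_nodes
  both <- en[, 1] %in% nodes & en[, 2] %in% nodes
  c(nodes, nrow(model$mesh$nodes) + which(both))
}

#' Expand prescribed displacements to tet10 midside nodes
#'
#' Midside nodes on edges whose both corners carry a prescribed value for
#' the same dof receive the mean of the corner values (exact for the linear
#' and bilinear boundary fields used in verification tests).
#'
#' @param model an `fe_model`.
#' @param prescribed data.frame (node, dof, value) on corner nodes.
#' @return augmented data.frame.
#' @export
expand_prescribed <- function(model, prescribed) {
  if (model$order != 2L || is.null(model$tet10)) return(prescribed)
  en <- model$tet10$edge_nodes
  n0 <- nrow(model$mesh$nodes)
  out <- prescribed
  for (d in unique(prescribed$dof)) {
    p <- prescribed[prescribed$dof == d, ]
    v <- setNames(p$value, p$node)
    both <- en[, 1] %in% p$node & en[, 2] %in% p$node
    if (any(both)) {
      mid <- n0 + which(both)
      val <- (v[as.character(en[both, 1])] +
                v[as.character(en[both, 2])]) / 2
      out <- rbind(out, data.frame(node = mid, dof = d,
                                   value = as.numeric(val)))
    }
  }
  out
}

all_coords <- function(model) rbind(model$nodes, model$virtual_nodes)

# Consistent gravity load vector (reference configuration).
gravity_load <- function(model) {
  g <- model$gravity
  nn <- n_total_nodes(model)
  Fg <- numeric(3 * nn)
  if (all(g == 0)) return(Fg)
  V <- .elem_volumes(model$nodes, model$elements)
  rho <- vapply(model$materials, function(m) m$density, numeric(1))[model$mat_id]
  nen <- ncol(model$elements)
  # consistent nodal weights of a uniform body force (tet10: corners -V/20,
  # midsides V/5)
  w <- if (nen == 4) rep(1 / 4, 4) else c(rep(-1 / 20, 4), rep(1 / 5, 6))
  for (a in seq_len(nen)) {
    nd <- model$elements[, a]
    for (j in 1:3) {
      idx <- 3 * (nd - 1) + j
      acc <- rowsum((rho * V * w[a] * g[j]), idx)
      Fg[as.integer(rownames(acc))] <- Fg[as.integer(rownames(acc))] + acc[, 1]
    }
  }
  Fg
}

# Unilateral plane constraints: penalty force pushing back any node that
# crosses the plane x . n > offset (n the outward normal toward the wall).
plane_assembly <- function(X, u, planes, want_K = TRUE, band = 0.2) {
  n <- nrow(X)
  f <- numeric(3 * n)
  ti <- tj <- integer(0); tx <- numeric(0)
  if (is.null(planes) || !nrow(planes)) return(list(f = f, i = ti, j = tj, x = tx))
  pos <- X + matrix(u, ncol = 3, byrow = TRUE)
  for (p in seq_len(nrow(planes))) {
    nv <- c(planes$nx[p], planes$ny[p], planes$nz[p])
    pen <- pmax(0, as.numeric(pos %*% nv) - planes$offset[p])
    hit <- which(pen > 0)
    if (!length(hit)) next
    k <- planes$k[p]
    for (nd in hit) {
      # C1 penalty: quadratic inside a transition band, linear beyond, so
      # the Newton iteration does not chatter at the contact boundary
      g <- pen[nd]
      if (g < band) { fmag <- k * g^2 / (2 * band); kt <- k * g / band }
      else { fmag <- k * (g - band / 2); kt <- k }
      dofs <- 3 * (nd - 1) + 1:3
      f[dofs] <- f[dofs] + fmag * nv
      if (want_K) {
        Kb <- kt * (nv %o% nv)
        ti <- c(ti, rep(dofs, times = 3))
        tj <- c(tj, rep(dofs, each = 3))
        tx <- c(tx, as.vector(Kb))
      }
    }
  }
  list(f = f, i = ti, j = tj, x = tx)
}

# Spring internal forces and tangent triplets at current positions.
spring_assembly <- function(X, u, springs, want_K = TRUE) {
  n <- nrow(X)
  f <- numeric(3 * n)
  ti <- tj <- integer(0); tx <- numeric(0)
  if (!nrow(springs)) return(list(f = f, i = ti, j = tj, x = tx))
  pos <- X + matrix(u, ncol = 3, byrow = TRUE)
  ia <- springs$a; ib <- springs$b
  d <- pos[ib, , drop = FALSE] - pos[ia, , drop = FALSE]
  d0 <- X[ib, , drop = FALSE] - X[ia, , drop = FALSE]
  L <- sqrt(rowSums(d^2))
  nt <- nrow(springs)
  blocks_i <- blocks_j <- integer(36 * nt); blocks_x <- numeric(36 * nt)
  ptr <- 0L
  vector_type <- springs$type == "cluster"
  for (s in seq_len(nt)) {
    k <- springs$k[s]; L0 <- springs$L0[s]
    if (vector_type[s]) {
      # vector spring: resists change of the relative vector; linear and
      # smooth at zero length (used for cluster force distribution)
      fs <- k * (d[s, ] - d0[s, ])
      Kb <- k * diag(3)
    } else if (L[s] > 1e-10) {
      nv <- d[s, ] / L[s]
      fs <- k * (L[s] - L0) * nv
      Kb <- k * (nv %o% nv) +
        k * (L[s] - L0) / L[s] * (diag(3) - nv %o% nv)
    } else {
      fs <- c(0, 0, 0)
      Kb <- k * diag(3)
    }
    da <- 3 * (ia[s] - 1) + 1:3
    db <- 3 * (ib[s] - 1) + 1:3
    f[da] <- f[da] - fs
    f[db] <- f[db] + fs
    if (want_K) {
      KK <- rbind(cbind(Kb, -Kb), cbind(-Kb, Kb))
      dofs <- c(da, db)
      idx <- ptr + seq_len(36)
      blocks_i[idx] <- rep(dofs, times = 6)
      blocks_j[idx] <- rep(dofs, each = 6)
      blocks_x[idx] <- as.vector(KK)
      ptr <- ptr + 36L
    }
  }
  list(f = f, i = blocks_i[seq_len(ptr)], j = blocks_j[seq_len(ptr)],
       x = blocks_x[seq_len(ptr)])
}

# Per-element growth stretches (transverse, axial) from the region map.
growth_vector <- function(model) {
  lg <- rep(1, nrow(model$elements))
  lax <- rep(1, nrow(model$elements))
  grl <- model$growth_lambda_region
  if (!is.null(grl))
    for (r in names(grl)) {
      g <- grl[[r]]
      lg[model$mesh$region == r] <- g[["trans"]]
      lax[model$mesh$region == r] <- g[["axial"]]
    }
  list(trans = lg, axial = lax)
}

# Material codes / Prony lists aligned with model$materials.
material_tables <- function(model) {
  mats <- lapply(model$materials, material_code)
  prony <- lapply(model$materials, function(m) {
    p <- m$viscoelastic
    if (is.null(p)) list(gamma = numeric(0), tau = numeric(0))
    else list(gamma = p$gamma, tau = p$tau)
  })
  list(mats = unname(mats), prony = unname(prony))
}

# Width of the per-element viscoelastic state rows.
state_width <- function(model) {
  nqp <- if (ncol(model$elements) == 4) 1L else 4L
  nv <- max(c(0L, vapply(model$materials, function(m)
    if (is.null(m$viscoelastic)) 0L else m$viscoelastic$N, integer(1))))
  nqp * 6L * (1L + nv)
}

#' Initialize a simulation state
#'
#' @param model an `fe_model`.
#' @return list of class `sim_state` with zero displacements, cleared
#'   viscoelastic history and time 0.
#' @export
init_state <- function(model) {
  nn <- n_total_nodes(model)
  structure(list(
    u = numeric(3 * nn),
    visco = matrix(0, nrow(model$elements), state_width(model)),
    time = 0,
    fields = NULL, log = list()),
    class = "sim_state")
}

fixed_dof_values <- function(model) {
  idx <- as.integer(outer(3 * (model$fixed - 1), 1:3, `+`))
  val <- rep(0, length(idx))
  if (!is.null(model$prescribed)) {
    idx <- c(idx, 3L * (model$prescribed$node - 1L) + model$prescribed$dof)
    val <- c(val, model$prescribed$value)
  }
  keep <- !duplicated(idx)
  list(idx = idx[keep], val = val[keep])
}

# One Newton solve at fixed loads/schedules. dt is the viscoelastic step
# size (Inf = fully relaxed long-term response). Returns the updated state
# or a structured failure (converged = FALSE, last good state preserved).
newton_solve <- function(model, state, settings, dt = Inf) {
  X <- all_coords(model)
  nn <- nrow(X)
  mt <- material_tables(model)
  lg <- growth_vector(model)
  gdir <- if (is.null(model$growth_dir)) numeric(0) else model$growth_dir
  Fg <- gravity_load(model)
  fd <- fixed_dof_values(model)
  free <- setdiff(seq_len(3 * nn), fd$idx)
  springs <- active_springs(model)

  u <- state$u
  u[fd$idx] <- fd$val
  Umat <- function(u) matrix(u, ncol = 3, byrow = TRUE)

  resid_of <- function(u, want_K) {
    asm <- .assemble_fem(X, Umat(u), model$elements, model$mat_id,
                         mt$mats, mt$prony, lg$trans, lg$axial, gdir,
                         state$visco, dt, want_K, TRUE)
    if (!asm$ok) return(asm)
    sp <- spring_assembly(X, u, springs, want_K)
    pl <- plane_assembly(X, u, model$planes, want_K)
    asm$residual <- asm$residual + sp$f + pl$f - Fg
    if (settings$reg_k > 0)
      asm$residual <- asm$residual + settings$reg_k * u
    asm$sp <- list(f = sp$f + pl$f, i = c(sp$i, pl$i), j = c(sp$j, pl$j),
                   x = c(sp$x, pl$x))
    asm
  }

  ref <- max(sqrt(sum(Fg^2)), settings$tol_abs / settings$tol_rel)
  asm <- resid_of(u, TRUE)
  if (!isTRUE(asm$ok))
    return(modifyList(state, list(converged = FALSE,
                                  failure = "inadmissible initial state")))
  rn <- sqrt(sum(asm$residual[free]^2))
  ref <- max(ref, rn)
  tol <- settings$tol_abs + settings$tol_rel * ref
  it <- 0L
  while (rn > tol && it < settings$max_iter) {
    it <- it + 1L
    K <- Matrix::sparseMatrix(
      i = c(asm$Ki, asm$sp$i), j = c(asm$Kj, asm$sp$j),
      x = c(asm$Kx, asm$sp$x), dims = c(3 * nn, 3 * nn))
    if (settings$reg_k > 0)
      K <- K + settings$reg_k * Matrix::Diagonal(3 * nn)
    du <- numeric(3 * nn)
    du[free] <- as.numeric(Matrix::solve(K[free, free, drop = FALSE],
                                         -asm$residual[free]))
    alpha <- 1
    repeat {
      u_try <- u
      u_try[free] <- u[free] + alpha * du[free]
      asm_try <- resid_of(u_try, FALSE)
      if (isTRUE(asm_try$ok)) {
        rn_try <- sqrt(sum(asm_try$residual[free]^2))
        if (rn_try < rn || alpha <= 2^-settings$max_halvings) break
      }
      alpha <- alpha / 2
      if (alpha < 2^-(settings$max_halvings + 2))
        return(modifyList(state, list(converged = FALSE,
                                      failure = "line search failed",
                                      iterations = it)))
    }
    u <- u_try
    asm <- resid_of(u, TRUE)
    if (!isTRUE(asm$ok))
      return(modifyList(state, list(converged = FALSE,
                                    failure = "inadmissible state",
                                    iterations = it)))
    rn <- sqrt(sum(asm$residual[free]^2))
  }
  if (rn > tol)
    return(modifyList(state, list(converged = FALSE,
                                  failure = "max iterations",
                                  iterations = it, residual_norm = rn)))
  state$u <- u
  state$visco <- asm$state
  state$fields <- asm$fields
  state$residual_norm <- rn
  state$reactions <- asm$residual
  state$min_J <- asm$min_J
  state$converged <- TRUE
  state$iterations <- it
  state$tolerance <- tol
  state
}

active_springs <- function(model) {
  s <- model$springs
  if (isTRUE(model$ties_active) && !is.null(model$tie_pairs) &&
      nrow(model$tie_pairs))
    s <- rbind(s, data.frame(a = model$tie_pairs[, 1],
                             b = model$tie_pairs[, 2],
                             k = model$tie_k, L0 = 0, type = "tie"))
  s
}

#' Solve a quasi-static equilibrium
#'
#' Newton iteration with line search and automatic step retreat: if the full
#' solve fails, the load (gravity, spring rest-length change, growth) path is
#' walked in substeps that halve on failure down to a floor. Viscoelastic
#' history advances by `dt` (default `Inf`: long-term relaxed response).
#'
#' @param model an `fe_model`.
#' @param settings a [solver_settings].
#' @param state starting [init_state] (default fresh).
#' @param dt viscoelastic time step (s).
#' @return updated `sim_state`; `$converged` flags success, on failure
#'   `$failure` describes the last error and the last good state is kept.
#' @export
solve_static <- function(model, settings = solver_settings(),
                         state = NULL, dt = Inf) {
  if (is.null(state)) state <- init_state(model)
  st <- newton_solve(model, state, settings, dt)
  if (isTRUE(st$converged)) return(st)
  # continuation on the prescribed displacements / gravity: walk the load
  # factor with automatic halving down to a floor
  s_done <- 0; ds <- 0.5
  pres0 <- model$prescribed
  grav0 <- model$gravity
  while (s_done < 1 - 1e-12) {
    s_try <- min(1, s_done + ds)
    m_s <- model
    if (!is.null(pres0)) {
      m_s$prescribed <- pres0
      m_s$prescribed$value <- pres0$value * s_try
    }
    m_s$gravity <- grav0 * s_try
    st_try <- newton_solve(m_s, state, settings, dt)
    if (isTRUE(st_try$converged)) {
      state <- st_try
      s_done <- s_try
      ds <- min(ds * 2, 0.5)
    } else {
      ds <- ds / 2
      if (ds < settings$min_dt_factor / 4)
        return(modifyList(state,
                          list(converged = FALSE,
                               failure = paste0("continuation stalled at ",
                                                "load factor ", s_done))))
    }
  }
  state
}

#' Element field table of a converged state
#'
#' @param model an `fe_model`.
#' @param state a converged `sim_state`.
#' @return data.frame with per-element volume-averaged Lagrange strain
#'   components (E11..E23), Jacobian `J`, reference volume, region and
#'   von Mises equivalent strain.
#' @export
element_fields <- function(model, state) {
  f <- state$fields
  if (is.null(f)) stop("state carries no fields; run solve_static first")
  E <- f[, 1:6, drop = FALSE]
  eq <- apply(E, 1, function(v)
    equivalent_strain(matrix(v[c(1, 4, 5, 4, 2, 6, 5, 6, 3)], 3, 3)))
  data.frame(E11 = E[, 1], E22 = E[, 2], E33 = E[, 3],
             E12 = E[, 4], E13 = E[, 5], E23 = E[, 6],
             J = f[, 7], volume0 = f[, 8],
             region = model$mesh$region, eq_strain = eq)
}

#' Deformed volume of a region
#'
#' @param model an `fe_model`.
#' @param state a converged state.
#' @param region region tag(s); default all.
#' @return volume (mm^3) of the deformed elements (reference volume times
#'   the element-average Jacobian).
#' @export
deformed_volume <- function(model, state, region = NULL) {
  f <- state$fields
  sel <- if (is.null(region)) rep(TRUE, nrow(f))
         else model$mesh$region %in% region
  sum(f[sel, 7] * f[sel, 8])
}

#' Set the kinematic growth stretch of a region
#'
#' Multiplicative kinematic growth: the deformation gradient splits as
#' \eqn{F = F_e F_g} in the target region and stress derives from the
#' elastic part \eqn{F_e} only, so growth stretches below 1 shrink the
#' stress-free configuration (atrophy) and stretches above 1 enlarge it
#' (overbulking prestretch). Isotropic by default; with `direction` and
#' `axial`, \eqn{F_g} stretches by `axial` along the direction and by
#' `lambda_g` transversely (used to thicken a flap without changing its
#' skin paddle dimensions).
#'
#' @param model an `fe_model`.
#' @param region region tag.
#' @param lambda_g (transverse) growth stretch, positive.
#' @param direction optional unit 3-vector (global growth axis).
#' @param axial growth stretch along `direction` (defaults to `lambda_g`).
#' @return the modified model.
#' @export
apply_growth <- function(model, region, lambda_g, direction = NULL,
                         axial = NULL) {
  if (is.null(axial)) axial <- lambda_g
  if (!(lambda_g > 0) || !(axial > 0)) stop("growth stretches must be positive")
  grl <- model$growth_lambda_region
  if (is.null(grl)) grl <- list()
  grl[[region]] <- c(trans = lambda_g, axial = axial)
  model$growth_lambda_region <- grl
  if (!is.null(direction)) model$growth_dir <- direction
  model
}
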