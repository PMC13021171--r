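# Surgical stage drivers: suture insetting, viscoelastic equilibration and
# post-operative atrophy. Each driver advances a model/state pair and records
# a per-stage convergence log.

#' Build a suture plan for a toy reconstruction
#'
#' Lays suture points along the resection rim at (approximately) the target
#' spacing, and resolves the paired node clusters on the recipient and flap
#' sides. On coarse toy meshes the spacing and cluster radius are enlarged
#' to the local mesh resolution so clusters are never empty.
#'
#' @param anatomy a `toy_anatomy`.
#' @param combined the combined recipient + flap `tet_model` from
#'   [assemble_reconstruction].
#' @param spacing target suture spacing (mm), default 5.
#' @param cluster_radius cluster radius (mm), default 2.
#' @param offset flap placement offset vector (mm).
#' @return list of class `suture_plan`: per-pair cluster node sets (global
#'   combined-mesh ids), cluster centers, spacing/radius actually used.
#' @export
plan_sutures <- function(anatomy, combined, spacing = 5, cluster_radius = 2,
                         offset = c(0, 0, 0)) {
  loop <- suture_line(anatomy)
  seg <- sqrt(rowSums(diff(loop)^2))
  h <- median(seg)
  spacing_used <- max(spacing, 1.3 * h)
  radius_used <- max(cluster_radius, 0.8 * h)
  pts <- place_suture_points(loop, spacing_used)
  n_res <- nrow(anatomy$resected$nodes)
  surf_rec <- sort(unique(as.vector(boundary_faces(
    anatomy$resected$elements))))
  flap_elems_local <- combined$elements[combined$region != "native", ,
                                        drop = FALSE] - n_res
  surf_flap_local <- sort(unique(as.vector(boundary_faces(flap_elems_local))))
  flap_nodes <- combined$nodes[-seq_len(n_res), , drop = FALSE]
  pairs <- lapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    rec <- cluster_nodes(anatomy$resected, p, radius_used,
                         surface_nodes = surf_rec)
    fl <- cluster_nodes(list(nodes = flap_nodes), p + offset, radius_used,
                        surface_nodes = surf_flap_local)
    list(point = p,
         recipient = rec,
         flap = fl + n_res)
  })
  structure(list(pairs = pairs, spacing = spacing_used,
                 cluster_radius = radius_used, points = pts,
                 offset = offset, mesh_h = h),
            class = "suture_plan")
}

#' @export
print.suture_plan <- function(x, ...) {
  cat(sprintf("<suture_plan> %d suture pairs, spacing %.2f mm, cluster radius %.2f mm\n",
              length(x$pairs), x$spacing, x$cluster_radius))
  invisible(x)
}

# Install cluster springs, virtual center nodes and tension elements for a
# suture plan. Returns the modified model; tension-element rows are flagged
# type == "tension" so their rest lengths can be ramped.
add_suture_elements <- function(model, plan, k_cluster = NULL,
                                k_tension = NULL) {
  if (is.null(k_cluster)) {
    mu <- ogden_shear_modulus(model$materials[[1]]$hyperelastic)
    k_cluster <- 30 * mu * plan$cluster_radius
  }
  if (is.null(k_tension)) k_tension <- k_cluster / 2
  X <- model$nodes
  springs <- model$springs
  vn <- model$virtual_nodes
  n0 <- model$n_mesh_nodes
  for (p in plan$pairs) {
    c_rec <- colMeans(X[p$recipient, , drop = FALSE])
    c_fl <- colMeans(X[p$flap, , drop = FALSE])
    vn <- rbind(vn, c_rec, c_fl)
    id_rec <- n0 + nrow(vn) - 1L
    id_fl <- n0 + nrow(vn)
    L_rec <- sqrt(colSums((t(X[p$recipient, , drop = FALSE]) - c_rec)^2))
    L_fl <- sqrt(colSums((t(X[p$flap, , drop = FALSE]) - c_fl)^2))
    springs <- rbind(
      springs,
      data.frame(a = id_rec, b = p$recipient, k = k_cluster, L0 = L_rec,
                 type = "cluster"),
      data.frame(a = id_fl, b = p$flap, k = k_cluster, L0 = L_fl,
                 type = "cluster"),
      data.frame(a = id_rec, b = id_fl, k = k_tension,
                 L0 = sqrt(sum((c_fl - c_rec)^2)), type = "tension"))
  }
  rownames(vn) <- NULL
  model$virtual_nodes <- vn
  model$springs <- springs
  model
}

# Current end-to-end gap of every tension element.
suture_gaps <- function(model, state) {
  s <- model$springs
  idx <- which(s$type == "tension")
  pos <- all_coords(model) + matrix(state$u, ncol = 3, byrow = TRUE)
  vapply(idx, function(i)
    sqrt(sum((pos[s$b[i], ] - pos[s$a[i], ])^2)), numeric(1))
}

#' Overbulking prestretch stage
#'
#' Applies the flap's overbulking as a kinematic growth prestretch of the
#' adipose region along the flap thickness direction, ramped to the target
#' level with the still-free flap held only by its (slack) suture elements
#' and weak grounding springs. The flap's stress-free subcutaneous volume
#' grows by exactly `1 + level` while the skin paddle keeps its reference
#' dimensions.
#'
#' @param model an `fe_model` (suture elements installed).
#' @param settings a [solver_settings].
#' @param state starting state (default fresh).
#' @param level overbulk fraction (0 = no-op).
#' @param direction flap thickness direction (unit 3-vector).
#' @param n_increments growth ramp increments.
#' @return list: `model` (carrying the prestretch), `state`.
#' @export
overbulk_prestretch <- function(model, settings = solver_settings(),
                                state = NULL, level = 0,
                                direction = c(0, 1, 0),
                                n_increments = 3L, calibrate = TRUE) {
  if (is.null(state)) state <- init_state(model)
  if (level <= 0) return(list(model = model, state = state))
  setts <- settings
  setts$reg_k <- max(settings$reg_k, 0.01)
  v_adip0 <- sum(.elem_volumes(model$nodes, model$elements)[
    model$mesh$region == "adipose"])
  solve_axial <- function(a_from, a_to, n) {
    a_done <- a_from
    da <- (a_to - a_from) / n
    while (a_done < a_to - 1e-12 || a_done > a_to + 1e-12) {
      a <- if (a_to >= a_from) min(a_to, a_done + da) else max(a_to, a_done - da)
      m_try <- apply_growth(model, "adipose", 1, direction = direction,
                            axial = a)
      st <- newton_solve(m_try, state, setts, dt = Inf)
      if (isTRUE(st$converged)) {
        model <<- m_try
        state <<- st
        a_done <- a
        da <- min(abs(da) * 1.5, abs(a_to - a_from) / n) * sign(a_to - a_from + 1e-15)
      } else {
        da <- da / 2
        if (abs(da) < abs(a_to - a_from) / (n * 64))
          stop("overbulk prestretch failed at growth stretch ", a)
      }
    }
    a_to
  }
  a_cur <- solve_axial(1, 1 + level, n_increments)
  if (calibrate) {
    # the skin paddle elastically restrains the expansion; push the growth
    # stretch until the realized adipose volume increase matches the level
    targ <- (1 + level) * v_adip0
    for (it in 1:4) {
      v_ad <- deformed_volume(model, state, "adipose")
      if (abs(v_ad / targ - 1) < 2e-3) break
      a_cur <- solve_axial(a_cur, a_cur * targ / v_ad, 1)
    }
  }
  list(model = model, state = state, axial = a_cur)
}

#' Virtual suturing stage
#'
#' Replicates the surgical action of tightening and securing sutures: the
#' tension elements between paired cluster centers shorten linearly from
#' their initial separation to a near-zero rest length (0.02 mm) over the
#' stage, each increment solved implicitly; increments that fail to converge
#' are bisected. Once the rims are apposed, node ties ("sticky" apposition)
#' are activated for every congruent interface pair whose gap is below
#' `tie_gap` and a final equilibrium is solved, preventing gaps or voids at
#' the flap-tongue interface.
#'
#' @param model an `fe_model` whose suture elements were installed by
#'   `add_suture_elements` (done by [run_reconstruction]).
#' @param settings a [solver_settings].
#' @param state optional starting state.
#' @param duration stage duration (s) for the viscoelastic clock, default 60.
#' @param n_increments rest-length ramp increments, default 8.
#' @param tie_gap gap threshold (mm) below which interface node ties engage.
#' @return list: updated `model` (ties active), `state` ("Day 0
#'   pre-relaxation"), `gaps` (per-suture final gap, mm).
#' @export
suture_step <- function(model, settings = solver_settings(), state = NULL,
                        duration = 60, n_increments = 8L, tie_gap = 0.2,
                        lock_factor = 25) {
  if (is.null(state)) state <- init_state(model)
  ten <- which(model$springs$type == "tension")
  if (!length(ten)) stop("model has no tension elements; plan sutures first")
  # weak grounding springs regularize the still-floating flap while the
  # sutures engage; the final tie-activation solve drops them again
  settings_ramp <- settings
  settings_ramp$reg_k <- max(settings$reg_k, 0.01)
  settings_ramp$max_iter <- max(settings$max_iter, 80L)
  L_init <- model$springs$L0[ten]
  L_final <- pmin(0.02, L_init)
  s_done <- 0
  ds <- 1 / n_increments
  log <- list()
  while (s_done < 1 - 1e-12) {
    s_try <- min(1, s_done + ds)
    m_try <- model
    m_try$springs$L0[ten] <- (1 - s_try) * L_init + s_try * L_final
    st <- newton_solve(m_try, state, settings_ramp,
                       dt = duration * (s_try - s_done))
    if (isTRUE(st$converged)) {
      model <- m_try
      state <- st
      state$time <- state$time + duration * (s_try - s_done)
      s_done <- s_try
      log[[length(log) + 1]] <- c(s = s_try, iter = st$iterations)
      ds <- min(ds * 1.5, 1 / n_increments)
    } else {
      ds <- ds / 2
      if (ds < settings$min_dt_factor / (4 * n_increments))
        stop("suture step failed to converge; per-suture gaps: ",
             paste(sprintf("%.2f", suture_gaps(model, state)), collapse = ", "))
    }
  }
  # lock phase: with the rims apposed, stiffen the tension elements so the
  # residual suture gaps close below the 0.1 mm contract
  model$springs$k[ten] <- lock_factor * model$springs$k[ten]
  st <- newton_solve(model, state, settings, dt = 1)
  if (isTRUE(st$converged)) {
    state <- st
    state$time <- state$time + 1
  } else {
    model$springs$k[ten] <- model$springs$k[ten] / lock_factor
    warning("suture lock phase failed to converge; gaps left at ramp level")
  }
  # activate sticky interface ties where apposition succeeded. Engagement is
  # progressive (each round of ties pulls further interface node pairs within
  # reach) and gentle: a newly engaged tie starts as an axial spring whose
  # rest length ramps from the current gap to zero, after which it acts as a
  # plain zero-rest-length (linear) spring.
  if (!is.null(model$tie_pairs) && nrow(model$tie_pairs)) {
    all_pairs <- model$tie_pairs
    active <- rep(FALSE, nrow(all_pairs))
    for (round in 1:8) {
      pos <- all_coords(model) + matrix(state$u, ncol = 3, byrow = TRUE)
      gap <- sqrt(rowSums((pos[all_pairs[, 1], , drop = FALSE] -
                           pos[all_pairs[, 2], , drop = FALSE])^2))
      newly <- which(!active & gap < tie_gap)
      if (!length(newly)) break
      new_rows <- data.frame(a = all_pairs[newly, 1],
                             b = all_pairs[newly, 2],
                             k = model$tie_k, L0 = gap[newly], type = "tie")
      first_new <- nrow(model$springs) + 1L
      model$springs <- rbind(model$springs, new_rows)
      idx_new <- seq(first_new, nrow(model$springs))
      engaged <- FALSE
      for (frac in c(0.5, 0.2, 0)) {
        m_try <- model
        m_try$springs$L0[idx_new] <- frac * new_rows$L0
        st <- newton_solve(m_try, state, settings, dt = 0.5)
        if (!isTRUE(st$converged)) break
        model <- m_try
        state <- st
        state$time <- state$time + 0.5
        engaged <- frac == 0
      }
      if (!engaged) {
        # drop the partially engaged batch and stop trying
        model$springs <- model$springs[-idx_new, , drop = FALSE]
        st <- newton_solve(model, state, settings, dt = 0.5)
        if (isTRUE(st$converged)) state <- st
        warning("tie engagement stalled after ", sum(active), " ties")
        break
      }
      active[newly] <- TRUE
    }
    model$tie_active_pairs <- all_pairs[active, , drop = FALSE]
    model$ties_active <- FALSE   # ties live in model$springs now
  }
  # the tie engagement redistributes load; re-tighten the tension elements
  # until every suture gap is comfortably below the 0.1 mm contract
  for (pass in 1:3) {
    if (max(suture_gaps(model, state)) <= 0.08) break
    m_try <- model
    m_try$springs$k[ten] <- 4 * model$springs$k[ten]
    st <- newton_solve(m_try, state, settings, dt = 0.5)
    if (!isTRUE(st$converged)) break
    model <- m_try
    state <- st
    state$time <- state$time + 0.5
  }
  list(model = model, state = state, gaps = suture_gaps(model, state),
       log = log)
}

#' Viscoelastic equilibration stage
#'
#' Holds all loads and lets the Prony-series transients decay over
#' `duration` seconds (default 300 s, the five-minute post-suturing
#' equilibration), using logarithmically growing time steps that resolve
#' the shortest relaxation times first. A purely elastic model is returned
#' unchanged; `duration = 0` is the identity.
#'
#' @param model an `fe_model`.
#' @param state the post-suturing state.
#' @param settings a [solver_settings].
#' @param duration total relaxation time (s).
#' @param n_steps number of log-spaced time steps.
#' @return updated state ("Day 0").
#' @export
relaxation_step <- function(model, state, settings = solver_settings(),
                            duration = 300, n_steps = 12L) {
  if (duration <= 0) return(state)
  has_visco <- any(vapply(model$materials, function(m)
    !is.null(m$viscoelastic) && m$viscoelastic$N > 0, logical(1)))
  if (!has_visco) return(state)
  # log spacing from ~0.05 s (shortest packaged relaxation time) to duration
  t_grid <- exp(seq(log(min(0.05, duration / 2)), log(duration),
                    length.out = n_steps))
  t_grid[n_steps] <- duration
  dts <- diff(c(0, t_grid))
  for (dt in dts) {
    st <- newton_solve(model, state, settings, dt = dt)
    if (!isTRUE(st$converged)) {
      # bisect the step once; viscoelastic steps are benign, fail hard after
      st <- newton_solve(model, state, settings, dt = dt / 2)
      if (isTRUE(st$converged))
        st <- newton_solve(model, st, settings, dt = dt / 2)
      if (!isTRUE(st$converged))
        stop("relaxation step failed at dt = ", dt)
    }
    state <- st
    state$time <- state$time + dt
  }
  state
}

#' Post-operative atrophy stage
#'
#' Evolves the Day-0 state to the one-year state by ramping an isotropic
#' negative growth stretch on the flap's subcutaneous (adipose) region.
#' The growth stretch is calibrated iteratively so the measured volume loss
#' matches `total_loss` within `tol` despite constraint interaction:
#' with `loss_accounting = "flap"` the 40% loss applies to the whole flap
#' (skin + adipose, the whole-flap convention behind the 66.7% overbulking
#' arithmetic); with `"adipose"` it applies to the adipose region alone.
#'
#' @param model an `fe_model` with a tagged adipose region.
#' @param state the Day-0 state.
#' @param settings a [solver_settings].
#' @param total_loss target fractional volume loss, default 0.40 (the
#'   clinically representative one-year loss under adjuvant radiotherapy).
#' @param n_increments growth ramp increments.
#' @param loss_accounting `"flap"` or `"adipose"`.
#' @param tol relative tolerance on the achieved loss (default 0.02).
#' @param max_calibration calibration passes after the initial ramp.
#' @return list: `model` (carrying the calibrated growth), `state`
#'   ("1 year"), `achieved_loss`, `lambda_g`.
#' @export
atrophy_step <- function(model, state, settings = solver_settings(),
                         total_loss = 0.40, n_increments = 6L,
                         loss_accounting = c("adipose", "flap"),
                         tol = 0.02, max_calibration = 4L,
                         horizon = 365 * 86400) {
  loss_accounting <- match.arg(loss_accounting)
  stopifnot(total_loss >= 0, total_loss < 1)
  if (!any(model$mesh$region == "adipose"))
    stop("no adipose region tagged; nothing to atrophy")
  if (total_loss == 0)
    return(list(model = model, state = state, achieved_loss = 0,
                lambda_g = 1))
  v_flap0 <- deformed_volume(model, state, c("skin", "adipose"))
  v_adip0 <- deformed_volume(model, state, "adipose")
  v_ref <- if (loss_accounting == "flap") v_flap0 else v_adip0
  lam3 <- if (loss_accounting == "flap")
    1 - total_loss * v_flap0 / v_adip0 else 1 - total_loss
  if (lam3 <= 0.02)
    stop("requested loss exceeds what the adipose region can supply")
  # atrophy scales the adipose growth tensor isotropically on top of any
  # overbulking prestretch
  g0 <- model$growth_lambda_region[["adipose"]]
  if (is.null(g0)) g0 <- c(trans = 1, axial = 1)
  at_scale <- function(s)
    apply_growth(model, "adipose", s * g0[["trans"]],
                 axial = s * g0[["axial"]])
  solve_scale <- function(s_from, s_to, n) {
    s_done <- s_from
    ds <- (s_to - s_from) / n
    while (abs(s_done - s_to) > 1e-12) {
      s <- if (s_to >= s_from) min(s_to, s_done + ds) else max(s_to, s_done + ds)
      s <- s_done + sign(s_to - s_from) * min(abs(ds), abs(s_to - s_done))
      m_try <- at_scale(s)
      st <- newton_solve(m_try, state, settings, dt = Inf)
      if (isTRUE(st$converged)) {
        model <<- m_try
        state <<- st
        s_done <- s
        ds <- sign(s_to - s_from) * min(abs(ds) * 1.5, abs(s_to - s_from) / n)
      } else {
        ds <- ds / 2
        if (abs(ds) < abs(s_to - s_from) / (n * 64))
          stop("atrophy growth ramp failed at scale ", s)
      }
    }
    s_to
  }
  s_cur <- solve_scale(1, lam3^(1 / 3), n_increments)
  measure <- function(st) {
    v <- deformed_volume(model, st,
                         if (loss_accounting == "flap")
                           c("skin", "adipose") else "adipose")
    1 - v / v_ref
  }
  achieved <- measure(state)
  it <- 0L
  while (abs(achieved - total_loss) > tol * max(total_loss, 0.05) &&
         it < max_calibration) {
    it <- it + 1L
    v_fin <- deformed_volume(model, state, c("skin", "adipose"))
    v_adip_fin <- deformed_volume(model, state, "adipose")
    target_v <- (1 - total_loss) * v_ref
    other <- if (loss_accounting == "flap") v_fin - v_adip_fin else 0
    s_new <- s_cur * (max(0.02, target_v - other) / v_adip_fin)^(1 / 3)
    s_cur <- solve_scale(s_cur, s_new, 1)
    achieved <- measure(state)
  }
  if (abs(achieved - total_loss) > 2 * tol)
    warning(sprintf("atrophy calibration off target: achieved %.3f vs %.3f",
                    achieved, total_loss))
  state$time <- state$time + horizon
  list(model = model, state = state, achieved_loss = achieved,
       lambda_g = s_cur,
       growth = model$growth_lambda_region[["adipose"]])
}
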