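#' Uniaxial stress-stretch curve container
#'
#' @param stretch stretches \eqn{\lambda \ge 1}, strictly increasing, first
#'   entry 1.
#' @param stress stresses (kPa), same length; first entry 0 (within 1e-6 of
#'   the curve's stress scale).
#' @param stress_kind `"nominal"` (first Piola, the usual experimental
#'   reporting) or `"cauchy"`.
#' @return An object of class `ss_curve`.
#' @export
ss_curve <- function(stretch, stress, stress_kind = c("nominal", "cauchy")) {
  stress_kind <- match.arg(stress_kind)
  stretch <- as.numeric(stretch); stress <- as.numeric(stress)
  stopifnot(length(stretch) == length(stress), length(stretch) >= 1L)
  if (any(diff(stretch) <= 0))
    stop("stretches must be strictly increasing")
  if (any(stretch < 1) || abs(stretch[1] - 1) > 1e-9)
    stop("curve must start at lambda = 1 (tension only)")
  scale <- max(abs(stress), 1e-12)
  if (abs(stress[1]) > 1e-6 * scale)
    stop("stress at lambda = 1 must be zero")
  structure(list(stretch = stretch, stress = stress,
                 stress_kind = stress_kind),
            class = "ss_curve")
}

#' Predicted uniaxial curve of a material
#'
#' Incompressible closed-form uniaxial response of the material's isochoric
#' part on a stretch grid (tension only).
#'
#' @param mat material or hyperelastic parameter object.
#' @param stretches grid of stretches, all \eqn{\ge 1}.
#' @param stress_kind stress measure for the returned curve.
#' @return An [ss_curve].
#' @export
uniaxial_curve <- function(mat, stretches,
                           stress_kind = c("nominal", "cauchy")) {
  stress_kind <- match.arg(stress_kind)
  stretches <- sort(as.numeric(stretches))
  if (any(stretches < 1))
    stop("compression stretches (lambda < 1) are out of scope")
  s <- if (stress_kind == "nominal")
    uniaxial_nominal_incompressible(mat, stretches)
  else uniaxial_stress_incompressible(mat, stretches)
  ss_curve(stretches, s, stress_kind)
}

#' Read / write stress-stretch curves as two-column CSV
#'
#' @param path file path; header line `stretch,stress_kPa`.
#' @param curve an [ss_curve] (for writing).
#' @param stress_kind measure recorded in the file (not stored in the CSV).
#' @return `read_ss_curve` returns an [ss_curve]; `write_ss_curve` its path,
#'   invisibly.
#' @export
read_ss_curve <- function(path, stress_kind = c("nominal", "cauchy")) {
  d <- read.csv(path)
  ss_curve(d[[1]], d[[2]], match.arg(stress_kind))
}

#' @rdname read_ss_curve
#' @export
write_ss_curve <- function(curve, path) {
  write.csv(data.frame(stretch = curve$stretch, stress_kPa = curve$stress),
            path, row.names = FALSE)
  invisible(path)
}

# Differential evolution (rand/1/bin) over a box, followed by an L-BFGS-B
# polish of the best member. Deterministic given `seed`; the caller's RNG
# state is left untouched.
de_optimize <- function(fn, lower, upper, seed, n_pop = 40L, n_gen = 200L,
                        cr = 0.9, f_weight = 0.7, tol = 1e-10) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  pop <- matrix(runif(n_pop * d, lower, upper), nrow = n_pop, byrow = TRUE)
  cost <- apply(pop, 1, fn)
  for (g in seq_len(n_gen)) {
    for (i in seq_len(n_pop)) {
      idx <- sample(setdiff(seq_len(n_pop), i), 3L)
      trial <- pop[idx[1], ] + f_weight * (pop[idx[2], ] - pop[idx[3], ])
      mask <- runif(d) < cr
      mask[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(mask, trial, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      tc <- fn(trial)
      if (tc <= cost[i]) { pop[i, ] <- trial; cost[i] <- tc }
    }
    if (diff(range(cost)) < tol) break
  }
  best <- which.min(cost)
  pol <- tryCatch(
    optim(pop[best, ], fn, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 500)),
    error = function(e) list(par = pop[best, ], value = cost[best],
                             convergence = 1L))
  if (pol$value <= cost[best])
    list(par = pol$par, value = pol$value, converged = pol$convergence == 0L)
  else
    list(par = pop[best, ], value = cost[best], converged = TRUE)
}

#' Fit an Ogden model to a uniaxial stress-stretch curve
#'
#' Stochastic global search (differential evolution) plus a local polish,
#' minimizing the root-mean-square stress misfit on the target grid.
#' Candidate parameter sets whose implied small-strain shear modulus is
#' non-positive are rejected by penalty, so fits are always mechanically
#' admissible. Parameter non-identifiability is expected (different Ogden
#' term sets can produce nearly identical curves); the misfit, not the
#' parameters, is the quality criterion.
#'
#' @param target an [ss_curve] with at least 8 samples.
#' @param n_terms number of Ogden terms (default 2).
#' @param bounds list with elements `c` and `m`, each a length-2 numeric
#'   range applied to every term of that kind; finite.
#' @param seed integer seed; the same seed returns an identical fit.
#' @param k bulk modulus assigned to the fitted parameter set (kPa).
#' @param n_pop,n_gen evolutionary search size (population, generations).
#' @return List of class `ogden_fit` with `params` ([ogden_params]),
#'   `residual` (RMS misfit, kPa), `converged`, `seed`.
#' @export
fit_ogden <- function(target, n_terms = 2L,
                      bounds = list(c = c(-200, 500), m = c(0.5, 45)),
                      seed = 1L, k = 200, n_pop = 40L, n_gen = 200L) {
  stopifnot(inherits(target, "ss_curve"))
  if (length(target$stretch) < 8L)
    stop("need at least 8 samples on the target curve")
  if (max(abs(target$stress)) <= 0)
    stop("degenerate target: all stresses are zero")
  if (!all(is.finite(unlist(bounds))))
    stop("bounds must be finite")
  if (bounds$c[1] >= bounds$c[2] || bounds$m[1] >= bounds$m[2])
    stop("infeasible bounds")
  lam <- target$stretch
  obs <- target$stress
  nominal <- target$stress_kind == "nominal"
  predict_stress <- function(cs, ms) {
    s <- Reduce(`+`, lapply(seq_along(cs), function(i)
      cs[i] / ms[i] * (lam^ms[i] - lam^(-ms[i] / 2))))
    if (nominal) s / lam else s
  }
  misfit <- function(par) {
    cs <- par[seq_len(n_terms)]
    ms <- par[n_terms + seq_len(n_terms)]
    # numeric small-strain modulus of the candidate (uniaxial tangent / 3)
    h <- 1e-5
    mu <- sum(cs / ms * ((1 + h)^ms - (1 + h)^(-ms / 2)) -
              cs / ms * ((1 - h)^ms - (1 - h)^(-ms / 2))) / (2 * h) / 3
    if (!is.finite(mu) || mu <= 0) return(1e8)
    r <- predict_stress(cs, ms) - obs
    v <- sqrt(mean(r^2))
    if (!is.finite(v)) 1e8 else v
  }
  lower <- c(rep(bounds$c[1], n_terms), rep(bounds$m[1], n_terms))
  upper <- c(rep(bounds$c[2], n_terms), rep(bounds$m[2], n_terms))
  res <- de_optimize(misfit, lower, upper, seed = seed,
                     n_pop = n_pop, n_gen = n_gen)
  params <- ogden_params(res$par[seq_len(n_terms)],
                         res$par[n_terms + seq_len(n_terms)], k = k)
  structure(list(params = params, residual = res$value,
                 converged = res$converged, seed = as.integer(seed)),
            class = "ogden_fit")
}

#' @export
print.ogden_fit <- function(x, ...) {
  cat(sprintf("<ogden_fit> RMS misfit %.4g kPa, %s (seed %d)\n", x$residual,
              if (x$converged) "converged" else "not converged", x$seed))
  cat(sprintf("  c = (%s) kPa, m = (%s)\n",
              paste(signif(x$params$c, 5), collapse = ", "),
              paste(signif(x$params$m, 5), collapse = ", ")))
  invisible(x)
}

#' Calibrate low / mid / high stiffness levels from three target curves
#'
#' Fits a two-term Ogden model to each of three pointwise-ordered target
#' curves (e.g. mean - SD, mean, mean + SD bands of experimental donor-skin
#' data), mirroring a three-level donor-site stiffness parameterization.
#' Crossing targets trigger a warning but the fits proceed.
#'
#' @param curves named list with elements `low`, `mid`, `high`, each an
#'   [ss_curve] on a common stretch grid.
#' @param seed integer seed (per-level seeds derived by offset).
#' @param ... forwarded to [fit_ogden].
#' @return Named list of three `ogden_fit` objects (`low`, `mid`, `high`).
#' @export
build_stiffness_levels <- function(curves, seed = 1L, ...) {
  stopifnot(all(c("low", "mid", "high") %in% names(curves)))
  lows <- curves$low$stress; mids <- curves$mid$stress
  highs <- curves$high$stress
  if (any(lows > mids + 1e-9) || any(mids > highs + 1e-9))
    warning("target curves cross; fitting anyway")
  fits <- list(low  = fit_ogden(curves$low,  seed = seed, ...),
               mid  = fit_ogden(curves$mid,  seed = seed + 1L, ...),
               high = fit_ogden(curves$high, seed = seed + 2L, ...))
  fits
}
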