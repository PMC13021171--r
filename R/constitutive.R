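#' Strain-energy density of a hyperelastic material
#'
#' Evaluates the uncoupled (isochoric + volumetric) strain energy for the
#' Yeoh or Ogden (FEBio convention) model at a deformation gradient `F`.
#' The isochoric part acts on the deviatoric invariants
#' \eqn{\bar I_1 = J^{-2/3} I_1} (Yeoh) or deviatoric stretches
#' \eqn{\bar\lambda_a = J^{-1/3}\lambda_a} (Ogden); the volumetric part is
#' \eqn{\frac{k}{2}(\ln J)^2}.
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @param mat an [nt_material] (its viscoelastic part is ignored here) or a
#'   bare `hyperelastic_params` object.
#' @return Energy density (kPa).
#' @export
strain_energy <- function(F, mat) {
  he <- as_hyper(mat)
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3L, 3L)))
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("invalid deformation: det(F) must be positive")
  vol <- he$k / 2 * log(J)^2
  if (he$model == "yeoh") {
    I1b <- J^(-2 / 3) * sum(F * F)
    iso <- sum(he$c * (I1b - 3)^seq_along(he$c))
  } else {
    lb <- J^(-1 / 3) * sqrt(eigen(crossprod(F), symmetric = TRUE,
                                  only.values = TRUE)$values)
    iso <- sum(he$c / he$m^2 * (colSums(outer(lb, he$m, `^`)) - 3))
  }
  iso + vol
}

#' Cauchy stress of a hyperelastic material
#'
#' Analytic Cauchy stress consistent with [strain_energy]: invariant
#' derivatives for Yeoh, spectral (principal-stretch) derivatives for Ogden.
#' The spectral route stays well defined at coincident principal stretches
#' because the principal Kirchhoff values depend continuously on the
#' stretches; eigenvectors of the left Cauchy-Green tensor are used directly.
#'
#' @inheritParams strain_energy
#' @return 3x3 symmetric Cauchy stress (kPa).
#' @export
cauchy_stress <- function(F, mat) {
  he <- as_hyper(mat)
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3L, 3L)))
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("invalid deformation: det(F) must be positive")
  I3 <- diag(3)
  if (he$model == "yeoh") {
    b <- tcrossprod(F)                       # F F^T
    I1b <- J^(-2 / 3) * sum(diag(b))
    psi1 <- sum(he$c * seq_along(he$c) * (I1b - 3)^(seq_along(he$c) - 1))
    dev_b <- J^(-2 / 3) * b - I1b / 3 * I3   # dev(bbar)
    sig <- 2 / J * psi1 * dev_b
  } else {
    eb <- eigen(tcrossprod(F), symmetric = TRUE)
    lam <- sqrt(pmax(eb$values, 0))
    lb <- J^(-1 / 3) * lam
    beta <- colSums(he$c / he$m * t(outer(lb, he$m, `^`)))  # beta_a
    tau <- beta - mean(beta)
    sig <- eb$vectors %*% diag(tau / J) %*% t(eb$vectors)
  }
  sig <- sig + he$k * log(J) / J * I3
  (sig + t(sig)) / 2
}

#' First Piola-Kirchhoff stress
#'
#' \eqn{P = J \sigma F^{-T}}; convenient for finite-difference consistency
#' checks against [strain_energy].
#'
#' @inheritParams strain_energy
#' @return 3x3 first Piola-Kirchhoff stress (kPa).
#' @export
pk1_stress <- function(F, mat) {
  F <- as.matrix(F)
  det(F) * cauchy_stress(F, mat) %*% t(solve(F))
}

# Deviatoric second Piola-Kirchhoff stress (reference configuration), used as
# the elastic input of the viscoelastic hereditary integral.
dev_pk2_stress <- function(F, mat) {
  he <- as_hyper(mat)
  F <- as.matrix(F)
  J <- det(F)
  sig <- cauchy_stress(F, mat) - he$k * log(J) / J * diag(3)
  Fi <- solve(F)
  J * Fi %*% sig %*% t(Fi)
}

as_hyper <- function(mat) {
  if (inherits(mat, "nt_material")) mat$hyperelastic
  else if (inherits(mat, "hyperelastic_params")) mat
  else stop("expected an nt_material or hyperelastic parameter object")
}

as_prony <- function(x) {
  if (inherits(x, "nt_material")) {
    if (is.null(x$viscoelastic)) prony_series() else x$viscoelastic
  } else if (inherits(x, "prony_series")) x
  else stop("expected a prony_series or nt_material")
}

#' Prony relaxation function G(t)
#'
#' \eqn{G(t) = 1 + \sum_i \gamma_i e^{-t/\tau_i}}; monotone non-increasing
#' with \eqn{G(\infty) = 1}. An empty series gives \eqn{G \equiv 1}.
#'
#' @param p a `prony_series` (or a material carrying one).
#' @param t time (s), non-negative; vectorized.
#' @return Dimensionless relaxation modulus, same length as `t`.
#' @export
relaxation_function <- function(p, t) {
  p <- as_prony(p)
  stopifnot(is.numeric(t))
  if (any(t < 0)) stop("t must be non-negative")
  if (p$N == 0L) return(rep(1, length(t)))
  1 + colSums(p$gamma * exp(-outer(p$tau, t, function(tau, t) t / tau)))
}

#' Percent of transient stress relaxation completed
#'
#' Fraction of the decaying (transient) part of \eqn{G(t)} that has elapsed
#' by time `t`:
#' \deqn{100\,\Big(1 - \frac{\sum_i \gamma_i e^{-t/\tau_i}}
#'   {\sum_i \gamma_i}\Big)\;\%.}
#' Used to justify the five-minute post-suturing equilibration stage: at
#' t = 300 s the packaged tissues have essentially completed their transient
#' relaxation.
#'
#' @inheritParams relaxation_function
#' @return Percentage in \[0, 100\], vectorized over `t`.
#' @export
relaxation_completion <- function(p, t) {
  p <- as_prony(p)
  if (any(t < 0)) stop("t must be non-negative")
  tot <- sum(p$gamma)
  if (p$N == 0L || tot <= 0)
    stop("relaxation completion undefined: series has no transient part")
  rem <- colSums(p$gamma * exp(-outer(p$tau, t, function(tau, t) t / tau)))
  100 * (1 - rem / tot)
}

#' Initialize viscoelastic history
#'
#' One exponential state tensor per Prony term plus the last elastic
#' deviatoric stress. A cleared history reproduces the purely hyperelastic
#' (long-term) response under slow loading and the instantaneous
#' \eqn{G(0)}-scaled response under fast loading.
#'
#' @param p a `prony_series`.
#' @return An object of class `visco_history`.
#' @export
visco_history <- function(p) {
  p <- as_prony(p)
  structure(list(H = replicate(p$N, matrix(0, 3, 3), simplify = FALSE),
                 S_prev = matrix(0, 3, 3), N = p$N),
            class = "visco_history")
}

#' One-step viscoelastic stress update
#'
#' Exponential-recursion discretization of the hereditary integral
#' \eqn{S(t) = \int_{-\infty}^t G(t-s)\, \dot S^e(s)\, ds} with midpoint
#' weighting of the increment:
#' \deqn{H_i^{n+1} = e^{-\Delta t/\tau_i} H_i^n +
#'       \gamma_i e^{-\Delta t/(2\tau_i)} (S^{e,n+1} - S^{e,n}),\qquad
#'       S^{n+1} = S^{e,n+1} + \sum_i H_i^{n+1}.}
#' The recursion is exact for pure decay (constant \eqn{S^e}) and first-order
#' accurate during ramps.
#'
#' @param h a `visco_history` from [visco_history] (updated copy returned).
#' @param S_e_new 3x3 elastic deviatoric second Piola-Kirchhoff stress at the
#'   end of the step (kPa).
#' @param dt time-step size (s), positive.
#' @param p the `prony_series` the history belongs to.
#' @return List with `stress` (3x3 total deviatoric stress) and `history`
#'   (updated `visco_history`).
#' @export
visco_stress_update <- function(h, S_e_new, dt, p) {
  p <- as_prony(p)
  stopifnot(inherits(h, "visco_history"), dt > 0)
  if (h$N != p$N) stop("history length does not match Prony series")
  S_e_new <- as.matrix(S_e_new)
  if (p$N == 0L)
    return(list(stress = S_e_new, history = h))
  dS <- S_e_new - h$S_prev
  S <- S_e_new
  for (i in seq_len(p$N)) {
    h$H[[i]] <- exp(-dt / p$tau[i]) * h$H[[i]] +
      p$gamma[i] * exp(-dt / (2 * p$tau[i])) * dS
    S <- S + h$H[[i]]
  }
  h$S_prev <- S_e_new
  list(stress = S, history = h)
}

#' Incompressible uniaxial Cauchy stress (closed form)
#'
#' Closed-form uniaxial Cauchy stress of the isochoric part under the
#' incompressibility assumption \eqn{\lambda_2 = \lambda_3 =
#' \lambda^{-1/2}}:
#' Yeoh \eqn{\sigma = 2(\lambda^2 - \lambda^{-1})\,(c_1 + 2 c_2 (I_1 - 3)
#'   + \dots)}; Ogden (FEBio)
#' \eqn{\sigma = \sum_i \frac{c_i}{m_i}(\lambda^{m_i} - \lambda^{-m_i/2})}.
#'
#' @param mat material or hyperelastic parameter object.
#' @param lambda axial stretch(es), > 0; vectorized.
#' @return Cauchy stress (kPa), same length as `lambda`.
#' @export
uniaxial_stress_incompressible <- function(mat, lambda) {
  he <- as_hyper(mat)
  stopifnot(all(lambda > 0))
  if (he$model == "yeoh") {
    I1 <- lambda^2 + 2 / lambda
    psi1 <- Reduce(`+`, lapply(seq_along(he$c), function(i)
      he$c[i] * i * (I1 - 3)^(i - 1)))
    2 * (lambda^2 - 1 / lambda) * psi1
  } else {
    Reduce(`+`, lapply(seq_along(he$c), function(i)
      he$c[i] / he$m[i] * (lambda^he$m[i] - lambda^(-he$m[i] / 2))))
  }
}

#' Incompressible uniaxial nominal (first Piola) stress
#'
#' `uniaxial_stress_incompressible` divided by the axial stretch.
#'
#' @inheritParams uniaxial_stress_incompressible
#' @return Nominal stress (kPa).
#' @export
uniaxial_nominal_incompressible <- function(mat, lambda) {
  uniaxial_stress_incompressible(mat, lambda) / lambda
}
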