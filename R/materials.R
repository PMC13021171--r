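#' Yeoh hyperelastic parameters
#'
#' Reduced-polynomial (Yeoh) strain energy
#' \deqn{\Psi = \sum_{i=1}^N c_i (\bar I_1 - 3)^i + \frac{k}{2}(\ln J)^2}
#' with deviatoric first invariant \eqn{\bar I_1 = J^{-2/3} I_1} and bulk
#' modulus \eqn{k}. Used for the native tongue.
#'
#' @param c numeric vector of coefficients \eqn{c_i} (kPa); `c[1] > 0`.
#' @param k bulk modulus (kPa), positive.
#' @return An object of class `yeoh_params`.
#' @export
yeoh_params <- function(c, k) {
  c <- as.numeric(c)
  stopifnot(length(c) >= 1L, is.finite(c), c[1] > 0, is.finite(k), k > 0)
  structure(list(model = "yeoh", c = c, k = as.numeric(k), N = length(c)),
            class = c("yeoh_params", "hyperelastic_params"))
}

#' Ogden hyperelastic parameters (FEBio convention)
#'
#' Strain energy
#' \deqn{\Psi = \sum_{i=1}^N \frac{c_i}{m_i^2}
#'   (\bar\lambda_1^{m_i} + \bar\lambda_2^{m_i} + \bar\lambda_3^{m_i} - 3)
#'   + \frac{k}{2}(\ln J)^2}
#' on the deviatoric principal stretches \eqn{\bar\lambda_a = J^{-1/3}\lambda_a}.
#' Individual \eqn{c_i} may be negative (some thigh-skin profiles are), but the
#' implied small-strain shear modulus must be positive.
#'
#' @param c numeric vector of coefficients \eqn{c_i} (kPa).
#' @param m numeric vector of dimensionless exponents \eqn{m_i}, same length.
#' @param k bulk modulus (kPa), positive.
#' @param check_modulus verify the implied ground-state shear modulus is
#'   positive (default `TRUE`).
#' @return An object of class `ogden_params`.
#' @export
ogden_params <- function(c, m, k, check_modulus = TRUE) {
  c <- as.numeric(c); m <- as.numeric(m)
  stopifnot(length(c) == length(m), length(c) >= 1L,
            is.finite(c), is.finite(m), all(m != 0), is.finite(k), k > 0)
  p <- structure(list(model = "ogden", c = c, m = m, k = as.numeric(k),
                      N = length(c)),
                 class = c("ogden_params", "hyperelastic_params"))
  if (check_modulus) {
    mu <- ogden_shear_modulus(p)
    if (!is.finite(mu) || mu <= 0)
      stop("Ogden term set implies a non-positive small-strain shear modulus")
  }
  p
}

#' Ground-state shear modulus of an Ogden term set
#'
#' For the FEBio convention the small-strain (incompressible) shear modulus is
#' \eqn{\mu = \frac{1}{2}\sum_i c_i \frac{m_i - 1}{m_i}
#'   + \frac{1}{2}\sum_i \frac{c_i}{m_i}} ... evaluated here numerically from
#' the uniaxial tangent at \eqn{\lambda = 1} (robust for any term signs):
#' \eqn{E = d\sigma/d\lambda|_{\lambda=1}}, \eqn{\mu = E/3}.
#'
#' @param p an `ogden_params` or `yeoh_params` object.
#' @return shear modulus (kPa).
#' @export
ogden_shear_modulus <- function(p) {
  h <- 1e-5
  s <- function(l) uniaxial_stress_incompressible(p, l)
  (s(1 + h) - s(1 - h)) / (2 * h) / 3
}

#' Prony relaxation series
#'
#' Dimensionless relaxation function \eqn{G(t) = 1 + \sum_i \gamma_i
#' e^{-t/\tau_i}} used for quasi-linear viscoelasticity; \eqn{G(\infty) = 1}
#' so the hyperelastic response is the long-term equilibrium response.
#'
#' @param gamma dimensionless relaxation coefficients \eqn{\gamma_i \ge 0};
#'   may be empty (purely elastic).
#' @param tau relaxation times \eqn{\tau_i} (s), positive, same length.
#' @return An object of class `prony_series`.
#' @export
prony_series <- function(gamma = numeric(0), tau = numeric(0)) {
  gamma <- as.numeric(gamma); tau <- as.numeric(tau)
  stopifnot(length(gamma) == length(tau), all(gamma >= 0), all(tau > 0))
  structure(list(gamma = gamma, tau = tau, N = length(gamma)),
            class = "prony_series")
}

#' Assemble a material from hyperelastic and viscoelastic parts
#'
#' @param hyperelastic a `yeoh_params` or `ogden_params` object.
#' @param viscoelastic a `prony_series` or `NULL` for a purely elastic tissue.
#' @param label tissue name; the packaged library uses
#'   `tongue`, `adipose`, `forearm-skin-L1..L3`, `thigh-skin-L1..L3`.
#' @param density mass density (kg/mm^3); default 1.05e-6 (soft tissue).
#' @return An object of class `nt_material`.
#' @export
nt_material <- function(hyperelastic, viscoelastic = NULL, label = "custom",
                        density = 1.05e-6) {
  stopifnot(inherits(hyperelastic, "hyperelastic_params"),
            is.null(viscoelastic) || inherits(viscoelastic, "prony_series"))
  structure(list(hyperelastic = hyperelastic, viscoelastic = viscoelastic,
                 label = label, density = density),
            class = "nt_material")
}

#' @export
print.nt_material <- function(x, ...) {
  he <- x$hyperelastic
  cat(sprintf("<nt_material '%s'>\n", x$label))
  if (he$model == "yeoh")
    cat(sprintf("  Yeoh N=%d  c = (%s) kPa, k = %g kPa\n", he$N,
                paste(signif(he$c, 4), collapse = ", "), he$k))
  else
    cat(sprintf("  Ogden N=%d  c = (%s) kPa, m = (%s), k = %g kPa\n", he$N,
                paste(signif(he$c, 4), collapse = ", "),
                paste(signif(he$m, 4), collapse = ", "), he$k))
  if (!is.null(x$viscoelastic) && x$viscoelastic$N > 0)
    cat(sprintf("  Prony N=%d  gamma = (%s), tau = (%s) s\n",
                x$viscoelastic$N,
                paste(signif(x$viscoelastic$gamma, 4), collapse = ", "),
                paste(signif(x$viscoelastic$tau, 5), collapse = ", ")))
  invisible(x)
}

#' Load the packaged soft-tissue material library
#'
#' Reads the YAML material file shipped with the package (native tongue,
#' subcutaneous adipose, and six donor-skin stiffness profiles: three for
#' forearm, three for thigh). Coefficients stored in Pa (`*_Pa` fields) are
#' converted to kPa on load.
#'
#' @param path optional path to an alternative YAML library file.
#' @return Named list of [nt_material] objects.
#' @export
material_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "materials.yaml", package = "neotongue")
  raw <- yaml::read_yaml(path)$materials
  out <- lapply(names(raw), function(nm) {
    r <- raw[[nm]]
    cs <- if (!is.null(r$c_kPa)) as.numeric(r$c_kPa)
          else c(as.numeric(r$c1_kPa), as.numeric(r$c2_Pa) * 1e-3)
    he <- if (identical(r$model, "yeoh")) yeoh_params(cs, r$k_kPa)
          else ogden_params(cs, as.numeric(r$m), r$k_kPa)
    ve <- if (!is.null(r$prony))
      prony_series(as.numeric(r$prony$gamma), as.numeric(r$prony$tau_s))
    nt_material(he, ve, label = nm)
  })
  names(out) <- names(raw)
  out
}

# Internal: flatten a material to the numeric vector consumed by the C++
# element kernels: c(model_id, k, N, c..., m...) with model_id 0=yeoh 1=ogden.
material_code <- function(mat) {
  he <- mat$hyperelastic
  if (he$model == "yeoh") c(0, he$k, he$N, he$c)
  else c(1, he$k, he$N, he$c, he$m)
}
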