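# Hyperelastic energies and stresses against closed forms, and the
# Prony-series quasi-linear viscoelasticity machinery.

test_that("material library carries the full packaged tissue set", {
  expect_setequal(names(lib),
                  c("tongue", "adipose",
                    paste0("forearm-skin-L", 1:3), paste0("thigh-skin-L", 1:3)))
  expect_s3_class(lib$tongue$hyperelastic, "yeoh_params")
  expect_s3_class(lib$adipose$hyperelastic, "ogden_params")
  # Pa-valued second skin coefficients are converted to kPa on load
  expect_equal(lib$`forearm-skin-L1`$hyperelastic$c[2], 1.39e-3)
  expect_equal(lib$`thigh-skin-L3`$hyperelastic$c[2], -120e-3)
})

test_that("strain energy matches hand evaluation and degenerate limits", {
  # undeformed reference
  for (m in lib) expect_equal(strain_energy(diag(3), m), 0)
  # isochoric uniaxial Yeoh, hand evaluation
  F <- diag(c(1.2, 1 / sqrt(1.2), 1 / sqrt(1.2)))
  I1 <- 1.44 + 2 / 1.2
  expect_equal(strain_energy(F, lib$tongue),
               1.037 * (I1 - 3) + 0.486 * (I1 - 3)^2, tolerance = 1e-12)
  # pure dilation: volumetric part only
  a <- 1.07
  expect_equal(strain_energy(a * diag(3), lib$tongue),
               100 / 2 * log(a^3)^2, tolerance = 1e-10)
  expect_equal(strain_energy(a * diag(3), lib$adipose),
               100 / 2 * log(a^3)^2, tolerance = 1e-10)
  expect_error(strain_energy(diag(c(-1, 1, 1)), lib$tongue),
               "det")
})

test_that("cauchy stress matches incompressible uniaxial closed forms", {
  F <- function(l) diag(c(l, 1 / sqrt(l), 1 / sqrt(l)))
  s <- cauchy_stress(F(1.2), lib$tongue)
  expect_equal(s[1, 1] - s[2, 2], 1.384, tolerance = 1e-3)
  s2 <- cauchy_stress(F(1.1), lib$adipose)
  expect_equal(s2[1, 1] - s2[2, 2], 1.530, tolerance = 1e-3)
  expect_equal(cauchy_stress(diag(3), lib$`thigh-skin-L2`),
               matrix(0, 3, 3), tolerance = 1e-12)
})

test_that("stress is the energy derivative on random deformations", {
  Fs <- random_F(100)
  mats <- lib[c("tongue", "adipose", "forearm-skin-L2", "thigh-skin-L1")]
  h <- 1e-6
  for (m in mats) {
    for (F in Fs[seq(1, 100, by = 4)]) {
      P <- pk1_stress(F, m)
      Pfd <- matrix(0, 3, 3)
      for (i in 1:3) for (j in 1:3) {
        Fp <- F; Fp[i, j] <- Fp[i, j] + h
        Fm <- F; Fm[i, j] <- Fm[i, j] - h
        Pfd[i, j] <- (strain_energy(Fp, m) - strain_energy(Fm, m)) / (2 * h)
      }
      expect_lt(max(abs(P - Pfd)) / max(abs(P)), 1e-5)
    }
  }
})

test_that("energy is objective and the isochoric/volumetric split is exact", {
  set.seed(7)
  for (F in random_F(10, seed = 7)) {
    Q <- random_rotation()
    for (m in lib[c("tongue", "adipose", "thigh-skin-L2")]) {
      expect_equal(strain_energy(Q %*% F, m), strain_energy(F, m),
                   tolerance = 1e-10)
      # unimodular part has zero volumetric energy: total equals isochoric
      Fb <- det(F)^(-1 / 3) * F
      he <- m$hyperelastic
      he_k0 <- he; he_k0$k <- 1e-12
      expect_equal(strain_energy(Fb, he), strain_energy(F, he_k0),
                   tolerance = 1e-8)
    }
  }
})

test_that("all packaged materials have a positive small-strain shear modulus", {
  for (m in lib) expect_gt(ogden_shear_modulus(m$hyperelastic), 0)
  # the negative-c2 thigh profiles are the delicate cases
  expect_gt(ogden_shear_modulus(lib$`thigh-skin-L1`$hyperelastic), 0)
  expect_gt(ogden_shear_modulus(lib$`thigh-skin-L3`$hyperelastic), 0)
  expect_error(ogden_params(c(-10), c(2), 100), "shear modulus")
})

test_that("relaxation function has the right limits and monotonicity", {
  p <- lib$tongue$viscoelastic
  expect_equal(relaxation_function(p, 0), 1 + sum(p$gamma))
  expect_equal(relaxation_function(p, 1e9), 1, tolerance = 1e-12)
  t <- seq(0, 500, by = 0.5)
  expect_true(all(diff(relaxation_function(p, t)) <= 0))
  expect_equal(relaxation_function(prony_series(), c(0, 5, 100)),
               c(1, 1, 1))
  expect_error(relaxation_function(p, -1), "non-negative")
})

test_that("relaxation completion reproduces the five-minute percentages", {
  expect_equal(round(relaxation_completion(lib$tongue, 300), 1), 97.1)
  expect_equal(round(relaxation_completion(lib$`forearm-skin-L2`, 300), 1),
               97.8)
  expect_equal(round(relaxation_completion(lib$adipose, 300), 0), 100)
  expect_equal(relaxation_completion(lib$tongue, 0), 0)
  t <- seq(0, 400, by = 1)
  expect_true(all(diff(relaxation_completion(lib$tongue, t)) >= 0))
  expect_true(all(relaxation_completion(lib$adipose, t) >= 0 &
                    relaxation_completion(lib$adipose, t) <= 100))
  expect_error(relaxation_completion(prony_series(), 10), "undefined|transient")
})

test_that("viscoelastic recursion reproduces the analytic step response", {
  # empty series: identity
  h0 <- visco_history(prony_series())
  S <- matrix(c(1, 0.2, 0, 0.2, -0.5, 0, 0, 0, -0.5), 3, 3)
  expect_equal(visco_stress_update(h0, S, 1, prony_series())$stress, S)

  # single-term series, step input applied at t = 0+, sampled at t = tau
  p1 <- prony_series(gamma = 2, tau = 4)
  run_to <- function(dt, t_end) {
    h <- visco_history(p1)
    up <- visco_stress_update(h, S, 1e-9, p1)   # instantaneous step
    h <- up$history
    t <- 0
    while (t < t_end - 1e-12) {
      up <- visco_stress_update(h, S, dt, p1)
      h <- up$history
      t <- t + dt
    }
    up$stress
  }
  S_tau <- run_to(4 / 100, 4)
  # transient fraction remaining at t = tau is e^{-1}
  frac <- (S_tau[1, 1] - S[1, 1]) / (2 * S[1, 1])
  expect_equal(frac, exp(-1), tolerance = 1e-3)

  # halving dt decreases the error of a ramp-and-hold trace monotonically
  # (reference: the same recursion at a very fine step)
  ramp_hold <- function(dt) {
    h <- visco_history(p1)
    t <- 0
    out <- NULL
    while (t < 4 - 1e-12) {
      t <- t + dt
      Se <- S * min(t, 2) / 2          # linear ramp to t = 2, then hold
      out <- visco_stress_update(h, Se, dt, p1)
      h <- out$history
    }
    out$stress[1, 1]
  }
  ref <- ramp_hold(4 / 4096)
  errs <- vapply(c(1, 0.5, 0.25), function(dt) abs(ramp_hold(dt) - ref),
                 numeric(1))
  expect_true(all(diff(errs) < 0))

  # mismatched history errors
  expect_error(visco_stress_update(visco_history(p1), S, 1,
                                   lib$tongue$viscoelastic),
               "match")
})

test_that("full relaxation trace follows G(t) under a held step", {
  p <- lib$adipose$viscoelastic
  S <- diag(c(2, -1, -1))
  h <- visco_history(p)
  up <- visco_stress_update(h, S, 1e-9, p)
  h <- up$history
  t <- 0; dt <- 0.02
  for (i in 1:500) {   # to t = 10 s
    up <- visco_stress_update(h, S, dt, p)
    h <- up$history
    t <- t + dt
  }
  expect_equal(up$stress[1, 1] / S[1, 1], relaxation_function(p, t),
               tolerance = 5e-3)
})
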