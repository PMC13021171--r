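# Factorial design enumeration, encoding, hierarchical OLS and diagnostics.

test_that("design enumeration is a complete Cartesian product", {
  full <- enumerate_design()
  expect_equal(nrow(full), 120L)
  expect_equal(nrow(unique(full)), 120L)
  expect_equal(nrow(enumerate_design(cases = "A", donors = "forearm",
                                     stiffness_levels = 0,
                                     overbulk_levels = 0)), 1L)
  d <- enumerate_design(cases = c("A", "B"), donors = c("forearm", "thigh"),
                        stiffness_levels = c(-1, 0, 1),
                        overbulk_levels = c(0, 0.2, 0.4, 0.6, 0.8))
  expect_equal(nrow(d), 2 * 2 * 3 * 5)
  expect_equal(nrow(unique(d)), nrow(d))
  # stable deterministic order
  expect_equal(d, enumerate_design(cases = c("A", "B"),
                                   overbulk_levels = c(0, 0.2, 0.4, 0.6,
                                                       0.8)))
})

test_that("encoding decomposes the six profiles into is_thigh x level", {
  out <- enumerate_design()
  dm <- encode_design(out)
  expect_equal(sum(dm$is_thigh), 60)
  expect_setequal(unique(dm$stiffness_level), c(-1, 0, 1))
  fore_mid <- out$donor == "forearm" & out$stiffness_level == 0
  expect_true(all(dm$is_thigh[fore_mid] == 0 &
                    dm$stiffness_level[fore_mid] == 0))
  thigh_hi <- out$donor == "thigh" & out$stiffness_level == 1
  expect_true(all(dm$is_thigh[thigh_hi] == 1 &
                    dm$stiffness_level[thigh_hi] == 1))
  # case dummies: reference A, at most one dummy active per row
  expect_true(all(rowSums(dm[, c("caseB", "caseC", "caseD")]) <= 1))
  expect_true(all(dm[out$case == "A", c("caseB", "caseC", "caseD")] == 0))
  # all-reference table has no dummy columns
  dmA <- encode_design(out[out$case == "A", ])
  expect_false(any(grepl("^case", names(dmA))))
  # unknown labels rejected
  bad <- out; bad$donor[1] <- "calf"
  expect_error(encode_design(bad), "donor")
})

test_that("OLS, nested F-test and VIF agree with brute-force oracles", {
  out <- synthesize_outcomes(
    truth = c(`(Intercept)` = 8, caseB = 1.1, caseC = 1.6, caseD = -0.6,
              overbulk = -3.4, is_thigh = -0.2, stiffness_level = -0.04,
              `overbulk:is_thigh` = 0.5),
    noise_sd = 0.1, seed = 99)
  dm <- encode_design(out)
  h <- fit_hierarchy(dm, "outcome")

  # brute-force normal equations on the main-effects design
  X <- cbind(1, as.matrix(dm[c("caseB", "caseC", "caseD", "overbulk",
                               "is_thigh", "stiffness_level")]))
  y <- dm$outcome
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(coef(h$main)), as.numeric(beta), tolerance = 1e-10)

  # brute-force nested F statistic
  rss <- function(fit) sum(resid(fit)^2)
  df1 <- length(coef(h$interaction)) - length(coef(h$main))
  df2 <- nrow(dm) - length(coef(h$interaction))
  Fb <- ((rss(h$main) - rss(h$interaction)) / df1) / (rss(h$interaction) / df2)
  expect_equal(h$comparison$F, Fb, tolerance = 1e-10)
  expect_equal(h$comparison$p, pf(Fb, df1, df2, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(h$comparison$df, c(df1, df2))

  # the planted strong interaction is detected and recovered
  expect_equal(h$selected_label, "interaction")
  ct <- coef_table(h)
  est <- ct[ct$predictor == "overbulk:is_thigh", ]
  expect_lt(abs(est$coefficient - 0.5), 2 * est$std_error)

  # VIF: brute force via 1/(1-R^2), and 1 for balanced orthogonal columns
  v <- vif_values(h$main)
  P <- X[, -1]
  for (j in seq_len(ncol(P))) {
    r2 <- summary(lm(P[, j] ~ P[, -j]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-10)
  }
  expect_equal(unname(v["stiffness_level"]), 1, tolerance = 1e-12)
  expect_equal(unname(v["is_thigh"]), 1, tolerance = 1e-12)
  expect_false(any(attr(v, "flagged")))
})

test_that("VIF matches the car reference implementation", {
  out <- synthesize_outcomes(
    truth = c(`(Intercept)` = 1, overbulk = 2, is_thigh = 0.5),
    noise_sd = 0.3, seed = 4)
  dm <- encode_design(out)
  fit <- lm(outcome ~ caseB + caseC + caseD + overbulk + is_thigh +
              stiffness_level, data = dm)
  expect_equal(as.numeric(vif_values(fit)), as.numeric(car::vif(fit)),
               tolerance = 1e-10)
})

test_that("main-effects truth is recovered and interactions not selected", {
  truth <- c(`(Intercept)` = 0.226, caseB = 0.051, caseC = 0.052,
             caseD = 0.004, overbulk = 0.093, is_thigh = 0.043,
             stiffness_level = 0.023)
  sel_int <- 0L
  n_rep <- 200L
  n_in <- 0L; n_tot <- 0L
  for (r in seq_len(n_rep)) {
    out <- synthesize_outcomes(truth, noise_sd = 0.02, seed = 1000L + r)
    h <- fit_hierarchy(encode_design(out), "outcome")
    if (h$selected_label == "interaction") sel_int <- sel_int + 1L
    if (r <= 40) {
      s <- summary(h$main)$coefficients
      n_in <- n_in + sum(abs(s[names(truth), 1] - truth) <=
                           2 * s[names(truth), 2])
      n_tot <- n_tot + length(truth)
    }
  }
  # under a pure main-effects truth the interaction model is rarely selected
  expect_lt(sel_int / n_rep, 0.10)
  # ~95% of coefficient draws fall within 2 SE of the truth
  expect_gt(n_in / n_tot, 0.88)
})

test_that("a planted interaction is detected with high power", {
  truth <- c(`(Intercept)` = 1, overbulk = 1, is_thigh = 0.3,
             `overbulk:is_thigh` = 0.5)   # 5x the noise SD
  hits <- 0L
  for (r in seq_len(60)) {
    out <- synthesize_outcomes(truth, noise_sd = 0.1, seed = 2000L + r)
    h <- fit_hierarchy(encode_design(out), "outcome")
    if (h$selected_label == "interaction") hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.95)
})

test_that("noiseless nested models give F near zero when truth is additive", {
  truth <- c(`(Intercept)` = 2, overbulk = -3, is_thigh = 1,
             stiffness_level = 0.5)
  out <- synthesize_outcomes(truth, noise_sd = 0, seed = 1)
  # add an infinitesimal jitter so the residual variance is nonzero
  out$outcome <- out$outcome + rnorm(nrow(out), 0, 1e-9)
  h <- fit_hierarchy(encode_design(out), "outcome")
  expect_lt(h$comparison$F, 10)  # no systematic interaction signal
  expect_equal(unname(coef(h$main)[c("overbulk", "is_thigh")]), c(-3, 1),
               tolerance = 1e-6)
})

test_that("the nested F-test holds its nominal type-I error", {
  truth <- c(`(Intercept)` = 1, overbulk = 2, is_thigh = 0.5,
             stiffness_level = -0.3)
  rej <- 0L
  n_rep <- 500L
  for (r in seq_len(n_rep)) {
    out <- synthesize_outcomes(truth, noise_sd = 0.5, seed = 30000L + r)
    h <- fit_hierarchy(encode_design(out), "outcome")
    if (h$comparison$p < 0.05) rej <- rej + 1L
  }
  expect_equal(rej / n_rep, 0.05, tolerance = 0.4)  # 0.05 +- 0.02
})

test_that("synthetic outcomes are deterministic in the seed and exact at zero noise", {
  truth <- c(`(Intercept)` = 1, overbulk = -2)
  o1 <- synthesize_outcomes(truth, noise_sd = 0.2, seed = 9)
  o2 <- synthesize_outcomes(truth, noise_sd = 0.2, seed = 9)
  o3 <- synthesize_outcomes(truth, noise_sd = 0.2, seed = 10)
  expect_identical(o1$outcome, o2$outcome)
  expect_false(identical(o1$outcome, o3$outcome))
  expect_identical(o1[1:4], o3[1:4])   # same design rows
  o0 <- synthesize_outcomes(truth, noise_sd = 0, seed = 1)
  expect_equal(o0$outcome, 1 - 2 * o0$overbulk)
  expect_error(synthesize_outcomes(c(`overbulk:atrophy` = 1)), "truth term")
})

test_that("fit reports export as JSON and text", {
  out <- synthesize_outcomes(c(`(Intercept)` = 1, overbulk = 2),
                             noise_sd = 0.1, seed = 2)
  h <- fit_hierarchy(encode_design(out), "outcome")
  jf <- tempfile(fileext = ".json"); tf <- tempfile(fileext = ".txt")
  report_fit(h, jf, tf)
  j <- jsonlite::read_json(jf)
  expect_true(all(c("selected", "f_test", "coefficients", "vif") %in% names(j)))
  expect_true(any(grepl("Predictor", readLines(tf))))
  unlink(c(jf, tf))
  # Q-Q data cover every residual
  expect_equal(nrow(h$qq), nrow(out))
  expect_true(all(diff(h$qq$sample) >= 0))
})
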