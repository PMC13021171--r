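#' Enumerate the full factorial study design
#'
#' Cartesian product of defect case, donor site, within-donor stiffness level
#' and overbulking level, in a stable deterministic order (case slowest,
#' overbulking fastest). The default levels give the 4 x 6 x 5 = 120-cell
#' design: four defect geometries, six skin stiffness profiles (two donor
#' sites x three levels), five adipose overbulking fractions.
#'
#' @param cases character vector of defect case labels.
#' @param donors donor sites (`forearm`, `thigh`).
#' @param stiffness_levels ordinal stiffness coding within donor site.
#' @param overbulk_levels adipose bulk-increase fractions.
#' @return `data.frame` with one row per simulation setup: columns `case`,
#'   `donor`, `stiffness_level`, `overbulk`.
#' @export
enumerate_design <- function(cases = c("A", "B", "C", "D"),
                             donors = c("forearm", "thigh"),
                             stiffness_levels = c(-1L, 0L, 1L),
                             overbulk_levels = c(0, 0.222, 0.444,
                                                 0.667, 0.889)) {
  stopifnot(length(cases) > 0, length(donors) > 0,
            length(stiffness_levels) > 0, length(overbulk_levels) > 0)
  d <- expand.grid(overbulk = overbulk_levels,
                   stiffness_level = stiffness_levels,
                   donor = donors, case = cases,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("case", "donor", "stiffness_level", "overbulk")]
  rownames(d) <- NULL
  d
}

#' Encode factorial outcomes for regression
#'
#' Builds the regression design matrix used by the hierarchical OLS analysis:
#' treatment dummies for `case` (reference = first level, conventionally A),
#' `overbulk` as a continuous fraction, `is_thigh` in \{0, 1\} and
#' `stiffness_level` in \{-1, 0, +1\}. The six stiffness profiles decompose
#' exactly into `is_thigh` x `stiffness_level`.
#'
#' @param outcomes `data.frame` with columns `case`, `donor`,
#'   `stiffness_level`, `overbulk` plus any outcome columns (carried through).
#' @param reference_case case label used as reference (default first sorted).
#' @return `data.frame` with dummy columns `case<L>` for each non-reference
#'   level, `overbulk`, `is_thigh`, `stiffness_level`, and the outcome
#'   columns.
#' @export
encode_design <- function(outcomes, reference_case = NULL) {
  need <- c("case", "donor", "stiffness_level", "overbulk")
  if (!all(need %in% names(outcomes)))
    stop("outcomes table must have columns: ", paste(need, collapse = ", "))
  if (!all(outcomes$donor %in% c("forearm", "thigh")))
    stop("unknown donor label: ",
         paste(setdiff(unique(outcomes$donor), c("forearm", "thigh")),
               collapse = ", "))
  lev <- sort(unique(as.character(outcomes$case)))
  if (is.null(reference_case)) reference_case <- lev[1]
  if (!reference_case %in% lev) stop("unknown case label: ", reference_case)
  dm <- data.frame(row.names = seq_len(nrow(outcomes)))
  for (l in setdiff(lev, reference_case))
    dm[[paste0("case", l)]] <- as.numeric(outcomes$case == l)
  dm$overbulk <- as.numeric(outcomes$overbulk)
  dm$is_thigh <- as.numeric(outcomes$donor == "thigh")
  dm$stiffness_level <- as.numeric(outcomes$stiffness_level)
  extra <- setdiff(names(outcomes), need)
  for (e in extra) dm[[e]] <- outcomes[[e]]
  attr(dm, "reference_case") <- reference_case
  dm
}

# Predictor-set helpers for the hierarchical models. The interaction set is
# all two-way terms among {case, overbulk, is_thigh, stiffness_level} except
# case x is_thigh and case x stiffness_level.
main_terms <- function(dm) {
  c(grep("^case", names(dm), value = TRUE),
    "overbulk", "is_thigh", "stiffness_level")
}

interaction_terms <- function(dm) {
  cs <- grep("^case", names(dm), value = TRUE)
  c(paste0("overbulk:", cs), "overbulk:is_thigh",
    "overbulk:stiffness_level", "is_thigh:stiffness_level")
}

#' Hierarchical OLS analysis of a factorial outcome
#'
#' Fits a main-effects model and a model augmented with the scientifically
#' relevant two-way interactions (all pairs among overbulking, donor site and
#' stiffness, plus overbulking x case), compares them with a nested ANOVA
#' F-test, and selects the interaction model when the F-test is significant
#' at `alpha`. The selected model is checked for multicollinearity (variance
#' inflation factors, flagged above 10) and residual normality data (Q-Q
#' coordinates) are exported for visual inspection.
#'
#' @param dm encoded design from [encode_design] including the outcome.
#' @param outcome name of the outcome column in `dm`.
#' @param alpha significance level of the nested F-test (default 0.05).
#' @return List of class `ols_hierarchy`: `main`, `interaction` (both `lm`),
#'   `comparison` (F, p, df), `selected` / `selected_label`, `vif`
#'   (per-predictor VIF with `flagged` attribute), `qq` (data.frame of
#'   theoretical and sample quantiles of standardized residuals),
#'   `adj_r_squared` per model.
#' @export
fit_hierarchy <- function(dm, outcome, alpha = 0.05) {
  stopifnot(outcome %in% names(dm))
  mt <- main_terms(dm)
  it <- interaction_terms(dm)
  f_main <- stats::reformulate(mt, response = outcome)
  f_int <- stats::reformulate(c(mt, it), response = outcome)
  m_main <- lm(f_main, data = dm)
  m_int <- lm(f_int, data = dm)
  if (any(!is.finite(coef(m_main))) || any(is.na(coef(m_main))))
    stop("rank-deficient main-effects design: ",
         paste(names(coef(m_main))[is.na(coef(m_main))], collapse = ", "))
  if (any(is.na(coef(m_int))))
    stop("rank-deficient interaction design: ",
         paste(names(coef(m_int))[is.na(coef(m_int))], collapse = ", "))
  cmp <- anova(m_main, m_int)
  Fstat <- cmp$F[2]
  pval <- cmp$`Pr(>F)`[2]
  sel_label <- if (is.finite(pval) && pval < alpha) "interaction" else "main"
  sel <- if (sel_label == "interaction") m_int else m_main
  v <- vif_values(sel)
  rs <- resid(sel) / sd(resid(sel))
  n <- length(rs)
  qq <- data.frame(theoretical = qnorm(stats::ppoints(n)), sample = sort(rs))
  structure(list(
    main = m_main, interaction = m_int,
    comparison = list(F = Fstat, p = pval,
                      df = c(cmp$Df[2], cmp$Res.Df[2]),
                      selected = sel_label),
    selected = sel, selected_label = sel_label,
    vif = v, qq = qq,
    adj_r_squared = c(main = summary(m_main)$adj.r.squared,
                      interaction = summary(m_int)$adj.r.squared)),
    class = "ols_hierarchy")
}

#' Variance inflation factors of a fitted linear model
#'
#' VIF of each non-intercept column of the model matrix, computed as
#' \eqn{1 / (1 - R_j^2)} where \eqn{R_j^2} is from regressing column j on
#' the remaining columns (with intercept). Values above 10 are flagged.
#'
#' @param fit an `lm` object.
#' @return Named numeric vector with attribute `flagged` (logical).
#' @export
vif_values <- function(fit) {
  X <- stats::model.matrix(fit)
  has_int <- "(Intercept)" %in% colnames(X)
  P <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  out <- vapply(seq_len(ncol(P)), function(j) {
    yj <- P[, j]
    Z <- cbind(if (has_int) 1, P[, -j, drop = FALSE])
    b <- qr.coef(qr(Z), yj)
    b[is.na(b)] <- 0
    r2 <- 1 - sum((yj - Z %*% b)^2) / sum((yj - mean(yj))^2)
    1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(P)
  attr(out, "flagged") <- out > 10
  out
}

#' @export
print.ols_hierarchy <- function(x, ...) {
  cat(sprintf("<ols_hierarchy> selected: %s model (F = %.4g, p = %.3g)\n",
              x$selected_label, x$comparison$F, x$comparison$p))
  cat(sprintf("  adj R^2: main %.4f, interaction %.4f\n",
              x$adj_r_squared["main"], x$adj_r_squared["interaction"]))
  print(coef_table(x$selected), digits = 4)
  invisible(x)
}

#' Coefficient table of a fitted model
#'
#' @param fit an `lm` object (or `ols_hierarchy`, using its selected model).
#' @return `data.frame` with predictor, coefficient, std. error, t, p.
#' @export
coef_table <- function(fit) {
  if (inherits(fit, "ols_hierarchy")) fit <- fit$selected
  s <- summary(fit)$coefficients
  data.frame(predictor = rownames(s), coefficient = s[, 1],
             std_error = s[, 2], t_statistic = s[, 3], p_value = s[, 4],
             row.names = NULL)
}

#' Write a fitted-model report
#'
#' JSON (machine-readable) plus a plain-text coefficient table laid out like
#' a journal regression table.
#'
#' @param h an `ols_hierarchy`.
#' @param json_path,text_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the report list.
#' @export
report_fit <- function(h, json_path = NULL, text_path = NULL) {
  ct <- coef_table(h$selected)
  rep <- list(selected = h$selected_label,
              f_test = list(F = h$comparison$F, p = h$comparison$p,
                            df = h$comparison$df),
              adj_r_squared = as.list(h$adj_r_squared),
              coefficients = ct,
              vif = as.list(unclass(h$vif)))
  if (!is.null(json_path))
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(text_path)) {
    con <- file(text_path, "w")
    on.exit(close(con))
    writeLines(sprintf("Selected model: %s   F = %.4g, p = %.3g",
                       h$selected_label, h$comparison$F, h$comparison$p), con)
    writeLines(sprintf("Adj. R-squared: %.4f", h$adj_r_squared[h$selected_label]),
               con)
    writeLines(sprintf("%-28s %12s %10s %10s %10s", "Predictor", "Coef.",
                       "Std.Err.", "t", "p"), con)
    for (i in seq_len(nrow(ct)))
      writeLines(sprintf("%-28s %12.4f %10.4f %10.2f %10.3g",
                         ct$predictor[i], ct$coefficient[i], ct$std_error[i],
                         ct$t_statistic[i], ct$p_value[i]), con)
  }
  invisible(rep)
}

#' Generate synthetic factorial outcomes with known coefficients
#'
#' Draws an outcome column linear in the encoded predictors plus i.i.d.
#' Gaussian noise; used to validate the hierarchical analysis by
#' parameter-recovery Monte Carlo.
#'
#' @param truth named coefficient vector over `(Intercept)` and any of the
#'   encoded main or interaction columns (e.g. `overbulk:is_thigh`);
#'   unnamed columns default to zero effect.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @param design factorial design (default the full 120-cell design).
#' @param outcome_name name of the generated outcome column.
#' @return Outcomes `data.frame`: design columns plus the outcome.
#' @export
synthesize_outcomes <- function(truth, noise_sd = 0, seed = 1L,
                                design = enumerate_design(),
                                outcome_name = "outcome") {
  dm <- encode_design(design)
  base <- c(grep("^case", names(dm), value = TRUE),
            "overbulk", "is_thigh", "stiffness_level")
  X <- cbind(`(Intercept)` = 1, as.matrix(dm[base]))
  for (tm in setdiff(names(truth), colnames(X))) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% base))
      stop("truth term not expressible in the design: ", tm)
    X <- cbind(X, Reduce(`*`, lapply(parts, function(p) dm[[p]])))
    colnames(X)[ncol(X)] <- tm
  }
  beta <- setNames(rep(0, ncol(X)), colnames(X))
  beta[names(truth)] <- truth
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  y <- as.numeric(X %*% beta) + rnorm(nrow(X), 0, noise_sd)
  out <- design
  out[[outcome_name]] <- y
  out
}
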