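#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk normality is evaluated on each group (on the paired
#' differences when `paired = TRUE`); if no evidence against normality is
#' found in either group at `alpha_normality`, a t-test is used, otherwise
#' a Wilcoxon test (rank-sum, or signed-rank when paired). For the
#' signed-rank test, zero differences are dropped (Wilcoxon's original
#' convention) and average ranks resolve ties; if all differences are zero
#' the comparison is a null identity and `p = 1` is returned. Constant
#' (zero-variance) input, for which the Shapiro test is undefined, is
#' routed to the Wilcoxon branch.
#'
#' @param x,y numeric samples (paired: equal length).
#' @param paired logical.
#' @param alpha_normality significance level of the normality gate.
#' @return data.frame with `estimate` (mean difference / location shift),
#'   `statistic`, `p_value`, `test_used` (`"t"` or `"wilcoxon"`),
#'   `shapiro_p_x`, `shapiro_p_y`.
#' @export
two_group_test <- function(x, y, paired = FALSE, alpha_normality = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L) {
    stop("each group needs n >= 3", call. = FALSE)
  }
  if (paired && length(x) != length(y)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  safe_shapiro <- function(v) {
    if (length(unique(v)) < 3L) return(0)  # degenerate: treat as non-normal
    shapiro.test(v)$p.value
  }
  if (paired) {
    d <- x - y
    if (all(d == 0)) {
      return(data.frame(estimate = 0, statistic = NA_real_, p_value = 1,
                        test_used = "wilcoxon", shapiro_p_x = NA_real_,
                        shapiro_p_y = NA_real_))
    }
    sp_x <- safe_shapiro(d); sp_y <- sp_x
  } else {
    sp_x <- safe_shapiro(x); sp_y <- safe_shapiro(y)
  }
  normal <- sp_x > alpha_normality && sp_y > alpha_normality
  if (normal) {
    ht <- t.test(x, y, paired = paired)
    est <- if (paired) unname(ht$estimate) else
      unname(ht$estimate[1] - ht$estimate[2])
    used <- "t"
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, paired = paired, conf.int = TRUE))
    est <- unname(ht$estimate)
    used <- "wilcoxon"
  }
  data.frame(estimate = est, statistic = unname(ht$statistic),
             p_value = ht$p.value, test_used = used,
             shapiro_p_x = sp_x, shapiro_p_y = sp_y)
}

#' Patient random-intercept linear mixed model
#'
#' Fits `value ~ fixed + (1 | patient)` by REML (lmerTest), testing the
#' fixed effect with a t statistic on Satterthwaite-approximated degrees of
#' freedom. Continuous fixed effects are centered and scaled to unit sd
#' before fitting (the estimate is reported per sd of the predictor);
#' factor fixed effects are used as-is. In a balanced two-condition design
#' with one observation per patient and condition, the p-value equals the
#' paired t-test's.
#'
#' @param data data.frame in long format.
#' @param value,fixed,patient column names of the response, the fixed
#'   effect and the patient identifier.
#' @return data.frame with `estimate`, `statistic`, `df`, `p_value`,
#'   `test_used = "lmm"` for the (first) fixed-effect contrast.
#' @export
lmm_random_intercept <- function(data, value, fixed, patient = "patient") {
  stopifnot(all(c(value, fixed, patient) %in% names(data)))
  df <- data.frame(.y = data[[value]], .x = data[[fixed]],
                   .patient = factor(data[[patient]]))
  df <- df[complete.cases(df), ]
  if (nlevels(droplevels(df$.patient)) < 2L) {
    stop("need >= 2 patients", call. = FALSE)
  }
  if (is.numeric(df$.x)) {
    if (sd(df$.x) == 0) stop("fixed effect is constant", call. = FALSE)
    df$.x <- as.numeric(scale(df$.x))
  } else {
    df$.x <- factor(df$.x)
    if (nlevels(droplevels(df$.x)) < 2L) {
      stop("fixed effect is constant", call. = FALSE)
    }
  }
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(.y ~ .x + (1 | .patient), data = df)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    co <- summary(fit)$coefficients
    return(data.frame(estimate = co[2, "Estimate"],
                      statistic = co[2, "t value"], df = co[2, "df"],
                      p_value = co[2, "Pr(>|t|)"], test_used = "lmm"))
  }
  # degenerate variance structure (e.g. zero residual variance when the
  # response is fully explained by the patient intercepts): Satterthwaite
  # machinery is undefined, but the REML point estimate still is; fall
  # back to lme4 and report the estimate with a normal-approximation p
  fit2 <- suppressMessages(suppressWarnings(
    lme4::lmer(.y ~ .x + (1 | .patient), data = df,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  co <- summary(fit2)$coefficients
  est <- co[2, "Estimate"]; se <- co[2, "Std. Error"]
  stat <- if (se > 0) est / se else NA_real_
  data.frame(estimate = est, statistic = stat, df = NA_real_,
             p_value = if (is.na(stat)) NA_real_ else
               2 * pnorm(-abs(stat)),
             test_used = "lmm")
}

#' Mixed-model differential expression across analytes with FDR control
#'
#' Applies [lmm_random_intercept()] per analyte of a normalized expression
#' container and adjusts the p-values across the analyte family by
#' Benjamini-Hochberg.
#'
#' @param se normalized expression container (see
#'   [cyclic_loess_normalize()]).
#' @param fixed `colData` column to test (e.g. `"region"`).
#' @param subset optional logical vector selecting AOIs (e.g. one cell
#'   type).
#' @return data.frame with one row per analyte: `analyte`, `estimate`,
#'   `statistic`, `df`, `p_value`, `q_value`.
#' @export
lmm_diffexp <- function(se, fixed = "region", subset = NULL) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  v <- exprs_values(se)
  ctrl <- SummarizedExperiment::rowData(se)$is_negative_control
  if (!is.null(ctrl)) v <- v[!ctrl, , drop = FALSE]
  if (!is.null(subset)) { v <- v[, subset, drop = FALSE]; cd <- cd[subset, ] }
  res <- do.call(rbind, lapply(rownames(v), function(a) {
    d <- data.frame(value = v[a, ], fixed = cd[[fixed]],
                    patient = cd$patient)
    out <- lmm_random_intercept(d, "value", "fixed", "patient")
    out$analyte <- a
    out
  }))
  res$q_value <- bh_fdr(res$p_value)
  res[, c("analyte", "estimate", "statistic", "df", "p_value", "q_value")]
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment `q_(i) = min_{j >= i} p_(j) * m / j` on the sorted
#' p-values, returned in the original order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks on ties; the p-value uses the
#' large-sample t approximation (exact enumeration is not attempted, so
#' tied data are handled uniformly).
#'
#' @param x,y numeric vectors of equal length, `n >= 4`.
#' @return data.frame with `estimate` (rho), `statistic`, `p_value`,
#'   `test_used = "spearman"`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need n >= 4", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("constant input", call. = FALSE)
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  data.frame(estimate = unname(ht$estimate), statistic = unname(ht$statistic),
             p_value = ht$p.value, test_used = "spearman")
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Multi-group comparison across (e.g.) the four T-cell subsets: one-way
#' ANOVA F test, followed by Tukey's Honestly Significant Difference test
#' over all group pairs. Reported pairwise estimates are differences in
#' group means (second minus first group of the contrast label), with
#' studentized-range adjusted p-values.
#'
#' @param values numeric response.
#' @param groups group labels (>= 3 groups, each n >= 2).
#' @return list with `anova` (data.frame `F`, `p_value`) and `pairwise`
#'   (data.frame `contrast`, `estimate`, `p_adj`).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 3L) stop("need >= 3 groups", call. = FALSE)
  if (any(table(groups) < 2L)) {
    stop("every group needs n >= 2", call. = FALSE)
  }
  fit <- aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$groups
  list(anova = data.frame(F = an[1, "F value"], p_value = an[1, "Pr(>F)"]),
       pairwise = data.frame(contrast = rownames(tk),
                             estimate = tk[, "diff"],
                             p_adj = tk[, "p adj"], row.names = NULL))
}

#' Contingency-table association test with a small-count gate
#'
#' Chi-square test without continuity correction by default; if any
#' expected cell count is below 5, Fisher's exact test is used instead and
#' recorded in `test_used`.
#'
#' @param table matrix of non-negative integer counts (2x2 or r x c).
#' @param expected_min threshold on expected counts that triggers the
#'   exact test, default 5.
#' @return data.frame with `statistic` (chi-square; `NA` for the exact
#'   branch), `estimate` (sample odds ratio for a 2x2 exact branch; else
#'   `NA`), `p_value`, `test_used` (`"chisq"` or `"fisher"`).
#' @export
contingency_test <- function(table, expected_min = 5) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("empty row or column margin", call. = FALSE)
  }
  cs <- suppressWarnings(chisq.test(table, correct = FALSE))
  if (any(cs$expected < expected_min)) {
    ft <- fisher.test(table)
    # sample (cross-product) odds ratio: invariant to count scaling,
    # unlike the exact test's conditional-MLE estimate
    est <- if (all(dim(table) == 2L)) {
      (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
    } else NA_real_
    data.frame(statistic = NA_real_, estimate = est, p_value = ft$p.value,
               test_used = "fisher")
  } else {
    data.frame(statistic = unname(cs$statistic), estimate = NA_real_,
               p_value = cs$p.value, test_used = "chisq")
  }
}
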