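#' Kaplan-Meier product-limit estimate
#'
#' Right-continuous step estimate of the survival function, starting at 1
#' at time 0. Censoring removes subjects from the risk set without a
#' survival drop.
#'
#' @param time positive follow-up times (years).
#' @param event event indicators (1 = event, 0 = censored).
#' @return data.frame with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
kaplan_meier <- function(time, event) {
  if (any(time < 0)) stop("times must be non-negative", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected chi-square statistic with hypergeometric
#' variance, 1 degree of freedom. Also reports the signed standardized
#' statistic `z = (O1 - E1) / sqrt(V1)` used by the maximally selected
#' rank-statistic search.
#'
#' @param time,event follow-up times and 0/1 event indicators.
#' @param group two-level group labels.
#' @return data.frame with `statistic` (chi-square), `z`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("need exactly 2 groups", call. = FALSE)
  if (sum(event) < 1L) stop("need at least one event", call. = FALSE)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  o <- sd_$obs[1]; e <- sd_$exp[1]
  v <- if (is.matrix(sd_$var)) sd_$var[1, 1] else sd_$var[1]
  z <- if (v > 0) (o - e) / sqrt(v) else 0
  chisq <- z^2
  data.frame(statistic = chisq, z = z,
             p_value = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Maximally selected rank-statistic cutpoint
#'
#' Dichotomizes a continuous covariate against overall survival: every
#' unique covariate value whose induced split (`covariate <= c` vs `> c`)
#' leaves both groups with at least `ceiling(min_group_prop * n)` subjects
#' is a candidate; the standardized log-rank statistic is computed at each
#' candidate and the cutpoint maximizing its absolute value is selected
#' (ties broken toward the smaller cutpoint). Candidates depend on the
#' covariate only through its ranks, so the selection is invariant to
#' strictly monotone transforms.
#'
#' The p-value at the selected cutpoint is the naive log-rank p and is
#' anti-conservative because the cutpoint was chosen to maximize the
#' statistic; it is returned as `selection_biased_p` and must not be read
#' as an honest significance level.
#'
#' @param covariate continuous covariate (non-constant).
#' @param time,event follow-up times and 0/1 event indicators.
#' @param min_group_prop minimum fraction of subjects per group, default
#'   0.1.
#' @return an object of class `cutpoint_result`: list with `cutpoint`,
#'   `statistic` (signed z at the selected cutpoint), `selection_biased_p`,
#'   `candidates` (data.frame `cutpoint`, `z`), `min_group_prop`, `n`.
#' @export
maxstat_cutpoint <- function(covariate, time, event, min_group_prop = 0.1) {
  n <- length(covariate)
  stopifnot(length(time) == n, length(event) == n)
  if (n < 10L) stop("need n >= 10", call. = FALSE)
  if (length(unique(covariate)) < 2L) {
    stop("covariate is constant", call. = FALSE)
  }
  min_n <- ceiling(min_group_prop * n)
  vals <- sort(unique(covariate))
  cand <- vals[vapply(vals, function(cp) {
    lo <- sum(covariate <= cp)
    lo >= min_n && (n - lo) >= min_n
  }, logical(1))]
  if (!length(cand)) {
    stop("no candidate cutpoint satisfies the minimum group proportion",
         call. = FALSE)
  }
  z <- vapply(cand, function(cp) {
    logrank_test(time, event, covariate > cp)$z
  }, numeric(1))
  best <- which.max(abs(z))  # which.max returns the first (smallest) argmax
  zb <- z[best]
  structure(list(cutpoint = cand[best], statistic = zb,
                 selection_biased_p = pchisq(zb^2, df = 1, lower.tail = FALSE),
                 candidates = data.frame(cutpoint = cand, z = z),
                 min_group_prop = min_group_prop, n = n),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(
    "cutpoint_result: cutpoint %.4g, |z| %.3f (n = %d, min group prop %.2f)\n",
    x$cutpoint, abs(x$statistic), x$n, x$min_group_prop))
  cat(sprintf(
    "  naive log-rank p %.3g [selection-biased: cutpoint chosen to maximize the statistic]\n",
    x$selection_biased_p))
  invisible(x)
}
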