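# Independent oracles and fixture builders. These deliberately re-derive
# expected values from first principles (explicit formulas, brute-force
# enumeration) and never call the implementation paths they check.

# Shannon index by direct formula evaluation, explicit loop.
oracle_sdi <- function(p, base = exp(1)) {
  p <- p / sum(p)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi, base = base)
  h
}

# Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[i:m] * m / (i:m))
  }
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Standardized two-group log-rank statistic from the O/E/V table,
# accumulated over distinct event times.
oracle_logrank_z <- function(time, event, in_group1) {
  o <- 0; e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_group1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in_group1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v <= 0) return(0)
  (o - e) / sqrt(v)
}

# Exhaustive maximally selected rank statistic: every admissible split,
# standardized log-rank via the hand formula above.
oracle_maxstat <- function(covariate, time, event, min_group_prop = 0.1) {
  n <- length(covariate)
  min_n <- ceiling(min_group_prop * n)
  best <- NULL
  for (cp in sort(unique(covariate))) {
    lo <- covariate <= cp
    if (sum(lo) < min_n || sum(!lo) < min_n) next
    z <- oracle_logrank_z(time, event, !lo)
    if (is.null(best) || abs(z) > abs(best$z) + 1e-12) {
      best <- list(cutpoint = cp, z = z)
    }
  }
  best
}

# All one-to-one matchings among candidate pairs, scored by
# (cardinality, total IoU); plain enumeration, no pruning.
oracle_best_matching <- function(pairs) {
  n <- nrow(pairs)
  best <- list(card = -1, total = -Inf)
  enumerate <- function(i, used_p, used_t, card, total) {
    if (i > n) {
      if (card > best$card ||
          (card == best$card && total > best$total + 1e-12)) {
        best <<- list(card = card, total = total)
      }
      return(invisible())
    }
    enumerate(i + 1, used_p, used_t, card, total)
    if (!(pairs$pred[i] %in% used_p) && !(pairs$truth[i] %in% used_t)) {
      enumerate(i + 1, c(used_p, pairs$pred[i]), c(used_t, pairs$truth[i]),
                card + 1, total + pairs$iou[i])
    }
  }
  enumerate(1, integer(0), integer(0), 0L, 0)
  best
}

# Textbook sparse PLS-DA on one block: one-step loading against the class
# contrast, soft-thresholded to `keep`, regression deflation.
oracle_splsda_scores <- function(X, y, ncomp, keep) {
  Xw <- scale(X)
  yc <- as.numeric(scale(as.integer(factor(y))))
  n <- nrow(X)
  S <- matrix(0, n, ncomp)
  for (h in seq_len(ncomp)) {
    g <- crossprod(Xw, yc)[, 1]
    if (keep < length(g)) {
      lam <- sort(abs(g), decreasing = TRUE)[keep + 1]
      g <- sign(g) * pmax(abs(g) - lam, 0)
    }
    a <- g / sqrt(sum(g^2))
    if (a[which.max(abs(a))] < 0) a <- -a
    t <- Xw %*% a
    S[, h] <- t
    Xw <- Xw - t %*% t(crossprod(Xw, t)[, 1] / sum(t^2))
  }
  S
}

# Draw a filled disk into a matrix (fixture construction).
paint_disk <- function(m, r0, c0, radius, value) {
  for (r in seq_len(nrow(m))) {
    for (c in seq_len(ncol(m))) {
      if ((r - r0)^2 + (c - c0)^2 <= radius^2) m[r, c] <- value
    }
  }
  m
}

# Two-class multiblock fixture with a planted mean shift.
make_shift_blocks <- function(n = 40, p = 20, n_informative = 5, shift = 2,
                              block_names = c("b1", "b2"), seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("lo", "hi"), length.out = n))
  blocks <- lapply(block_names, function(b) {
    X <- matrix(rnorm(n * p), n, p)
    X[y == "hi", seq_len(n_informative)] <-
      X[y == "hi", seq_len(n_informative)] + shift
    colnames(X) <- sprintf("%s_f%03d", b, seq_len(p))
    X
  })
  names(blocks) <- block_names
  list(blocks = blocks, outcome = y)
}
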