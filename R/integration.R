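#' Multiblock dataset for discriminant integration
#'
#' Bundles several omics blocks measured on the same samples with a
#' two-class outcome. Complete cases are required: every sample must be
#' present, in the same order, in every block, with no missing entries.
#'
#' @param blocks named list of numeric matrices (samples x features) with
#'   identical row order; feature names must be unique within a block.
#' @param outcome two-level factor (or coercible) of length `nrow`.
#' @return an object of class `block_dataset`.
#' @export
block_dataset <- function(blocks, outcome) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    stop("blocks must be named", call. = FALSE)
  }
  n <- nrow(blocks[[1]])
  for (b in names(blocks)) {
    if (!is.matrix(blocks[[b]]) || !is.numeric(blocks[[b]])) {
      stop("block '", b, "' must be a numeric matrix", call. = FALSE)
    }
    if (nrow(blocks[[b]]) != n) {
      stop("all blocks must share the sample dimension", call. = FALSE)
    }
    if (anyNA(blocks[[b]])) {
      stop("block '", b, "' has missing entries; integration requires complete cases",
           call. = FALSE)
    }
    if (is.null(colnames(blocks[[b]]))) {
      colnames(blocks[[b]]) <- sprintf("%s_f%03d", b, seq_len(ncol(blocks[[b]])))
    }
  }
  outcome <- factor(outcome)
  if (length(outcome) != n) stop("outcome length mismatch", call. = FALSE)
  if (nlevels(outcome) != 2L) {
    stop("outcome must have exactly two classes", call. = FALSE)
  }
  if (any(table(outcome) < 2L)) {
    stop("each outcome class needs >= 2 samples", call. = FALSE)
  }
  structure(list(blocks = blocks, outcome = outcome), class = "block_dataset")
}

#' Configuration for multiblock sparse PLS-DA
#'
#' The outcome is encoded as a centered, scaled dummy matrix and treated as
#' an additional block connected to every data block with design weight
#' 1.0, while data blocks are connected to each other with
#' `design_weight` (default 0.1) — a design maximizing discrimination over
#' cross-block agreement.
#'
#' @param design_weight between-data-block design weight, default 0.1.
#' @param ncomp number of components, default 2.
#' @param keepX named list (per block) of per-component feature counts to
#'   retain; `NULL` keeps all features.
#' @param distance `"centroid"` or `"mahalanobis"` score-space distance
#'   for prediction.
#' @param cv_folds,cv_repeats cross-validation folds and repeats for
#'   performance estimation.
#' @param tune_repeats CV repeats used during `keepX` tuning.
#' @param n_permutations label permutations for the significance test.
#' @param max_iter,tol convergence controls of the alternating update.
#' @param seed integer seed for CV fold draws and permutations.
#' @return an object of class `integration_config`.
#' @export
integration_config <- function(design_weight = 0.1, ncomp = 2L,
                               keepX = NULL,
                               distance = c("centroid", "mahalanobis"),
                               cv_folds = 5L, cv_repeats = 10L,
                               tune_repeats = 10L, n_permutations = 199L,
                               max_iter = 500L, tol = 1e-6, seed = 1L) {
  distance <- match.arg(distance)
  stopifnot_scalar_number(design_weight, "design_weight", 0)
  stopifnot_scalar_number(ncomp, "ncomp", 1)
  structure(list(design_weight = design_weight, ncomp = as.integer(ncomp),
                 keepX = keepX, distance = distance,
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 tune_repeats = as.integer(tune_repeats),
                 n_permutations = as.integer(n_permutations),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "integration_config")
}

# Keep the `keep` largest-|x| entries, soft-thresholded by the largest
# excluded magnitude (no-op when keep >= length(x)).
soft_keep <- function(x, keep) {
  p <- length(x)
  if (keep >= p) return(x)
  ax <- abs(x)
  lambda <- sort(ax, decreasing = TRUE)[keep + 1L]
  sign(x) * pmax(ax - lambda, 0)
}

normalize_vec <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm < .Machine$double.eps) x else x / nrm
}

resolve_keepX <- function(keepX, blocks, ncomp) {
  out <- lapply(names(blocks), function(b) {
    p <- ncol(blocks[[b]])
    v <- if (is.null(keepX) || is.null(keepX[[b]])) rep(p, ncomp)
         else rep_len(keepX[[b]], ncomp)
    if (any(v < 1) || any(v > p)) {
      stop("keepX for block '", b, "' must lie in [1, ", p, "]", call. = FALSE)
    }
    as.integer(v)
  })
  names(out) <- names(blocks)
  out
}

#' Fit a design-weighted multiblock sparse PLS-DA model
#'
#' Components are extracted by maximizing the design-weighted sum of
#' covariances between block scores (including the score of the
#' centered/scaled outcome-dummy block) by alternating least squares: each
#' block loading is updated toward the design-weighted sum of the other
#' blocks' scores, sparsified by soft thresholding to its `keepX` largest
#' entries and normalized to unit Euclidean norm, until the loadings
#' change by less than `tol`. After each component every block (and the
#' outcome dummy) is deflated by regression on its own score, which makes
#' successive scores within a block orthogonal. Features are standardized
#' (zero mean, unit variance) before fitting. Loadings are
#' sign-indeterminate; each block/component is canonicalized so its
#' largest-magnitude loading is positive.
#'
#' @param data a [block_dataset()].
#' @param config an [integration_config()].
#' @return an object of class `diablo_model`: per-block `loadings`,
#'   `deflation`, `scores`, `centroids` (class centroids in score space),
#'   `selected` (non-zero-loading features), per-block training balanced
#'   error rates, the scaling parameters, and the fitting metadata.
#' @export
fit_block_splsda <- function(data, config = integration_config()) {
  stopifnot(inherits(data, "block_dataset"),
            inherits(config, "integration_config"))
  blocks <- data$blocks
  outcome <- data$outcome
  B <- length(blocks)
  n <- nrow(blocks[[1]])
  ncomp <- config$ncomp
  keepX <- resolve_keepX(config$keepX, blocks, ncomp)

  centers <- lapply(blocks, colMeans)
  scales <- lapply(blocks, function(X) {
    s <- apply(X, 2, sd)
    s[s < .Machine$double.eps] <- 1
    s
  })
  Xs <- lapply(names(blocks), function(b) {
    scale(blocks[[b]], center = centers[[b]], scale = scales[[b]])[, ,
                                                                   drop = FALSE]
  })
  names(Xs) <- names(blocks)
  Y <- scale(model.matrix(~ outcome - 1))
  yc <- as.numeric(scale(as.integer(outcome)))  # signed class contrast

  # design: data blocks weakly coupled, all strongly coupled to the outcome
  C <- matrix(config$design_weight, B + 1L, B + 1L)
  C[B + 1L, ] <- 1; C[, B + 1L] <- 1
  diag(C) <- 0

  loadings <- lapply(Xs, function(X) matrix(0, ncol(X), ncomp,
                                            dimnames = list(colnames(X), NULL)))
  deflation <- lapply(Xs, function(X) matrix(0, ncol(X), ncomp,
                                             dimnames = list(colnames(X), NULL)))
  scores <- lapply(Xs, function(X) matrix(0, n, ncomp))
  y_loadings <- matrix(0, ncol(Y), ncomp)
  iters <- integer(ncomp)

  Xw <- Xs; Yw <- Y
  for (h in seq_len(ncomp)) {
    a <- lapply(names(Xw), function(b) {
      normalize_vec(soft_keep(crossprod(Xw[[b]], yc)[, 1], keepX[[b]][h]))
    })
    names(a) <- names(Xw)
    b_y <- normalize_vec(crossprod(Yw, yc)[, 1])
    t_blk <- lapply(names(Xw), function(b) Xw[[b]] %*% a[[b]])
    names(t_blk) <- names(Xw)
    t_y <- Yw %*% b_y
    for (it in seq_len(config$max_iter)) {
      a_old <- unlist(a)
      for (bi in seq_len(B)) {
        b <- names(Xw)[bi]
        target <- t_y * C[bi, B + 1L]
        for (kj in seq_len(B)) {
          if (kj != bi && C[bi, kj] > 0) target <- target + C[bi, kj] * t_blk[[kj]]
        }
        a[[b]] <- normalize_vec(soft_keep(crossprod(Xw[[b]], target)[, 1],
                                          keepX[[b]][h]))
        t_blk[[b]] <- Xw[[b]] %*% a[[b]]
      }
      target <- Reduce(`+`, lapply(seq_len(B),
                                   function(kj) C[B + 1L, kj] * t_blk[[kj]]))
      b_y <- normalize_vec(crossprod(Yw, target)[, 1])
      t_y <- Yw %*% b_y
      if (max(abs(unlist(a) - a_old)) < config$tol) break
    }
    iters[h] <- it
    for (b in names(Xw)) {
      # canonical sign: largest-magnitude loading positive
      flip <- sign(a[[b]][which.max(abs(a[[b]]))])
      if (flip < 0) { a[[b]] <- -a[[b]]; t_blk[[b]] <- -t_blk[[b]] }
      loadings[[b]][, h] <- a[[b]]
      scores[[b]][, h] <- t_blk[[b]]
      tt <- sum(t_blk[[b]]^2)
      d <- if (tt > 0) crossprod(Xw[[b]], t_blk[[b]])[, 1] / tt else
        numeric(ncol(Xw[[b]]))
      deflation[[b]][, h] <- d
      Xw[[b]] <- Xw[[b]] - t_blk[[b]] %*% t(d)
    }
    y_loadings[, h] <- b_y
    # the outcome dummy is rank 1 for two classes and is not deflated:
    # every component is extracted against the full class contrast (as in
    # univariate-response PLS, where response deflation is a no-op)
  }

  centroids <- lapply(scores, function(S) {
    cent <- matrix(NA_real_, nlevels(outcome), ncomp,
                   dimnames = list(levels(outcome), NULL))
    for (cl in levels(outcome)) {
      cent[cl, ] <- colMeans(S[outcome == cl, , drop = FALSE])
    }
    cent
  })
  selected <- lapply(loadings, function(L) {
    lapply(seq_len(ncomp), function(h) rownames(L)[L[, h] != 0])
  })
  model <- structure(list(
    loadings = loadings, deflation = deflation, scores = scores,
    y_loadings = y_loadings, centroids = centroids, selected = selected,
    centers = centers, scales = scales, outcome = outcome,
    classes = levels(outcome), keepX = keepX, config = config,
    block_names = names(blocks), iterations = iters), class = "diablo_model")
  # training-set per-block balanced error rates (used for vote tie-breaks)
  train_votes <- predict(model, data$blocks)$block_class
  model$train_ber <- vapply(names(blocks), function(b) {
    balanced_error_rate(outcome, train_votes[[b]])
  }, numeric(1))
  model
}

#' @export
print.diablo_model <- function(x, ...) {
  cat(sprintf("diablo_model: %d block(s), %d component(s), classes %s\n",
              length(x$block_names), x$config$ncomp,
              paste(x$classes, collapse = " / ")))
  for (b in x$block_names) {
    cat(sprintf("  %s: keepX %s, training BER %.3f\n", b,
                paste(x$keepX[[b]], collapse = "/"), x$train_ber[[b]]))
  }
  invisible(x)
}

balanced_error_rate <- function(truth, predicted) {
  truth <- factor(truth)
  per_class <- vapply(levels(truth), function(cl) {
    idx <- truth == cl
    mean(predicted[idx] != cl)
  }, numeric(1))
  mean(per_class)
}

project_block <- function(model, block_name, newX) {
  Xn <- scale(newX, center = model$centers[[block_name]],
              scale = model$scales[[block_name]])
  ncomp <- model$config$ncomp
  Tn <- matrix(0, nrow(Xn), ncomp)
  for (h in seq_len(ncomp)) {
    Tn[, h] <- Xn %*% model$loadings[[block_name]][, h]
    Xn <- Xn - Tn[, h] %*% t(model$deflation[[block_name]][, h])
  }
  Tn
}

#' Predict class membership for new samples
#'
#' Each block projects its new samples into the trained score space (same
#' scaling and deflation chain as training) and votes for the class with
#' the nearest centroid under the configured distance: plain Euclidean
#' (`"centroid"`) or Mahalanobis under the pooled within-class covariance
#' of the training scores. The final label is the majority vote across
#' blocks; ties are resolved by the block with the lowest training
#' balanced error rate.
#'
#' @param object a `diablo_model`.
#' @param newdata named list of matrices with the training blocks' feature
#'   columns.
#' @param ... unused.
#' @return list with `class` (final labels), `block_class` (per-block
#'   votes) and `block_scores`.
#' @export
predict.diablo_model <- function(object, newdata, ...) {
  stopifnot(all(object$block_names %in% names(newdata)))
  ncomp <- object$config$ncomp
  block_class <- list(); block_scores <- list()
  for (b in object$block_names) {
    nd <- newdata[[b]]
    if (!identical(colnames(nd), rownames(object$loadings[[b]]))) {
      if (is.null(colnames(nd)) ||
          !all(rownames(object$loadings[[b]]) %in% colnames(nd))) {
        stop("feature names of block '", b,
             "' do not match the training block", call. = FALSE)
      }
      nd <- nd[, rownames(object$loadings[[b]]), drop = FALSE]
    }
    Tn <- project_block(object, b, nd)
    cent <- object$centroids[[b]]
    if (object$config$distance == "mahalanobis") {
      Str <- object$scores[[b]]
      resid <- Str - cent[as.character(object$outcome), , drop = FALSE]
      W <- crossprod(resid) / (nrow(Str) - length(object$classes))
      W <- W + diag(1e-8, ncol(W))
      Wi <- solve(W)
      d2 <- vapply(object$classes, function(cl) {
        df <- sweep(Tn, 2, cent[cl, ])
        rowSums((df %*% Wi) * df)
      }, numeric(nrow(Tn)))
    } else {
      d2 <- vapply(object$classes, function(cl) {
        rowSums(sweep(Tn, 2, cent[cl, ])^2)
      }, numeric(nrow(Tn)))
    }
    d2 <- matrix(d2, nrow = nrow(Tn),
                 dimnames = list(NULL, object$classes))
    block_class[[b]] <- object$classes[max.col(-d2, ties.method = "first")]
    block_scores[[b]] <- Tn
  }
  votes <- do.call(cbind, block_class)
  best_block <- object$block_names[which.min(object$train_ber %||%
                                               rep(0, length(object$block_names)))]
  final <- apply(votes, 1, function(v) {
    tab <- table(factor(v, levels = object$classes))
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) top else v[[best_block]]
  })
  list(class = factor(final, levels = object$classes),
       block_class = block_class, block_scores = block_scores)
}

stratified_folds <- function(outcome, k) {
  idx <- seq_along(outcome)
  folds <- integer(length(outcome))
  for (cl in levels(outcome)) {
    members <- sample(idx[outcome == cl])
    folds[members] <- rep_len(seq_len(k), length(members))
  }
  folds
}

#' Cross-validated balanced error rate
#'
#' Stratified k-fold cross-validation, repeated; the model is refitted on
#' each training split and the balanced error rate (mean of per-class
#' misclassification rates) measured on the held-out fold.
#'
#' @param data a [block_dataset()].
#' @param config an [integration_config()]; `cv_folds` folds.
#' @param repeats number of CV repetitions (default `config$cv_repeats`).
#' @param seed RNG seed (default `config$seed`).
#' @return list with `ber` (mean balanced error rate) and `per_repeat`.
#' @export
cv_block_splsda <- function(data, config = integration_config(),
                            repeats = NULL, seed = NULL) {
  repeats <- repeats %||% config$cv_repeats
  seed <- seed %||% config$seed
  k <- config$cv_folds
  if (k > min(table(data$outcome))) {
    stop("cv_folds exceeds the size of the smallest class", call. = FALSE)
  }
  set.seed(seed)
  per_repeat <- vapply(seq_len(repeats), function(r) {
    folds <- stratified_folds(data$outcome, k)
    truth_all <- character(0); pred_all <- character(0)
    for (f in seq_len(k)) {
      test <- folds == f
      train <- block_dataset(lapply(data$blocks,
                                    function(X) X[!test, , drop = FALSE]),
                             data$outcome[!test])
      fit <- fit_block_splsda(train, config)
      pr <- predict(fit, lapply(data$blocks,
                                function(X) X[test, , drop = FALSE]))
      truth_all <- c(truth_all, as.character(data$outcome[test]))
      pred_all <- c(pred_all, as.character(pr$class))
    }
    balanced_error_rate(factor(truth_all, levels = levels(data$outcome)),
                        pred_all)
  }, numeric(1))
  list(ber = mean(per_repeat), per_repeat = per_repeat)
}

#' Tune the number of retained features per block
#'
#' Evaluates every point of a per-block `keepX` grid by repeated
#' cross-validated balanced error rate and returns the point with the
#' lowest mean BER; ties go to the sparsest model (smallest total keepX).
#'
#' @param data a [block_dataset()].
#' @param config an [integration_config()].
#' @param grid named list (per block) of candidate keepX vectors, e.g.
#'   `list(mrna = seq(10, 50, 10), protein = seq(5, 15, 5))`.
#' @return list with `keepX` (chosen, as a config-ready list), `results`
#'   (data.frame of all grid points and their mean BER).
#' @export
tune_keepX <- function(data, config = integration_config(), grid) {
  stopifnot(is.list(grid), all(names(data$blocks) %in% names(grid)))
  combos <- expand.grid(lapply(grid[names(data$blocks)], as.integer),
                        KEEP.OUT.ATTRS = FALSE)
  if (!nrow(combos)) stop("empty keepX grid", call. = FALSE)
  # every grid point is evaluated on the same fold draws (paired
  # comparison), so equal-signal points tie exactly
  bers <- vapply(seq_len(nrow(combos)), function(i) {
    cfg <- config
    cfg$keepX <- lapply(as.list(combos[i, , drop = FALSE]), identity)
    cv_block_splsda(data, cfg, repeats = config$tune_repeats,
                    seed = config$seed)$ber
  }, numeric(1))
  total <- rowSums(combos)
  ord <- order(bers, total)  # min BER, then sparsest
  best <- combos[ord[1], , drop = FALSE]
  list(keepX = lapply(as.list(best), as.integer),
       results = data.frame(combos, ber = bers))
}

#' Label-permutation significance test for the integration model
#'
#' The observed cross-validated balanced error rate is compared with the
#' null distribution obtained by refitting after randomly shuffling the
#' outcome labels: `p = (1 + #{permuted BER <= observed BER}) /
#' (n_permutations + 1)`. Observed and permuted BERs use the identical CV
#' procedure.
#'
#' @param data a [block_dataset()].
#' @param config an [integration_config()]; `n_permutations` shuffles.
#' @param cv_repeats CV repeats used for both observed and permuted BER
#'   (default 1, for tractable permutation counts).
#' @return list with `p_value`, `observed_ber`, `permuted_ber`.
#' @export
permutation_test <- function(data, config = integration_config(),
                             cv_repeats = 1L) {
  n_perm <- config$n_permutations
  if (n_perm < 19L) stop("need at least 19 permutations", call. = FALSE)
  observed <- cv_block_splsda(data, config, repeats = cv_repeats,
                              seed = config$seed)$ber
  permuted <- vapply(seq_len(n_perm), function(i) {
    set.seed(config$seed + 7919L * i)
    shuffled <- block_dataset(data$blocks, sample(data$outcome))
    cv_block_splsda(shuffled, config, repeats = cv_repeats,
                    seed = config$seed + i)$ber
  }, numeric(1))
  list(p_value = (1 + sum(permuted <= observed)) / (n_perm + 1),
       observed_ber = observed, permuted_ber = permuted)
}

#' Selected-feature association table
#'
#' Summarizes a fitted model as one row per selected feature: block,
#' component, loading value and the sign of its association with the
#' second outcome class (the analog of a circos/loading plot, as a table).
#'
#' @param model a `diablo_model`.
#' @return data.frame with `block`, `component`, `feature`, `loading`,
#'   `association` (+1/-1 toward the second class level).
#' @export
selected_features <- function(model) {
  stopifnot(inherits(model, "diablo_model"))
  rows <- list()
  for (b in model$block_names) {
    L <- model$loadings[[b]]
    for (h in seq_len(ncol(L))) {
      nz <- which(L[, h] != 0)
      if (!length(nz)) next
      # orientation: does a positive score point toward class 2?
      orient <- sign(model$centroids[[b]][2, h] - model$centroids[[b]][1, h])
      rows[[length(rows) + 1L]] <- data.frame(
        block = b, component = h, feature = rownames(L)[nz],
        loading = L[nz, h],
        association = ifelse(orient * L[nz, h] >= 0, 1L, -1L))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
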