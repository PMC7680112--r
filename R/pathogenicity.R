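## General pathogenicity predictor: two-sample t-test feature selection
## (p < 0.01), z-score normalization, PCA at 99% retained variance, then a
## bagged ensemble of 30 tanh feed-forward networks (4 hidden units each)
## trained with resilient propagation on balanced bootstrap samples.  The
## prediction score is the mean of the 30 member scores.

#' Two-sample t-test feature selection
#'
#' Welch t-test per feature between the two label groups; features with
#' p < `alpha` are retained in their original order.  Features with zero
#' variance in both groups are excluded with a warning (the statistic is
#' undefined there), never an error.
#'
#' @param feature_matrix Numeric matrix (rows = variants, named columns).
#' @param labels Two-level label vector (e.g. pathogenic / unlabeled).
#' @param alpha Retention threshold on the p-value (default 0.01).
#' @return Character vector of retained feature names.
#' @export
select_features <- function(feature_matrix, labels, alpha = 0.01) {
  groups <- unique(labels)
  if (length(groups) != 2) {
    stop("exactly two label groups are required", call. = FALSE)
  }
  A <- feature_matrix[labels == groups[1], , drop = FALSE]
  B <- feature_matrix[labels == groups[2], , drop = FALSE]
  if (nrow(A) < 2 || nrow(B) < 2) {
    stop("each group needs at least 2 rows", call. = FALSE)
  }
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- apply(A, 2, stats::var); vB <- apply(B, 2, stats::var)
  nA <- nrow(A); nB <- nrow(B)
  se2 <- vA / nA + vB / nB
  dead <- se2 == 0
  if (any(dead)) {
    warning("excluding zero-variance feature(s): ",
            paste(colnames(feature_matrix)[dead], collapse = ", "),
            call. = FALSE)
  }
  tt <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  keep <- !dead & !is.na(p) & p < alpha
  colnames(feature_matrix)[keep]
}

#' Fit preprocessing state on a training partition
#'
#' Missing (masked) values are imputed with the training-column mean and
#' flagged with an added indicator feature; then t-test selection,
#' z-scoring and PCA retaining at least `retained_variance` of the
#' variance are fitted.  The state is fitted only on the rows given here
#' and applied unchanged elsewhere (no leakage into test partitions).
#'
#' @param feature_matrix Numeric matrix, `NA` for masked entries.
#' @param labels Two-level label vector.
#' @param alpha Selection threshold (default 0.01).
#' @param retained_variance PCA retained-variance fraction (default 0.99).
#' @return A `preprocess_state`.
#' @export
fit_preprocess <- function(feature_matrix, labels, alpha = 0.01,
                           retained_variance = 0.99) {
  # columns masked for every training row carry no information: drop them
  # up front (they would otherwise impute to a constant)
  all_missing <- colSums(!is.na(feature_matrix)) == 0
  feature_matrix <- feature_matrix[, !all_missing, drop = FALSE]
  impute_means <- colMeans(feature_matrix, na.rm = TRUE)
  had_missing <- colnames(feature_matrix)[colSums(is.na(feature_matrix)) > 0]
  X <- impute_with(feature_matrix, impute_means, had_missing)
  selected <- select_features(X, labels, alpha)
  if (length(selected) == 0) {
    # under a pure-noise labeling nothing may survive; fall back to all
    # informative columns so downstream contracts (chance-level CV on
    # permuted labels) still hold
    warning("no features pass t-test selection; keeping all non-constant features",
            call. = FALSE)
    selected <- colnames(X)[apply(X, 2, stats::sd) > 0]
    if (length(selected) == 0) {
      stop("all features are constant", call. = FALSE)
    }
  }
  Xs <- X[, selected, drop = FALSE]
  mu <- colMeans(Xs)
  sdv <- apply(Xs, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- scale(Xs, center = mu, scale = sdv)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cum >= retained_variance)[1]
  structure(list(impute_means = impute_means, had_missing = had_missing,
                 selected = selected, mean = mu, sd = sdv,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 retained_variance = cum[k]),
            class = "preprocess_state")
}

impute_with <- function(feature_matrix, means, indicator_cols) {
  X <- feature_matrix
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- means[colnames(X)[j]]
  }
  if (length(indicator_cols) > 0) {
    ind <- 1 * is.na(feature_matrix[, indicator_cols, drop = FALSE])
    colnames(ind) <- paste0(indicator_cols, "_missing")
    X <- cbind(X, ind)
  }
  X
}

#' Apply fitted preprocessing to a feature matrix
#' @param state A `preprocess_state`.
#' @param feature_matrix Matrix with (at least) the training columns;
#'   missing features raise an error naming them.
#' @return Projected numeric matrix (rows x retained components).
#' @export
apply_preprocess <- function(state, feature_matrix) {
  base_cols <- names(state$impute_means)
  absent <- setdiff(base_cols, colnames(feature_matrix))
  if (length(absent) > 0) {
    stop("feature matrix is missing feature(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  X <- impute_with(feature_matrix[, base_cols, drop = FALSE],
                   state$impute_means, state$had_missing)
  Z <- scale(X[, state$selected, drop = FALSE], center = state$mean,
             scale = state$sd)
  Z %*% state$rotation
}

#' Train the bagged pathogenicity ensemble
#'
#' Each member draws a class-balanced bootstrap (with replacement, 2 x the
#' minority-class size), holds out 25% of it as a validation set to pick
#' the stopping iteration, and trains with resilient propagation under the
#' three stopping rules (optimal iteration reached / 1000 epochs / 500
#' validation checks).  Deterministic given `seed`.
#'
#' @param feature_matrix Numeric matrix, `NA` for masked entries.
#' @param labels Vector with both classes present (canonically
#'   `pathogenic` vs `unlabeled`; the positive class is `pathogenic` when
#'   present, otherwise the first level).
#' @param n_members Ensemble size (default 30).
#' @param hidden Hidden units per member (default 4).
#' @param alpha Feature-selection threshold (default 0.01).
#' @param retained_variance PCA retained variance (default 0.99).
#' @param max_epochs,max_val_checks Stopping caps (defaults 1000 / 500).
#' @param seed Integer seed.
#' @return An `ensemble_model`.
#' @export
train_ensemble <- function(feature_matrix, labels, n_members = 30L,
                           hidden = 4L, alpha = 0.01,
                           retained_variance = 0.99, max_epochs = 1000L,
                           max_val_checks = 500L, seed = 1L) {
  classes <- unique(labels)
  if (length(classes) != 2) {
    stop("both classes must be present in the labels", call. = FALSE)
  }
  positive <- if ("pathogenic" %in% classes) "pathogenic" else classes[1]
  y <- as.numeric(labels == positive)
  pre <- fit_preprocess(feature_matrix, labels, alpha, retained_variance)
  P <- apply_preprocess(pre, feature_matrix)
  pos_idx <- which(y == 1); neg_idx <- which(y == 0)
  n_min <- min(length(pos_idx), length(neg_idx))
  members <- vector("list", n_members)
  member_seeds <- seed + seq_len(n_members)
  for (m in seq_len(n_members)) {
    set.seed(member_seeds[m])
    boot <- c(sample(pos_idx, n_min, replace = TRUE),
              sample(neg_idx, n_min, replace = TRUE))
    yb <- y[boot]
    Xb <- P[boot, , drop = FALSE]
    val <- sample.int(length(boot), max(2L, floor(length(boot) * 0.25)))
    members[[m]] <- rprop_train(Xb[-val, , drop = FALSE], yb[-val],
                                Xb[val, , drop = FALSE], yb[val],
                                hidden = hidden, max_epochs = max_epochs,
                                max_val_checks = max_val_checks)
  }
  structure(list(preprocess = pre, networks = members,
                 member_seeds = member_seeds, positive_class = positive,
                 n_members = n_members, hidden = hidden),
            class = "ensemble_model")
}

#' Predict pathogenicity scores
#'
#' The general score is the arithmetic mean of the member scores, each
#' already mapped to \[0, 1\].
#'
#' @param object An `ensemble_model`.
#' @param feature_matrix Feature matrix with the training column layout
#'   (`NA` entries are mean-imputed from the training state).
#' @param ... Unused.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
predict.ensemble_model <- function(object, feature_matrix, ...) {
  P <- apply_preprocess(object$preprocess, feature_matrix)
  scores <- vapply(object$networks, function(net) rprop_predict(net, P),
                   numeric(nrow(P)))
  if (nrow(P) == 1) scores <- matrix(scores, nrow = 1)
  rowMeans(scores)
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf(
    "ensemble_model: %d members, %d hidden units, %d selected features, %d components\n",
    x$n_members, x$hidden, length(x$preprocess$selected),
    ncol(x$preprocess$rotation)))
  invisible(x)
}
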