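## Evaluation machinery: sequence-identity clustering for stringent fold
## assignment, per-protein / per-cluster k-fold plans, ROC/AUC, the
## two-sided label-noise AUC correction, and the 25-residue fragment
## redundancy filter for independent test-set construction.

## Best ungapped-overlap identity between two sequences:
## max over all offsets of (positional matches) / (length of the shorter).
pair_identity <- function(a, b) {
  va <- utf8ToInt(a); vb <- utf8ToInt(b)
  la <- length(va); lb <- length(vb)
  best <- 0L
  for (off in (-(lb - 1L)):(la - 1L)) {
    ia <- max(1L, 1L + off):min(la, lb + off)
    ib <- ia - off
    m <- sum(va[ia] == vb[ib])
    if (m > best) best <- m
  }
  best / min(la, lb)
}

#' Greedy sequence-identity clustering
#'
#' CD-HIT-style greedy incremental clustering: proteins are sorted by
#' decreasing length; each joins the first existing cluster whose
#' representative shares at least `identity_threshold` identity (matches /
#' shorter-sequence length under the best ungapped overlap), otherwise it
#' founds a new cluster with itself as representative.
#'
#' @param proteins A [protein_set()].
#' @param identity_threshold Fraction in (0, 1\] (default 0.5).
#' @return Named integer vector: protein id -> cluster index.
#' @export
cluster_sequences <- function(proteins, identity_threshold = 0.5) {
  if (!(identity_threshold > 0 && identity_threshold <= 1)) {
    stop("identity threshold must lie in (0, 1]", call. = FALSE)
  }
  ord <- order(-nchar(proteins), names(proteins), method = "radix")
  reps <- integer(0)  # indices (into ord) of cluster representatives
  assign <- integer(length(proteins))
  names(assign) <- names(proteins)
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (pair_identity(proteins[[reps[ci]]], proteins[[i]]) >=
          identity_threshold) {
        assign[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- length(reps)
    }
  }
  assign
}

#' Build a k-fold cross-validation plan over units
#'
#' Units (protein ids or cluster ids) are shuffled by the seed and dealt
#' round-robin into `k` folds, so all data points of one unit share a
#' fold.
#'
#' @param units Character or integer vector of unique unit ids.
#' @param k Fold count (default 10).
#' @param seed Integer seed.
#' @param unit_type `"protein"` or `"cluster"` (metadata only).
#' @return A `crossval_plan`: list with `assignment` (named unit -> fold),
#'   `k`, `unit_type`, `seed`.
#' @export
make_folds <- function(units, k = 10L, seed = 1L, unit_type = "protein") {
  units <- unique(units)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (length(units) < k) {
    stop(sprintf("only %d units for %d folds", length(units), k),
         call. = FALSE)
  }
  set.seed(seed)
  shuffled <- sample(units)
  fold <- rep_len(seq_len(k), length(shuffled))
  structure(list(assignment = stats::setNames(fold, shuffled), k = k,
                 unit_type = unit_type, seed = seed),
            class = "crossval_plan")
}

#' ROC curve and AUC
#'
#' AUC by the Mann-Whitney identity (midranks, so ties count half); the
#' curve is traced over the sorted unique score thresholds.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical/0-1 vector, or character with the positive class
#'   `"pathogenic"`.
#' @return A `roc_result`: `auc`, `curve` (data.frame `fpr`, `tpr`),
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels) == "pathogenic"
  }
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores)  # midranks: tied pairs contribute 1/2
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord]); fp <- cumsum(!labels[ord])
  last <- !duplicated(scores[ord], fromLast = TRUE)
  curve <- data.frame(fpr = c(0, fp[last] / n_neg),
                      tpr = c(0, tp[last] / n_pos))
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' Label-noise-corrected AUC
#'
#' With a fraction `rho_pos` of the positive-labeled class truly negative
#' and a fraction `rho_neg` of the negative-labeled (unlabeled) class
#' truly positive, the observed AUC is an attenuated linear mixture of the
#' clean AUC and chance; inverting gives
#' `(auc_observed - (rho_pos + rho_neg) / 2) / (1 - rho_pos - rho_neg)`,
#' clipped to \[0, 1\].
#'
#' @param auc_observed Observed AUC in \[0, 1\].
#' @param rho_pos Fraction of mislabeled positives in \[0, 1).
#' @param rho_neg Fraction of true positives among the negatives/unlabeled.
#' @return Corrected AUC.
#' @export
corrected_auc <- function(auc_observed, rho_pos, rho_neg) {
  stopifnot(auc_observed >= 0, auc_observed <= 1,
            rho_pos >= 0, rho_pos < 1, rho_neg >= 0, rho_neg < 1)
  denom <- 1 - rho_pos - rho_neg
  if (denom <= 0) stop("rho_pos + rho_neg must be < 1", call. = FALSE)
  min(1, max(0, (auc_observed - (rho_pos + rho_neg) / 2) / denom))
}

fragment_of <- function(sequence, position, half) {
  lo <- max(1L, position - half)
  hi <- min(nchar(sequence), position + half)
  list(chars = strsplit(substr(sequence, lo, hi), "")[[1]],
       offset = lo - position)  # offset of first char relative to center
}

fragment_identity <- function(fa, fb, fragment_length) {
  half <- (fragment_length - 1L) %/% 2L
  grid <- (-half):half
  a <- rep(NA_character_, length(grid)); b <- a
  a[grid %in% (fa$offset + seq_along(fa$chars) - 1L)] <- fa$chars
  b[grid %in% (fb$offset + seq_along(fb$chars) - 1L)] <- fb$chars
  both <- !is.na(a) & !is.na(b)
  if (!any(both)) return(0)
  sum(a[both] == b[both]) / sum(both)
}

#' Fragment-based redundancy filter
#'
#' Fragments of `fragment_length` residues centered at each mutation
#' position (clipped at the termini) are compared position-by-position,
#' aligned on their centers; identity is matches over the overlap length.
#' A candidate is removed iff any reference fragment matches at or above
#' `identity_threshold`.
#'
#' @param candidate_variants,reference_variants Variant data.frames
#'   ([read_variants()] layout).
#' @param candidate_proteins,reference_proteins [protein_set()]s the two
#'   tables refer to.
#' @param fragment_length Odd fragment length (default 25).
#' @param identity_threshold Removal threshold (default 0.5; 0.8 is the
#'   lenient variant).
#' @return The retained rows of `candidate_variants`.
#' @export
fragment_filter <- function(candidate_variants, reference_variants,
                            candidate_proteins, reference_proteins,
                            fragment_length = 25L,
                            identity_threshold = 0.5) {
  if (fragment_length %% 2L != 1L) {
    stop("fragment length must be odd", call. = FALSE)
  }
  half <- (fragment_length - 1L) %/% 2L
  ref_frags <- lapply(seq_len(nrow(reference_variants)), function(i) {
    v <- reference_variants[i, ]
    fragment_of(reference_proteins[[v$protein_id]], v$position, half)
  })
  keep <- vapply(seq_len(nrow(candidate_variants)), function(i) {
    v <- candidate_variants[i, ]
    fc <- fragment_of(candidate_proteins[[v$protein_id]], v$position, half)
    for (fr in ref_frags) {
      if (fragment_identity(fc, fr, fragment_length) >= identity_threshold) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  out <- candidate_variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Out-of-fold ensemble scores under a cross-validation plan
#'
#' For each fold, an ensemble (including its preprocessing state) is
#' fitted on the training partition only and applied to the held-out
#' partition, so every row receives exactly one out-of-fold score.
#'
#' @param feature_matrix Numeric matrix, one row per variant.
#' @param labels Label vector (see [train_ensemble()]).
#' @param row_units Unit id (protein or cluster) of each row.
#' @param plan A [make_folds()] plan over those units.
#' @param ... Passed to [train_ensemble()] (e.g. `n_members`, `seed`).
#' @return Numeric vector of out-of-fold scores aligned with the rows.
#' @export
crossval_scores <- function(feature_matrix, labels, row_units, plan, ...) {
  fold_of_row <- plan$assignment[as.character(row_units)]
  if (anyNA(fold_of_row)) {
    stop("rows reference units absent from the plan", call. = FALSE)
  }
  scores <- rep(NA_real_, nrow(feature_matrix))
  for (f in seq_len(plan$k)) {
    test <- fold_of_row == f
    if (!any(test)) next
    model <- train_ensemble(feature_matrix[!test, , drop = FALSE],
                            labels[!test], ...)
    scores[test] <- predict(model, feature_matrix[test, , drop = FALSE])
  }
  scores
}
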