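## Loss/gain mechanism inference.  Given calibrated posterior probabilities
## that a property is present on the wild-type and on the mutant sequence,
## the probability of losing the property is
##   Pr(loss) = Pr(present | wt) * (1 - Pr(present | mt))
## and of gaining it
##   Pr(gain) = (1 - Pr(present | wt)) * Pr(present | mt).
## The property score is max(loss, gain); at uninformative posteriors
## (both 0.5) loss = gain = 0.25, the baseline for implicating a property.

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  x
}

#' Probability of property loss
#' @param post_wt,post_mt Posterior probabilities of property presence on
#'   the wild-type and mutant sequence, both in \[0,1\].  Vectorized.
#' @return `post_wt * (1 - post_mt)`.
#' @export
loss_probability <- function(post_wt, post_mt) {
  check_prob(post_wt, "post_wt"); check_prob(post_mt, "post_mt")
  post_wt * (1 - post_mt)
}

#' Probability of property gain
#' @inheritParams loss_probability
#' @return `(1 - post_wt) * post_mt`.
#' @export
gain_probability <- function(post_wt, post_mt) {
  check_prob(post_wt, "post_wt"); check_prob(post_mt, "post_mt")
  (1 - post_wt) * post_mt
}

#' Call the mechanism for one property at one variant
#'
#' Loss and gain are evaluated at every window position of the site
#' posteriors; the focal position is the one maximizing max(loss, gain).
#' Site-specific (PTM-like) properties are restricted to the substitution
#' position itself.  The direction is `loss` or `gain` by the larger
#' score, replaced by `altered` for bidirectional properties.
#'
#' @param site_post A `site_posteriors` object from [score_site()], or any
#'   list with `wt_posteriors`, `mt_posteriors`, `positions` and
#'   `focal_index`.
#' @param definition A [property_definition()].
#' @return A one-row data.frame (`property`, `loss`, `gain`,
#'   `property_score`, `direction`, `focal_position`).
#' @export
call_mechanism <- function(site_post, definition) {
  wt <- check_prob(site_post$wt_posteriors, "wt posteriors")
  mt <- check_prob(site_post$mt_posteriors, "mt posteriors")
  if (length(wt) == 0 || length(wt) != length(mt)) {
    stop("empty or mismatched posterior window", call. = FALSE)
  }
  idx <- if (isTRUE(definition$site_specific)) {
    site_post$focal_index
  } else {
    seq_along(wt)
  }
  loss <- loss_probability(wt[idx], mt[idx])
  gain <- gain_probability(wt[idx], mt[idx])
  score <- pmax(loss, gain)
  best <- idx[which.max(score)]
  k <- which.max(score)
  direction <- if (isTRUE(definition$bidirectional)) {
    "altered"
  } else if (loss[k] >= gain[k]) "loss" else "gain"
  data.frame(property = definition$name,
             loss = loss[k], gain = gain[k],
             property_score = score[k],
             direction = direction,
             focal_position = site_post$positions[best],
             stringsAsFactors = FALSE)
}

#' Empirical p-value of a score against a neutral pool
#'
#' `(r + 1) / (n + 1)` where `r` counts pool scores at least as high as
#' the observed score (add-one correction so no p-value is zero and
#' Benjamini-Hochberg stays valid downstream).
#'
#' @param score Observed loss/gain score (vectorized).
#' @param neutral_pool Numeric vector of scores computed on putatively
#'   neutral substitutions (non-empty).
#' @return p-values in (0, 1\].
#' @export
empirical_pvalue <- function(score, neutral_pool) {
  if (length(neutral_pool) == 0) {
    stop("empty neutral score pool", call. = FALSE)
  }
  pool <- sort(neutral_pool)
  n <- length(pool)
  # r = n - (number strictly below score)
  r <- n - findInterval(score, pool, left.open = TRUE)
  (r + 1) / (n + 1)
}

#' Rank mechanism calls
#'
#' Descending property score; ties broken by ascending empirical p-value,
#' then lexicographic property name, so the ordering is a deterministic
#' total order.
#'
#' @param calls Data.frame of mechanism calls with at least `property`,
#'   `property_score` and `empirical_p` columns.
#' @return The same data.frame, reordered.
#' @export
rank_mechanisms <- function(calls) {
  if (nrow(calls) == 0) return(calls)
  ord <- order(-calls$property_score, calls$empirical_p, calls$property,
               method = "radix")
  out <- calls[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
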