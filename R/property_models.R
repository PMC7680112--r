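## Per-residue positive-unlabeled property predictors.  Each property (a
## structural or functional feature of a residue: a PTM site, a binding
## region, a secondary-structure state, ...) gets a window classifier
## trained to separate labeled-positive windows from unlabeled windows.
## Raw scores are turned into posterior probabilities of property presence
## by Elkan-Noto scaling (divide by the mean raw score on held-out labeled
## positives) followed by an affine prior-matching adjustment so that the
## mean posterior over an unlabeled reference pool equals the class prior.

#' Define a property
#'
#' @param name Property name (used in reports and feature names).
#' @param ontology_group Broader class the property belongs to (free-form
#'   config vocabulary, e.g. "structure", "ptm", "binding").
#' @param site_specific `TRUE` for properties tied to the exact residue
#'   (PTM-like); their mechanism calls never move off the substituted
#'   position.
#' @param bidirectional `TRUE` for properties reported as "altered"
#'   (e.g. macromolecular binding, where one partner may be gained while
#'   another is lost).
#' @param prior Class prior: probability that a random residue carries the
#'   property, strictly inside (0, 1).
#' @return A `property_definition`.
#' @export
property_definition <- function(name, ontology_group = "structure",
                                site_specific = FALSE,
                                bidirectional = FALSE, prior = 0.05) {
  if (!(prior > 0 && prior < 1)) {
    stop("prior must lie strictly inside (0, 1)", call. = FALSE)
  }
  structure(list(name = name, ontology_group = ontology_group,
                 site_specific = site_specific,
                 bidirectional = bidirectional, prior = prior),
            class = "property_definition")
}

## One-hot encoding of the residue window centered at `position`; positions
## beyond the termini and ambiguity codes encode as all-zero blocks.
encode_window <- function(sequence, position, window) {
  h <- (window - 1L) %/% 2L
  L <- nchar(sequence)
  out <- matrix(0, length(position), 20L * window)
  chars <- strsplit(sequence, "")[[1]]
  for (k in seq_len(window)) {
    pos <- position + (k - h - 1L)
    ok <- pos >= 1L & pos <= L
    aa <- chars[pos[ok]]
    j <- match(aa, AA_ALPHABET)
    keep <- !is.na(j)
    rows <- which(ok)[keep]
    out[cbind(rows, (k - 1L) * 20L + j[keep])] <- 1
  }
  out
}

#' Train a positive-unlabeled property predictor
#'
#' A window classifier (tanh feed-forward net, same family as the
#' pathogenicity ensemble members) is trained to discriminate
#' labeled-positive windows from unlabeled windows.  A quarter of the
#' positives is held out to estimate the Elkan-Noto calibration constant
#' `c` (mean raw score on held-out positives); a quarter of the remaining
#' training data is held out as the early-stopping validation set.
#'
#' @param positive_sites,unlabeled_sites Data.frames with `protein_id` and
#'   `position` columns.  At least 20 positives are required and the
#'   unlabeled pool must be larger than the positive pool.
#' @param proteins A [protein_set()].
#' @param definition A [property_definition()].
#' @param window Odd window width (default 11: the site and 5 residues to
#'   each side).
#' @param seed Integer seed; training is deterministic given it.
#' @param hidden Hidden units (default 4).
#' @param max_epochs,max_val_checks Stopping-rule caps (defaults 1000/500).
#' @return A `property_model`.
#' @export
train_property_predictor <- function(positive_sites, unlabeled_sites,
                                     proteins, definition, window = 11L,
                                     seed = 1L, hidden = 4L,
                                     max_epochs = 1000L,
                                     max_val_checks = 500L) {
  if (nrow(positive_sites) < 20) {
    stop(sprintf("property '%s': need >= 20 positive sites, got %d",
                 definition$name, nrow(positive_sites)), call. = FALSE)
  }
  if (nrow(unlabeled_sites) <= nrow(positive_sites)) {
    stop(sprintf("property '%s': unlabeled pool must exceed the positive pool",
                 definition$name), call. = FALSE)
  }
  enc <- function(sites) {
    do.call(rbind, lapply(split(sites, sites$protein_id), function(g) {
      encode_window(proteins[[g$protein_id[1]]], g$position, window)
    }))
  }
  set.seed(seed)
  Xp <- enc(positive_sites)
  Xu <- enc(unlabeled_sites)

  n_cal <- max(5L, floor(nrow(Xp) * 0.25))
  cal_idx <- sample.int(nrow(Xp), n_cal)
  Xp_cal <- Xp[cal_idx, , drop = FALSE]
  Xp_tr <- Xp[-cal_idx, , drop = FALSE]

  X <- rbind(Xp_tr, Xu)
  y <- c(rep(1, nrow(Xp_tr)), rep(0, nrow(Xu)))
  val_idx <- sample.int(nrow(X), max(2L, floor(nrow(X) * 0.25)))
  net <- rprop_train(X[-val_idx, , drop = FALSE], y[-val_idx],
                     X[val_idx, , drop = FALSE], y[val_idx],
                     hidden = hidden, max_epochs = max_epochs,
                     max_val_checks = max_val_checks)

  c_const <- mean(rprop_predict(net, Xp_cal))
  if (c_const <= 0) {
    stop(sprintf("property '%s': degenerate calibration constant 0",
                 definition$name), call. = FALSE)
  }
  prior_scale <- solve_prior_scale(rprop_predict(net, Xu) / c_const,
                                   definition$prior)
  structure(list(definition = definition, net = net, window = window,
                 calibration_constant = c_const, prior_scale = prior_scale,
                 seed = seed),
            class = "property_model")
}

#' Raw window-classifier scores at given positions
#' @param model A `property_model`.
#' @param sequence Amino-acid sequence string.
#' @param positions 1-based positions to score.
#' @return Raw scores in \[0, 1\].
#' @export
property_raw_scores <- function(model, sequence, positions) {
  rprop_predict(model$net, encode_window(sequence, positions, model$window))
}

## Fixed-point solve for the prior-matching factor k such that
## mean(min(1, base * k)) = prior over the unlabeled reference pool.  The
## clip is applied inside the mean so the match is exact even when some
## scaled scores saturate.
solve_prior_scale <- function(base, prior) {
  if (mean(base) <= 0) return(1)
  k <- prior / mean(base)
  for (it in 1:30) {
    m <- mean(pmin(1, base * k))
    if (m <= 0) break
    k_new <- k * prior / m
    if (abs(k_new - k) < 1e-12) { k <- k_new; break }
    k <- k_new
  }
  k
}

#' Calibrate a raw property score to a posterior probability
#'
#' Elkan-Noto scaling by the calibration constant `c` (mean raw score on
#' held-out labeled positives) times the frozen prior-matching factor,
#' clipped once to \[0, 1\].  Monotone in the raw score; `raw = c` maps to
#' 1 before the prior-matching rescale.
#'
#' @param raw Raw score(s) in \[0, 1\].
#' @param model A `property_model` with `calibration_constant > 0`.
#' @return Posterior probabilities in \[0, 1\].
#' @export
calibrate_posterior <- function(raw, model) {
  if (is.null(model$calibration_constant) ||
      model$calibration_constant <= 0) {
    stop("calibration constant must be > 0", call. = FALSE)
  }
  check_prob(raw, "raw score")
  pmin(1, (raw / model$calibration_constant) * model$prior_scale)
}

#' Score the substitution site and its neighborhood
#'
#' Calibrated posteriors for positions `i - 5 .. i + 5` (clipped at the
#' termini) on the wild-type sequence and on the full mutated sequence
#' (the substitution is introduced into the whole sequence, not patched
#' into a window).
#'
#' @param model A `property_model`.
#' @param proteins A [protein_set()].
#' @param sub A [substitution()].
#' @param flank Neighborhood half-width (default 5).
#' @return A `site_posteriors` list: `positions`, `wt_posteriors`,
#'   `mt_posteriors`, `focal_index`.
#' @export
score_site <- function(model, proteins, sub, flank = 5L) {
  s_wt <- proteins[[sub$protein_id]]
  s_mt <- mutate_sequence(sub, proteins)
  lo <- max(1L, sub$position - flank)
  hi <- min(nchar(s_wt), sub$position + flank)
  positions <- lo:hi
  wt <- calibrate_posterior(property_raw_scores(model, s_wt, positions),
                            model)
  mt <- calibrate_posterior(property_raw_scores(model, s_mt, positions),
                            model)
  structure(list(positions = positions, wt_posteriors = wt,
                 mt_posteriors = mt,
                 focal_index = match(sub$position, positions)),
            class = "site_posteriors")
}

#' Category-6 feature block and mechanism calls for a set of variants
#'
#' For every variant and property model, scores the site, calls the
#' mechanism, and returns both the per-variant feature block (wt and mt
#' posteriors plus loss and gain at the focal position) and the raw calls.
#'
#' @param models Named list of `property_model`s.
#' @param proteins A [protein_set()].
#' @param variants Variant data.frame ([read_variants()] layout).
#' @return List with `features` (matrix, one row per variant, columns
#'   `<property>_{wt,mt,loss,gain}`) and `calls` (data.frame with a
#'   `variant_index` column).
#' @export
property_change_scores <- function(models, proteins, variants) {
  props <- names(models)
  cols <- as.vector(t(outer(props, c("wt", "mt", "loss", "gain"),
                            paste, sep = "_")))
  feats <- matrix(NA_real_, nrow(variants), length(cols),
                  dimnames = list(NULL, cols))
  calls <- vector("list", nrow(variants) * length(props))
  k <- 0L
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    sub <- substitution(v$protein_id, v$position, v$ref_aa, v$alt_aa,
                        proteins)
    for (p in props) {
      sp <- score_site(models[[p]], proteins, sub)
      call <- call_mechanism(sp, models[[p]]$definition)
      j <- match(sp$focal_index, seq_along(sp$positions))
      at <- match(call$focal_position, sp$positions)
      feats[i, paste0(p, "_wt")] <- sp$wt_posteriors[at]
      feats[i, paste0(p, "_mt")] <- sp$mt_posteriors[at]
      feats[i, paste0(p, "_loss")] <- call$loss
      feats[i, paste0(p, "_gain")] <- call$gain
      k <- k + 1L
      calls[[k]] <- cbind(variant_index = i, call)
    }
  }
  list(features = feats, calls = do.call(rbind, calls[seq_len(k)]))
}

#' Neutral score pools for empirical p-values
#'
#' Property scores of putatively neutral substitutions, kept per property
#' and sorted ascending.
#'
#' @param models Named list of `property_model`s.
#' @param proteins A [protein_set()].
#' @param neutral_variants Variant data.frame of putatively neutral
#'   substitutions.
#' @return Named list of sorted numeric vectors.
#' @export
build_neutral_pools <- function(models, proteins, neutral_variants) {
  pc <- property_change_scores(models, proteins, neutral_variants)
  pools <- lapply(split(pc$calls$property_score, pc$calls$property), sort)
  pools[names(models)]
}
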