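## Enrichment analyses: FPR-calibrated score thresholds, the signed
## enrichment statistic E = (d_f - n_f) / (d_f + n_f) with one-sided
## Fisher tests and Benjamini-Hochberg correction, the top-3 mechanism
## case/control comparison (one-sided binomial), odds ratios at score
## thresholds, score binning, and shared-gene removal.

#' Score threshold at a target false-positive rate
#'
#' The smallest observed score `t` such that the fraction of neutral
#' scores at or above `t` does not exceed `target_fpr` (if 5% of neutral
#' variants score 0.4 or higher, the 5% FPR threshold is 0.4).
#'
#' @param neutral_scores Non-empty numeric vector of scores on putatively
#'   neutral variants.
#' @param target_fpr Target false-positive rate in (0, 1).
#' @return Threshold score.  When even the maximum score is exceeded by
#'   more than `target_fpr` of the pool, a threshold just above the
#'   maximum is returned so that the defining property still holds.
#' @export
fpr_threshold <- function(neutral_scores, target_fpr) {
  if (length(neutral_scores) == 0) stop("empty neutral pool", call. = FALSE)
  if (!(target_fpr > 0 && target_fpr < 1)) {
    stop("target FPR must lie in (0, 1)", call. = FALSE)
  }
  ss <- sort(neutral_scores)
  u <- unique(ss)
  n <- length(ss)
  frac_ge <- (n - findInterval(u, ss, left.open = TRUE)) / n
  ok <- which(frac_ge <= target_fpr)
  if (length(ok) > 0) u[ok[1]] else max(ss) + .Machine$double.eps
}

#' Signed enrichment statistic
#'
#' `E = (d_f - n_f) / (d_f + n_f)`: positive when the property is
#' enriched among disease variants, negative when depleted.
#'
#' @param d_f Fraction of disease variants affecting the property.
#' @param n_f Fraction of neutral variants affecting the property.
#' @return E in \[-1, 1\]; `NA` (no-call) when both fractions are zero.
#' @export
enrichment_statistic <- function(d_f, n_f) {
  stopifnot(d_f >= 0, d_f <= 1, n_f >= 0, n_f <= 1)
  ifelse(d_f + n_f == 0, NA_real_, (d_f - n_f) / (d_f + n_f))
}

#' Property enrichment between disease and neutral variant sets
#'
#' Per property, the loss/gain score threshold is calibrated on the
#' neutral calls at the target FPR (maximal effect: the property score,
#' i.e. max of loss and gain); variants at or above it count as affected.
#' Enrichment/depletion is tested with a one-sided Fisher's exact test in
#' the direction of E's sign and corrected across properties with
#' Benjamini-Hochberg.  PTM-like (site-specific) properties are optionally
#' split into exact-site and neighborhood sub-tests, by whether the
#' substitution sits on the call's focal position.
#'
#' @param disease_calls,neutral_calls Mechanism-call data.frames (one row
#'   per variant x property) with columns `property`, `property_score`,
#'   and, for the PTM split, `focal_position` plus `variant_position`.
#' @param properties Named list of [property_definition()]s to test.
#' @param fpr Target FPR for the per-property threshold (default 0.01).
#' @param ptm_split Split site-specific properties into exact-site /
#'   neighborhood sub-tests (default `FALSE`).
#' @return Data.frame: `property`, `d_f`, `n_f`, `E`, `direction`,
#'   `p_raw`, `p_adjusted`.
#' @export
property_enrichment <- function(disease_calls, neutral_calls, properties,
                                fpr = 0.01, ptm_split = FALSE) {
  if (nrow(disease_calls) == 0 || nrow(neutral_calls) == 0) {
    stop("both call sets must be non-empty", call. = FALSE)
  }
  tests <- list()
  for (p in names(properties)) {
    dc <- disease_calls[disease_calls$property == p, , drop = FALSE]
    nc <- neutral_calls[neutral_calls$property == p, , drop = FALSE]
    if (nrow(dc) == 0 || nrow(nc) == 0) next
    if (ptm_split && isTRUE(properties[[p]]$site_specific)) {
      at_site <- function(calls) calls$focal_position == calls$variant_position
      tests[[paste0(p, ":site")]] <-
        list(dc = dc[at_site(dc), , drop = FALSE],
             nc = nc[at_site(nc), , drop = FALSE], pool = nc)
      tests[[paste0(p, ":neighborhood")]] <-
        list(dc = dc[!at_site(dc), , drop = FALSE],
             nc = nc[!at_site(nc), , drop = FALSE], pool = nc)
    } else {
      tests[[p]] <- list(dc = dc, nc = nc, pool = nc)
    }
  }
  rows <- lapply(names(tests), function(nm) {
    te <- tests[[nm]]
    if (nrow(te$dc) == 0 || nrow(te$nc) == 0) return(NULL)
    thr <- fpr_threshold(te$pool$property_score, fpr)
    d_aff <- sum(te$dc$property_score >= thr)
    n_aff <- sum(te$nc$property_score >= thr)
    d_f <- d_aff / nrow(te$dc)
    n_f <- n_aff / nrow(te$nc)
    E <- enrichment_statistic(d_f, n_f)
    if (is.na(E)) {
      return(data.frame(property = nm, d_f = d_f, n_f = n_f, E = NA_real_,
                        direction = "no-call", p_raw = NA_real_,
                        stringsAsFactors = FALSE))
    }
    tab <- matrix(c(d_aff, nrow(te$dc) - d_aff,
                    n_aff, nrow(te$nc) - n_aff), 2, byrow = TRUE)
    side <- if (E >= 0) "greater" else "less"
    p <- stats::fisher.test(tab, alternative = side)$p.value
    data.frame(property = nm, d_f = d_f, n_f = n_f, E = E,
               direction = if (E >= 0) "enriched" else "depleted",
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out) || nrow(out) == 0) {
    stop("no testable properties", call. = FALSE)
  }
  out$p_adjusted <- NA_real_
  tested <- !is.na(out$p_raw)
  out$p_adjusted[tested] <- stats::p.adjust(out$p_raw[tested],
                                            method = "BH")
  rownames(out) <- NULL
  out
}

#' Top-3 mechanism enrichment between case and control reports
#'
#' Variants whose general score is at or above `score_threshold` enter the
#' analysis; per property, the fraction of case variants carrying it in
#' their top-3 ranked mechanisms is tested one-sided (greater) against the
#' control fraction as the binomial null proportion, BH-corrected across
#' properties.
#'
#' @param case_reports,control_reports Lists of [prediction_report()]s.
#' @param score_threshold General-score inclusion threshold (e.g. the 5%
#'   FPR threshold).
#' @param top_k Mechanisms counted per variant (default 3).
#' @return Data.frame: `property`, `case_fraction`, `control_fraction`,
#'   `n_case`, `p_raw`, `p_adjusted`.
#' @export
top3_mechanism_enrichment <- function(case_reports, control_reports,
                                      score_threshold, top_k = 3L) {
  keep <- function(reports) {
    Filter(function(r) r$general_score >= score_threshold, reports)
  }
  cases <- keep(case_reports); controls <- keep(control_reports)
  if (length(cases) == 0 || length(controls) == 0) {
    stop("no variants pass the score threshold in one of the sets",
         call. = FALSE)
  }
  topk_props <- function(r) {
    utils::head(rank_mechanisms(r$mechanisms)$property, top_k)
  }
  case_top <- lapply(cases, topk_props)
  ctrl_top <- lapply(controls, topk_props)
  props <- sort(unique(unlist(c(case_top, ctrl_top))))
  rows <- lapply(props, function(p) {
    x <- sum(vapply(case_top, function(tp) p %in% tp, logical(1)))
    ctrl_frac <- mean(vapply(ctrl_top, function(tp) p %in% tp, logical(1)))
    n <- length(case_top)
    p_raw <- if (ctrl_frac >= 1) 1 else
      stats::binom.test(x, n, p = max(ctrl_frac, .Machine$double.eps),
                        alternative = "greater")$p.value
    data.frame(property = p, case_fraction = x / n,
               control_fraction = ctrl_frac, n_case = n, p_raw = p_raw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "BH")
  out
}

#' Odds ratio of exceeding a score threshold, case vs control
#'
#' @param case_scores,control_scores Non-empty numeric score vectors.
#' @param threshold Scores at or above it count as predicted pathogenic.
#' @return List: `odds_ratio` (cross-product ratio; Haldane 0.5-continuity
#'   applied when a cell is zero, noted in `continuity`), `p_value`
#'   (two-sided Fisher), `table` (2x2 counts, groups x >= threshold).
#' @export
odds_ratio_analysis <- function(case_scores, control_scores, threshold) {
  if (length(case_scores) == 0 || length(control_scores) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  a <- sum(case_scores >= threshold)
  b <- length(case_scores) - a
  d <- sum(control_scores >= threshold)
  e <- length(control_scores) - d
  tab <- matrix(c(a, b, d, e), 2, byrow = TRUE,
                dimnames = list(c("case", "control"),
                                c("pathogenic", "benign")))
  continuity <- any(tab == 0)
  or <- if (continuity) {
    ((a + 0.5) * (e + 0.5)) / ((b + 0.5) * (d + 0.5))
  } else {
    (a * e) / (b * d)
  }
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(odds_ratio = or, p_value = p, table = tab, continuity = continuity)
}

#' Bin scores into fixed intervals
#'
#' Right-open bins except the last (which is closed at 1).
#'
#' @param scores Scores in \[0, 1\].
#' @param bin_edges Strictly increasing edges covering \[0, 1\] (default
#'   deciles).
#' @return Named vector of per-bin fractions summing to 1.
#' @export
bin_scores <- function(scores, bin_edges = seq(0, 1, by = 0.1)) {
  check_prob(scores, "scores")
  if (is.unsorted(bin_edges, strictly = TRUE) ||
      bin_edges[1] > 0 || bin_edges[length(bin_edges)] < 1) {
    stop("bin edges must be strictly increasing and cover [0, 1]",
         call. = FALSE)
  }
  idx <- findInterval(scores, bin_edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, length(bin_edges) - 1)
  labs <- paste0("[", utils::head(bin_edges, -1), ",",
                 bin_edges[-1], c(rep(")", length(bin_edges) - 2), "]"))
  stats::setNames(counts / length(scores), labs)
}

#' Remove genes mutated in both case and control sets
#'
#' @param case_variants,control_variants Variant data.frames.
#' @param gene_of Named character vector mapping protein id -> gene; must
#'   cover every protein in both sets.
#' @return List with filtered `case` and `control` data.frames (their
#'   gene sets are disjoint).
#' @export
remove_shared_genes <- function(case_variants, control_variants, gene_of) {
  genes_for <- function(v) {
    g <- gene_of[v$protein_id]
    if (anyNA(g)) {
      stop("missing gene mapping for variant(s) in protein: ",
           paste(unique(v$protein_id[is.na(g)]), collapse = ", "),
           call. = FALSE)
    }
    g
  }
  gc <- genes_for(case_variants)
  gk <- genes_for(control_variants)
  shared <- intersect(gc, gk)
  list(case = case_variants[!gc %in% shared, , drop = FALSE],
       control = control_variants[!gk %in% shared, , drop = FALSE])
}
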