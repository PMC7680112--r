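## Mixture-proportion (class-prior) estimation from score distributions.
## Given a sample from a mixture alpha * f1 + (1 - alpha) * f0 and a
## sample from the component f1, the profile log-likelihood over alpha --
## with f1 fixed by a histogram fit to the component sample and f0 left
## nonparametric -- is flat up to the largest alpha consistent with the
## mixture and falls off beyond it.  The estimate is the largest alpha
## whose profile stays within a tolerance of the plateau (an AlphaMax-style
## inflection criterion).

#' Estimate a mixture proportion from two score samples
#'
#' @param mixture_scores Scores in \[0, 1\] drawn from the mixture.
#' @param component_scores Scores in \[0, 1\] drawn from the component
#'   whose proportion is sought.
#' @param grid Alpha grid (default 101 points on \[0, 1\]).
#' @param n_bins Histogram bins on \[0, 1\] (default 20).
#' @param tol Plateau tolerance in mean log-likelihood per observation
#'   (default 1e-3).
#' @param em_iter EM iterations per grid point (default 200; the
#'   nonparametric part is warm-started along the grid).
#' @return A `mixture_estimate`: `alpha`, `loglik_profile` (data.frame
#'   `alpha`, `loglik`), `n_mixture`, `n_component`.
#' @export
estimate_mixture_proportion <- function(mixture_scores, component_scores,
                                        grid = seq(0, 1, length.out = 101),
                                        n_bins = 20L, tol = 1e-3,
                                        em_iter = 200L) {
  if (length(mixture_scores) == 0 || length(component_scores) == 0) {
    stop("both score samples must be non-empty", call. = FALSE)
  }
  check_prob(mixture_scores, "mixture scores")
  check_prob(component_scores, "component scores")
  if (stats::sd(mixture_scores) == 0 || stats::sd(component_scores) == 0) {
    stop("degenerate (constant) score sample", call. = FALSE)
  }
  # equal-frequency bins on the pooled sample: binning is then a function
  # of ranks only, so the estimate is exactly invariant under strictly
  # monotone transforms applied to both samples
  pooled <- c(mixture_scores, component_scores)
  breaks <- unique(stats::quantile(pooled,
                                   probs = seq(0, 1,
                                               length.out = n_bins + 1),
                                   type = 1, names = FALSE))
  if (length(breaks) < 3) {
    stop("degenerate (constant) score sample", call. = FALSE)
  }
  n_bins <- length(breaks) - 1L
  binof <- function(x) findInterval(x, breaks, rightmost.closed = TRUE,
                                    all.inside = TRUE)
  m_counts <- tabulate(binof(mixture_scores), n_bins)
  c_counts <- tabulate(binof(component_scores), n_bins)
  # smoothed component density on the bins (pseudocount keeps the
  # likelihood finite where the component sample happens to be empty)
  f1 <- (c_counts + 0.5) / sum(c_counts + 0.5)
  n <- sum(m_counts)
  mhat <- m_counts / n

  nz <- m_counts > 0  # empty bins contribute nothing to the likelihood
  loglik <- function(dens) sum(m_counts[nz] * log(dens[nz]))
  profile <- numeric(length(grid))
  g <- mhat  # warm start for the nonparametric remainder
  for (gi in seq_along(grid)) {
    a <- grid[gi]
    if (a >= 1) {
      profile[gi] <- loglik(f1)
      next
    }
    for (it in seq_len(em_iter)) {
      dens <- a * f1 + (1 - a) * g
      resp <- ifelse(dens > 0, (1 - a) * g / dens, 0)
      g_new <- mhat * resp
      s <- sum(g_new)
      if (s == 0) break
      g_new <- g_new / s
      if (max(abs(g_new - g)) < 1e-10) { g <- g_new; break }
      g <- g_new
    }
    profile[gi] <- loglik(a * f1 + (1 - a) * g)
  }
  best <- max(profile)
  ok <- profile >= best - tol * n
  alpha_hat <- max(grid[ok])
  structure(list(alpha = alpha_hat,
                 loglik_profile = data.frame(alpha = grid,
                                             loglik = profile),
                 n_mixture = length(mixture_scores),
                 n_component = length(component_scores)),
            class = "mixture_estimate")
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat(sprintf("mixture_estimate: alpha = %.4f (n_mixture = %d, n_component = %d)\n",
              x$alpha, x$n_mixture, x$n_component))
  invisible(x)
}

#' Pathogenic fraction of a variant cohort
#'
#' Treats the cohort's score distribution as a mixture whose component of
#' interest is the pathogenic score distribution, and delegates to
#' [estimate_mixture_proportion()].
#'
#' @param cohort_scores Scores of the cohort (the mixture).
#' @param pathogenic_reference_scores Scores of known pathogenic variants
#'   (the component).
#' @param ... Passed to [estimate_mixture_proportion()].
#' @return A `mixture_estimate`.
#' @export
estimate_cohort_pathogenic_fraction <- function(cohort_scores,
                                                pathogenic_reference_scores,
                                                ...) {
  estimate_mixture_proportion(cohort_scores, pathogenic_reference_scores,
                              ...)
}

#' Two-sided label-noise estimates from score samples
#'
#' `rho_neg`: proportion of the unlabeled sample that follows the
#' positive-labeled score distribution.  `rho_pos`: proportion of the
#' positive-labeled sample that follows the unlabeled-background
#' distribution (roles swapped).
#'
#' @param positive_scores,unlabeled_scores Score samples in \[0, 1\].
#' @param ... Passed to [estimate_mixture_proportion()].
#' @return List with `rho_neg` and `rho_pos` `mixture_estimate`s.
#' @export
estimate_label_noise <- function(positive_scores, unlabeled_scores, ...) {
  list(rho_neg = estimate_mixture_proportion(unlabeled_scores,
                                             positive_scores, ...),
       rho_pos = estimate_mixture_proportion(positive_scores,
                                             unlabeled_scores, ...))
}
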