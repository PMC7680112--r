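test_that("FPR thresholds satisfy their defining property", {
  pool <- seq(0.05, 0.95, by = 0.1)
  expect_equal(fpr_threshold(pool, 0.2), 0.85)  # 2/10 scores >= 0.85
  set.seed(71)
  for (rep in 1:10) {
    scores <- runif(50)
    fpr <- runif(1, 0.02, 0.5)
    t <- fpr_threshold(scores, fpr)
    expect_lte(mean(scores >= t), fpr)
  }
  expect_error(fpr_threshold(numeric(0), 0.05), "empty")
  expect_error(fpr_threshold(runif(5), 0), "\\(0, 1\\)")
})

test_that("near-1 FPR returns the smallest score satisfying the rate", {
  set.seed(72)
  scores <- runif(30)  # all distinct
  # at the minimum the >=-fraction is exactly 1 > 1 - eps, so the first
  # score that satisfies the defining property is the second smallest
  expect_equal(fpr_threshold(scores, 1 - 1e-9), sort(scores)[2])
  expect_lte(mean(scores >= fpr_threshold(scores, 1 - 1e-9)), 1 - 1e-9)
})

test_that("the enrichment statistic is signed and bounded", {
  expect_equal(enrichment_statistic(0.3, 0.1), 0.5)
  expect_equal(enrichment_statistic(0.2, 0.2), 0)
  expect_equal(enrichment_statistic(0, 0.2), -1)
  expect_equal(enrichment_statistic(0.2, 0), 1)
  expect_true(is.na(enrichment_statistic(0, 0)))
})

make_calls <- function(property, scores, var_pos = NULL, focal = NULL) {
  data.frame(property = property, property_score = scores,
             variant_position = if (is.null(var_pos)) seq_along(scores)
                                else var_pos,
             focal_position = if (is.null(focal)) seq_along(scores)
                              else focal,
             stringsAsFactors = FALSE)
}

test_that("a planted property is detected and a null is not", {
  props <- list(planted = property_definition("planted"),
                nullp = property_definition("nullp"))
  set.seed(73)
  n <- 2000
  disease <- rbind(
    make_calls("planted", ifelse(runif(n) < 0.30, runif(n, 0.8, 1),
                                 runif(n, 0, 0.3))),
    make_calls("nullp", runif(n, 0, 0.5)))
  neutral <- rbind(
    make_calls("planted", ifelse(runif(n) < 0.01, runif(n, 0.8, 1),
                                 runif(n, 0, 0.3))),
    make_calls("nullp", runif(n, 0, 0.5)))
  res <- property_enrichment(disease, neutral, props, fpr = 0.01)
  planted <- res[res$property == "planted", ]
  expect_identical(planted$direction, "enriched")
  expect_lt(planted$p_adjusted, 0.05)
  expect_gt(planted$E, 0.5)
})

test_that("identical groups produce no significant property across seeds", {
  props <- list(a = property_definition("a"), b = property_definition("b"))
  rejected <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    disease <- rbind(make_calls("a", runif(400)), make_calls("b", runif(400)))
    neutral <- rbind(make_calls("a", runif(400)), make_calls("b", runif(400)))
    res <- property_enrichment(disease, neutral, props, fpr = 0.05)
    rejected <- rejected + sum(res$p_adjusted < 0.05, na.rm = TRUE)
  }
  expect_lte(rejected / (5 * 2), 0.05)
})

test_that("the PTM split tests exact-site and neighborhood separately", {
  props <- list(ptm = property_definition("ptm", site_specific = TRUE))
  set.seed(74)
  n <- 400
  at_site <- rep(c(TRUE, FALSE), length.out = n)
  mk <- function(p_hit) {
    make_calls("ptm", ifelse(runif(n) < p_hit, runif(n, 0.9, 1),
                             runif(n, 0, 0.2)),
               var_pos = seq_len(n),
               focal = ifelse(at_site, seq_len(n), seq_len(n) + 3L))
  }
  res <- property_enrichment(mk(0.4), mk(0.02), props, fpr = 0.01,
                             ptm_split = TRUE)
  expect_setequal(res$property, c("ptm:site", "ptm:neighborhood"))
})

test_that("Fisher p-values match the hypergeometric tail oracle", {
  # one-sided (greater) for table [[30,70],[10,90]]
  p_pkg <- stats::fisher.test(matrix(c(30, 70, 10, 90), 2, byrow = TRUE),
                              alternative = "greater")$p.value
  oracle <- sum(dhyper(30:40, 40, 160, 100))
  expect_equal(p_pkg, oracle)
  # the same table drives property_enrichment's p-value
  props <- list(q = property_definition("q"))
  disease <- make_calls("q", c(rep(1, 30), rep(0, 70)))
  neutral <- make_calls("q", c(rep(1, 10), rep(0, 90)))
  res <- property_enrichment(disease, neutral, props, fpr = 0.11)
  expect_equal(res$p_raw, oracle)
})

test_that("top-3 enrichment uses the exact binomial tail", {
  mk_report <- function(id, ps, score, props, scores) {
    prediction_report(
      structure(list(protein_id = id, position = 1L, ref_aa = "A",
                     alt_aa = "V"), class = "substitution"),
      score,
      data.frame(property = props, direction = "loss",
                 property_score = scores,
                 empirical_p = seq_along(props) / 100,
                 stringsAsFactors = FALSE))
  }
  other <- sprintf("o%d", 1:4)
  with_p <- function() mk_report("x", 1, 0.9, c("target", other),
                                 c(0.9, 0.8, 0.7, 0.6, 0.5))
  without_p <- function() mk_report("x", 1, 0.9, other[1:4],
                                    c(0.8, 0.7, 0.6, 0.5))
  cases <- c(replicate(30, with_p(), simplify = FALSE),
             replicate(70, without_p(), simplify = FALSE))
  controls <- c(replicate(10, with_p(), simplify = FALSE),
                replicate(90, without_p(), simplify = FALSE))
  res <- top3_mechanism_enrichment(cases, controls, score_threshold = 0.5)
  row <- res[res$property == "target", ]
  expect_equal(row$case_fraction, 0.30)
  expect_equal(row$control_fraction, 0.10)
  expect_equal(row$p_raw, sum(dbinom(30:100, 100, 0.1)))
})

test_that("top-3 is one-sided and short reports count all mechanisms", {
  mk <- function(score, props, scores) {
    prediction_report(
      structure(list(protein_id = "x", position = 1L, ref_aa = "A",
                     alt_aa = "V"), class = "substitution"),
      score,
      data.frame(property = props, direction = "loss",
                 property_score = scores,
                 empirical_p = rep(0.5, length(props)),
                 stringsAsFactors = FALSE))
  }
  # case fraction (0.1) below control fraction (0.5): never significant
  cases <- c(replicate(5, mk(1, "p", 0.9), simplify = FALSE),
             replicate(45, mk(1, "q", 0.9), simplify = FALSE))
  controls <- c(replicate(25, mk(1, "p", 0.9), simplify = FALSE),
                replicate(25, mk(1, "q", 0.9), simplify = FALSE))
  res <- top3_mechanism_enrichment(cases, controls, 0.5)
  expect_gt(res$p_raw[res$property == "p"], 0.3)

  # a 2-mechanism report contributes both properties to the top 3
  two <- replicate(10, mk(1, c("a", "b"), c(0.9, 0.1)), simplify = FALSE)
  res2 <- top3_mechanism_enrichment(two, two, 0.5)
  expect_equal(res2$case_fraction, c(1, 1))

  expect_error(top3_mechanism_enrichment(cases, controls, 2), "threshold")
})

test_that("odds ratios match direct arithmetic and brute-force counting", {
  set.seed(75)
  case_scores <- c(rep(1, 100), rep(0, 2886))
  ctrl_scores <- c(rep(1, 20), rep(0, 824))
  o <- odds_ratio_analysis(case_scores, ctrl_scores, 0.5)
  expect_equal(o$odds_ratio, (100 * 824) / (2886 * 20))
  expect_equal(round(o$odds_ratio, 3), 1.428)

  equal <- odds_ratio_analysis(c(1, 1, 0, 0), c(1, 1, 0, 0), 0.5)
  expect_equal(equal$odds_ratio, 1)

  cs <- runif(300); ks <- runif(200)
  for (t in runif(50)) {
    o2 <- odds_ratio_analysis(cs, ks, t)
    a <- sum(cs >= t); b <- sum(cs < t); d <- sum(ks >= t); e <- sum(ks < t)
    if (a * b * d * e > 0) {
      expect_equal(o2$odds_ratio, (a * e) / (b * d))
    } else {
      expect_true(o2$continuity)
    }
  }
})

test_that("score binning is right-open, complete and accurate", {
  expect_equal(unname(bin_scores(rep(0.55, 10))[6]), 1)
  set.seed(76)
  s <- runif(100000)
  frac <- bin_scores(s)
  expect_equal(sum(frac), 1)
  expect_true(all(abs(frac - 0.1) < 0.005))
  expect_error(bin_scores(c(0.5, 1.5)), "\\[0, 1\\]")
  expect_error(bin_scores(s, c(0, 0.5)), "cover")
})

test_that("shared-gene removal leaves disjoint gene sets", {
  gene_of <- c(p1 = "G1", p2 = "G2", p3 = "G3")
  v <- function(ids) data.frame(protein_id = ids,
                                token = paste0("A", seq_along(ids), "V"),
                                stringsAsFactors = FALSE)
  out <- remove_shared_genes(v(c("p1", "p1", "p2")), v(c("p2", "p3")),
                             gene_of)
  expect_identical(out$case$protein_id, c("p1", "p1"))
  expect_identical(out$control$protein_id, "p3")

  disjoint <- remove_shared_genes(v("p1"), v("p2"), gene_of)
  expect_identical(nrow(disjoint$case), 1L)
  expect_identical(nrow(disjoint$control), 1L)

  expect_error(remove_shared_genes(v("p9"), v("p1"), gene_of),
               "missing gene mapping")

  set.seed(77)
  for (rep in 1:5) {
    genes <- stats::setNames(paste0("G", sample(1:5, 8, TRUE)),
                             paste0("p", 1:8))
    cs <- v(sample(names(genes), 6, TRUE))
    ks <- v(sample(names(genes), 6, TRUE))
    out <- remove_shared_genes(cs, ks, genes)
    expect_length(intersect(genes[out$case$protein_id],
                            genes[out$control$protein_id]), 0)
  }
})

test_that("BH adjustment matches reference enumeration and is monotone", {
  bh_oracle <- function(p) {
    m <- length(p)
    adj <- numeric(m)
    for (i in seq_len(m)) {
      # min over all thresholds k whose order statistic covers p_i
      r <- rank(p, ties.method = "max")[i]
      adj[i] <- min(vapply(r:m, function(k) {
        m * sort(p)[k] / k
      }, numeric(1)), 1)
    }
    adj
  }
  set.seed(78)
  for (rep in 1:10) {
    p <- runif(sample(3:12, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p))
    adj <- stats::p.adjust(p, "BH")
    expect_true(all(adj[order(p)] == cummax(adj[order(p)])))
    expect_true(all(adj <= 1 & adj >= p))
  }
})
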