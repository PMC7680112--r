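test_that("greedy clustering groups identical and splits unrelated sequences", {
  ps <- protein_set(c(a = "MKLVAEDGHIRSTPWY", b = "MKLVAEDGHIRSTPWY",
                      c = "CCCCCCCCNNNNNNNN"))
  cl <- cluster_sequences(ps)
  expect_identical(cl[["a"]], cl[["b"]])
  expect_false(cl[["a"]] == cl[["c"]])
})

test_that("clustering yields a partition on random proteomes", {
  for (seed in 1:3) {
    cfg <- fixture_config(n_proteins = 15L, length_mean = 80, seed = seed)
    ps <- generate_proteome(cfg)
    cl <- cluster_sequences(ps)
    expect_identical(sort(names(cl)), sort(names(ps)))
    expect_true(all(cl >= 1 & cl <= length(ps)))
    expect_false(anyNA(cl))
  }
})

test_that("fold plans deal units round-robin, deterministically", {
  plan <- make_folds(letters[1:10], k = 10, seed = 3)
  expect_identical(sort(unname(plan$assignment)), 1:10)
  plan2 <- make_folds(letters[1:10], k = 10, seed = 3)
  expect_identical(plan2$assignment, plan$assignment)
  expect_error(make_folds(letters[1:5], k = 10), "5 units for 10 folds")
  expect_error(make_folds(letters[1:5], k = 1), "k must be")
})

test_that("per-cluster plans never split a cluster across folds", {
  for (seed in 1:5) {
    cfg <- fixture_config(n_proteins = 20L, length_mean = 60,
                          n_pathogenic = 30L, n_unlabeled = 60L,
                          seed = seed)
    fx <- generate_fixture(cfg)
    cl <- cluster_sequences(fx$proteins)
    units <- cl[fx$variants$protein_id]
    plan <- make_folds(unique(units), k = 3, seed = seed,
                       unit_type = "cluster")
    fold_of_row <- plan$assignment[as.character(units)]
    per_cluster <- tapply(fold_of_row, units, function(f) length(unique(f)))
    expect_true(all(per_cluster == 1))
  }
})

test_that("roc_auc matches the all-pairs oracle exactly, ties included", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 200
    scores <- round(runif(n), 1)  # coarse grid forces ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    r <- roc_auc(scores, labels)
    pos <- scores[labels]; neg <- scores[!labels]
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(r$auc, mean(pairs))
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
  }
  expect_identical(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("the noise correction is anchored at its fixed points", {
  expect_equal(corrected_auc(0.8, 0, 0), 0.8)
  for (r in list(c(0.1, 0.2), c(0.028, 0.058), c(0.3, 0.3))) {
    expect_equal(corrected_auc(0.5, r[1], r[2]), 0.5)
  }
  expect_error(corrected_auc(0.9, 0.6, 0.5), "< 1")
})

test_that("injected label noise is inverted by the correction", {
  set.seed(32)
  n <- 50000
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  scores <- ifelse(labels, rnorm(n, 1), rnorm(n, 0))
  clean_auc <- roc_auc(scores, labels)$auc
  rho_pos <- 0.05; rho_neg <- 0.1
  noisy <- labels
  noisy[labels][runif(n / 2) < rho_pos] <- FALSE
  noisy[!labels][runif(n / 2) < rho_neg] <- TRUE
  # rho definitions are w.r.t. the observed label groups
  rp <- sum(!labels & noisy) / sum(noisy)
  rn <- sum(labels & !noisy) / sum(!noisy)
  observed <- roc_auc(scores, noisy)$auc
  recovered <- corrected_auc(observed, rp, rn)
  expect_lt(abs(recovered - clean_auc), 0.01)
})

test_that("fragment filtering removes redundant neighborhoods", {
  # shared 25-mer context in two otherwise different proteins
  core <- "ACDEFGHIKLMNPQRSTVWYACDEF"  # 25 residues, center at 13
  cand_p <- protein_set(c(x = paste0("MMMM", core, "MMMM")))
  ref_p <- protein_set(c(y = paste0("WWWW", core, "WWWW")))
  cand <- data.frame(protein_id = "x", position = 17L, ref_aa = "P",
                     alt_aa = "A", token = "P17A", label = "unlabeled",
                     stringsAsFactors = FALSE)
  ref <- data.frame(protein_id = "y", position = 17L, ref_aa = "P",
                    alt_aa = "A", token = "P17A", label = "unlabeled",
                    stringsAsFactors = FALSE)
  expect_identical(nrow(fragment_filter(cand, ref, cand_p, ref_p)), 0L)

  # 13/25 positions matching (52%): removed at 50%, kept at 80%
  alt13 <- paste0(substr(core, 1, 13), "GGGGGGGGGGGG")
  ref_p2 <- protein_set(c(y = paste0("WWWW", alt13, "WWWW")))
  expect_identical(nrow(fragment_filter(cand, ref, cand_p, ref_p2)), 0L)
  expect_identical(nrow(fragment_filter(cand, ref, cand_p, ref_p2,
                                        identity_threshold = 0.8)), 1L)

  # 12/25 (48%): retained at both thresholds
  alt12 <- paste0(substr(core, 1, 12), "GGGGGGGGGGGGG")
  ref_p3 <- protein_set(c(y = paste0("WWWW", alt12, "WWWW")))
  expect_identical(nrow(fragment_filter(cand, ref, cand_p, ref_p3)), 1L)
  expect_identical(nrow(fragment_filter(cand, ref, cand_p, ref_p3,
                                        identity_threshold = 0.8)), 1L)
})

test_that("raising the identity threshold removes fewer candidates", {
  for (seed in 1:3) {
    cfg <- fixture_config(n_proteins = 10L, length_mean = 60,
                          n_pathogenic = 20L, n_unlabeled = 20L,
                          seed = 100 + seed)
    fx <- generate_fixture(cfg)
    cand <- fx$variants[fx$variants$label == "unlabeled", ]
    ref <- fx$variants[fx$variants$label == "pathogenic", ]
    kept50 <- fragment_filter(cand, ref, fx$proteins, fx$proteins, 25L, 0.5)
    kept80 <- fragment_filter(cand, ref, fx$proteins, fx$proteins, 25L, 0.8)
    expect_true(all(kept50$token %in% kept80$token))
  }
})
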