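test_that("planted-motif predictor separates true sites from background", {
  fx <- phospho_fixture()
  # held-out truth: all S[TP] positions in the proteome vs random others
  truth_key <- paste(fx$sites$protein_id, fx$sites$position)
  set.seed(9)
  neg <- list()
  for (id in names(fx$proteins)) {
    L <- nchar(fx$proteins[[id]])
    pos <- sample.int(L, min(L, 10))
    keep <- !paste(id, pos) %in% truth_key
    neg[[id]] <- data.frame(protein_id = id, position = pos[keep])
  }
  neg <- do.call(rbind, neg)
  score_at <- function(sites) {
    unlist(lapply(split(sites, sites$protein_id), function(g) {
      property_raw_scores(fx$model, fx$proteins[[g$protein_id[1]]],
                          g$position)
    }), use.names = FALSE)
  }
  auc <- roc_auc(c(score_at(fx$sites), score_at(neg)),
                 c(rep(TRUE, nrow(fx$sites)), rep(FALSE, nrow(neg))))$auc
  expect_gt(auc, 0.95)
})

test_that("shuffled site labels give chance-level discrimination", {
  fx <- phospho_fixture()
  set.seed(13)
  pool <- rbind(fx$sites[, c("protein_id", "position")], fx$unlabeled)
  shuffled <- pool[sample.int(nrow(pool)), ]
  fake_pos <- shuffled[seq_len(nrow(fx$sites)), ]
  fake_unl <- shuffled[-seq_len(nrow(fx$sites)), ]
  m <- train_property_predictor(fake_pos, fake_unl, fx$proteins,
                                property_definition("shuffled"),
                                seed = 13L)
  score_at <- function(sites) {
    unlist(lapply(split(sites, sites$protein_id), function(g) {
      property_raw_scores(m, fx$proteins[[g$protein_id[1]]], g$position)
    }), use.names = FALSE)
  }
  truth_key <- paste(fx$sites$protein_id, fx$sites$position)
  lab <- paste(shuffled$protein_id, shuffled$position) %in% truth_key
  auc <- roc_auc(score_at(shuffled), lab)$auc
  expect_gt(auc, 0.35)
  expect_lt(auc, 0.65)
})

test_that("training is deterministic under the seed", {
  fx <- phospho_fixture()
  def <- default_property_rules()$phosphorylation$definition
  m2 <- train_property_predictor(fx$sites[, c("protein_id", "position")],
                                 fx$unlabeled, fx$proteins, def,
                                 seed = 101L)
  s <- fx$proteins[[1]]
  expect_identical(property_raw_scores(m2, s, 1:20),
                   property_raw_scores(fx$model, s, 1:20))
})

test_that("training preconditions are enforced by name", {
  fx <- phospho_fixture()
  few <- fx$sites[1:5, c("protein_id", "position")]
  expect_error(
    train_property_predictor(few, fx$unlabeled, fx$proteins,
                             property_definition("rare")),
    "rare.*20 positive")
  expect_error(
    train_property_predictor(fx$sites[, c("protein_id", "position")],
                             fx$sites[1:3, c("protein_id", "position")],
                             fx$proteins, property_definition("phos")),
    "unlabeled pool must exceed")
})

test_that("posterior calibration is anchored and monotone", {
  model <- list(calibration_constant = 0.4, prior_scale = 1)
  expect_equal(calibrate_posterior(0, model), 0)
  expect_equal(calibrate_posterior(0.4, model), 1)  # raw = c caps at 1
  expect_equal(calibrate_posterior(0.2, model), 0.5)
  r <- sort(runif(50))
  expect_true(all(diff(calibrate_posterior(r, model)) >= 0))
  expect_true(all(calibrate_posterior(r, model) <= 1))
  expect_error(calibrate_posterior(0.5, list(calibration_constant = 0)),
               "> 0")
})

test_that("mean posterior over the unlabeled pool approximates the prior", {
  fx <- phospho_fixture()
  post <- calibrate_posterior(
    unlist(lapply(split(fx$unlabeled, fx$unlabeled$protein_id), function(g) {
      property_raw_scores(fx$model, fx$proteins[[g$protein_id[1]]],
                          g$position)
    }), use.names = FALSE), fx$model)
  prior <- fx$model$definition$prior
  expect_lt(abs(mean(post) - prior) / prior, 0.1)
})

test_that("score_site clips at termini and is identity-consistent", {
  fx <- phospho_fixture()
  id <- names(fx$proteins)[1]
  ref <- substr(fx$proteins[[id]], 1, 1)
  alt <- setdiff(c("A", "G"), ref)[1]
  sub1 <- substitution(id, 1, ref, alt, fx$proteins)
  sp <- score_site(fx$model, fx$proteins, sub1)
  expect_identical(sp$positions, 1:6)  # clipped left
  expect_identical(sp$focal_index, 1L)
  expect_true(all(sp$wt_posteriors >= 0 & sp$wt_posteriors <= 1))

  # synonymous sanity (test-only object: the constructor forbids X -> X)
  fake <- structure(list(protein_id = id, position = 10L,
                         ref_aa = substr(fx$proteins[[id]], 10, 10),
                         alt_aa = substr(fx$proteins[[id]], 10, 10)),
                    class = "substitution")
  sp2 <- score_site(fx$model, fx$proteins, fake)
  expect_identical(sp2$wt_posteriors, sp2$mt_posteriors)
})

test_that("destroying a planted phosphosite lowers the focal posterior", {
  fx <- phospho_fixture()
  # pick planted S sites where an S -> A substitution removes the motif
  hits <- 0L; checked <- 0L
  for (i in seq_len(nrow(fx$sites))) {
    id <- fx$sites$protein_id[i]; pos <- fx$sites$position[i]
    if (substr(fx$proteins[[id]], pos, pos) != "S") next
    sub <- substitution(id, pos, "S", "A", fx$proteins)
    sp <- score_site(fx$model, fx$proteins, sub)
    checked <- checked + 1L
    if (sp$mt_posteriors[sp$focal_index] <
        sp$wt_posteriors[sp$focal_index]) hits <- hits + 1L
    if (checked >= 25) break
  }
  expect_gt(hits / checked, 0.9)
})

test_that("posteriors are local to the scorer's receptive field", {
  fx <- phospho_fixture()
  id <- names(fx$proteins)[2]
  s <- fx$proteins[[id]]
  pos <- 30L
  raw1 <- property_raw_scores(fx$model, s, pos)
  # mutate far outside the +/-5 window
  far <- paste0(substr(s, 1, 49), "W", substr(s, 51, nchar(s)))
  raw2 <- property_raw_scores(fx$model, far, pos)
  expect_identical(raw1, raw2)
})
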