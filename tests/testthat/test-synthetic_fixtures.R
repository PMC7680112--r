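test_that("proteome generation is deterministic and matches its targets", {
  cfg <- fixture_config(n_proteins = 1000L, length_mean = 300, seed = 81L)
  ps <- generate_proteome(cfg)
  ps2 <- generate_proteome(cfg)
  expect_identical(unclass(ps), unclass(ps2))
  expect_lt(abs(mean(nchar(ps)) - 300) / 300, 0.05)

  # residue composition tracks the configured background
  freq <- table(factor(strsplit(paste(ps, collapse = ""), "")[[1]],
                       levels = mutmech:::AA_ALPHABET))
  freq <- as.numeric(freq) / sum(freq)
  expect_lt(max(abs(freq - mutmech:::AA_BACKGROUND)), 0.01)
})

test_that("motif planting annotates all and only matching positions", {
  cfg <- fixture_config(n_proteins = 10L, length_mean = 100, seed = 82L)
  ps <- generate_proteome(cfg)
  rules <- default_property_rules()["phosphorylation"]
  sites <- plant_property_sites(ps, rules, seed = 82L)
  # oracle: exhaustive scan for S followed by T or P
  expected <- list()
  for (id in names(ps)) {
    chars <- strsplit(ps[[id]], "")[[1]]
    hits <- which(chars == "S" &
                    c(chars[-1], "") %in% c("T", "P"))
    if (length(hits)) {
      expected[[id]] <- data.frame(protein_id = id, position = hits)
    }
  }
  expected <- do.call(rbind, expected)
  got <- sites[order(sites$protein_id, sites$position), ]
  expect_identical(got$position, expected$position)
  expect_identical(got$protein_id, expected$protein_id)

  sites2 <- plant_property_sites(ps, rules, seed = 82L)
  expect_identical(sites2, sites)

  # a motif with no occurrences yields an empty annotation
  none <- plant_property_sites(
    protein_set(c(q = "AAAAAAA")),
    list(x = list(motif = "WWWW", site_offset = 1L,
                  definition = property_definition("x"))))
  expect_identical(nrow(none), 0L)

  dup <- c(rules, rules)
  expect_error(plant_property_sites(ps, dup, seed = 1L),
               "overlapping rules")
})

test_that("variant generation respects labels, truth and noise rates", {
  cfg0 <- fixture_config(n_proteins = 20L, length_mean = 80,
                         n_pathogenic = 50L, n_unlabeled = 100L, seed = 83L)
  fx <- generate_fixture(cfg0)
  expect_identical(
    fx$variants$true_label[fx$variants$label == "pathogenic"],
    rep("pathogenic", 50))
  expect_true(all(fx$variants$true_label[fx$variants$label == "unlabeled"]
                  == "benign"))
  # every variant is valid against its protein
  for (i in sample(nrow(fx$variants), 20)) {
    v <- fx$variants[i, ]
    expect_identical(substr(fx$proteins[[v$protein_id]], v$position,
                            v$position), v$ref_aa)
    expect_false(v$ref_aa == v$alt_aa)
  }

  cfgn <- fixture_config(n_proteins = 150L, length_mean = 150,
                         n_pathogenic = 500L, n_unlabeled = 10000L,
                         rho_pos = 0.028, rho_neg = 0.058, seed = 84L)
  psn <- generate_proteome(cfgn)
  sn <- plant_property_sites(psn, cfgn$property_rules, seed = cfgn$seed)
  vn <- generate_variants(psn, sn, cfgn)
  unl <- vn[vn$label == "unlabeled", ]
  expect_equal(sum(unl$true_label == "pathogenic"), 10000 * 0.058)
  pat <- vn[vn$label == "pathogenic", ]
  expect_equal(sum(pat$true_label == "benign"), round(500 * 0.028))
})

test_that("pathogenic variants carry the planted physicochemical signal", {
  fx <- bundle_fixture()
  delta <- function(v) {
    abs(mutmech:::AA_SCALES[mutmech:::aa_index(v$alt_aa), "hydropathy"] -
          mutmech:::AA_SCALES[mutmech:::aa_index(v$ref_aa), "hydropathy"])
  }
  d_path <- mean(delta(fx$variants[fx$variants$true_label == "pathogenic", ]))
  d_ben <- mean(delta(fx$variants[fx$variants$true_label == "benign", ]))
  expect_gt(d_path, d_ben)
})

test_that("beta-mixture samples match their stated moments and limits", {
  gm1 <- generate_mixture_scores(1, c(8, 2), c(2, 8), n = 4000L, seed = 85L)
  expect_gt(stats::ks.test(gm1$mixture, gm1$component)$p.value, 0.01)
  expect_true(all(gm1$is_component))

  gm0 <- generate_mixture_scores(0, c(8, 2), c(2, 8), n = 4000L, seed = 86L)
  expect_false(any(gm0$is_component))

  gm <- generate_mixture_scores(0.3, c(8, 2), c(2, 8), n = 50000L,
                                seed = 87L)
  target <- 0.3 * (8 / 10) + 0.7 * (2 / 10)
  expect_lt(abs(mean(gm$mixture) - target), 0.01)
  gm_b <- generate_mixture_scores(0.3, c(8, 2), c(2, 8), n = 50000L,
                                  seed = 87L)
  expect_identical(gm_b$mixture, gm$mixture)
})
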