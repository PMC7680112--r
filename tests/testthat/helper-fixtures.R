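# Shared fixture builders.  Everything is generated in code at test time;
# the small ones are cached per test file via local() closures.

tiny_proteins <- function() {
  protein_set(c(p1 = "MKLVAEDGHIRSTPWYQNCF",
                p2 = "AAAAASTPAAAAA",
                p3 = "MSTPGSRGSNKSHAD"))
}

# small trained property model on a planted phosphorylation-like motif
# ("S[TP]", site-specific); cached so several tests share one training run
phospho_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- fixture_config(n_proteins = 40L, length_mean = 150,
                          n_pathogenic = 50L, n_unlabeled = 100L,
                          seed = 101L)
    proteins <- generate_proteome(cfg)
    rules <- default_property_rules()["phosphorylation"]
    sites <- plant_property_sites(proteins, rules, seed = 101L)
    # unlabeled pool: random non-site positions
    set.seed(101L)
    lens <- nchar(proteins)
    all_pos <- data.frame(protein_id = rep(names(proteins), lens),
                          position = unlist(lapply(lens, seq_len)),
                          stringsAsFactors = FALSE)
    pool <- all_pos[!paste(all_pos$protein_id, all_pos$position) %in%
                      paste(sites$protein_id, sites$position), ]
    unl <- pool[sample.int(nrow(pool), 4 * nrow(sites)), ]
    model <- train_property_predictor(
      sites[, c("protein_id", "position")], unl, proteins,
      default_property_rules()$phosphorylation$definition, seed = 101L)
    cache <<- list(proteins = proteins, sites = sites, unlabeled = unl,
                   model = model)
    cache
  }
})

# moderately sized trained bundle shared across pipeline-level tests
bundle_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- fixture_config(n_proteins = 40L, length_mean = 150,
                          n_pathogenic = 120L, n_unlabeled = 240L,
                          seed = 202L)
    fx <- generate_fixture(cfg)
    bundle <- suppressWarnings(
      train_bundle(fx$proteins, fx$variants, fx$sites, seed = 202L,
                   n_members = 5L))
    cache <<- c(fx, list(bundle = bundle))
    cache
  }
})

# two-Gaussian-blob feature matrix with a clean linear separation
blob_data <- function(n_per_class = 100L, d = 5L, sep = 4, seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per_class * d), ncol = d),
             matrix(stats::rnorm(n_per_class * d, mean = sep), ncol = d))
  colnames(X) <- paste0("f", seq_len(d))
  list(X = X, labels = rep(c("pathogenic", "unlabeled"),
                           each = n_per_class))
}
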