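## High-level pipeline: train the per-property PU predictors (with
## data-driven class priors), assemble the six-category feature matrix,
## train the pathogenicity ensemble, and produce ranked prediction
## reports.  A trained state travels as a "model bundle".

BUNDLE_VERSION <- 1L

#' Train all property predictors for an annotated proteome
#'
#' One PU window classifier per property present in `sites`.  Unlabeled
#' training windows are sampled from non-annotated positions (a pool
#' `unlabeled_ratio` times the positive count).  Unless a prior is fixed
#' in the definition, the class prior is estimated from the model's raw
#' scores by mixture-proportion estimation on the unlabeled pool, and the
#' calibration is prior-matched to it.
#'
#' @param proteins A [protein_set()].
#' @param sites Site annotations (`protein_id`, `position`, `property`).
#' @param definitions Named list of [property_definition()]s (defaults to
#'   the fixture ontology definitions for the properties present).
#' @param seed Integer seed.
#' @param unlabeled_ratio Unlabeled windows per positive (default 4).
#' @param estimate_priors Estimate priors from the unlabeled pool
#'   (default `TRUE`).
#' @param ... Passed to [train_property_predictor()].
#' @return Named list of `property_model`s.
#' @export
train_property_models <- function(proteins, sites, definitions = NULL,
                                  seed = 1L, unlabeled_ratio = 4,
                                  estimate_priors = TRUE, ...) {
  props <- sort(unique(sites$property))
  if (is.null(definitions)) {
    rules <- default_property_rules()
    definitions <- lapply(rules, `[[`, "definition")
    names(definitions) <- vapply(definitions, `[[`, character(1), "name")
  }
  site_key <- paste(sites$protein_id, sites$position)
  lens <- nchar(proteins)
  all_pos <- data.frame(
    protein_id = rep(names(proteins), lens),
    position = unlist(lapply(lens, seq_len)),
    stringsAsFactors = FALSE)
  models <- list()
  for (i in seq_along(props)) {
    p <- props[i]
    def <- definitions[[p]]
    if (is.null(def)) def <- property_definition(p)
    pos_sites <- sites[sites$property == p, c("protein_id", "position")]
    if (nrow(pos_sites) < 20) {
      warning(sprintf("skipping property '%s': only %d positive site(s)",
                      p, nrow(pos_sites)), call. = FALSE)
      next
    }
    pool <- all_pos[!paste(all_pos$protein_id, all_pos$position) %in%
                      site_key, , drop = FALSE]
    set.seed(seed + i)
    n_unl <- min(nrow(pool), max(nrow(pos_sites) + 1L,
                                 round(unlabeled_ratio * nrow(pos_sites))))
    unl_sites <- pool[sample.int(nrow(pool), n_unl), , drop = FALSE]
    model <- train_property_predictor(pos_sites, unl_sites, proteins, def,
                                      seed = seed + i, ...)
    if (estimate_priors) {
      model <- reestimate_property_prior(model, proteins, unl_sites,
                                         pos_sites, seed = seed + i)
    }
    models[[p]] <- model
  }
  models
}

## Replace the definition prior by a mixture-proportion estimate of the
## property's prevalence in the unlabeled pool, and re-fit the
## prior-matching factor of the calibration accordingly.
reestimate_property_prior <- function(model, proteins, unlabeled_sites,
                                      positive_sites, seed = 1L) {
  raw_at <- function(sites) {
    unlist(lapply(split(sites, sites$protein_id), function(g) {
      property_raw_scores(model, proteins[[g$protein_id[1]]], g$position)
    }), use.names = FALSE)
  }
  raw_unl <- raw_at(unlabeled_sites)
  raw_pos <- raw_at(positive_sites)
  est <- try(estimate_mixture_proportion(raw_unl, raw_pos), silent = TRUE)
  if (inherits(est, "try-error")) return(model)
  prior <- min(0.95, max(0.005, est$alpha))
  model$definition$prior <- prior
  model$prior_scale <- solve_prior_scale(
    raw_unl / model$calibration_constant, prior)
  model
}

#' Train a full model bundle
#'
#' Property predictors, the category-6 feature block, the pathogenicity
#' ensemble, neutral score pools for empirical p-values, and the neutral
#' general-score distribution for FPR thresholds.
#'
#' @param proteins A [protein_set()].
#' @param variants Labeled variant table (`pathogenic` / `unlabeled`).
#' @param sites Property-site annotations.
#' @param seed Integer seed.
#' @param n_members Ensemble size (default 30).
#' @param config Optional [feature_config()]; its `property_names` are
#'   overwritten by the trained property names.
#' @param ... Passed to [train_ensemble()].
#' @return A `model_bundle`.
#' @export
train_bundle <- function(proteins, variants, sites, seed = 1L,
                         n_members = 30L, config = NULL, ...) {
  models <- train_property_models(proteins, sites, seed = seed)
  if (is.null(config)) {
    config <- feature_config(categories = c("sequence", "substitution",
                                            "property_change"))
  }
  config$property_names <- names(models)
  pc <- property_change_scores(models, proteins, variants)
  fm <- extract_feature_matrix(proteins, variants, config,
                               property_change_matrix = pc$features)
  ensemble <- train_ensemble(fm$matrix, variants$label,
                             n_members = n_members, seed = seed, ...)
  neutral <- variants[variants$label == "unlabeled", , drop = FALSE]
  neutral_idx <- which(variants$label == "unlabeled")
  pools <- lapply(split(pc$calls[pc$calls$variant_index %in% neutral_idx,
                                 "property_score"],
                        pc$calls$property[pc$calls$variant_index %in%
                                            neutral_idx]), sort)
  scores <- predict(ensemble, fm$matrix)
  structure(list(version = BUNDLE_VERSION, property_models = models,
                 feature_config = config, ensemble = ensemble,
                 neutral_pools = pools[names(models)],
                 neutral_general_scores = scores[neutral_idx],
                 seed = seed),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("model_bundle v%d: %d property models, ensemble of %d networks\n",
              x$version, length(x$property_models),
              x$ensemble$n_members))
  invisible(x)
}

#' Save / load a model bundle
#'
#' Serialized with R's native format; the bundle carries a version field
#' checked on load.
#' @param bundle A `model_bundle`.
#' @param path File path.
#' @export
save_model_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  bundle <- readRDS(path)
  if (!inherits(bundle, "model_bundle") ||
      !identical(bundle$version, BUNDLE_VERSION)) {
    stop("not a compatible model bundle: ", path, call. = FALSE)
  }
  bundle
}

#' Predict variants and rank their mechanisms
#'
#' @param bundle A `model_bundle`.
#' @param proteins A [protein_set()].
#' @param variants Variant table ([read_variants()] layout).
#' @param pssms,homolog_profiles Optional named lists by protein id (only
#'   used when the bundle's feature config enables those categories).
#' @return List of [prediction_report()]s, one per variant, mechanisms
#'   ordered by descending property score.
#' @export
predict_variants <- function(bundle, proteins, variants, pssms = NULL,
                             homolog_profiles = NULL) {
  pc <- property_change_scores(bundle$property_models, proteins, variants)
  fm <- extract_feature_matrix(proteins, variants, bundle$feature_config,
                               pssms = pssms,
                               homolog_profiles = homolog_profiles,
                               property_change_matrix = pc$features)
  general <- predict(bundle$ensemble, fm$matrix)
  lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    sub <- substitution(v$protein_id, v$position, v$ref_aa, v$alt_aa,
                        proteins)
    calls <- pc$calls[pc$calls$variant_index == i, , drop = FALSE]
    calls$empirical_p <- vapply(seq_len(nrow(calls)), function(j) {
      empirical_pvalue(calls$property_score[j],
                       bundle$neutral_pools[[calls$property[j]]])
    }, numeric(1))
    prediction_report(sub, general[i],
                      rank_mechanisms(calls[, c("property", "direction",
                                                "property_score",
                                                "empirical_p",
                                                "focal_position")]))
  })
}
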