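## Six-category feature representation for a (sequence, substitution) pair:
## (1) sequence context, (2) substitution deltas, (3) PSSM, (4) predicted
## conservation, (5) homolog count profile, (6) changes in predicted
## structural/functional properties.  The full published inventory of 1345
## features is not reproduced; a representative, fixed set per category is.
## Optional categories that are unavailable at extraction time are masked,
## never silently zeroed.

#' Feature extraction configuration
#'
#' @param categories Character vector of enabled categories, a subset of
#'   `c("sequence", "substitution", "pssm", "conservation", "homolog",
#'   "property_change")`.
#' @param window Odd window width for sequence-context and PSSM features.
#' @param property_names Property names expected in category 6 (order fixes
#'   the feature layout).
#' @return A `feature_config` list.
#' @export
feature_config <- function(categories = c("sequence", "substitution", "pssm",
                                          "conservation", "homolog",
                                          "property_change"),
                           window = 11L,
                           property_names = character()) {
  categories <- match.arg(categories, several.ok = TRUE)
  if (window %% 2L != 1L || window < 1L) {
    stop("window must be odd and >= 1", call. = FALSE)
  }
  structure(list(categories = categories, window = as.integer(window),
                 property_names = property_names),
            class = "feature_config")
}

#' Residue composition over a clipped window
#'
#' Frequencies of the 20 canonical residues over the window of odd width
#' `window` centered at `position`; the window is clipped at the termini
#' and ambiguity-code positions are dropped from the denominator.
#'
#' @param sequence Amino-acid sequence string.
#' @param position 1-based center position.
#' @param window Odd window width.
#' @return Named 20-vector of frequencies summing to 1.
#' @export
window_composition <- function(sequence, position, window = 11L) {
  if (window %% 2L != 1L || window < 1L) {
    stop("window must be odd and >= 1", call. = FALSE)
  }
  h <- (window - 1L) %/% 2L
  lo <- max(1L, position - h)
  hi <- min(nchar(sequence), position + h)
  chars <- strsplit(substr(sequence, lo, hi), "")[[1]]
  chars <- chars[chars != "X"]
  counts <- table(factor(chars, levels = AA_ALPHABET))
  stats::setNames(as.numeric(counts) / max(1L, length(chars)), AA_ALPHABET)
}

#' Substitution delta features
#'
#' Per physicochemical scale, `value(alt) - value(ref)`, plus a small
#' categorical transition encoding (class change, charge-sign change,
#' proline/glycine involvement).  Deltas are antisymmetric in ref/alt.
#'
#' @param ref_aa,alt_aa Canonical single-letter residues.
#' @param scales Character vector of scale names (columns of the shipped
#'   scale table).
#' @return Named numeric vector.
#' @export
substitution_delta_features <- function(ref_aa, alt_aa,
                                        scales = colnames(AA_SCALES)) {
  i <- aa_index(ref_aa); j <- aa_index(alt_aa)
  deltas <- AA_SCALES[j, scales] - AA_SCALES[i, scales]
  names(deltas) <- paste0("delta_", scales)
  trans <- c(
    class_changed = as.numeric(AA_CLASSES[i] != AA_CLASSES[j]),
    charge_sign_change = as.numeric(sign(AA_SCALES[i, "charge"]) !=
                                      sign(AA_SCALES[j, "charge"])),
    proline_involved = as.numeric(ref_aa == "P" || alt_aa == "P"),
    glycine_involved = as.numeric(ref_aa == "G" || alt_aa == "G")
  )
  if (ref_aa == alt_aa) trans[] <- 0  # identity substitution: no transition
  c(deltas, trans)
}

## ---- PSSM -----------------------------------------------------------------

#' Read a PSSM from whitespace-delimited text
#'
#' Format: a header line naming the 20-letter alphabet order, then one row
#' of 20 numeric scores per sequence position.
#'
#' @param path Input path.
#' @param protein_id Protein the matrix belongs to.
#' @return A `pssm` object (L x 20 matrix, columns in canonical order).
#' @export
read_pssm <- function(path, protein_id = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*($|#)", lines)]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 20 || anyNA(match(header, AA_ALPHABET))) {
    stop("PSSM header must name the 20-letter alphabet", call. = FALSE)
  }
  vals <- lapply(lines[-1], function(l) as.numeric(strsplit(trimws(l),
                                                            "\\s+")[[1]]))
  if (any(lengths(vals) != 20)) {
    stop("every PSSM row must have 20 scores", call. = FALSE)
  }
  m <- do.call(rbind, vals)
  colnames(m) <- header
  pssm(m[, AA_ALPHABET, drop = FALSE], protein_id)
}

#' Construct a PSSM object
#' @param matrix L x 20 numeric matrix, columns named by residue.
#' @param protein_id Owning protein id.
#' @return A `pssm` object.
#' @export
pssm <- function(matrix, protein_id = NA_character_) {
  if (ncol(matrix) != 20) stop("PSSM must have 20 columns", call. = FALSE)
  if (is.null(colnames(matrix))) colnames(matrix) <- AA_ALPHABET
  matrix <- matrix[, AA_ALPHABET, drop = FALSE]
  structure(list(protein_id = protein_id, matrix = matrix), class = "pssm")
}

#' Write a PSSM to text
#' @param x A `pssm` object.
#' @param path Output path.
#' @export
write_pssm <- function(x, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste(AA_ALPHABET, collapse = " "), con)
  utils::write.table(format(x$matrix, digits = 6), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

pssm_features <- function(psm, sub, window) {
  m <- psm$matrix
  if (nrow(m) < sub$position) {
    stop(sprintf("PSSM for %s has %d rows but position %d requested",
                 sub$protein_id, nrow(m), sub$position), call. = FALSE)
  }
  h <- (window - 1L) %/% 2L
  rows <- max(1L, sub$position - h):min(nrow(m), sub$position + h)
  focal <- m[sub$position, ]
  c(pssm_ref = unname(focal[sub$ref_aa]),
    pssm_alt = unname(focal[sub$alt_aa]),
    pssm_delta = unname(focal[sub$alt_aa] - focal[sub$ref_aa]),
    pssm_win_max = mean(apply(m[rows, , drop = FALSE], 1, max)),
    pssm_win_mean = mean(m[rows, ]),
    pssm_win_sd = stats::sd(as.numeric(m[rows, ])))
}

## ---- Predicted conservation ----------------------------------------------

## Frozen linear surrogate mapping windowed PSSM summaries to a predicted
## per-column entropy (high = variable, low = conserved).  Coefficients were
## fit once on synthetic alignment columns (scripts/fit_conservation_surrogate.R)
## and shipped as plain text so feature vectors are reproducible.
conservation_surrogate_coefs <- function() {
  path <- system.file("extdata", "conservation_surrogate_coefs.tsv",
                      package = "mutmech")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stats::setNames(tab$coef, tab$term)
}

pssm_window_summaries <- function(m, position, window) {
  h <- (window - 1L) %/% 2L
  rows <- max(1L, position - h):min(nrow(m), position + h)
  sub <- m[rows, , drop = FALSE]
  c(intercept = 1,
    row_max = mean(apply(sub, 1, max)),
    row_spread = mean(apply(sub, 1, function(r) max(r) - mean(r))),
    row_sd = mean(apply(sub, 1, stats::sd)),
    focal_max = max(m[position, ]))
}

#' Predicted-conservation features from a PSSM
#'
#' A frozen linear surrogate maps windowed PSSM summaries to a predicted
#' column entropy at the focal position and its window mean.  With a
#' flat (all-equal) PSSM the summaries are all zero and the surrogate
#' returns its baseline (the fitted intercept).
#'
#' @param psm A `pssm` object.
#' @param position Focal 1-based position.
#' @param window Odd window width.
#' @return Named numeric vector `c(cons_focal, cons_window)`.
#' @export
estimate_conservation_features <- function(psm, position, window = 11L) {
  cf <- conservation_surrogate_coefs()
  m <- psm$matrix
  pred1 <- sum(cf * pssm_window_summaries(m, position, 1L))
  predw <- sum(cf * pssm_window_summaries(m, position, window))
  c(cons_focal = pred1, cons_window = predw)
}

## ---- Homolog profiles -----------------------------------------------------

HOMOLOG_BINS <- c(50, 60, 70, 80, 90, 99)

#' Homolog count profile from pairwise identities
#'
#' Cumulative counts of homologous proteins at identity thresholds of at
#' least 50, 60, 70, 80, 90 and 99 percent.
#'
#' @param pairwise_identities Numeric vector of percent identities in
#'   \[0, 100\].
#' @return A `homolog_profile`: named integer vector of cumulative counts,
#'   non-increasing across increasing thresholds.
#' @export
homolog_count_features <- function(pairwise_identities) {
  if (any(pairwise_identities < 0 | pairwise_identities > 100)) {
    stop("percent identities must lie in [0, 100]", call. = FALSE)
  }
  counts <- vapply(HOMOLOG_BINS,
                   function(t) sum(pairwise_identities >= t), integer(1))
  structure(stats::setNames(counts, paste0("homologs_ge", HOMOLOG_BINS)),
            class = "homolog_profile")
}

## ---- Assembly -------------------------------------------------------------

feature_layout <- function(config) {
  layout <- list(
    sequence = c(paste0("comp_", AA_ALPHABET), "rel_position", "log_length",
                 "win_hydropathy", "win_charge"),
    substitution = c(paste0("delta_", colnames(AA_SCALES)), "class_changed",
                     "charge_sign_change", "proline_involved",
                     "glycine_involved"),
    pssm = c("pssm_ref", "pssm_alt", "pssm_delta", "pssm_win_max",
             "pssm_win_mean", "pssm_win_sd"),
    conservation = c("cons_focal", "cons_window"),
    homolog = paste0("homologs_ge", HOMOLOG_BINS),
    property_change = if (length(config$property_names) > 0) {
      as.vector(t(outer(config$property_names, c("wt", "mt", "loss", "gain"),
                        paste, sep = "_")))
    } else character()
  )
  names_all <- unlist(layout, use.names = FALSE)
  cats <- rep(names(layout), lengths(layout))
  list(names = names_all, category = cats)
}

#' Extract the feature vector for one substitution
#'
#' Pure function of its inputs: the same (sequence, substitution, config,
#' optional inputs) always yields the identical vector.  Categories that
#' are disabled in the config, or whose optional input (PSSM, homolog
#' profile, property scores) is absent, are flagged in `missing_mask` with
#' `NA` values rather than silently zeroed.
#'
#' @param proteins A [protein_set()].
#' @param sub A [substitution()].
#' @param config A [feature_config()].
#' @param pssm Optional `pssm` object for the protein.
#' @param homolog_profile Optional [homolog_count_features()] result.
#' @param property_changes Optional named numeric vector with entries
#'   `<property>_{wt,mt,loss,gain}` from the property/mechanism layer.
#' @return A `feature_vector`: list with `values`, `names`, `category`,
#'   `missing_mask` of equal length.
#' @export
extract_features <- function(proteins, sub, config = feature_config(),
                             pssm = NULL, homolog_profile = NULL,
                             property_changes = NULL) {
  lay <- feature_layout(config)
  values <- stats::setNames(rep(NA_real_, length(lay$names)), lay$names)
  s <- proteins[[sub$protein_id]]
  w <- config$window

  if ("sequence" %in% config$categories) {
    comp <- window_composition(s, sub$position, w)
    values[paste0("comp_", AA_ALPHABET)] <- comp
    values["rel_position"] <- sub$position / nchar(s)
    values["log_length"] <- log(nchar(s))
    values["win_hydropathy"] <- sum(comp * AA_SCALES[, "hydropathy"])
    values["win_charge"] <- sum(comp * AA_SCALES[, "charge"])
  }
  if ("substitution" %in% config$categories) {
    d <- substitution_delta_features(sub$ref_aa, sub$alt_aa)
    values[names(d)] <- d
  }
  if ("pssm" %in% config$categories && !is.null(pssm)) {
    if (nrow(pssm$matrix) != nchar(s)) {
      stop(sprintf("PSSM row count %d does not match sequence length %d for %s",
                   nrow(pssm$matrix), nchar(s), sub$protein_id),
           call. = FALSE)
    }
    values[names(pssm_features(pssm, sub, w))] <- pssm_features(pssm, sub, w)
  }
  if ("conservation" %in% config$categories && !is.null(pssm)) {
    cv <- estimate_conservation_features(pssm, sub$position, w)
    values[names(cv)] <- cv
  }
  if ("homolog" %in% config$categories && !is.null(homolog_profile)) {
    values[names(homolog_profile)] <- log1p(as.numeric(homolog_profile))
  }
  if ("property_change" %in% config$categories &&
      !is.null(property_changes)) {
    keep <- intersect(names(property_changes), lay$names)
    values[keep] <- property_changes[keep]
  }
  structure(list(values = unname(values), names = lay$names,
                 category = lay$category, missing_mask = is.na(values)),
            class = "feature_vector")
}

#' Extract a feature matrix for a variant table
#'
#' @param proteins A [protein_set()].
#' @param variants Variant data.frame ([read_variants()] layout).
#' @param config A [feature_config()].
#' @param pssms Optional named list of `pssm` objects keyed by protein id.
#' @param homolog_profiles Optional named list keyed by protein id.
#' @param property_change_matrix Optional numeric matrix (one row per
#'   variant) of category-6 scores with layout-compatible column names.
#' @return List with `matrix` (numeric, NA where masked), `category`
#'   (per-column tag) and `missing_mask`.
#' @export
extract_feature_matrix <- function(proteins, variants,
                                   config = feature_config(),
                                   pssms = NULL, homolog_profiles = NULL,
                                   property_change_matrix = NULL) {
  lay <- feature_layout(config)
  mat <- matrix(NA_real_, nrow(variants), length(lay$names),
                dimnames = list(NULL, lay$names))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    sub <- substitution(v$protein_id, v$position, v$ref_aa, v$alt_aa,
                        proteins)
    pc <- if (!is.null(property_change_matrix)) {
      property_change_matrix[i, ]
    } else NULL
    fv <- extract_features(proteins, sub, config,
                           pssm = pssms[[v$protein_id]],
                           homolog_profile = homolog_profiles[[v$protein_id]],
                           property_changes = pc)
    mat[i, ] <- fv$values
  }
  list(matrix = mat, category = lay$category, missing_mask = is.na(mat))
}
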