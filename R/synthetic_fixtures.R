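## Synthetic-fixture generators: everything needed to build and test the
## pipeline with no downloads.  Random proteomes with i.i.d. residues,
## motif-planted property sites, planted pathogenic/benign variants with
## controllable effect sizes and label noise, PSSM stand-ins derived from
## synthetic alignment columns, and beta-mixture score samples.  All
## generators are deterministic under their seed.

## Background residue composition for random proteomes: approximate
## vertebrate proteome frequencies (rounded), renormalized.
AA_BACKGROUND <- local({
  f <- c(A = 7.0, R = 5.6, N = 3.6, D = 4.7, C = 2.3, Q = 4.8, E = 7.1,
         G = 6.6, H = 2.6, I = 4.3, L = 10.0, K = 5.7, M = 2.2, F = 3.6,
         P = 6.3, S = 8.3, T = 5.3, W = 1.2, Y = 2.7, V = 6.0)
  f[AA_ALPHABET] / sum(f)
})

## Default property ontology for fixtures: eight properties covering
## structure, binding, catalysis and PTMs (site-specific), with one
## bidirectional binding property, standing in for a full ontology of
## dozens of real predictors.
#' Default fixture property rules
#'
#' Each rule: a regular-expression motif planted in the proteome, the
#' 1-based offset of the annotated site within a match, and the property
#' definition.
#' @return Named list of rules (`motif`, `site_offset`, `definition`).
#' @export
default_property_rules <- function() {
  rule <- function(motif, off, name, group, site_specific = FALSE,
                   bidirectional = FALSE) {
    list(motif = motif, site_offset = off,
         definition = property_definition(name, group, site_specific,
                                          bidirectional))
  }
  list(
    phosphorylation = rule("S[TP]", 1L, "phosphorylation", "ptm",
                           site_specific = TRUE),
    glycosylation = rule("N[ACDEFGHIKLMNQRSTVWY][ST]", 1L, "glycosylation",
                         "ptm", site_specific = TRUE),
    methylation = rule("R[GS]", 1L, "methylation", "ptm",
                       site_specific = TRUE),
    helix = rule("[ALE]{4}", 2L, "helix", "structure"),
    strand = rule("[VIF]{3}", 2L, "strand", "structure"),
    catalytic_site = rule("H[ACGILMV][DE]", 1L, "catalytic_site",
                          "function"),
    ppi_interface = rule("[WY][ACDEFGHIKLMNPQRSTVWY][WYF]", 2L,
                         "ppi_interface", "binding", bidirectional = TRUE),
    disorder = rule("[PES]{4}", 2L, "disorder", "structure")
  )
}

#' Fixture configuration
#'
#' Defaults define the stated world of the test fixtures: an 80-protein
#' proteome with gamma-distributed lengths around 200 residues, the
#' default 8-property ontology, 400 pathogenic and 800 unlabeled variants,
#' and no label noise unless asked for.
#'
#' @param n_proteins Number of proteins.
#' @param length_mean Mean sequence length (gamma-distributed, shape 6,
#'   minimum 30).
#' @param property_rules Named rule list (see [default_property_rules()]).
#' @param n_pathogenic,n_unlabeled Variant counts.
#' @param rho_pos Fraction of pathogenic-labeled variants that are truly
#'   benign.
#' @param rho_neg Fraction of unlabeled variants that are truly
#'   pathogenic.
#' @param seed Mandatory integer seed.
#' @return A `fixture_config`.
#' @export
fixture_config <- function(n_proteins = 80L, length_mean = 200,
                           property_rules = default_property_rules(),
                           n_pathogenic = 400L, n_unlabeled = 800L,
                           rho_pos = 0, rho_neg = 0, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(rho_pos >= 0, rho_pos <= 1, rho_neg >= 0, rho_neg <= 1)
  structure(list(n_proteins = n_proteins, length_mean = length_mean,
                 property_rules = property_rules,
                 n_pathogenic = n_pathogenic, n_unlabeled = n_unlabeled,
                 rho_pos = rho_pos, rho_neg = rho_neg,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

#' Generate a random proteome
#'
#' I.i.d. residues from the background composition; lengths gamma
#' distributed (shape 6) around `length_mean` with a floor of 30.
#'
#' @param config A [fixture_config()].
#' @return A [protein_set()].
#' @export
generate_proteome <- function(config) {
  set.seed(config$seed)
  lens <- pmax(30L, round(stats::rgamma(config$n_proteins, shape = 6,
                                        scale = config$length_mean / 6)))
  seqs <- vapply(lens, function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = AA_BACKGROUND),
          collapse = "")
  }, character(1))
  protein_set(stats::setNames(seqs, sprintf("prot%03d",
                                            seq_len(config$n_proteins))))
}

#' Plant property-site annotations by motif matching
#'
#' Every motif occurrence in the proteome is annotated with the rule's
#' property at `site_offset` within the match.  Two rules for the same
#' property are rejected.
#'
#' @param proteome A [protein_set()].
#' @param rules Named rule list (see [default_property_rules()]).
#' @param seed Seed for the optional subsampling.
#' @param max_sites_per_property Optional cap (subsampled per seed).
#' @return Data.frame: `protein_id`, `position`, `property`.
#' @export
plant_property_sites <- function(proteome, rules = default_property_rules(),
                                 seed = 1L, max_sites_per_property = Inf) {
  props <- vapply(rules, function(r) r$definition$name, character(1))
  if (anyDuplicated(props)) {
    stop("overlapping rules for property: ",
         paste(unique(props[duplicated(props)]), collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  rows <- list()
  for (r in rules) {
    for (id in names(proteome)) {
      m <- gregexpr(paste0("(?=", r$motif, ")"), proteome[[id]],
                    perl = TRUE)[[1]]
      if (m[1] == -1) next
      rows[[length(rows) + 1L]] <-
        data.frame(protein_id = id,
                   position = as.integer(m) + r$site_offset - 1L,
                   property = r$definition$name, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(protein_id = character(), position = integer(),
                      property = character(), stringsAsFactors = FALSE))
  }
  if (is.finite(max_sites_per_property)) {
    out <- do.call(rbind, lapply(split(out, out$property), function(g) {
      if (nrow(g) > max_sites_per_property) {
        g[sample.int(nrow(g), max_sites_per_property), , drop = FALSE]
      } else g
    }))
  }
  rownames(out) <- NULL
  out
}

## z-scored scale space; used to pick maximally disruptive and maximally
## conservative replacement residues.
aa_scale_z <- function() scale(AA_SCALES)

## residues ordered by distance from `ref` in z-scored scale space
aa_by_distance <- function(ref) {
  Z <- aa_scale_z()
  d <- sqrt(rowSums(sweep(Z, 2, Z[aa_index(ref), ])^2))
  AA_ALPHABET[order(d, decreasing = TRUE)]
}

## a disruptive substitution shifts >= min_scales scales by >= min_sd SD
is_disruptive <- function(ref, alt, min_scales = 3L, min_sd = 2) {
  Z <- aa_scale_z()
  sum(abs(Z[aa_index(alt), ] - Z[aa_index(ref), ]) >= min_sd) >= min_scales
}

disruptive_alt <- function(ref) aa_by_distance(ref)[1]

conservative_alt <- function(ref) {
  cand <- rev(aa_by_distance(ref))
  cand <- cand[cand != ref]
  cand[1]
}

#' Generate labeled variants with planted effects and label noise
#'
#' Pathogenic-type variants either destroy a planted property site
#' (substituting the site residue for the physicochemically most distant
#' residue) or apply a large physicochemical shift at a random position;
#' benign-type variants are conservative substitutions away from planted
#' sites.  A fraction `rho_neg` of the unlabeled pool is truly
#' pathogenic-type, and a fraction `rho_pos` of the pathogenic-labeled set
#' is truly benign-type; ground truth is kept in `true_label`.
#'
#' @param proteome A [protein_set()].
#' @param sites Planted-site annotations from [plant_property_sites()].
#' @param config A [fixture_config()] (counts and noise rates).
#' @return Variant data.frame with `label` (observed) and `true_label`.
#' @export
generate_variants <- function(proteome, sites, config) {
  set.seed(config$seed + 1L)
  site_key <- paste(sites$protein_id, sites$position)
  lens <- nchar(proteome)

  random_position <- function(avoid_sites) {
    repeat {
      id <- sample(names(proteome), 1L)
      pos <- sample.int(lens[[id]], 1L)
      ref <- substr(proteome[[id]], pos, pos)
      if (ref == "X") next
      if (avoid_sites && paste(id, pos) %in% site_key) next
      return(list(id = id, pos = pos, ref = ref))
    }
  }
  make_pathogenic <- function() {
    if (nrow(sites) > 0 && stats::runif(1) < 0.5) {
      i <- sample.int(nrow(sites), 1L)
      id <- sites$protein_id[i]; pos <- sites$position[i]
      ref <- substr(proteome[[id]], pos, pos)
      if (ref != "X") {
        return(data.frame(protein_id = id, position = pos, ref_aa = ref,
                          alt_aa = disruptive_alt(ref),
                          stringsAsFactors = FALSE))
      }
    }
    p <- random_position(avoid_sites = FALSE)
    data.frame(protein_id = p$id, position = p$pos, ref_aa = p$ref,
               alt_aa = disruptive_alt(p$ref), stringsAsFactors = FALSE)
  }
  make_benign <- function() {
    p <- random_position(avoid_sites = TRUE)
    data.frame(protein_id = p$id, position = p$pos, ref_aa = p$ref,
               alt_aa = conservative_alt(p$ref), stringsAsFactors = FALSE)
  }
  n_avail <- sum(lens)
  if (config$n_pathogenic + config$n_unlabeled > n_avail) {
    stop("requested more variants than available positions", call. = FALSE)
  }

  n_p <- config$n_pathogenic
  n_u <- config$n_unlabeled
  n_p_true <- round(n_p * (1 - config$rho_pos))
  n_u_path <- round(n_u * config$rho_neg)

  rows <- c(replicate(n_p_true, make_pathogenic(), simplify = FALSE),
            replicate(n_p - n_p_true, make_benign(), simplify = FALSE),
            replicate(n_u_path, make_pathogenic(), simplify = FALSE),
            replicate(n_u - n_u_path, make_benign(), simplify = FALSE))
  out <- do.call(rbind, rows)
  out$token <- paste0(out$ref_aa, out$position, out$alt_aa)
  out$label <- c(rep("pathogenic", n_p), rep("unlabeled", n_u))
  out$true_label <- c(rep("pathogenic", n_p_true),
                      rep("benign", n_p - n_p_true),
                      rep("pathogenic", n_u_path),
                      rep("benign", n_u - n_u_path))
  rownames(out) <- NULL
  out
}

#' Generate a PSSM stand-in from synthetic alignment columns
#'
#' Per position, a conservation weight `w ~ Beta(2, 2)` mixes a point mass
#' on the observed residue with a Dirichlet(1) background column; the PSSM
#' row is the log2 odds of the column probabilities against the uniform
#' background.  The true column entropy (nats) is returned for oracle
#' tests of the conservation surrogate.
#'
#' @param sequence Amino-acid sequence string.
#' @param seed Integer seed.
#' @param protein_id Id recorded on the PSSM.
#' @return List: `pssm` (a `pssm` object), `entropy` (per-position).
#' @export
generate_pssm <- function(sequence, seed = 1L, protein_id = NA_character_) {
  set.seed(seed)
  L <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  m <- matrix(0, L, 20, dimnames = list(NULL, AA_ALPHABET))
  entropy <- numeric(L)
  for (i in seq_len(L)) {
    w <- stats::rbeta(1, 2, 2)
    bg <- stats::rgamma(20, 1); bg <- bg / sum(bg)
    p <- (1 - w) * bg
    j <- match(chars[i], AA_ALPHABET)
    if (is.na(j)) j <- sample.int(20, 1)  # ambiguity code: random column
    p[j] <- p[j] + w
    entropy[i] <- -sum(p * log(p))
    m[i, ] <- log2(p / (1 / 20))
  }
  list(pssm = pssm(m, protein_id), entropy = entropy)
}

#' Generate homolog identity lists
#'
#' Poisson-many homologs per protein with identities uniform on
#' \[40, 100\]\%%.
#'
#' @param protein_ids Character vector of ids.
#' @param seed Integer seed.
#' @param mean_homologs Poisson mean (default 6).
#' @return Named list of percent-identity vectors.
#' @export
generate_homolog_identities <- function(protein_ids, seed = 1L,
                                        mean_homologs = 6) {
  set.seed(seed)
  out <- lapply(protein_ids, function(id) {
    stats::runif(stats::rpois(1, mean_homologs), 40, 100)
  })
  stats::setNames(out, protein_ids)
}

#' Generate beta-mixture score samples
#'
#' The mixture sample draws each observation from `Beta(shapes_component)`
#' with probability `alpha` and from `Beta(shapes_other)` otherwise; the
#' component sample is pure `Beta(shapes_component)`.
#'
#' @param alpha Mixture proportion in \[0, 1\].
#' @param shapes_component,shapes_other Length-2 positive shape pairs.
#' @param n Sample size for each sample.
#' @param seed Integer seed.
#' @return List: `mixture`, `component`, `is_component` (ground truth for
#'   the mixture draws).
#' @export
generate_mixture_scores <- function(alpha, shapes_component = c(8, 2),
                                    shapes_other = c(2, 8), n = 20000L,
                                    seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, all(shapes_component > 0),
            all(shapes_other > 0))
  set.seed(seed)
  from_comp <- stats::runif(n) < alpha
  mixture <- numeric(n)
  mixture[from_comp] <- stats::rbeta(sum(from_comp), shapes_component[1],
                                     shapes_component[2])
  mixture[!from_comp] <- stats::rbeta(sum(!from_comp), shapes_other[1],
                                      shapes_other[2])
  component <- stats::rbeta(n, shapes_component[1], shapes_component[2])
  list(mixture = mixture, component = component, is_component = from_comp)
}

#' Generate a complete fixture
#'
#' Proteome, planted sites and labeled variants in one call; the standard
#' entry point for end-to-end tests and the `simulate` subcommand.
#'
#' @param config A [fixture_config()].
#' @return List: `proteins`, `sites`, `variants`, `config`.
#' @export
generate_fixture <- function(config) {
  proteins <- generate_proteome(config)
  sites <- plant_property_sites(proteins, config$property_rules,
                                seed = config$seed)
  variants <- generate_variants(proteins, sites, config)
  list(proteins = proteins, sites = sites, variants = variants,
       config = config)
}
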