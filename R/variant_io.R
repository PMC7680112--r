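## Core domain types and file I/O.
##
## Proteins are held as a named character vector (id -> sequence) of class
## "protein_set"; substitutions as class "substitution" records; prediction
## reports as a list of per-variant entries serialized to a fixed-column TSV.

VALID_RESIDUES <- paste0(paste(AA_ALPHABET, collapse = ""), "X")

#' Construct a protein set
#'
#' @param sequences Named character vector of amino-acid sequences (ids as
#'   names).  Sequences are uppercased; the 20 canonical residues plus the
#'   ambiguity code `X` are permitted.
#' @return A `protein_set` (named character vector).
#' @export
protein_set <- function(sequences) {
  if (length(sequences) == 0) stop("empty protein set", call. = FALSE)
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every sequence must be named by a protein id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate protein id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  sequences <- toupper(sequences)
  if (any(!nzchar(sequences))) {
    stop("empty sequence for id(s): ",
         paste(ids[!nzchar(sequences)], collapse = ", "), call. = FALSE)
  }
  bad <- grepl(sprintf("[^%s]", VALID_RESIDUES), sequences)
  if (any(bad)) {
    stop("illegal residue character in sequence(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  structure(sequences, class = "protein_set")
}

#' @export
print.protein_set <- function(x, ...) {
  cat(sprintf("protein_set with %d sequence(s), lengths %d-%d\n",
              length(x), min(nchar(x)), max(nchar(x))))
  invisible(x)
}

#' Read a FASTA file of protein sequences
#'
#' One record per header line; sequence lines are folded and uppercased.
#' Malformed headers, illegal residue characters and duplicate ids are
#' rejected with the offending line number in the error message.
#'
#' @param path Path to a FASTA file (UTF-8, uncompressed).
#' @return A [protein_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*$", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) {
    stop(sprintf("%s: line %d: expected FASTA header ('>')", path, lineno[1]),
         call. = FALSE)
  }
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[is_header])
  if (any(ids == ">") || any(!nzchar(sub("^>", "", lines[is_header])))) {
    bad <- lineno[is_header][!nzchar(sub(">\\s*", "", lines[is_header]))][1]
    stop(sprintf("%s: line %d: malformed (empty) FASTA header", path, bad),
         call. = FALSE)
  }
  seq_lines <- toupper(lines)
  bad_char <- !is_header &
    grepl(sprintf("[^%s]", VALID_RESIDUES), seq_lines)
  if (any(bad_char)) {
    stop(sprintf("%s: line %d: illegal residue character", path,
                 lineno[bad_char][1]), call. = FALSE)
  }
  rec <- cumsum(is_header)
  seqs <- vapply(split(seq_lines[!is_header], rec[!is_header]),
                 paste, character(1), collapse = "")
  present <- as.character(seq_len(sum(is_header)))
  out <- stats::setNames(rep("", length(ids)), ids)
  out[as.integer(names(seqs))] <- seqs
  if (any(!nzchar(out))) {
    bad <- lineno[is_header][!nzchar(out)][1]
    stop(sprintf("%s: line %d: header with no sequence", path, bad),
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("%s: duplicate protein id '%s'", path,
                 ids[duplicated(ids)][1]), call. = FALSE)
  }
  protein_set(out)
}

#' Write a protein set to FASTA
#'
#' @param proteins A [protein_set()].
#' @param path Output path.
#' @param width Line-fold width (default 60).
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (id in names(proteins)) {
    writeLines(paste0(">", id), con)
    s <- proteins[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a validated substitution
#'
#' A protein-level amino-acid change at a 1-based position.  The reference
#' residue must match the sequence, must differ from the alternate, and may
#' not be the ambiguity code `X`.
#'
#' @param protein_id Protein identifier (present in `proteins`).
#' @param position 1-based residue position.
#' @param ref_aa,alt_aa Single-letter reference / alternate residues.
#' @param proteins A [protein_set()] used for validation.
#' @return A `substitution` object.
#' @export
substitution <- function(protein_id, position, ref_aa, alt_aa, proteins) {
  if (!protein_id %in% names(proteins)) {
    stop("unknown protein id: ", protein_id, call. = FALSE)
  }
  seqc <- proteins[[protein_id]]
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > nchar(seqc)) {
    stop(sprintf("position %s out of range 1..%d for protein %s",
                 position, nchar(seqc), protein_id), call. = FALSE)
  }
  have <- substr(seqc, position, position)
  if (have == "X") {
    stop(sprintf("position %d of %s is the ambiguity code X; variants at X positions are not scorable",
                 position, protein_id), call. = FALSE)
  }
  if (have != ref_aa) {
    stop(sprintf("reference mismatch for %s position %d: expected %s, token says %s",
                 protein_id, position, have, ref_aa), call. = FALSE)
  }
  if (ref_aa == alt_aa) {
    stop(sprintf("%s%d%s: reference equals alternate", ref_aa, position, alt_aa),
         call. = FALSE)
  }
  if (!alt_aa %in% AA_ALPHABET || !ref_aa %in% AA_ALPHABET) {
    stop("residues must be canonical single-letter codes", call. = FALSE)
  }
  structure(list(protein_id = protein_id, position = position,
                 ref_aa = ref_aa, alt_aa = alt_aa),
            class = "substitution")
}

#' Parse a substitution token like "R551C"
#'
#' @param token Token of the form `<ref><position><alt>`, e.g. `"R551C"`.
#' @param protein_id Protein the token refers to.
#' @param proteins A [protein_set()].
#' @return A validated [substitution()].
#' @export
parse_substitution <- function(token, protein_id, proteins) {
  m <- regmatches(token, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", token))[[1]]
  if (length(m) != 4) {
    stop("malformed substitution token: ", token,
         " (expected e.g. R551C)", call. = FALSE)
  }
  substitution(protein_id, as.integer(m[3]), toupper(m[2]), toupper(m[4]),
               proteins)
}

#' Format a substitution as its token
#' @param sub A [substitution()].
#' @return Token string, e.g. `"R551C"`.
#' @export
format_substitution <- function(sub) {
  paste0(sub$ref_aa, sub$position, sub$alt_aa)
}

#' @export
print.substitution <- function(x, ...) {
  cat(sprintf("%s %s\n", x$protein_id, format_substitution(x)))
  invisible(x)
}

#' Apply a substitution to its sequence
#' @param sub A [substitution()].
#' @param proteins A [protein_set()].
#' @return The full mutated sequence as a character scalar.
#' @export
mutate_sequence <- function(sub, proteins) {
  s <- proteins[[sub$protein_id]]
  paste0(substr(s, 1L, sub$position - 1L), sub$alt_aa,
         substr(s, sub$position + 1L, nchar(s)))
}

VARIANT_LABELS <- c("pathogenic", "unlabeled", "benign")

#' Read a variant table
#'
#' Whitespace- or tab-separated lines: `protein_id substitution_token
#' [label]`.  Labels are from `pathogenic`, `unlabeled`, `benign`; absent
#' labels default to `unlabeled`.  Every substitution is validated against
#' the supplied proteins.
#'
#' @param path Path to the table.
#' @param proteins A [protein_set()].
#' @return A data.frame with columns `protein_id`, `position`, `ref_aa`,
#'   `alt_aa`, `token`, `label`.
#' @export
read_variants <- function(path, proteins) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*($|#)", lines)]
  if (length(lines) == 0) stop("no variants in ", path, call. = FALSE)
  parts <- strsplit(trimws(lines), "[ \t]+")
  rows <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < 2) {
      stop(sprintf("%s: malformed variant line: '%s'", path, lines[i]),
           call. = FALSE)
    }
    label <- if (length(p) >= 3) p[3] else "unlabeled"
    if (!label %in% VARIANT_LABELS) {
      stop(sprintf("%s: unknown label '%s' (expected %s)", path, label,
                   paste(VARIANT_LABELS, collapse = "/")), call. = FALSE)
    }
    s <- parse_substitution(p[2], p[1], proteins)
    data.frame(protein_id = s$protein_id, position = s$position,
               ref_aa = s$ref_aa, alt_aa = s$alt_aa,
               token = format_substitution(s), label = label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a variant table
#' @param variants Data.frame as returned by [read_variants()].
#' @param path Output path.
#' @export
write_variants <- function(variants, path) {
  writeLines(paste(variants$protein_id, variants$token, variants$label),
             file(path, encoding = "UTF-8"))
  invisible(path)
}

#' Assemble a prediction report entry
#'
#' @param sub A [substitution()].
#' @param general_score Pathogenicity score in \[0,1\].
#' @param mechanisms A data.frame of mechanism calls (may have zero rows)
#'   as produced by [rank_mechanisms()].
#' @return A `prediction_report` object.
#' @export
prediction_report <- function(sub, general_score, mechanisms = NULL) {
  stopifnot(general_score >= 0, general_score <= 1)
  if (is.null(mechanisms)) {
    mechanisms <- data.frame(property = character(), direction = character(),
                             property_score = numeric(),
                             empirical_p = numeric(),
                             stringsAsFactors = FALSE)
  }
  structure(list(substitution = sub, general_score = general_score,
                 mechanisms = mechanisms),
            class = "prediction_report")
}

REPORT_COLUMNS <- c("protein", "substitution", "general_score", "property",
                    "direction", "property_score", "empirical_p")

#' Write prediction reports to TSV
#'
#' One summary row per variant (property columns `.`) followed by one row
#' per ranked mechanism.  The header line is prefixed with `#` and the
#' column order is fixed so that test diffs are bit-exact.  Scores are
#' printed with six decimals.
#'
#' @param reports List of [prediction_report()] objects (non-empty).
#' @param path Output path.
#' @export
write_report <- function(reports, path) {
  if (length(reports) == 0) stop("no reports to write", call. = FALSE)
  con <- try(file(path, open = "wt", encoding = "UTF-8"), silent = TRUE)
  if (inherits(con, "try-error")) {
    stop("cannot open for writing: ", path, call. = FALSE)
  }
  on.exit(close(con))
  writeLines(paste0("#", paste(REPORT_COLUMNS, collapse = "\t")), con)
  fmt <- function(x) sprintf("%.6f", x)
  for (r in reports) {
    s <- r$substitution
    writeLines(paste(s$protein_id, format_substitution(s),
                     fmt(r$general_score), ".", ".", ".", ".", sep = "\t"),
               con)
    if (nrow(r$mechanisms) > 0) {
      writeLines(paste(s$protein_id, format_substitution(s),
                       fmt(r$general_score), r$mechanisms$property,
                       r$mechanisms$direction, fmt(r$mechanisms$property_score),
                       fmt(r$mechanisms$empirical_p), sep = "\t"),
                 con)
    }
  }
  invisible(path)
}

#' Read a prediction report TSV back into report objects
#'
#' @param path Path written by [write_report()].
#' @param proteins A [protein_set()] for substitution validation.
#' @return List of `prediction_report` objects.
#' @export
read_report <- function(path, proteins) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  header <- sub("^#", "", lines[1])
  if (!identical(strsplit(header, "\t")[[1]], REPORT_COLUMNS)) {
    stop("unrecognized report header in ", path, call. = FALSE)
  }
  body <- lines[-1]
  f <- strsplit(body, "\t", fixed = TRUE)
  key <- vapply(f, function(p) paste(p[1], p[2]), character(1))
  out <- list()
  for (k in unique(key)) {
    rows <- f[key == k]
    summ <- rows[[which(vapply(rows, function(p) p[4] == ".", logical(1)))[1]]]
    sub <- parse_substitution(summ[2], summ[1], proteins)
    mech_rows <- Filter(function(p) p[4] != ".", rows)
    mech <- if (length(mech_rows) > 0) {
      data.frame(property = vapply(mech_rows, `[`, character(1), 4),
                 direction = vapply(mech_rows, `[`, character(1), 5),
                 property_score = as.numeric(vapply(mech_rows, `[`,
                                                    character(1), 6)),
                 empirical_p = as.numeric(vapply(mech_rows, `[`,
                                                 character(1), 7)),
                 stringsAsFactors = FALSE)
    } else NULL
    out[[length(out) + 1L]] <-
      prediction_report(sub, as.numeric(summ[3]), mech)
  }
  out
}
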