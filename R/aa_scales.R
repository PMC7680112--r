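#' @keywords internal
"_PACKAGE"

## Canonical amino-acid alphabet, fixed ordering used for all 20-vectors
## (compositions, PSSM columns).  "X" is accepted in sequences as an
## ambiguity code but is never a member of this alphabet.
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

aa_index <- function(aa) {
  i <- match(aa, AA_ALPHABET)
  if (anyNA(i)) {
    stop("unknown residue(s): ", paste(unique(aa[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  i
}

## Physicochemical scales.  Values are the field-standard published scales:
## Kyte-Doolittle hydropathy, Zamyatnin residue volume (A^3), Grantham
## polarity, net side-chain charge at pH 7, and monoisotopic residue mass
## (Da).  The set is frozen: feature vectors must be reproducible across
## runs and package versions.
AA_SCALES <- local({
  hydropathy <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
                  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
                  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
                  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
  volume <- c(A =  88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
              Q = 143.8, E = 138.4, G =  60.1, H = 153.2, I = 166.7,
              L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
              S =  89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)
  polarity <- c(A =  8.1, R = 10.5, N = 11.6, D = 13.0, C =  5.5,
                Q = 10.5, E = 12.3, G =  9.0, H = 10.4, I =  5.2,
                L =  4.9, K = 11.3, M =  5.7, F =  5.2, P =  8.0,
                S =  9.2, T =  8.6, W =  5.4, Y =  6.2, V =  5.9)
  charge <- c(A = 0, R = 1, N = 0, D = -1, C = 0,
              Q = 0, E = -1, G = 0, H = 0.1, I = 0,
              L = 0, K = 1, M = 0, F = 0, P = 0,
              S = 0, T = 0, W = 0, Y = 0, V = 0)
  mass <- c(A =  71.037, R = 156.101, N = 114.043, D = 115.027,
            C = 103.009, Q = 128.059, E = 129.043, G =  57.021,
            H = 137.059, I = 113.084, L = 113.084, K = 128.095,
            M = 131.040, F = 147.068, P =  97.053, S =  87.032,
            T = 101.048, W = 186.079, Y = 163.063, V =  99.068)
  m <- cbind(hydropathy = hydropathy[AA_ALPHABET],
             volume     = volume[AA_ALPHABET],
             polarity   = polarity[AA_ALPHABET],
             charge     = charge[AA_ALPHABET],
             mass       = mass[AA_ALPHABET])
  rownames(m) <- AA_ALPHABET
  m
})

## Coarse physicochemical classes used for the categorical transition
## encoding of a substitution.
AA_CLASSES <- local({
  cls <- c(A = "hydrophobic", R = "positive", N = "polar", D = "negative",
           C = "polar", Q = "polar", E = "negative", G = "special",
           H = "positive", I = "hydrophobic", L = "hydrophobic",
           K = "positive", M = "hydrophobic", F = "aromatic",
           P = "special", S = "polar", T = "polar", W = "aromatic",
           Y = "aromatic", V = "hydrophobic")
  cls[AA_ALPHABET]
})

#' Amino-acid scale lookup
#'
#' Returns the value of a named physicochemical scale for one residue.
#' Available scales: `hydropathy` (Kyte-Doolittle), `volume`, `polarity`,
#' `charge`, `mass`.
#'
#' @param aa Single-letter residue code (one of the 20 canonical codes).
#' @param scale Scale name.
#' @return Numeric scalar.
#' @export
aa_scale_value <- function(aa, scale) {
  scale <- match.arg(scale, colnames(AA_SCALES))
  AA_SCALES[aa_index(aa), scale]
}

## Uniform residue background (used by synthetic generators and PSSM
## log-odds when no background is supplied).
AA_UNIFORM_BG <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
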