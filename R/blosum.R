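#' Amino-acid alphabet and BLOSUM62 access
#'
#' The 20 canonical amino acids, in the row order of the BLOSUM62 matrix.
#' @export
AMINO_ACIDS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Ambiguity / non-standard codes treated as gap-equivalent in scoring.
GAP_EQUIVALENT <- c("X", "B", "Z", "J", "U", "O", "*")

.blosum_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix (20 x 20 canonical block)
#'
#' Returns the canonical 20-amino-acid block of the BLOSUM62 matrix shipped
#' with Biostrings.
#'
#' @return Integer matrix with dimnames `AMINO_ACIDS`.
#' @export
blosum62 <- function() {
  if (is.null(.blosum_env$B)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_env$B <- e$BLOSUM62[AMINO_ACIDS, AMINO_ACIDS]
  }
  .blosum_env$B
}

#' BLOSUM62 background amino-acid frequencies
#'
#' The background residue frequencies associated with the BLOSUM62 matrix
#' (the marginal frequencies used in its construction), normalised to sum to
#' one. Used to draw random residues for the Monte-Carlo null band and to
#' seed root sequences in the simulator.
#'
#' @return Named numeric vector over `AMINO_ACIDS`, summing to 1.
#' @export
blosum62_background <- function() {
  p <- c(A = 0.07422, R = 0.05161, N = 0.04465, D = 0.05363, C = 0.02469,
         Q = 0.03426, E = 0.05431, G = 0.07415, H = 0.02621, I = 0.06792,
         L = 0.09891, K = 0.05816, M = 0.02499, F = 0.04742, P = 0.03854,
         S = 0.05723, T = 0.05089, W = 0.01303, Y = 0.03228, V = 0.07292)
  p / sum(p)
}

# Normalise scoring symbols: canonical residues kept, ambiguity codes mapped
# to '-', anything else is an error.
normalize_symbols <- function(chars) {
  chars <- toupper(chars)
  chars[chars %in% GAP_EQUIVALENT] <- "-"
  bad <- setdiff(unique(chars), c(AMINO_ACIDS, "-"))
  if (length(bad) > 0) {
    stop("symbol(s) outside the amino-acid alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  chars
}

#' Score one residue pair under BLOSUM62 with a flat gap penalty
#'
#' Two residues score their BLOSUM62 entry; a residue against a gap scores
#' `-gap_penalty`; a gap against a gap carries no signal and returns `NA`
#' (callers exclude such pairs from column means). Ambiguity codes (`X` etc.)
#' are treated as gaps.
#'
#' @param a,b Character vectors of single symbols (residue or `-`); recycled.
#' @param gap_penalty Positive penalty applied when exactly one symbol is a
#'   gap (default 3).
#' @return Numeric vector of pair scores, `NA` for gap-gap pairs.
#' @export
#' @examples
#' pair_score("A", "A")   # 4
#' pair_score("A", "-")   # -3
pair_score <- function(a, b, gap_penalty = 3) {
  a <- normalize_symbols(a)
  b <- normalize_symbols(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- rep(NA_real_, n)
  both <- a != "-" & b != "-"
  one <- xor(a == "-", b == "-")
  B <- blosum62()
  if (any(both)) out[both] <- B[cbind(a[both], b[both])]
  out[one] <- -gap_penalty
  out
}
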