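#' Test sequences for the PTS1 tripeptide
#'
#' A protein carries the peroxisomal targeting signal 1 when its C-terminal
#' tripeptide matches `[SAC][KRH]L`. A single trailing stop (`*`) is
#' stripped before testing; non-standard characters in the final three
#' positions never match.
#'
#' @param sequences Character vector of amino-acid sequences.
#' @param warn Warn on empty sequences (default `TRUE`).
#' @return Logical vector.
#' @export
has_pts1 <- function(sequences, warn = TRUE) {
  if (warn && any(!nzchar(sequences))) {
    warning("empty sequence(s) scored as no PTS1")
  }
  s <- sub("\\*$", "", toupper(sequences))
  grepl("[SAC][KRH]L$", s)
}

#' Scan a proteome for PTS1
#'
#' @param proteome Tibble with columns `id`, `sequence`.
#' @return The input with `tripeptide` and `matched` columns.
#' @export
pts1_scan <- function(proteome) {
  s <- sub("\\*$", "", toupper(proteome$sequence))
  proteome$tripeptide <- ifelse(nchar(s) >= 3,
                                substr(s, nchar(s) - 2, nchar(s)), NA)
  proteome$matched <- has_pts1(proteome$sequence, warn = FALSE)
  proteome
}

#' Proteome-level PTS1 prevalence
#'
#' Proteins shorter than three residues count in the denominator but can
#' never match.
#'
#' @param proteome Tibble with columns `id`, `sequence`.
#' @return One-row tibble (`n_proteins`, `n_matched`, `percent`).
#' @export
pts1_percentage <- function(proteome) {
  if (nrow(proteome) == 0) stop("empty proteome", call. = FALSE)
  matched <- has_pts1(proteome$sequence, warn = FALSE)
  tibble::tibble(n_proteins = nrow(proteome), n_matched = sum(matched),
                 percent = 100 * mean(matched))
}

#' Ratio of mean PTS1 percentages between two taxon groups
#'
#' @param results Tibble with columns `species`, `percent` (one row per
#'   proteome).
#' @param groups Taxon-group tibble.
#' @param group_a,group_b Group labels; the ratio is `mean(a) / mean(b)`.
#' @return Numeric ratio (`NA` with a warning when group_b's mean is 0).
#' @export
pts1_group_ratio <- function(results, groups, group_a, group_b) {
  pick <- function(g) {
    sp <- group_species(groups, g)
    v <- results$percent[results$species %in% sp]
    if (length(v) == 0) stop("no proteomes in group ", g, call. = FALSE)
    mean(v)
  }
  a <- pick(group_a)
  b <- pick(group_b)
  if (b == 0) {
    warning("group ", group_b, " has mean PTS1 percentage 0; ratio undefined")
    return(NA_real_)
  }
  a / b
}
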