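#' Read a homology hit table
#'
#' Supports the 12-column BLAST tabular format (`outfmt6`: query, subject,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore) and a minimal whitespace-separated 4-column dialect (query,
#' subject, evalue, bitscore). Subject species are derived from subject ids
#' by `id_to_species`. Rows whose e-value exceeds `ceiling` are dropped and
#' counted; the kept + dropped counts always sum to the input row count
#' (attribute `n_dropped`).
#'
#' @param path Path to the hit table.
#' @param dialect `"outfmt6"` or `"minimal"`.
#' @param ceiling Maximal e-value counted as a hit. The BLASTP searches in
#'   this workflow use 1e-3, the hmmscan searches 1e-5; the default matches a
#'   BLAST-derived table.
#' @param id_to_species Function mapping subject ids to species labels.
#' @return A tibble with columns `query_id`, `subject_id`, `subject_species`,
#'   `evalue`, `bitscore`, with attribute `n_dropped`.
#' @export
read_hit_table <- function(path, dialect = c("minimal", "outfmt6"),
                           ceiling = 1e-3, id_to_species = species_from_id) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- tibble::tibble(query_id = character(), subject_id = character(),
                          subject_species = character(), evalue = double(),
                          bitscore = double())
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  split_by <- if (dialect == "outfmt6") "\t" else "[ \t]+"
  fields <- strsplit(lines, split_by)
  ncols <- if (dialect == "outfmt6") 12L else 4L
  nf <- lengths(fields)
  if (any(nf < ncols)) {
    stop("line ", which(nf < ncols)[1], " of ", path, " has fewer than ",
         ncols, " columns", call. = FALSE)
  }
  ecol <- if (dialect == "outfmt6") 11L else 3L
  bcol <- if (dialect == "outfmt6") 12L else 4L
  ev_chr <- vapply(fields, `[[`, character(1), ecol)
  ev <- suppressWarnings(as.numeric(ev_chr))
  if (anyNA(ev)) {
    stop("non-numeric e-value '", ev_chr[which(is.na(ev))[1]], "' at line ",
         which(is.na(ev))[1], " of ", path, call. = FALSE)
  }
  bs <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), bcol)))
  if (anyNA(bs)) {
    stop("non-numeric bitscore at line ", which(is.na(bs))[1], " of ", path,
         call. = FALSE)
  }
  if (any(ev < 0)) stop("negative e-value in ", path, call. = FALSE)
  if (any(bs < 0)) stop("negative bitscore in ", path, call. = FALSE)
  subj <- vapply(fields, `[[`, character(1), 2L)
  tb <- tibble::tibble(
    query_id = vapply(fields, `[[`, character(1), 1L),
    subject_id = subj,
    subject_species = id_to_species(subj),
    evalue = ev,
    bitscore = bs
  )
  keep <- tb$evalue <= ceiling
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " of ", nrow(tb),
            " hit(s) above the e-value ceiling ", format(ceiling),
            " dropped from ", path)
  }
  out <- tb[keep, ]
  attr(out, "n_dropped") <- n_dropped
  out
}
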