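#' Read a protein FASTA file into a tibble
#'
#' Identifiers are the first whitespace-delimited token of each header;
#' sequences are uppercased with line wraps concatenated. Trailing stop
#' characters (`*`) are preserved here and handled by downstream consumers.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a readable FASTA file: ", path, " (",
                             conditionMessage(e), ")", call. = FALSE)
  )
  if (length(set) == 0) {
    stop("empty or record-free FASTA file: ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(id = ids, sequence = unname(toupper(as.character(set))))
}

#' Write a tibble of sequences as FASTA
#'
#' @param seqs Tibble with columns `id`, `sequence`.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(all(c("id", "sequence") %in% names(seqs)))
  wrap <- function(s) {
    if (nchar(s) == 0) return("")
    starts <- seq(1, nchar(s), by = width)
    paste(substring(s, starts, pmin(starts + width - 1, nchar(s))),
          collapse = "\n")
  }
  lines <- paste0(">", seqs$id, "\n", vapply(seqs$sequence, wrap, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a grouped alignment
#'
#' A grouped alignment is a tibble with one row per aligned sequence
#' (`seq_id`, `species`, `group`, `sequence`) and an attribute
#' `column_count`; all aligned sequences must have equal length and no row
#' may be all gaps.
#'
#' @param seq_id,species,sequence Parallel character vectors.
#' @param groups Taxon-group tibble from [taxon_groups()].
#' @param allow_unmapped If `TRUE`, species absent from `groups` fall into
#'   group `OTHER`; otherwise they are an error.
#' @return A `grouped_alignment` tibble.
#' @export
grouped_alignment <- function(seq_id, species, sequence, groups,
                              allow_unmapped = FALSE) {
  sequence <- toupper(sequence)
  lens <- nchar(sequence)
  if (length(unique(lens)) > 1) {
    off <- seq_id[lens != stats::median(lens)]
    stop("aligned sequences have unequal lengths; offending ids: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  allgap <- gsub("-", "", sequence) == ""
  if (any(allgap)) {
    stop("all-gap alignment row(s): ", paste(seq_id[allgap], collapse = ", "),
         call. = FALSE)
  }
  idx <- match(species, groups$species)
  if (anyNA(idx)) {
    unknown <- unique(species[is.na(idx)])
    if (!allow_unmapped) {
      stop("species not in taxon-group map: ",
           paste(unknown, collapse = ", "),
           " (use allow_unmapped = TRUE to place them in OTHER)",
           call. = FALSE)
    }
  }
  grp <- ifelse(is.na(idx), "OTHER", groups$group[idx])
  out <- tibble::tibble(seq_id = seq_id, species = species, group = grp,
                        sequence = sequence)
  attr(out, "column_count") <- unname(lens[1])
  class(out) <- c("grouped_alignment", class(out))
  out
}

# Internal constructor that skips the all-gap-row check: column trimming can
# legitimately leave a sequence with no residues in the kept interval.
new_grouped_alignment <- function(seq_id, species, group, sequence) {
  out <- tibble::tibble(seq_id = seq_id, species = species, group = group,
                        sequence = sequence)
  attr(out, "column_count") <- unname(nchar(sequence[1]))
  class(out) <- c("grouped_alignment", class(out))
  out
}

#' Read an aligned FASTA file into a grouped alignment
#'
#' Species labels are derived from sequence ids via `id_to_species`
#' (default: prefix before the first `|`, see [species_from_id()]).
#'
#' @param path Path to an aligned FASTA file.
#' @param groups Taxon-group tibble.
#' @param id_to_species Function mapping ids to species labels.
#' @param allow_unmapped Passed to [grouped_alignment()].
#' @return A `grouped_alignment` tibble.
#' @export
read_alignment <- function(path, groups, id_to_species = species_from_id,
                           allow_unmapped = FALSE) {
  fa <- read_fasta(path)
  grouped_alignment(fa$id, id_to_species(fa$id), fa$sequence, groups,
                    allow_unmapped = allow_unmapped)
}

#' Number of columns in a grouped alignment
#' @param aln A `grouped_alignment`.
#' @return Integer column count.
#' @export
column_count <- function(aln) {
  attr(aln, "column_count")
}

#' Write a grouped alignment as aligned FASTA
#' @param aln A `grouped_alignment`.
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  write_fasta(tibble::tibble(id = aln$seq_id, sequence = aln$sequence), path)
}

# Character matrix view (rows = sequences, columns = alignment columns).
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequence, ""))
  rownames(m) <- aln$seq_id
  m
}
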