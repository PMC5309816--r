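#' Read a gene-family presence/absence matrix
#'
#' The file is a TSV with a `family_id` column followed by one logical/0-1
#' column per species. Returned in long (tidy) form.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `family_id`, `species`, `present` (logical).
#' @export
read_presence_matrix <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    family_id = "c", .default = "d"), comment = "#", progress = FALSE)
  if (!"family_id" %in% names(tb) || ncol(tb) < 2) {
    stop("presence matrix needs a family_id column plus species columns: ",
         path, call. = FALSE)
  }
  long <- tidyr::pivot_longer(tb, -"family_id", names_to = "species",
                              values_to = "present")
  long$present <- long$present > 0
  empty <- dplyr::group_by(long, .data$family_id)
  empty <- dplyr::summarise(empty, any = any(.data$present))
  if (any(!empty$any)) {
    stop("family absent from every species: ",
         paste(empty$family_id[!empty$any], collapse = ", "), call. = FALSE)
  }
  long
}

#' Write a long presence table as a wide presence/absence TSV
#' @param presence Long tibble (`family_id`, `species`, `present`).
#' @param path Output path.
#' @export
write_presence_matrix <- function(presence, path) {
  wide <- tidyr::pivot_wider(
    dplyr::mutate(presence, present = as.integer(.data$present)),
    names_from = "species", values_from = "present", values_fill = 0L)
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Write a deterministic TSV report
#'
#' Columns are written in their existing order with a header row; rerunning
#' on the same input produces a byte-identical file. An empty record set
#' yields a header-only file with a warning.
#'
#' @param records A data frame.
#' @param path Output path.
#' @param header_lines Optional character vector of `#`-prefixed comment
#'   lines written above the header (used by the pipeline to echo seed and
#'   parameters).
#' @export
write_report_tsv <- function(records, path, header_lines = NULL) {
  if (nrow(records) == 0) {
    warning("writing header-only report: no records")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(header_lines)) {
    writeLines(header_lines, con, sep = "\n")
  }
  df <- as.data.frame(records)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))
  })
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0) {
    writeLines(do.call(paste, c(df, sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}
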