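#' Taxon group labels
#'
#' Roles a species can play in the differential-conservation analysis:
#' `PEZ` (Pezizomycotina reference clade), `NEOLECTA` (the multicellular
#' Taphrinomycotina anchor), `SACCH` (budding-yeast comparator),
#' `TAPH_YEAST` (fission-yeast comparator), `OTHER`.
#' @export
GROUP_LEVELS <- c("PEZ", "NEOLECTA", "SACCH", "TAPH_YEAST", "OTHER")

#' Build a taxon-group map
#'
#' @param species Character vector of species labels (unique).
#' @param group Character vector of group labels from [GROUP_LEVELS].
#' @return A tibble with columns `species`, `group`.
#' @export
taxon_groups <- function(species, group) {
  species <- as.character(species)
  group <- as.character(group)
  if (length(species) != length(group)) {
    stop("species and group must have equal length", call. = FALSE)
  }
  if (anyDuplicated(species)) {
    stop("duplicate species labels: ",
         paste(unique(species[duplicated(species)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(group), GROUP_LEVELS)
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(species = species, group = group)
}

#' Read a taxon-group map from a two-column TSV
#'
#' Expects columns `species` and `group` (header required).
#'
#' @param path Path to a TSV file.
#' @return A tibble as from [taxon_groups()].
#' @export
read_taxon_groups <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        comment = "#", progress = FALSE)
  if (!all(c("species", "group") %in% names(tb))) {
    stop("taxon-group file must have columns 'species' and 'group': ", path,
         call. = FALSE)
  }
  taxon_groups(tb$species, tb$group)
}

#' Write a taxon-group map
#' @param groups Tibble from [taxon_groups()].
#' @param path Output TSV path.
#' @export
write_taxon_groups <- function(groups, path) {
  readr::write_tsv(groups, path, progress = FALSE)
  invisible(path)
}

group_species <- function(groups, which) {
  groups$species[groups$group %in% which]
}

# Validate the single-Neolecta requirement shared by the candidate filter and
# the similarity profile.
the_neolecta <- function(groups) {
  neo <- group_species(groups, "NEOLECTA")
  if (length(neo) != 1) {
    stop("exactly one NEOLECTA species is required, found ", length(neo),
         call. = FALSE)
  }
  neo
}

#' Default identifier-to-species rule
#'
#' Sequence and hit identifiers are mapped to species labels by taking the
#' prefix before the first `|`; identifiers without `|` are used whole.
#'
#' @param ids Character vector of sequence identifiers.
#' @return Character vector of species labels.
#' @export
species_from_id <- function(ids) {
  sub("\\|.*$", "", ids)
}
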