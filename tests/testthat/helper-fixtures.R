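# Shared fixtures: tiny trees, group maps and alignments built in code.

toy_tree <- function() {
  ape::read.tree(text = "((A:0.1,B:0.3):0.2,X:0.35);")
}

toy_groups <- function() {
  taxon_groups(c("A", "B", "X"), c("PEZ", "PEZ", "OTHER"))
}

# Alignment with one Neolecta row, n_pez PEZ rows and n_sacch SACCH rows.
make_aln <- function(neo, pez, sacch) {
  species <- c("Nirr", paste0("Pez", seq_along(pez)),
               paste0("Yst", seq_along(sacch)))
  groups <- taxon_groups(species, c("NEOLECTA", rep("PEZ", length(pez)),
                                    rep("SACCH", length(sacch))))
  grouped_alignment(seq_id = species, species = species,
                    sequence = c(neo, pez, sacch), groups = groups)
}

# Random gap-free alignment rows over the canonical alphabet.
random_seq <- function(n) {
  paste(sample(AMINO_ACIDS, n, replace = TRUE), collapse = "")
}

group_species_test <- function(groups, g) {
  groups$species[groups$group == g]
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
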