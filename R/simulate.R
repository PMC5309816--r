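#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic-data generator: a
#' 17-taxon Ascomycota-like species tree (14 Pezizomycotina tips, one
#' *Neolecta*, one budding yeast, one fission yeast), protein families in
#' three classes — `conserved` (clock-like), `divergent` (yeast terminal
#' branches inflated by `yeast_multiplier`), `lost` (family deleted from each
#' yeast with probability `loss_prob`) — and a planted PTS1 fraction.
#'
#' Default branch lengths put within-Pezizomycotina pairwise identity near
#' 85% at `base_rate = 1`, the regime in which the tiered filter is meant to
#' operate.
#'
#' @param tree_spec `"default"` or a Newick string (requires `groups`).
#' @param groups Taxon-group tibble; required when `tree_spec` is custom.
#' @param n_families Number of protein families to simulate.
#' @param seq_length Protein length in residues (no indels are simulated, so
#'   tip sequences are positionally aligned).
#' @param base_rate Substitutions/site per unit branch length.
#' @param yeast_multiplier Rate multiplier (>= 1) applied to the two yeast
#'   terminal branches in `divergent` families.
#' @param loss_prob Per-yeast loss probability in `lost` families.
#' @param class_proportions Named numeric `(conserved, divergent, lost)`
#'   summing to 1.
#' @param pts1_fraction Fraction of proteins per proteome given a planted
#'   C-terminal `[SAC][KRH]L` tripeptide.
#' @param scale_c Slope of the surrogate -log10 e-value mapping
#'   `n = max(0, scale_c * S)` over the ungapped pairwise BLOSUM62 score `S`.
#' @param query_tip Tip playing the *Neurospora* query role (must be PEZ).
#' @param seed Integer seed; every generator output is a pure function of
#'   this configuration including the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(tree_spec = "default", groups = NULL,
                       n_families = 200, seq_length = 300, base_rate = 1,
                       yeast_multiplier = 5, loss_prob = 1,
                       class_proportions = c(conserved = 0.5,
                                             divergent = 0.25, lost = 0.25),
                       pts1_fraction = 0.07, scale_c = 0.3,
                       query_tip = "Ncra", seed = 1) {
  stopifnot(length(class_proportions) == 3)
  if (is.null(names(class_proportions))) {
    names(class_proportions) <- c("conserved", "divergent", "lost")
  }
  if (any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must be non-negative and sum to 1", call. = FALSE)
  }
  if (seq_length < 50) stop("seq_length must be >= 50", call. = FALSE)
  if (yeast_multiplier < 1) stop("yeast_multiplier must be >= 1", call. = FALSE)
  if (loss_prob < 0 || loss_prob > 1) stop("loss_prob must be in [0,1]",
                                           call. = FALSE)
  if (pts1_fraction < 0 || pts1_fraction > 1) {
    stop("pts1_fraction must be in [0,1]", call. = FALSE)
  }
  structure(list(
    tree_spec = tree_spec, groups = groups, n_families = n_families,
    seq_length = seq_length, base_rate = base_rate,
    yeast_multiplier = yeast_multiplier, loss_prob = loss_prob,
    class_proportions = class_proportions, pts1_fraction = pts1_fraction,
    scale_c = scale_c, query_tip = query_tip, seed = as.integer(seed)
  ), class = "sim_config")
}

# Default 17-taxon topology: a Pezizomycotina crown of seven shallow cherries
# (tip depth ~0.08 substitutions/site, within-clade identity near 85%),
# Neolecta and fission yeast as a Taphrinomycotina clade, budding yeast
# sister to the Pezizomycotina. Non-PEZ depths are set so that in conserved
# (clock-like) families every cross-clade comparison still saturates the
# -log10 e-value cap -- mirroring real searches, where strong hits report
# e-value 0.0 -- while the divergent-class rate multiplier pulls yeast hits
# far below it.
default_species_newick <- function() {
  cherry <- function(a, b) sprintf("(%s:0.03,%s:0.03):0.05", a, b)
  pez <- c(cherry("Ncra", "Cglo"), cherry("Mgri", "Fgra"),
           cherry("Tree", "Pans"), cherry("Bcin", "Sscl"),
           cherry("Aory", "Anig"), cherry("Afum", "Cimm"),
           cherry("Snod", "Tmel"))
  core <- pez[1]
  for (i in 2:7) core <- sprintf("(%s,%s):0.002", core, pez[i])
  sprintf("((Nirr:0.10,Spom:0.14):0.02,(Scer:0.18,%s:0.05):0.02);", core)
}

default_taxon_groups <- function() {
  pez <- c("Ncra", "Cglo", "Mgri", "Fgra", "Tree", "Pans", "Bcin", "Sscl",
           "Aory", "Anig", "Afum", "Cimm", "Snod", "Tmel")
  taxon_groups(c(pez, "Nirr", "Scer", "Spom"),
               c(rep("PEZ", 14), "NEOLECTA", "SACCH", "TAPH_YEAST"))
}

#' Build the simulated species tree and taxon-group map
#'
#' @param config A [sim_config()].
#' @return A list with elements `tree` (`phylo`) and `groups` (tibble).
#' @export
make_species_tree <- function(config) {
  if (identical(config$tree_spec, "default")) {
    tree <- ape::read.tree(text = default_species_newick())
    groups <- default_taxon_groups()
  } else {
    tree <- ape::read.tree(text = config$tree_spec)
    if (is.null(tree)) stop("unparseable tree_spec", call. = FALSE)
    if (is.null(config$groups)) {
      stop("custom tree_spec requires a groups table", call. = FALSE)
    }
    groups <- config$groups
  }
  if (any(tree$edge.length <= 0)) {
    stop("species tree branch lengths must be strictly positive",
         call. = FALSE)
  }
  pez <- intersect(group_species(groups, "PEZ"), tree$tip.label)
  if (length(pez) < 2) {
    stop("species tree must contain at least 2 PEZ tips", call. = FALSE)
  }
  missing <- setdiff(tree$tip.label, groups$species)
  if (length(missing) > 0) {
    stop("tree tips missing from group map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  list(tree = tree, groups = groups)
}

#' Evolve one protein family along a tree
#'
#' The root sequence is drawn i.i.d. from the BLOSUM62 background
#' frequencies. Along each branch of length `t` with multiplier `m`, every
#' site substitutes independently with probability `1 - exp(-rate * m * t)`;
#' replacements are drawn from the background frequencies renormalised to
#' exclude the current residue. No indels are simulated, so tip sequences
#' are positionally aligned.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param rate Substitutions/site per unit branch length (>= 0).
#' @param branch_multipliers Optional named numeric of per-tip multipliers
#'   applied to terminal branches (default 1 everywhere).
#' @param seq_length Number of residues.
#' @param seed Integer seed.
#' @return Tibble (`tip`, `sequence`) with attributes `edge_subs` (realised
#'   substitution count per edge, in `tree$edge` order) and `root_sequence`.
#' @export
evolve_family <- function(tree, rate, branch_multipliers = NULL, seq_length,
                          seed) {
  if (rate < 0) stop("rate must be non-negative", call. = FALSE)
  bg <- blosum62_background()
  ntip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  mult <- rep(1, nrow(tree$edge))
  if (!is.null(branch_multipliers)) {
    child <- tree$edge[, 2]
    tip_edges <- child <= ntip
    hit <- match(tree$tip.label[child[tip_edges]], names(branch_multipliers))
    mult[tip_edges][!is.na(hit)] <- branch_multipliers[hit[!is.na(hit)]]
  }
  with_seed(seed, {
    seqs <- vector("list", nnode)
    seqs[[root]] <- sample.int(20L, seq_length, replace = TRUE, prob = bg)
    edge_subs <- integer(nrow(tree$edge))
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      p_sub <- 1 - exp(-rate * mult[e] * tree$edge.length[e])
      s <- seqs[[parent]]
      hit <- which(runif(seq_length) < p_sub)
      if (length(hit) > 0) {
        repl <- sample.int(20L, length(hit), replace = TRUE, prob = bg)
        same <- which(repl == s[hit])
        while (length(same) > 0) {  # rejection: replacement must differ
          repl[same] <- sample.int(20L, length(same), replace = TRUE,
                                   prob = bg)
          same <- same[repl[same] == s[hit][same]]
        }
        s[hit] <- repl
      }
      edge_subs[e] <- length(hit)
      seqs[[child]] <- s
    }
    out <- tibble::tibble(
      tip = tree$tip.label,
      sequence = vapply(seqs[seq_len(ntip)], function(x) {
        paste(AMINO_ACIDS[x], collapse = "")
      }, character(1))
    )
    attr(out, "edge_subs") <- edge_subs
    attr(out, "edge") <- tree$edge
    attr(out, "root_sequence") <- paste(AMINO_ACIDS[seqs[[root]]],
                                        collapse = "")
    out
  })
}

#' Realised gene tree of an evolved family
#'
#' Species-tree topology with branch lengths set to the realised
#' substitutions/site on each branch — the idealised analogue of an ML gene
#' tree estimated from the family alignment.
#'
#' @param tree The species tree the family was evolved on.
#' @param family Output of [evolve_family()].
#' @param seq_length Residues used in the simulation.
#' @return A `phylo` object.
#' @export
realized_gene_tree <- function(tree, family, seq_length) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree$edge.length <- attr(family, "edge_subs") / seq_length
  tree
}

#' Simulate a full set of protein families with ground truth
#'
#' @param config A [sim_config()].
#' @return A list: `tree`, `groups`, `truth` (tibble `family_id`, `class`,
#'   `lost_sacch`, `lost_taph`), `sequences` (long tibble `family_id`, `tip`,
#'   `species`, `sequence` for retained copies), `presence` (long tibble),
#'   `families` (list of [evolve_family()] outputs, for gene trees).
#' @export
simulate_families <- function(config) {
  if (config$n_families < 1) stop("n_families must be >= 1", call. = FALSE)
  st <- make_species_tree(config)
  tree <- st$tree
  groups <- st$groups
  if (!config$query_tip %in% group_species(groups, "PEZ")) {
    stop("query_tip must be a PEZ tip", call. = FALSE)
  }
  sacch <- group_species(groups, "SACCH")
  taph <- group_species(groups, "TAPH_YEAST")
  yeasts <- c(sacch, taph)
  n <- config$n_families
  props <- config$class_proportions
  counts <- floor(props * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    counts[order(props * n - counts, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(props * n - counts, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  classes <- rep(names(props), counts)
  fam_ids <- sprintf("fam%04d", seq_len(n))
  losses <- with_seed(derive_seed(config$seed, 1L), {
    matrix(runif(n * length(yeasts)) < config$loss_prob, nrow = n,
           dimnames = list(NULL, yeasts))
  })
  losses[classes != "lost", ] <- FALSE
  families <- vector("list", n)
  seq_rows <- vector("list", n)
  for (i in seq_len(n)) {
    mults <- NULL
    if (classes[i] == "divergent") {
      mults <- stats::setNames(rep(config$yeast_multiplier, length(yeasts)),
                               yeasts)
    }
    fam <- evolve_family(tree, config$base_rate, mults, config$seq_length,
                         seed = derive_seed(config$seed, 100L + i))
    families[[i]] <- fam
    lost_tips <- yeasts[losses[i, ]]
    kept <- fam[!fam$tip %in% lost_tips, ]
    seq_rows[[i]] <- tibble::tibble(
      family_id = fam_ids[i], tip = kept$tip, species = kept$tip,
      sequence = kept$sequence)
  }
  sequences <- dplyr::bind_rows(seq_rows)
  presence <- tidyr::crossing(family_id = fam_ids,
                              species = tree$tip.label)
  presence <- dplyr::left_join(
    presence,
    dplyr::mutate(sequences[, c("family_id", "species")], present = TRUE),
    by = c("family_id", "species"))
  presence$present <- !is.na(presence$present)
  lost_in <- function(sp) if (length(sp) == 1) losses[, sp] else
    apply(losses[, sp, drop = FALSE], 1, any)
  truth <- tibble::tibble(
    family_id = fam_ids, class = classes,
    lost_sacch = lost_in(sacch), lost_taph = lost_in(taph))
  truth$class_label <- dplyr::case_when(
    truth$lost_sacch & truth$lost_taph ~ "lost-in-both",
    truth$lost_sacch ~ "lost-in-SACCH",
    truth$lost_taph ~ "lost-in-TAPH",
    TRUE ~ truth$class
  )
  names(families) <- fam_ids
  list(tree = tree, groups = groups, truth = truth, sequences = sequences,
       presence = presence, families = families)
}

#' Emulate a homology hit table from simulated families
#'
#' For each family and each retained non-query tip, the ungapped pairwise
#' BLOSUM62 score `S` between the query tip's sequence and that tip's
#' sequence is mapped to a surrogate `-log10` e-value `n = max(0, scale_c *
#' S)`; the emitted e-value is `10^-n` (which may underflow to 0 for near-
#' identical sequences; the reader's cap handles this). The surrogate is a
#' declared synthetic stand-in for real search e-values: only its
#' monotonic decrease with divergence matters downstream. Lost copies emit no
#' record. Records above the presence ceiling are still emitted; the reader
#' applies the ceiling.
#'
#' @param sim Output of [simulate_families()].
#' @param scale_c Slope of the surrogate mapping (default from the config).
#' @param query_tip Query species label.
#' @return A hit tibble as from [read_hit_table()] (unfiltered).
#' @export
emulate_hit_table <- function(sim, scale_c = 0.3, query_tip = "Ncra") {
  B <- blosum62()
  code <- function(s) match(strsplit(s, "")[[1]], AMINO_ACIDS)
  rows <- lapply(split(sim$sequences, sim$sequences$family_id), function(fam) {
    qrow <- fam[fam$tip == query_tip, ]
    if (nrow(qrow) == 0) return(NULL)
    q <- code(qrow$sequence)
    subj <- fam[fam$tip != query_tip, ]
    if (nrow(subj) == 0) return(NULL)
    S <- vapply(subj$sequence, function(s) {
      sum(B[cbind(q, code(s))])
    }, numeric(1), USE.NAMES = FALSE)
    n <- pmax(0, scale_c * S)
    tibble::tibble(
      query_id = fam$family_id[1],
      subject_id = paste0(subj$tip, "|", fam$family_id[1]),
      subject_species = subj$tip,
      evalue = 10^(-n),
      bitscore = pmax(S, 0)
    )
  })
  dplyr::bind_rows(rows)
}

#' Plant PTS1 tripeptides into a proteome
#'
#' Exactly `round(fraction * N)` proteins (among those of length >= 3) have
#' their last three residues replaced by a tripeptide drawn uniformly from
#' `{S,A,C} x {K,R,H} x {L}`; every remaining protein is rewritten if needed
#' so its C-terminus does **not** match the pattern, making the planted
#' fraction exactly recoverable.
#'
#' @param proteins Tibble with columns `id`, `sequence`.
#' @param fraction Fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return The input tibble with a logical `planted` column.
#' @export
plant_pts1 <- function(proteins, fraction, seed) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0,1]",
                                         call. = FALSE)
  n <- nrow(proteins)
  eligible <- which(nchar(proteins$sequence) >= 3)
  if (length(eligible) < n) {
    warning(n - length(eligible),
            " protein(s) shorter than 3 residues skipped")
  }
  n_plant <- round(fraction * n)
  if (n_plant > length(eligible)) {
    stop("not enough proteins of length >= 3 to plant ", n_plant, " PTS1",
         call. = FALSE)
  }
  first <- c("S", "A", "C")
  second <- c("K", "R", "H")
  out <- proteins
  out$planted <- FALSE
  with_seed(seed, {
    chosen <- if (n_plant > 0) {
      eligible[sample.int(length(eligible), n_plant)]
    } else integer(0)
    if (n_plant > 0) {
      tri <- paste0(sample(first, n_plant, replace = TRUE),
                    sample(second, n_plant, replace = TRUE), "L")
      body <- substr(out$sequence[chosen], 1,
                     nchar(out$sequence[chosen]) - 3)
      out$sequence[chosen] <- paste0(body, tri)
      out$planted[chosen] <- TRUE
    }
    spoil <- setdiff(seq_len(n), chosen)
    hit <- spoil[has_pts1(out$sequence[spoil], warn = FALSE)]
    if (length(hit) > 0) {  # break the match without touching the pattern class
      out$sequence[hit] <- paste0(
        substr(out$sequence[hit], 1, nchar(out$sequence[hit]) - 1), "G")
    }
  })
  out
}

#' Write a complete synthetic fixture bundle
#'
#' Materialises one simulation as the on-disk inputs of every downstream
#' stage: species tree, taxon map, per-family alignments, minimal-dialect
#' hit table, per-species proteome FASTAs with planted PTS1, presence
#' matrix, truth table, and a manifest with md5 checksums.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created; must not already contain a
#'   manifest).
#' @return The manifest tibble (`filename`, `role`, `md5`), invisibly
#'   written to `manifest.tsv`.
#' @export
write_fixture_bundle <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(outdir, recursive = TRUE))
  sim <- simulate_families(config)
  paths <- character(0)
  roles <- character(0)
  add <- function(p, role) {
    paths <<- c(paths, p)
    roles <<- c(roles, role)
  }
  tre <- file.path(outdir, "species_tree.nwk")
  write_newick(sim$tree, tre); add(tre, "species_tree")
  tax <- file.path(outdir, "taxa.tsv")
  write_taxon_groups(sim$groups, tax); add(tax, "taxon_groups")
  aln_dir <- file.path(outdir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  for (fid in unique(sim$sequences$family_id)) {
    fam <- sim$sequences[sim$sequences$family_id == fid, ]
    p <- file.path(aln_dir, paste0(fid, ".fasta"))
    write_fasta(tibble::tibble(id = paste0(fam$tip, "|", fid),
                               sequence = fam$sequence), p)
    add(p, "alignment")
  }
  tree_dir <- file.path(outdir, "gene_trees")
  dir.create(tree_dir, showWarnings = FALSE)
  for (fid in names(sim$families)) {
    p <- file.path(tree_dir, paste0(fid, ".nwk"))
    write_newick(realized_gene_tree(sim$tree, sim$families[[fid]],
                                    config$seq_length), p)
    add(p, "gene_tree")
  }
  hits <- emulate_hit_table(sim, scale_c = config$scale_c,
                            query_tip = config$query_tip)
  hp <- file.path(outdir, "hits.tsv")
  writeLines(paste(hits$query_id, hits$subject_id,
                   formatC(hits$evalue, format = "g", digits = 6),
                   formatC(hits$bitscore, format = "g", digits = 6),
                   sep = "\t"), hp)
  add(hp, "hit_table")
  prot_dir <- file.path(outdir, "proteomes")
  dir.create(prot_dir, showWarnings = FALSE)
  sp_all <- sim$tree$tip.label
  for (k in seq_along(sp_all)) {
    sp <- sp_all[k]
    seqs <- sim$sequences[sim$sequences$species == sp, ]
    prot <- tibble::tibble(id = paste0(sp, "|", seqs$family_id),
                           sequence = seqs$sequence)
    prot <- plant_pts1(prot, config$pts1_fraction,
                       seed = derive_seed(config$seed, 5000L + k))
    p <- file.path(prot_dir, paste0(sp, ".fasta"))
    write_fasta(prot[, c("id", "sequence")], p)
    add(p, "proteome")
  }
  pm <- file.path(outdir, "presence.tsv")
  write_presence_matrix(sim$presence, pm); add(pm, "presence_matrix")
  tt <- file.path(outdir, "truth.tsv")
  readr::write_tsv(sim$truth, tt, progress = FALSE); add(tt, "truth")
  manifest <- tibble::tibble(
    filename = sub(paste0("^", gsub("([.\\\\+*?^$(){}|\\[\\]])", "\\\\\\1",
                                    outdir), "/?"), "", paths),
    role = roles,
    md5 = unname(tools::md5sum(paths))
  )
  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"),
                   progress = FALSE)
  ok <- TRUE
  invisible(manifest)
}
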