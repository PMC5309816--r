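# Independent brute-force oracles. These re-derive expectations from the
# definitions by plain enumeration and stay separate from the implementation
# paths they check.

# Candidate classification from a raw hit list, literal if/else chains.
bf_classify <- function(gene_id, hits, groups, min_pez = 7 / 14) {
  rows <- hits[hits$query_id == gene_id, , drop = FALSE]
  nle <- ifelse(rows$evalue == 0, 300, pmin(-log10(rows$evalue), 300))
  best_for <- function(sp_set) {
    vals <- nle[rows$subject_species %in% sp_set]
    if (length(vals) == 0) NA_real_ else max(vals)
  }
  pez_sp <- groups$species[groups$group == "PEZ"]
  n_present <- 0
  for (sp in pez_sp) {
    if (any(rows$subject_species == sp)) n_present <- n_present + 1
  }
  neo <- best_for(groups$species[groups$group == "NEOLECTA"])
  call_for <- function(yst) {
    if (is.na(neo) || neo < 1) return("INELIGIBLE")
    if (is.na(yst)) return("ABSENT")
    gap <- neo - yst
    if (neo > 200) {
      if (gap >= 60) "DIVERGENT" else "CONSERVED"
    } else if (neo >= 100) {
      if (gap >= 40) "DIVERGENT" else "CONSERVED"
    } else {
      if (gap >= 20) "DIVERGENT" else "CONSERVED"
    }
  }
  cs <- call_for(best_for(groups$species[groups$group == "SACCH"]))
  ct <- call_for(best_for(groups$species[groups$group == "TAPH_YEAST"]))
  list(
    call_sacch = cs, call_taph = ct, pez_present_count = n_present,
    selected = (n_present / length(pez_sp) >= min_pez) &&
      !is.na(neo) && neo >= 1 &&
      (cs %in% c("ABSENT", "DIVERGENT") || ct %in% c("ABSENT", "DIVERGENT"))
  )
}

# Column differential score by explicit pair enumeration.
bf_column_score <- function(neo, pez_chars, sacch_chars, gap_penalty = 3) {
  B <- blosum62()
  score_pair <- function(a, b) {
    if (a == "-" && b == "-") return(NA_real_)
    if (a == "-" || b == "-") return(-gap_penalty)
    B[a, b]
  }
  grp <- function(chars) {
    vals <- c()
    for (ch in chars) {
      v <- score_pair(neo, ch)
      if (!is.na(v)) vals <- c(vals, v)
    }
    if (length(vals) == 0) NA_real_ else mean(vals)
  }
  grp(pez_chars) - grp(sacch_chars)
}

# Exact Mann-Whitney p by enumerating all C(n_a + n_b, n_a) assignments.
bf_mw_exact_p <- function(a, b, alternative) {
  pooled <- c(a, b)
  n <- length(pooled)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(a, b)
  idx <- utils::combn(n, length(a))
  us <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  switch(alternative,
         less = mean(us <= u_obs),
         greater = mean(us >= u_obs),
         two.sided = min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs))))
}

# PTS1 by looping over the nine admissible tripeptides.
bf_pts1 <- function(seq) {
  s <- toupper(seq)
  if (grepl("\\*$", s)) s <- substr(s, 1, nchar(s) - 1)
  if (nchar(s) < 3) return(FALSE)
  tail3 <- substr(s, nchar(s) - 2, nchar(s))
  for (p1 in c("S", "A", "C")) {
    for (p2 in c("K", "R", "H")) {
      if (tail3 == paste0(p1, p2, "L")) return(TRUE)
    }
  }
  FALSE
}

# Node tip-set bitmasks for a phylo tree (tips in tip.label order).
tree_masks <- function(tr) {
  ntip <- length(tr$tip.label)
  mask <- integer(ntip + tr$Nnode)
  mask[seq_len(ntip)] <- bitwShiftL(1L, seq_len(ntip) - 1L)
  po <- ape::reorder.phylo(tr, "postorder")$edge
  for (e in seq_len(nrow(po))) {
    mask[po[e, 1]] <- bitwOr(mask[po[e, 1]], mask[po[e, 2]])
  }
  mask
}

# Exhaustive minimal Dollo loss count over all single-gain scenarios.
bf_dollo_min_losses <- function(tr, pattern_mask, mask = tree_masks(tr)) {
  edges <- tr$edge
  child_mask <- mask[edges[, 2]]
  best <- Inf
  for (gn in which(bitwAnd(mask, pattern_mask) == pattern_mask)) {
    below <- which(bitwAnd(child_mask, mask[gn]) == child_mask &
                     edges[, 2] != gn)
    for (k in 0:length(below)) {
      if (k >= best) break
      combs <- if (k == 0) list(integer(0)) else
        utils::combn(below, k, simplify = FALSE)
      found <- FALSE
      for (cmb in combs) {
        lossmask <- Reduce(bitwOr, child_mask[cmb], 0L)
        if (bitwAnd(mask[gn], bitwNot(lossmask)) == pattern_mask) {
          best <- k
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  }
  best
}
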