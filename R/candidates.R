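#' Thresholds for the tiered differential-conservation filter
#'
#' The yeast best hit must trail the *N. irregularis* best hit by at least
#' 60, 40 or 20 units of -log10(e-value) when the *N. irregularis* hit falls
#' in the range (200, +Inf), \[100, 200\] or \[1, 100) respectively. An
#' e-value of exactly 0 is capped at `nle_cap`. Presence in a species means
#' a hit at or below `presence_ceiling`; candidate genes must be present in
#' at least `min_pez_fraction` of the Pezizomycotina panel (7/14 in the
#' original 14-species panel).
#'
#' @param tiers Tibble with columns `lower`, `upper`, `gap`; the tier
#'   containing `nle` is the one with `lower <= nle <= upper`, bounds being
#'   open/closed as in the defaults ((200, Inf\], \[100, 200\], \[1, 100)).
#' @param nle_cap Cap for `-log10(0)` (default 300).
#' @param presence_ceiling Maximal e-value counted as a hit (default 1e-3).
#' @param min_pez_fraction Minimal fraction of PEZ species with a hit
#'   (default 0.5, i.e. 7 of 14).
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(tiers = NULL, nle_cap = 300,
                              presence_ceiling = 1e-3,
                              min_pez_fraction = 0.5) {
  if (is.null(tiers)) {
    tiers <- tibble::tibble(lower = c(200, 100, 1),
                            upper = c(Inf, 200, 100),
                            gap = c(60, 40, 20))
  }
  if (any(tiers$gap <= 0)) stop("tier gaps must be positive", call. = FALSE)
  structure(list(tiers = tiers, nle_cap = nle_cap,
                 presence_ceiling = presence_ceiling,
                 min_pez_fraction = min_pez_fraction),
            class = "filter_thresholds")
}

#' Negative log10 of an e-value, with a cap at zero
#'
#' @param evalue Numeric e-values in `[0, 1]`.
#' @param cap Value returned for an e-value of exactly 0, and upper bound on
#'   the result (default 300).
#' @return `min(-log10(evalue), cap)`, vectorised.
#' @export
neg_log10_evalue <- function(evalue, cap = 300) {
  if (cap <= 0) stop("cap must be positive", call. = FALSE)
  if (any(evalue < 0 | evalue > 1, na.rm = TRUE)) {
    stop("e-values must lie in [0, 1]", call. = FALSE)
  }
  ifelse(evalue == 0, cap, pmin(-log10(evalue), cap))
}

#' Best hit per subject species for one query
#'
#' Ties on -log10(e-value) break by higher bitscore, then lexicographically
#' smallest subject id, so results are deterministic.
#'
#' @param hits Hit tibble (see [read_hit_table()]).
#' @param query_id Query to extract.
#' @param cap Passed to [neg_log10_evalue()].
#' @return Tibble (`subject_species`, `nle`, `subject_id`, `bitscore`), one
#'   row per species with at least one hit.
#' @export
best_hit_per_species <- function(hits, query_id, cap = 300) {
  h <- hits[hits$query_id == query_id, ]
  if (nrow(h) == 0) {
    return(tibble::tibble(subject_species = character(), nle = double(),
                          subject_id = character(), bitscore = double()))
  }
  h$nle <- neg_log10_evalue(h$evalue, cap)
  h <- dplyr::arrange(h, .data$subject_species, dplyr::desc(.data$nle),
                      dplyr::desc(.data$bitscore), .data$subject_id)
  h <- dplyr::slice_head(dplyr::group_by(h, .data$subject_species), n = 1)
  dplyr::ungroup(h)[, c("subject_species", "nle", "subject_id", "bitscore")]
}

#' Pezizomycotina presence criterion
#'
#' @param best_hits Output of [best_hit_per_species()] (already
#'   ceiling-filtered on read).
#' @param groups Taxon-group tibble.
#' @param thresholds A [filter_thresholds()].
#' @return Tibble (`pez_present_count`, `pez_total`, `pez_passed`).
#' @export
pez_presence <- function(best_hits, groups, thresholds = filter_thresholds()) {
  pez <- group_species(groups, "PEZ")
  if (length(pez) == 0) stop("no PEZ species configured", call. = FALSE)
  count <- sum(best_hits$subject_species %in% pez)
  tibble::tibble(
    pez_present_count = count, pez_total = length(pez),
    pez_passed = count / length(pez) >= thresholds$min_pez_fraction)
}

# Tier gap required for a given Neolecta nle; NA when nle < 1 (ineligible).
tier_gap <- function(nle, tiers) {
  out <- rep(NA_real_, length(nle))
  # defaults encode (200, Inf], [100, 200], [1, 100): lower bound open only
  # for the top tier, upper bound open only for the bottom tier
  for (i in seq_len(nrow(tiers))) {
    lo <- tiers$lower[i]; hi <- tiers$upper[i]
    in_tier <- if (is.infinite(hi)) nle > lo else
      if (i == nrow(tiers)) nle >= lo & nle < hi else nle >= lo & nle <= hi
    out[in_tier & is.na(out)] <- tiers$gap[i]
  }
  out
}

#' Tiered per-yeast conservation call
#'
#' @param nle_neolecta -log10 e-value of the best *N. irregularis* hit
#'   (vectorised).
#' @param nle_yeast Same for the yeast; `NA` when the yeast has no hit.
#' @param thresholds A [filter_thresholds()].
#' @return Character vector in `{ABSENT, DIVERGENT, CONSERVED, INELIGIBLE}`:
#'   `INELIGIBLE` when `nle_neolecta < 1`; `ABSENT` when the yeast has no
#'   hit; `DIVERGENT` when `nle_neolecta - nle_yeast` meets the tier's gap;
#'   else `CONSERVED`.
#' @export
tiered_call <- function(nle_neolecta, nle_yeast,
                        thresholds = filter_thresholds()) {
  n <- max(length(nle_neolecta), length(nle_yeast))
  nle_neolecta <- rep_len(nle_neolecta, n)
  nle_yeast <- rep_len(nle_yeast, n)
  gap_req <- tier_gap(nle_neolecta, thresholds$tiers)
  out <- ifelse(is.na(gap_req), "INELIGIBLE",
         ifelse(is.na(nle_yeast), "ABSENT",
         ifelse(nle_neolecta - nle_yeast >= gap_req, "DIVERGENT",
                "CONSERVED")))
  out
}

#' Classify one query gene
#'
#' Combines the Pezizomycotina presence criterion with the tiered calls
#' against each yeast. A gene is `selected` when the presence criterion
#' passes, the *N. irregularis* hit is eligible (`nle >= 1`), and at least
#' one yeast call is `ABSENT` or `DIVERGENT` (loss or divergence in either
#' yeast suffices).
#'
#' @param gene_id Query id.
#' @param hits Hit tibble.
#' @param groups Taxon-group tibble (exactly one NEOLECTA species).
#' @param thresholds A [filter_thresholds()].
#' @return One-row tibble (`gene_id`, `nle_neolecta`, `nle_sacch`,
#'   `call_sacch`, `nle_taph`, `call_taph`, `pez_present_count`, `selected`).
#' @export
classify_gene <- function(gene_id, hits, groups,
                          thresholds = filter_thresholds()) {
  neo <- the_neolecta(groups)
  best <- best_hit_per_species(hits, gene_id, cap = thresholds$nle_cap)
  pres <- pez_presence(best, groups, thresholds)
  nle_of <- function(sp_set) {
    b <- best[best$subject_species %in% sp_set, ]
    if (nrow(b) == 0) NA_real_ else max(b$nle)
  }
  nle_neo <- nle_of(neo)
  nle_sacch <- nle_of(group_species(groups, "SACCH"))
  nle_taph <- nle_of(group_species(groups, "TAPH_YEAST"))
  nle_neo_eff <- if (is.na(nle_neo)) 0 else nle_neo
  call_sacch <- tiered_call(nle_neo_eff, nle_sacch, thresholds)
  call_taph <- tiered_call(nle_neo_eff, nle_taph, thresholds)
  divergentish <- c("ABSENT", "DIVERGENT")
  tibble::tibble(
    gene_id = gene_id,
    nle_neolecta = nle_neo, nle_sacch = nle_sacch, call_sacch = call_sacch,
    nle_taph = nle_taph, call_taph = call_taph,
    pez_present_count = pres$pez_present_count,
    selected = pres$pez_passed && !is.na(nle_neo) && nle_neo >= 1 &&
      (call_sacch %in% divergentish || call_taph %in% divergentish)
  )
}

#' Classify every query gene in a hit table
#'
#' @inheritParams classify_gene
#' @return A `candidate_set` tibble, one row per query.
#' @export
classify_genes <- function(hits, groups, thresholds = filter_thresholds()) {
  ids <- sort(unique(hits$query_id))
  out <- dplyr::bind_rows(lapply(ids, classify_gene, hits = hits,
                                 groups = groups, thresholds = thresholds))
  class(out) <- c("candidate_set", class(out))
  out
}

#' Summarise a set of candidate calls
#'
#' Among selected genes, the fractions with both yeast calls `ABSENT`, both
#' `DIVERGENT`, mixed (one of each), or lost/divergent in only one yeast.
#' The four fractions sum to 1.
#'
#' @param records A `candidate_set` tibble.
#' @return One-row tibble (`n_selected`, `frac_absent_both`,
#'   `frac_divergent_both`, `frac_mixed_both`, `frac_either_only`).
#' @export
summarize_candidates <- function(records) {
  if (nrow(records) == 0) stop("no candidate records", call. = FALSE)
  sel <- records[records$selected, ]
  if (nrow(sel) == 0) {
    warning("no selected candidates; summary fractions reported as 0")
    return(tibble::tibble(n_selected = 0L, frac_absent_both = 0,
                          frac_divergent_both = 0, frac_mixed_both = 0,
                          frac_either_only = 0))
  }
  dv <- c("ABSENT", "DIVERGENT")
  both_in <- sel$call_sacch %in% dv & sel$call_taph %in% dv
  tibble::tibble(
    n_selected = nrow(sel),
    frac_absent_both = mean(sel$call_sacch == "ABSENT" &
                              sel$call_taph == "ABSENT"),
    frac_divergent_both = mean(sel$call_sacch == "DIVERGENT" &
                                 sel$call_taph == "DIVERGENT"),
    frac_mixed_both = mean(both_in & sel$call_sacch != sel$call_taph),
    frac_either_only = mean(!both_in)
  )
}

#' @method glance candidate_set
#' @export
glance.candidate_set <- function(x, ...) {
  summarize_candidates(x)
}

#' Reciprocal-best-hit presence call
#'
#' A developmental gene is called present in a target species when its best
#' forward hit exists and that hit's best reciprocal hit in the reference
#' proteome is the source protein itself.
#'
#' @param forward_best Subject id of the best forward hit (`NA` if none).
#' @param reciprocal_best Subject id of the reciprocal best hit (`NA` if
#'   none).
#' @param source_protein_id Id of the source protein.
#' @return `"PRESENT"` or `"ABSENT"`, vectorised.
#' @export
reciprocal_presence_call <- function(forward_best, reciprocal_best,
                                     source_protein_id) {
  ifelse(!is.na(forward_best) & !is.na(reciprocal_best) &
           reciprocal_best == source_protein_id, "PRESENT", "ABSENT")
}
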