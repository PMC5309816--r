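test_that("neg_log10_evalue maps, caps and validates", {
  expect_equal(neg_log10_evalue(1e-3), 3)
  expect_equal(neg_log10_evalue(0), 300)
  expect_equal(neg_log10_evalue(1), 0)
  expect_equal(neg_log10_evalue(1e-320), 300)
  expect_error(neg_log10_evalue(1.5), "\\[0, 1\\]")
  expect_error(neg_log10_evalue(-0.1), "\\[0, 1\\]")
})

test_that("best hits pick maximal nle with bitscore then id tie-breaks", {
  hits <- tibble::tibble(
    query_id = "g1",
    subject_id = c("sp1|a", "sp1|b", "sp2|a", "sp2|b", "sp2|c"),
    subject_species = c("sp1", "sp1", "sp2", "sp2", "sp2"),
    evalue = c(1e-50, 1e-80, 1e-10, 1e-10, 1e-10),
    bitscore = c(100, 90, 100, 120, 120))
  b <- best_hit_per_species(hits, "g1")
  expect_equal(b$nle[b$subject_species == "sp1"], 80)
  # equal evalue: higher bitscore wins, then smaller subject id
  expect_equal(b$subject_id[b$subject_species == "sp2"], "sp2|b")
  expect_equal(nrow(best_hit_per_species(hits, "nope")), 0)
})

test_that("the Pezizomycotina presence criterion is 7 of 14", {
  pez <- paste0("P", 1:14)
  g <- taxon_groups(c(pez, "Nirr"), c(rep("PEZ", 14), "NEOLECTA"))
  bh <- function(n) tibble::tibble(subject_species = pez[seq_len(n)],
                                   nle = 50, subject_id = "x", bitscore = 1)
  expect_true(pez_presence(bh(7), g)$pez_passed)
  expect_false(pez_presence(bh(6), g)$pez_passed)
  expect_true(pez_presence(bh(14), g)$pez_passed)
  expect_error(pez_presence(bh(7), taxon_groups("Nirr", "NEOLECTA")),
               "PEZ")
})

test_that("tiered calls follow the 60/40/20 gap rules with stated bounds", {
  expect_equal(tiered_call(250, 150), "DIVERGENT")  # gap 100 >= 60
  expect_equal(tiered_call(150, 115), "CONSERVED")  # gap 35 < 40
  expect_equal(tiered_call(200, 155), "DIVERGENT")  # 200 in [100,200], 45>=40
  expect_equal(tiered_call(50, NA), "ABSENT")
  expect_equal(tiered_call(0.5, 0.1), "INELIGIBLE")
  expect_equal(tiered_call(0.5, NA), "INELIGIBLE")  # ineligibility first
  expect_equal(tiered_call(100, 60), "DIVERGENT")   # 100 in [100,200]
  expect_equal(tiered_call(99.9, 79.9), "DIVERGENT")# bottom tier, gap 20
})

test_that("classify_gene composes presence and per-yeast calls", {
  pez <- paste0("P", 1:14)
  g <- taxon_groups(c(pez, "Nirr", "Scer", "Spom"),
                    c(rep("PEZ", 14), "NEOLECTA", "SACCH", "TAPH_YEAST"))
  mk <- function(sp, nle) tibble::tibble(
    query_id = "g1", subject_id = paste0(sp, "|h"), subject_species = sp,
    evalue = 10^(-nle), bitscore = 1)
  hits <- dplyr::bind_rows(
    lapply(pez[1:10], mk, nle = 100),
    mk("Nirr", 250), mk("Scer", 150), mk("Spom", 240))
  rec <- classify_gene("g1", hits, g)
  expect_true(rec$selected)
  expect_equal(rec$call_sacch, "DIVERGENT")
  expect_equal(rec$call_taph, "CONSERVED")
  expect_equal(rec$pez_present_count, 10)

  few <- dplyr::bind_rows(lapply(pez[1:5], mk, nle = 100),
                          mk("Nirr", 250), mk("Scer", 150))
  expect_false(classify_gene("g1", few, g)$selected)

  noneo <- dplyr::bind_rows(lapply(pez[1:10], mk, nle = 100),
                            mk("Scer", 150))
  expect_false(classify_gene("g1", noneo, g)$selected)
})

test_that("classification agrees with a brute-force oracle on random genes", {
  pez <- paste0("P", 1:14)
  g <- taxon_groups(c(pez, "Nirr", "Scer", "Spom"),
                    c(rep("PEZ", 14), "NEOLECTA", "SACCH", "TAPH_YEAST"))
  set.seed(77)
  genes <- paste0("g", 1:50)
  rows <- lapply(genes, function(gene) {
    sp <- sample(g$species, sample(3:17, 1))
    tibble::tibble(query_id = gene, subject_id = paste0(sp, "|h"),
                   subject_species = sp,
                   evalue = 10^(-runif(length(sp), 0, 320)),
                   bitscore = runif(length(sp), 10, 500))
  })
  hits <- dplyr::bind_rows(rows)
  recs <- classify_genes(hits, g)
  for (gene in genes) {
    oracle <- bf_classify(gene, hits, g)
    rec <- recs[recs$gene_id == gene, ]
    expect_equal(rec$call_sacch, oracle$call_sacch)
    expect_equal(rec$call_taph, oracle$call_taph)
    expect_equal(rec$pez_present_count, oracle$pez_present_count)
    expect_equal(rec$selected, oracle$selected)
  }
})

test_that("worsening a yeast hit never deselects; shrinking the Neolecta hit
           never upgrades CONSERVED to DIVERGENT within a tier", {
  # selection is monotone in yeast divergence
  for (nle_neo in c(50, 150, 250)) {
    for (nle_y in seq(0, nle_neo, by = 5)) {
      c1 <- tiered_call(nle_neo, nle_y)
      c2 <- tiered_call(nle_neo, max(nle_y - 10, 0))
      if (c1 == "DIVERGENT") expect_true(c2 %in% c("DIVERGENT"))
    }
  }
  # within the top tier, lowering nle_neo shrinks the gap
  expect_equal(tiered_call(280, 230), "CONSERVED")
  expect_equal(tiered_call(260, 230), "CONSERVED")
  # within [100,200]
  expect_equal(tiered_call(190, 155), "CONSERVED")
  expect_equal(tiered_call(150, 115), "CONSERVED")
})

test_that("candidate summaries count both/mixed/either fractions", {
  rec <- tibble::tibble(
    gene_id = paste0("g", 1:5),
    nle_neolecta = 200, nle_sacch = 1, nle_taph = 1,
    call_sacch = c("ABSENT", "ABSENT", "DIVERGENT", "ABSENT", "CONSERVED"),
    call_taph = c("ABSENT", "ABSENT", "DIVERGENT", "DIVERGENT", "ABSENT"),
    pez_present_count = 14, selected = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  s <- summarize_candidates(rec)
  expect_equal(s$n_selected, 4L)
  expect_equal(s$frac_absent_both, 0.5)
  expect_equal(s$frac_divergent_both, 0.25)
  expect_equal(s$frac_mixed_both, 0.25)
  expect_equal(s$frac_absent_both + s$frac_divergent_both +
                 s$frac_mixed_both + s$frac_either_only, 1)

  rec$selected <- FALSE
  expect_warning(s0 <- summarize_candidates(rec), "no selected")
  expect_equal(s0$n_selected, 0L)
})

test_that("reciprocal best-hit presence calls follow the stated rule", {
  expect_equal(reciprocal_presence_call("tgt|x", "src|p1", "src|p1"),
               "PRESENT")
  expect_equal(reciprocal_presence_call("tgt|x", "src|p2", "src|p1"),
               "ABSENT")
  expect_equal(reciprocal_presence_call(NA, NA, "src|p1"), "ABSENT")
})
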