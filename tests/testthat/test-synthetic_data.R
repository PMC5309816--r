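test_that("default species tree has 17 tips, 14 PEZ, and is deterministic", {
  st <- make_species_tree(sim_config(seed = 1))
  expect_equal(length(st$tree$tip.label), 17)
  expect_equal(sum(st$groups$group == "PEZ"), 14)
  expect_true(all(st$tree$edge.length > 0))
  st2 <- make_species_tree(sim_config(seed = 1))
  expect_identical(ape::write.tree(st$tree), ape::write.tree(st2$tree))
})

test_that("a species tree with fewer than 2 PEZ tips is rejected", {
  g <- taxon_groups(c("A", "N", "S"), c("PEZ", "NEOLECTA", "SACCH"))
  cfg <- sim_config(tree_spec = "((A:0.1,N:0.1):0.1,S:0.2);", groups = g)
  expect_error(make_species_tree(cfg), "2 PEZ")
})

test_that("rate zero leaves every tip identical to the root", {
  st <- make_species_tree(sim_config())
  fam <- evolve_family(st$tree, rate = 0, seq_length = 80, seed = 5)
  expect_true(all(fam$sequence == attr(fam, "root_sequence")))
  expect_equal(sum(attr(fam, "edge_subs")), 0)
})

test_that("per-branch substitution fraction follows 1 - exp(-rate*m*t)", {
  tr <- ape::read.tree(text = "(A:0.5,B:0.01);")
  L <- 10000
  fam <- evolve_family(tr, rate = 1, seq_length = L, seed = 11)
  subs <- attr(fam, "edge_subs")
  edge_len <- tr$edge.length[match(1:2, tr$edge[, 2])]  # tips A, B
  for (i in 1:2) {
    p <- 1 - exp(-edge_len[i])
    expect_lt(abs(subs[match(i, attr(fam, "edge")[, 2])] - L * p),
              3 * sqrt(L * p * (1 - p)) + 1)
  }
})

test_that("a very long branch drives identity down to background collision", {
  tr <- ape::read.tree(text = "(A:50,B:0.0001);")
  fam <- evolve_family(tr, rate = 1, seq_length = 5000, seed = 3)
  root <- strsplit(attr(fam, "root_sequence"), "")[[1]]
  a <- strsplit(fam$sequence[fam$tip == "A"], "")[[1]]
  expect_lt(mean(a == root), 0.10)
})

test_that("evolution is deterministic given the seed", {
  st <- make_species_tree(sim_config())
  f1 <- evolve_family(st$tree, 1, seq_length = 60, seed = 42)
  f2 <- evolve_family(st$tree, 1, seq_length = 60, seed = 42)
  expect_identical(f1$sequence, f2$sequence)
  expect_error(evolve_family(st$tree, -1, seq_length = 60, seed = 1),
               "non-negative")
})

test_that("hit surrogate matches direct BLOSUM62 self-score on identity", {
  # a homopolymer of alanines: self score = length * B[A,A] = 300 * 4
  st <- make_species_tree(sim_config())
  seqs <- tibble::tibble(
    family_id = "fam0001",
    tip = c("Ncra", "Nirr"), species = c("Ncra", "Nirr"),
    sequence = strrep("A", 300))
  sim <- list(sequences = seqs)
  h <- emulate_hit_table(sim, scale_c = 0.3, query_tip = "Ncra")
  expect_equal(h$bitscore, 1200)
  expect_equal(h$evalue, 10^(-0.3 * 1200))
})

test_that("lost copies emit no hit and scale_c 0 gives unit e-values", {
  cfg <- sim_config(n_families = 10, seed = 2)
  sim <- simulate_families(cfg)
  h <- emulate_hit_table(sim, scale_c = cfg$scale_c)
  lost <- sim$presence[!sim$presence$present, ]
  if (nrow(lost) > 0) {
    expect_equal(nrow(dplyr::inner_join(
      h, lost, by = c(query_id = "family_id",
                      subject_species = "species"))), 0)
  }
  h0 <- emulate_hit_table(sim, scale_c = 0)
  expect_true(all(h0$evalue == 1))
})

test_that("divergent families score yeasts below PEZ in surrogate nle", {
  sim <- simulate_families(sim_config(n_families = 30, seed = 8))
  h <- emulate_hit_table(sim)
  h$nle <- neg_log10_evalue(h$evalue)
  div <- sim$truth$family_id[sim$truth$class == "divergent"]
  hd <- h[h$query_id %in% div, ]
  yeast <- hd$nle[hd$subject_species %in% c("Scer", "Spom")]
  pez <- hd$nle[hd$subject_species %in%
                  group_species_test(sim$groups, "PEZ")]
  expect_lt(median(yeast), median(pez))
})

test_that("plant_pts1 plants exactly round(fraction*N) and spoils the rest", {
  set.seed(1)
  prot <- tibble::tibble(id = paste0("p", 1:100),
                         sequence = replicate(100, random_seq(50)))
  out <- plant_pts1(prot, 0.07, seed = 9)
  expect_equal(sum(out$planted), 7)
  expect_true(all(has_pts1(out$sequence[out$planted])))
  expect_false(any(has_pts1(out$sequence[!out$planted])))
  tri <- substr(out$sequence[out$planted], 48, 50)
  expect_true(all(grepl("^[SAC][KRH]L$", tri)))

  none <- plant_pts1(prot, 0, seed = 9)
  expect_equal(sum(has_pts1(none$sequence)), 0)
})

test_that("short proteins are skipped with a warning and never planted", {
  prot <- tibble::tibble(id = c("a", "b"), sequence = c("ML", random_seq(30)))
  expect_warning(out <- plant_pts1(prot, 0.5, seed = 1), "shorter")
  expect_false(out$planted[1])
})

test_that("fixture bundles are complete and seed-reproducible", {
  cfg <- sim_config(n_families = 6, seed = 4)
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- write_fixture_bundle(cfg, d1)
  m2 <- write_fixture_bundle(cfg, d2)
  expect_gte(nrow(m1), 6)
  expect_setequal(unique(m1$role),
                  c("species_tree", "taxon_groups", "alignment", "gene_tree",
                    "hit_table", "proteome", "presence_matrix", "truth"))
  expect_identical(m1$md5, m2$md5)
  expect_error(write_fixture_bundle(sim_config(n_families = 0), tempfile()),
               "n_families")
})

test_that("simulated presence matrices are Dollo-consistent single origins", {
  sim <- simulate_families(sim_config(n_families = 40, seed = 6))
  # every family is present in all PEZ tips and Neolecta (losses only in
  # yeasts), so the minimal reconstruction has a gain at the root
  for (fid in sim$truth$family_id[sim$truth$class == "lost"][1:5]) {
    pres <- sim$presence[sim$presence$family_id == fid &
                           sim$presence$present, ]
    g <- dollo_gain_node(sim$tree, pres$species)
    expect_equal(g, length(sim$tree$tip.label) + 1L)  # root
  }
})
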