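test_that("pair scores follow BLOSUM62 with a flat gap penalty", {
  expect_equal(pair_score("A", "A"), 4)
  expect_equal(pair_score("A", "R"), -1)
  expect_equal(pair_score("A", "-"), -3)
  expect_equal(pair_score("-", "A", gap_penalty = 5), -5)
  expect_true(is.na(pair_score("-", "-")))
  expect_equal(pair_score("X", "A"), -3)  # ambiguity scores as gap
  expect_error(pair_score("1", "A"), "alphabet")
})

test_that("trimming drops gappy columns and restores a -cons floor", {
  # 10 rows; column 1 has 3 gaps (0.7 < 0.8, dropped), column 2 has 2
  # (0.8 >= 0.8, kept)
  rows <- c(rep("AA", 5), "-A", "-A", "-A", "A-", "A-")
  species <- paste0("P", 1:10)
  g <- taxon_groups(species, rep("PEZ", 10))
  aln <- grouped_alignment(species, species, rows, g)
  tr <- trim_alignment(aln)
  expect_equal(tr$kept, 2L)

  # every column fails the threshold (3 gaps each, staggered so no row is
  # all-gap): exactly ceil(0.5 * 10) = 5 restored, leftmost first on ties
  m <- matrix("A", 10, 10)
  for (j in 1:10) m[(c(j, j + 1, j + 2) - 1) %% 10 + 1, j] <- "-"
  rows2 <- apply(m, 1, paste, collapse = "")
  aln2 <- grouped_alignment(species, species, rows2, g)
  tr2 <- trim_alignment(aln2)
  expect_equal(tr2$kept, 1:5)
})

test_that("column scores match the worked examples", {
  # Neolecta A, PEZ {A, A}, SACCH {R}: x = 4, y = -1, raw = 5
  aln <- make_aln("A", c("A", "A"), "R")
  cs <- column_scores(aln)
  expect_equal(cs$x, 4)
  expect_equal(cs$y, -1)
  expect_equal(cs$raw, 5)

  # Neolecta A, PEZ {A, -}, SACCH {-}: x = (4-3)/2, y = -3, raw = 3.5
  aln2 <- make_aln("AA", c("AA", "-A"), "-A")
  cs2 <- column_scores(aln2)
  expect_equal(cs2$x[1], 0.5)
  expect_equal(cs2$y[1], -3)
  expect_equal(cs2$raw[1], 3.5)
  expect_equal(cs2$missing_in_yeast, c(TRUE, FALSE))

  # Neolecta gapped: no neolecta_pos
  aln3 <- make_aln("-A", c("AA", "AA"), "RR")
  cs3 <- column_scores(aln3)
  expect_true(is.na(cs3$neolecta_pos[1]))
  expect_equal(cs3$neolecta_pos[2], 1)

  g0 <- taxon_groups(c("Nirr", "Yst1"), c("NEOLECTA", "SACCH"))
  aln0 <- grouped_alignment(c("Nirr", "Yst1"), c("Nirr", "Yst1"),
                            c("A", "R"), g0)
  expect_error(column_scores(aln0), "PEZ")
})

test_that("column scores equal brute-force pair enumeration on random data", {
  set.seed(123)
  alphabet <- c(AMINO_ACIDS, "-")
  n_pez <- 4
  n_sac <- 3
  L <- 1000
  mk_row <- function() paste(sample(alphabet, L, TRUE,
                                    prob = c(rep(1, 20), 6)), collapse = "")
  neo <- mk_row()
  pez <- replicate(n_pez, mk_row())
  sac <- replicate(n_sac, mk_row())
  aln <- make_aln(neo, pez, sac)
  cs <- column_scores(aln)
  neo_c <- strsplit(neo, "")[[1]]
  pez_c <- do.call(rbind, strsplit(pez, ""))
  sac_c <- do.call(rbind, strsplit(sac, ""))
  for (j in sample(L, 200)) {
    expect_equal(cs$raw[j], bf_column_score(neo_c[j], pez_c[, j], sac_c[, j]))
  }
})

test_that("swapping PEZ and SACCH labels negates every raw score", {
  set.seed(5)
  alphabet <- c(AMINO_ACIDS, "-")
  mk_row <- function() paste(sample(alphabet, 300, TRUE), collapse = "")
  neo <- mk_row()
  pez <- replicate(3, mk_row())
  sac <- replicate(3, mk_row())
  a1 <- make_aln(neo, pez, sac)
  a2 <- make_aln(neo, sac, pez)
  expect_equal(column_scores(a1)$raw, -column_scores(a2)$raw)
})

test_that("Savitzky-Golay reproduces polynomials and preserves NA masks", {
  expect_equal(smooth_profile(rep(2, 100)), rep(2, 100))
  ramp <- seq(0, 5, length.out = 120)
  expect_equal(smooth_profile(ramp), ramp, tolerance = 1e-9)
  t <- seq(-3, 3, length.out = 201)
  y <- t^5 - 2 * t^3 + t
  sm <- smooth_profile(y)
  expect_equal(sm, y, tolerance = 1e-8)

  y2 <- ramp
  y2[c(10, 50)] <- NA
  sm2 <- smooth_profile(y2)
  expect_true(all(is.na(sm2[c(10, 50)])))
  expect_false(anyNA(sm2[-c(10, 50)]))

  expect_error(smooth_profile(1:100, window = 5, order = 5), "order")
  expect_warning(smooth_profile(1:5, window = 41, order = 5), "too short")
})

test_that("short inputs shrink the window instead of padding", {
  # length 21 < window 41: largest odd window that fits is 21
  t <- seq(-1, 1, length.out = 21)
  y <- 3 * t^2 + t
  expect_equal(smooth_profile(y, window = 41, order = 5), y,
               tolerance = 1e-9)
})

test_that("the null band is symmetric, deterministic and validated", {
  nb1 <- null_band(5, 5, n_samples = 20000, seed = 3)
  nb2 <- null_band(5, 5, n_samples = 20000, seed = 3)
  expect_identical(nb1$q_low, nb2$q_low)
  expect_identical(nb1$q_high, nb2$q_high)
  expect_lt(abs(nb1$mean), 0.05)  # symmetric construction: mean near 0
  expect_lte(nb1$q_low, nb1$q_high)
  expect_error(null_band(0, 5, 20000, 1), "group sizes")
  expect_error(null_band(5, 5, 500, 1), "n_samples")
})

test_that("conservation flags require identity in both reference groups", {
  expect_true(conservation_flags(make_aln("A", c("A", "A", "A"), "A")))
  expect_false(conservation_flags(make_aln("A", c("A", "A", "R"), "A")))
  # Neolecta gapped, or a reference group with no residue, never flags
  fl <- conservation_flags(make_aln("-A", c("AA", "AA"), "AA"))
  expect_equal(fl, c(FALSE, TRUE))
  fl2 <- conservation_flags(make_aln("AA", c("AA", "AA"), "A-"))
  expect_equal(fl2, c(TRUE, FALSE))
})

test_that("region lengths count non-gap residues in a column interval", {
  aln <- make_aln("A--AL", c("AAAAL", "A---L"), "AA---")
  rl <- region_lengths(aln, c(1, 5))
  expect_equal(rl$length, c(3, 5, 2, 2))
  expect_equal(region_lengths(aln, c(3, 3))$length, c(0, 1, 0, 0))
  expect_error(region_lengths(aln, c(4, 2)), "inverted")
})

test_that("mann_whitney_u reproduces exact and approximate branches", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 1 / 20)
  expect_equal(mw$method, "exact")

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3), alternative = "two.sided")
  expect_equal(same$p_value, 1)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact enumeration oracle agrees with the implementation", {
  set.seed(31)
  for (alt in c("less", "greater", "two.sided")) {
    a <- sample(1:100, 4)
    b <- sample(101:200, 5) - 100.5  # no ties with a
    mw <- mann_whitney_u(a, b, alternative = alt)
    expect_equal(mw$p_value, bf_mw_exact_p(a, b, alt), tolerance = 1e-12)
  }
})

test_that("profiles lean positive when PEZ matches Neolecta and vice versa", {
  set.seed(10)
  L <- 200
  neo <- random_seq(L)
  rnd <- function() random_seq(L)
  # SACCH rows identical to Neolecta, PEZ random: scores mostly negative
  aln_neg <- make_aln(neo, c(rnd(), rnd()), c(neo, neo))
  pr_neg <- build_profile(aln_neg, n_nulls = 2000, seed = 2)
  expect_gt(mean(tidy(pr_neg)$smoothed < 0, na.rm = TRUE), 0.8)
  # PEZ rows identical to Neolecta: scores mostly positive
  aln_pos <- make_aln(neo, c(neo, neo), c(rnd(), rnd()))
  pr_pos <- build_profile(aln_pos, n_nulls = 2000, seed = 2)
  expect_gt(mean(tidy(pr_pos)$smoothed > 0, na.rm = TRUE), 0.8)
  # profile indexed by ungapped Neolecta length
  expect_equal(nrow(tidy(pr_pos)), L)
  g <- glance(pr_pos)
  expect_equal(g$n_positions, L)
  expect_gt(g$frac_positive, 0.8)
})

test_that("profiles stay positive on rate-inflated synthetic families", {
  st <- make_species_tree(sim_config())
  ok <- 0L
  for (i in 1:20) {
    fam <- evolve_family(st$tree, rate = 1,
                         branch_multipliers = c(Scer = 5, Spom = 5),
                         seq_length = 120, seed = 400 + i)
    aln <- grouped_alignment(fam$tip, fam$tip, fam$sequence, st$groups)
    pr <- build_profile(aln, n_nulls = 2000, seed = i)
    if (mean(tidy(pr)$smoothed > 0, na.rm = TRUE) >= 0.8) ok <- ok + 1L
  }
  expect_gte(ok, 16)  # mean profile positive over >=80% of positions
})
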