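---
title: "Methods: differential conservation scanning with divscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential conservation scanning with divscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscan)
```

## The scientific question

Complex multicellularity (CM) in the Ascomycota is concentrated in the
Pezizomycotina, while budding yeast (*Saccharomyces cerevisiae*,
Saccharomycotina) and fission yeast (*Schizosaccharomyces pombe*,
Taphrinomycotina) represent independently simplified lineages. The
multicellular genus *Neolecta*, nested among the otherwise yeast-like
Taphrinomycotina, makes a differential screen possible: genes conserved in
*Neolecta* and the Pezizomycotina but lost or strongly divergent in both
yeasts are candidates for CM-associated functions. divscan implements the
computational machinery of that screen as composable, tested R functions.

## The candidate filter

Homology-search strength is summarised as `nle = -log10(e-value)`, capped
at 300 because search tools report `0.0` below their floating-point floor
(`neg_log10_evalue()`). For each query gene:

1. **Presence criterion** — the gene must have a hit (e-value at or below
   1e-3) in at least half of the Pezizomycotina panel, i.e. 7 of 14 species
   in the original design (`pez_presence()`; expressed as a fraction so
   other panels work).
2. **Tiered differential** — the best yeast hit must trail the best
   *Neolecta* hit by at least 60, 40 or 20 nle units when the *Neolecta*
   nle falls in (200, Inf), [100, 200] or [1, 100) respectively
   (`tiered_call()`). Below nle 1 a gene is ineligible; a yeast with no
   surviving hit is called `ABSENT`, a sufficient gap `DIVERGENT`,
   otherwise `CONSERVED`. Boundary values 100 and 200 belong to the middle
   tier, matching the printed interval notation.
3. **Selection** — a gene is selected when the presence criterion holds,
   the *Neolecta* hit is eligible, and at least one yeast is `ABSENT` or
   `DIVERGENT`. We read "in either yeast" as a logical OR for selection
   while retaining per-yeast calls, because the downstream summary reports
   both-yeast fractions (`summarize_candidates()`).

Ties among equal best e-values break by higher bitscore, then
lexicographically smallest subject id — an arbitrary but deterministic
rule the upstream tools do not fix. Whether the original screen applied
the presence criterion before or after the *Neolecta* range check is not
decidable from the description; divscan applies both conjunctively.

Reciprocal-best-hit presence calls for curated developmental genes
(`reciprocal_presence_call()`) are a classification over precomputed
forward (e ≤ 1e-5) and reciprocal (e ≤ 1e-3) hit tables; divscan never
runs BLAST or HMMER itself, it only consumes their tabular output.

## The divergence score s(x)

Given a gene tree with branch lengths in substitutions/site, let `d(x)`
be the path distance from tip `x` to the most recent common ancestor of
the Pezizomycotina tips and `p` the number of Pezizomycotina tips present;
then

> s(x) = d(x) − (1/p) Σᵢ d(pezᵢ).

Pezizomycotina scores sum to zero by construction; positive scores mark
lineages more divergent than the Pezizomycotina average. ML gene trees
arrive unrooted; when the non-Pezizomycotina tips form a split, divscan
roots there first. Non-monophyletic Pezizomycotina tips (topology noise in
real gene trees) are handled by taking the MRCA with a warning rather than
failing. `greyscale()` maps scores affinely onto [0, 1] (lighter = more
divergent), clipped, with the non-Pezizomycotina score range as default
anchors.

## The similarity profile

For every alignment column, `x` is the mean BLOSUM62 pair score between
the single *Neolecta* residue and each Pezizomycotina row, `y` the same
against the Saccharomycotina rows, and the signal is `raw = x − y`
(`column_scores()`). Design choices where the original description leaves
room:

* "Sum-of-pairs" is interpreted as *Neolecta*-versus-group pairs averaged
  per pair, so `x` and `y` are comparable between a 14-member and a
  5-member group.
* A residue against a gap scores −3 (the stated flat gap penalty);
  gap–gap pairs carry no signal and are excluded; a column whose group
  pairs are all gap–gap is undefined and interpolated before smoothing,
  then masked.
* `X` and other ambiguity codes score as gaps, since BLOSUM62 ambiguity
  handling is not part of the method's description.

Profiles are smoothed with a Savitzky–Golay filter (window 41, order 5,
`smooth_profile()`). Edges are handled by refitting the polynomial to the
truncated window — no phantom padding values — which preserves the
filter's defining property of reproducing polynomials up to the fitted
order. Sequences shorter than the window shrink it to the largest odd
length that fits.

The insignificance band (`null_band()`) is the 5th–95th percentile range
of raw scores over random gap-free columns drawn i.i.d. from the BLOSUM62
background amino-acid frequencies (the canonical 20-value marginal
distribution of the matrix, embedded as a constant). The production
default is 1,000,000 columns; the test suite and worked examples use
10^4–10^5, where the band quantiles are already stable to two decimals. A
smoothed score above the band marks significant *Neolecta*–Pezizomycotina
similarity excess, below it the yeast-ward excess — one-sided per
direction, matching the "higher than 95% of random scores" rule and its
mirror.

Residues flagged `conserved` require the *Neolecta* residue to match at
least 70% of non-gap residues in *both* reference groups; the threshold is
configurable because the original figure legend names no value.
`region_lengths()` counts non-gap residues per row over a column interval,
and `mann_whitney_u()` tests group-wise length contraction — exact by full
enumeration for n ≤ 12 without ties, otherwise the normal approximation
with tie and continuity corrections (delegated to `stats::wilcox.test()`;
the package's test suite checks both branches against an independent
enumeration).

Alignment trimming (`trim_alignment()`) mirrors the `-gt 0.8 -cons 0.5`
rule: keep columns with at least 80% non-gap characters, and if fewer than
half the columns survive, restore the highest-occupancy columns (leftmost
first on ties) up to exactly half. The restoration order is not documented
by the trimming tool's description; occupancy ranking is our assumption.

## Dollo gain/loss mapping

Under Dollo parsimony a family arises exactly once and is never regained.
The gain node is the MRCA of the tips carrying the family; the minimal
loss set places one loss on each edge whose child subtree contains no
carrier while its parent lies on the subtree spanning the carriers
(`dollo_gain_node()`, `dollo_losses()`). `gain_loss_map()` aggregates
per-node gains, losses and net change over a presence/absence matrix. The
test suite verifies minimality and uniqueness against exhaustive search
over every rooted topology with up to six tips and every presence pattern.

## PTS1 scanning

A protein is predicted to carry the peroxisomal targeting signal 1 when
its C-terminal tripeptide matches `[SAC][KRH]L` (`has_pts1()`). A single
trailing stop `*` is stripped first — predicted proteomes often carry
stops — and any other non-standard character in the last three positions
prevents a match. `pts1_group_ratio()` compares mean per-proteome
percentages between taxon groups, the statistic behind the roughly
two-fold PTS1 depletion in Ascomycota yeasts relative to the
Pezizomycotina.

## The synthetic-data generator

Because the original inputs (a genome assembly plus 41 public proteomes
and external search-tool runs) are not reproducible at desk scale, divscan
ships a generator whose ground truth exercises every stage
(`sim_config()`, `simulate_families()`, `write_fixture_bundle()`).

* **Tree.** A fixed 17-taxon topology: 14 Pezizomycotina tips in seven
  shallow cherries (within-clade pairwise identity ≈ 85% at
  `base_rate = 1`, the regime the tiered filter operates in), *Neolecta*
  plus fission yeast as a Taphrinomycotina clade, budding yeast sister to
  the Pezizomycotina.
* **Families.** 200 families by default, split 50/25/25 into `conserved`
  (clock-like), `divergent` (both yeast terminal branches inflated ×5) and
  `lost` (each yeast loses its copy with probability 1). Sequences evolve
  site-independently — substitution probability `1 − exp(−rate·m·t)` per
  branch, replacements from the BLOSUM62 background excluding the current
  residue, no indels — so tip sequences stay positionally aligned and one
  simulation feeds both the hit-table filter and the alignment profile.
  Indel realism is orthogonal to every implemented statistic.
* **Hit tables.** Real e-values cannot be generated without a search tool,
  so the generator emits a declared surrogate:
  `-log10(e) = max(0, 0.3 · S)` with `S` the ungapped pairwise BLOSUM62
  score against the *Neurospora*-role query tip. Only its monotone
  decrease with divergence matters for recovery tests. Non-Pezizomycotina
  depths are set so that conserved-family comparisons saturate the nle cap
  (as real strong hits reporting e-value `0.0` do), making the conserved
  tier gap identically zero, while the ×5 multiplier places divergent-
  family yeast hits far below the tier thresholds. This is what makes the
  generator's recovery contract sharp: all divergent and lost families are
  selected, no conserved family is.
* **PTS1 and presence.** `plant_pts1()` plants exactly `round(f·N)`
  matching C-termini and rewrites every other terminus to a non-match, so
  planted prevalences are recovered exactly. Presence matrices follow the
  loss events and are single-origin (Dollo-consistent) by construction.

What passing tests on this generator do **not** show: robustness to indel
misalignment, to non-stationary amino-acid composition, to paralogy (the
generator has exactly one copy per species), or to real e-value noise.
They demonstrate the correctness of the statistics, not the biological
difficulty of the original inputs.

## The pipeline driver

`run_pipeline()` executes simulate → candidates → divergence → profile →
dollo → pts1 → report from a single flat configuration and one global
seed, expanded into fixed per-stage substreams so any stage can be rerun
reproducibly. Every output TSV carries a comment header echoing stage,
seed and parameters, and reruns are byte-identical. The package's
functions are the interface; there is no shell wrapper, since users of an
analysis package of this kind work in R. Problem sizes used by the test
suite (for example 10^4–10^5 null columns, 12–40-family pipelines,
200-family recovery runs) are the package's desk-scale defaults for
exercising the statistics; the generator's scientific defaults (200
families, multiplier 5, 10^6 null columns) are stated above.

## Known limitations

* The e-value surrogate is linear in the alignment score; real e-values
  depend on database size and composition. Only monotonicity is relied on.
* `s(x)` uses literal path distance; for non-Pezizomycotina species the
  path may traverse the gene-tree root, so rooting errors propagate into
  the score (mitigated by the PEZ-split rooting rule).
* Dollo parsimony forbids regain by assumption; horizontally re-acquired
  families would be misattributed.
* The Mann–Whitney exact branch requires tie-free samples; tied length
  data fall back to the corrected normal approximation.
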