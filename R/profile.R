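#' Trim alignment columns by gap fraction
#'
#' Keeps columns whose non-gap fraction is at least `gap_threshold`. If
#' fewer than `min_cons * column_count` columns survive, columns are
#' restored in order of decreasing non-gap fraction (ties: leftmost first)
#' until exactly `ceiling(min_cons * column_count)` are kept. This mirrors
#' the `-gt 0.8 -cons 0.5` trimming applied upstream of tree inference.
#'
#' @param aln A `grouped_alignment`.
#' @param gap_threshold Minimal non-gap fraction to keep a column.
#' @param min_cons Minimal fraction of columns to retain.
#' @return List: `aln` (trimmed `grouped_alignment`) and `kept` (strictly
#'   increasing original column indices).
#' @export
trim_alignment <- function(aln, gap_threshold = 0.8, min_cons = 0.5) {
  if (nrow(aln) == 0) stop("empty alignment", call. = FALSE)
  stopifnot(gap_threshold > 0, gap_threshold <= 1,
            min_cons > 0, min_cons <= 1)
  m <- aln_matrix(aln)
  nongap <- colMeans(m != "-")
  keep <- nongap >= gap_threshold
  floor_n <- ceiling(min_cons * ncol(m))
  if (sum(keep) < floor_n) {
    ord <- order(-nongap, seq_along(nongap))  # best first, leftmost on ties
    keep <- rep(FALSE, ncol(m))
    keep[ord[seq_len(floor_n)]] <- TRUE
  }
  kept <- which(keep)
  trimmed <- new_grouped_alignment(
    aln$seq_id, aln$species, aln$group,
    apply(m[, kept, drop = FALSE], 1, paste, collapse = ""))
  list(aln = trimmed, kept = kept)
}

#' Per-column group-differential sum-of-pairs scores
#'
#' For every alignment column, `x` is the mean BLOSUM62 pair score between
#' the single *Neolecta* residue and each PEZ row, `y` the same against the
#' SACCH rows, and `raw = x - y`. Gap-gap pairs are excluded from the means;
#' a column where every pair of a group is gap-gap has an undefined score
#' (`NA`). Columns where the *Neolecta* row is gapped carry no `neolecta_pos`.
#'
#' @param aln A `grouped_alignment` with exactly one NEOLECTA row, and at
#'   least one PEZ and one SACCH row.
#' @param gap_penalty Residue-vs-gap penalty (default 3).
#' @return Tibble (`column_index`, `neolecta_pos`, `x`, `y`, `raw`,
#'   `missing_in_yeast`).
#' @export
column_scores <- function(aln, gap_penalty = 3) {
  neo_rows <- which(aln$group == "NEOLECTA")
  pez_rows <- which(aln$group == "PEZ")
  sac_rows <- which(aln$group == "SACCH")
  if (length(neo_rows) != 1) {
    stop("exactly one NEOLECTA row required, found ", length(neo_rows),
         call. = FALSE)
  }
  if (length(pez_rows) == 0 || length(sac_rows) == 0) {
    stop("need at least one PEZ and one SACCH row", call. = FALSE)
  }
  m <- aln_matrix(aln)
  nc <- ncol(m)
  neo <- m[neo_rows, ]
  group_mean <- function(rows) {
    sc <- matrix(vapply(rows, function(r) pair_score(neo, m[r, ],
                                                     gap_penalty),
                        numeric(nc)), nrow = nc)
    res <- rowMeans(sc, na.rm = TRUE)
    res[rowSums(!is.na(sc)) == 0] <- NA_real_
    res
  }
  x <- group_mean(pez_rows)
  y <- group_mean(sac_rows)
  neo_norm <- normalize_symbols(neo)
  pos <- cumsum(neo_norm != "-")
  pos[neo_norm == "-"] <- NA_integer_
  sac_gap <- vapply(seq_len(nc), function(j) {
    all(normalize_symbols(m[sac_rows, j]) == "-")
  }, logical(1))
  tibble::tibble(column_index = seq_len(nc), neolecta_pos = pos,
                 x = x, y = y, raw = x - y, missing_in_yeast = sac_gap)
}

# Savitzky-Golay coefficient row for evaluating the fitted polynomial at
# offset 0, given window offsets `t`.
sg_coef <- function(t, order) {
  u <- t / max(abs(t), 1)  # scale offsets for conditioning
  X <- outer(u, 0:order, "^")
  qr.solve(X, diag(length(t)))[1, ]
}

#' Savitzky-Golay smoothing with truncated-window edges
#'
#' Least-squares local polynomial smoother (default window 41, order 5).
#' Positions where the input is `NA` are linearly interpolated before
#' smoothing and masked back to `NA` afterwards. Near the ends the window is
#' truncated to the available samples and the polynomial refit (no padding).
#' If the input is shorter than the window, the window shrinks to the
#' largest odd length that fits; when even that cannot hold `order + 2`
#' samples, smoothing is skipped with a warning.
#'
#' @param values Numeric vector (may contain `NA`).
#' @param window Odd window length (default 41).
#' @param order Polynomial order (default 5); must be < window.
#' @return Numeric vector of smoothed values, same length and `NA` pattern.
#' @export
smooth_profile <- function(values, window = 41, order = 5) {
  if (order >= window) stop("order must be < window", call. = FALSE)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  n <- length(values)
  nas <- is.na(values)
  if (all(nas)) return(values)
  x <- values
  if (any(nas)) {
    idx <- which(!nas)
    x <- stats::approx(idx, values[idx], xout = seq_len(n), rule = 2)$y
  }
  if (n < window) {
    window <- if (n %% 2 == 1) n else n - 1
    if (window < order + 2) {
      warning("input too short to smooth (", n, " samples); returning input")
      out <- values
      return(out)
    }
  }
  h <- (window - 1) / 2
  center <- sg_coef(-h:h, order)
  out <- stats::filter(x, rev(center), sides = 2)
  out <- as.numeric(out)
  for (i in seq_len(min(h, n))) {        # leading edge: truncated window
    t <- (max(1, i - h):min(n, i + h)) - i
    out[i] <- sum(sg_coef(t, order) * x[i + t])
  }
  for (i in seq(max(1, n - h + 1), n)) { # trailing edge
    t <- (max(1, i - h):min(n, i + h)) - i
    out[i] <- sum(sg_coef(t, order) * x[i + t])
  }
  out[nas] <- NA_real_
  out
}

#' Monte-Carlo null band for the differential score
#'
#' Draws random alignment columns — one *Neolecta* residue plus `n_pez` PEZ
#' and `n_sacch` SACCH residues, all i.i.d. from the BLOSUM62 background
#' frequencies, no gaps — scores them exactly as [column_scores()], and
#' returns the 5th and 95th percentiles. A smoothed score outside the band
#' is considered significant (above: excess *Neolecta*-Pezizomycotina
#' similarity; below: excess yeast similarity).
#'
#' @param n_pez,n_sacch Group sizes (>= 1).
#' @param n_samples Number of random columns (default 1e6).
#' @param seed Integer seed.
#' @return A `null_band` list: `q_low`, `q_high`, `mean`, `n_samples`,
#'   `seed`.
#' @export
null_band <- function(n_pez, n_sacch, n_samples = 1000000, seed = 1) {
  if (n_pez < 1 || n_sacch < 1) stop("group sizes must be >= 1",
                                     call. = FALSE)
  if (n_samples < 1000) stop("n_samples must be >= 1000", call. = FALSE)
  raw <- with_seed(seed, null_scores(n_pez, n_sacch, n_samples))
  q <- unname(quantile(raw, c(0.05, 0.95)))
  structure(list(q_low = q[1], q_high = q[2], mean = mean(raw),
                 n_samples = n_samples, seed = seed),
            class = "null_band")
}

# Raw differential scores of random background columns (used by null_band
# and by coverage checks). Chunked to bound memory.
null_scores <- function(n_pez, n_sacch, n_samples, chunk = 100000L) {
  B <- blosum62()
  bg <- blosum62_background()
  out <- numeric(n_samples)
  done <- 0L
  while (done < n_samples) {
    m <- min(chunk, n_samples - done)
    neo <- sample.int(20L, m, replace = TRUE, prob = bg)
    score_group <- function(k) {
      g <- matrix(sample.int(20L, m * k, replace = TRUE, prob = bg),
                  nrow = m)
      rowMeans(matrix(B[cbind(rep(neo, k), as.vector(g))], nrow = m))
    }
    out[done + seq_len(m)] <- score_group(n_pez) - score_group(n_sacch)
    done <- done + m
  }
  out
}

#' Flag residues conserved across *Neolecta* and both reference groups
#'
#' A column is flagged when the *Neolecta* residue is a non-gap identical to
#' at least `min_fraction` of the non-gap residues in the PEZ group **and**
#' in the SACCH group (groups with no non-gap residue cannot satisfy this).
#'
#' @param aln A `grouped_alignment` (one NEOLECTA row).
#' @param min_fraction Identity fraction threshold in (0.5, 1\] (default
#'   0.7).
#' @return Logical vector, one element per alignment column.
#' @export
conservation_flags <- function(aln, min_fraction = 0.7) {
  stopifnot(min_fraction > 0.5, min_fraction <= 1)
  m <- aln_matrix(aln)
  neo <- normalize_symbols(m[which(aln$group == "NEOLECTA")[1], ])
  frac_ok <- function(rows, j) {
    v <- normalize_symbols(m[rows, j])
    v <- v[v != "-"]
    length(v) > 0 && mean(v == neo[j]) >= min_fraction
  }
  pez_rows <- which(aln$group == "PEZ")
  sac_rows <- which(aln$group == "SACCH")
  vapply(seq_len(ncol(m)), function(j) {
    neo[j] != "-" && frac_ok(pez_rows, j) && frac_ok(sac_rows, j)
  }, logical(1))
}

#' Ungapped region lengths per sequence
#'
#' Counts non-gap characters within a 1-based inclusive column interval for
#' every alignment row — the per-species lengths of a domain or linker
#' region, for contraction tests.
#'
#' @param aln A `grouped_alignment`.
#' @param column_interval Integer vector `c(from, to)`.
#' @return Tibble (`seq_id`, `species`, `group`, `length`).
#' @export
region_lengths <- function(aln, column_interval) {
  from <- column_interval[1]; to <- column_interval[2]
  if (from > to) stop("inverted column interval", call. = FALSE)
  if (from < 1 || to > column_count(aln)) {
    stop("interval outside alignment columns", call. = FALSE)
  }
  seg <- substr(aln$sequence, from, to)
  tibble::tibble(seq_id = aln$seq_id, species = aln$species,
                 group = aln$group,
                 length = nchar(gsub("-", "", seg)))
}

#' Mann-Whitney U test
#'
#' `U` counts pairs where an `a` observation exceeds a `b` observation, with
#' half-weight for ties. The p-value is exact (full enumeration of rank
#' arrangements) when `length(a) + length(b) <= 12` and there are no ties,
#' and otherwise uses the normal approximation with tie and continuity
#' corrections.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (stochastic
#'   ordering of `a` relative to `b`).
#' @return One-row tibble (`U`, `p_value`, `method`, `alternative`, `n_a`,
#'   `n_b`).
#' @export
mann_whitney_u <- function(sample_a, sample_b,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(sub("^two-sided$", "two.sided", alternative[1]),
                           c("two.sided", "less", "greater"))
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- any(duplicated(c(sample_a, sample_b)))
  exact <- (length(sample_a) + length(sample_b) <= 12) && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    sample_a, sample_b, alternative = alternative, exact = exact,
    correct = !exact))
  tibble::tibble(U = unname(wt$statistic), p_value = wt$p.value,
                 method = if (exact) "exact" else "normal_approximation",
                 alternative = alternative,
                 n_a = length(sample_a), n_b = length(sample_b))
}

#' Build the full similarity profile of a grouped alignment
#'
#' Composition of [column_scores()], mapping to ungapped *Neolecta*
#' positions, [smooth_profile()], [null_band()] and [conservation_flags()].
#' The profile is indexed by *Neolecta* position (columns where *Neolecta*
#' is gapped drop out); undefined raw scores are interpolated for smoothing
#' and masked afterwards.
#'
#' @param aln A `grouped_alignment` (one NEOLECTA row, >= 1 PEZ and SACCH).
#' @param window,order Savitzky-Golay parameters (defaults 41, 5).
#' @param n_nulls Random columns for the null band (default 1e6).
#' @param gap_penalty Residue-vs-gap penalty (default 3).
#' @param min_fraction Conservation-flag identity threshold (default 0.7).
#' @param seed Seed for the null band.
#' @return A `similarity_profile` object; see [tidy.similarity_profile()].
#' @export
build_profile <- function(aln, window = 41, order = 5, n_nulls = 1000000,
                          gap_penalty = 3, min_fraction = 0.7, seed = 1) {
  cs <- column_scores(aln, gap_penalty = gap_penalty)
  cons <- conservation_flags(aln, min_fraction = min_fraction)
  keep <- !is.na(cs$neolecta_pos)
  prof <- cs[keep, ]
  prof$conserved <- cons[keep]
  # rows are already in increasing neolecta_pos order (cumsum construction)
  prof$smoothed <- smooth_profile(prof$raw, window = window, order = order)
  band <- null_band(sum(aln$group == "PEZ"), sum(aln$group == "SACCH"),
                    n_samples = n_nulls, seed = seed)
  prof$q_low <- band$q_low
  prof$q_high <- band$q_high
  prof$significant <- !is.na(prof$smoothed) &
    (prof$smoothed > band$q_high | prof$smoothed < band$q_low)
  structure(list(
    profile = prof[, c("neolecta_pos", "column_index", "raw", "smoothed",
                       "q_low", "q_high", "significant", "conserved",
                       "missing_in_yeast")],
    band = band,
    params = list(window = window, order = order, n_nulls = n_nulls,
                  gap_penalty = gap_penalty, min_fraction = min_fraction,
                  seed = seed)
  ), class = "similarity_profile")
}
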