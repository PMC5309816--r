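#' Tidy a similarity profile
#'
#' @param x A `similarity_profile` from [build_profile()].
#' @param ... Unused.
#' @return Tibble with one row per ungapped *Neolecta* position
#'   (`neolecta_pos`, `column_index`, `raw`, `smoothed`, `q_low`, `q_high`,
#'   `significant`, `conserved`, `missing_in_yeast`).
#' @method tidy similarity_profile
#' @export
tidy.similarity_profile <- function(x, ...) {
  x$profile
}

#' One-row summary of a similarity profile
#'
#' @param x A `similarity_profile`.
#' @param ... Unused.
#' @return Tibble (`n_positions`, `frac_positive`, `frac_significant`,
#'   `frac_conserved`, `q_low`, `q_high`).
#' @method glance similarity_profile
#' @export
glance.similarity_profile <- function(x, ...) {
  p <- x$profile
  tibble::tibble(
    n_positions = nrow(p),
    frac_positive = mean(p$smoothed > 0, na.rm = TRUE),
    frac_significant = mean(p$significant, na.rm = TRUE),
    frac_conserved = mean(p$conserved, na.rm = TRUE),
    q_low = x$band$q_low, q_high = x$band$q_high)
}

#' @export
print.similarity_profile <- function(x, ...) {
  cat("<similarity_profile> ", nrow(x$profile), " Neolecta positions; band [",
      format(x$band$q_low, digits = 4), ", ",
      format(x$band$q_high, digits = 4), "] from ",
      x$band$n_samples, " null columns\n", sep = "")
  invisible(x)
}

#' Tidy a Dollo gain/loss map
#'
#' @param x A `gain_loss_map` from [gain_loss_map()].
#' @param ... Unused.
#' @return The per-node tibble (`node`, `label`, `gains`, `losses`, `net`).
#' @method tidy gain_loss_map
#' @export
tidy.gain_loss_map <- function(x, ...) {
  x$nodes
}

#' One-row summary of a Dollo gain/loss map
#'
#' @param x A `gain_loss_map`.
#' @param ... Unused.
#' @return Tibble (`n_families`, `total_losses`, `n_loss_nodes`).
#' @method glance gain_loss_map
#' @export
glance.gain_loss_map <- function(x, ...) {
  tibble::tibble(n_families = sum(x$nodes$gains),
                 total_losses = sum(x$nodes$losses),
                 n_loss_nodes = sum(x$nodes$losses > 0))
}

#' @export
print.gain_loss_map <- function(x, ...) {
  g <- glance(x)
  cat("<gain_loss_map> ", g$n_families, " families; ", g$total_losses,
      " losses across ", g$n_loss_nodes, " nodes\n", sep = "")
  invisible(x)
}
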