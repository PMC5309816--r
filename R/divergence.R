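#' Pezizomycotina ancestral node of a gene tree
#'
#' The most recent common ancestor of all PEZ tips present in the tree. If
#' the tree is unrooted it is first rooted on the split separating the PEZ
#' tips from the rest (when that split exists). Non-monophyletic PEZ tips
#' are handled by taking the MRCA with a warning, since real gene trees
#' carry topology noise.
#'
#' @param tree A `phylo` object.
#' @param groups Taxon-group tibble.
#' @return A list: `tree` (possibly re-rooted) and `node` (MRCA index).
#' @export
pez_root <- function(tree, groups) {
  pez <- intersect(group_species(groups, "PEZ"), tree$tip.label)
  if (length(pez) < 2) {
    stop("need at least 2 PEZ tips in the tree, found ", length(pez),
         call. = FALSE)
  }
  if (!ape::is.rooted(tree)) {
    out <- setdiff(tree$tip.label, pez)
    if (length(out) > 0 && ape::is.monophyletic(tree, out)) {
      tree <- ape::root(tree, outgroup = out, resolve.root = TRUE)
    }
  }
  node <- ape::getMRCA(tree, pez)
  desc <- tree$tip.label[descendant_tips(tree, node)]
  if (length(setdiff(desc, pez)) > 0) {
    warning("PEZ tips are not monophyletic; using their MRCA")
  }
  list(tree = tree, node = node)
}

# Tip indices below a node (node may itself be a tip).
descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, descendant_tips, tree = tree))
}

#' Path length between a tip and a node
#'
#' Sum of branch lengths along the unique path through the tree.
#'
#' @param tree A `phylo` object.
#' @param tip Tip label.
#' @param node Node index.
#' @return Non-negative numeric.
#' @export
path_length <- function(tree, tip, node) {
  i <- match(tip, tree$tip.label)
  if (is.na(i)) stop("unknown tip: ", tip, call. = FALSE)
  if (i == node) return(0)
  path <- ape::nodepath(tree, i, node)
  len <- 0
  for (k in seq_len(length(path) - 1)) {
    e <- which((tree$edge[, 1] == path[k] & tree$edge[, 2] == path[k + 1]) |
                 (tree$edge[, 1] == path[k + 1] & tree$edge[, 2] == path[k]))
    len <- len + tree$edge.length[e]
  }
  len
}

#' Clade-referenced divergence scores s(x)
#'
#' For each tip `x`, `d(x)` is its path distance to the Pezizomycotina
#' ancestral node and `s(x) = d(x) - mean(d over PEZ tips)`. PEZ scores sum
#' to zero by construction; positive scores mark lineages more divergent
#' than the Pezizomycotina average.
#'
#' @param tree A `phylo` gene tree with branch lengths (substitutions/site).
#' @param groups Taxon-group tibble.
#' @return A `divergence_scores` tibble (`species`, `group`, `d_x`, `s`).
#' @export
divergence_scores <- function(tree, groups) {
  pr <- pez_root(tree, groups)
  tree <- pr$tree
  d <- vapply(tree$tip.label, function(tp) path_length(tree, tp, pr$node),
              numeric(1))
  grp <- groups$group[match(tree$tip.label, groups$species)]
  grp[is.na(grp)] <- "OTHER"
  pez_mean <- mean(d[grp == "PEZ"])
  out <- tibble::tibble(species = tree$tip.label, group = grp,
                        d_x = unname(d), s = unname(d) - pez_mean)
  class(out) <- c("divergence_scores", class(out))
  out
}

#' Greyscale shades for divergence scores
#'
#' Affine map of `s` onto `[0, 1]`, clipped; larger scores (more divergence
#' from the Pezizomycotina) map to lighter shades (closer to 1).
#'
#' @param scores A `divergence_scores` tibble.
#' @param s_lo,s_hi Score range mapped to shades 0 and 1; defaults to the
#'   range of non-PEZ scores.
#' @return The input with a `shade` column.
#' @export
greyscale <- function(scores, s_lo = NULL, s_hi = NULL) {
  ref <- scores$s[scores$group != "PEZ"]
  if (length(ref) == 0) ref <- scores$s
  if (is.null(s_lo)) s_lo <- min(ref)
  if (is.null(s_hi)) s_hi <- max(ref)
  if (s_hi <= s_lo) {
    warning("degenerate score range; all shades set to 0.5")
    scores$shade <- 0.5
    return(scores)
  }
  scores$shade <- pmin(1, pmax(0, (scores$s - s_lo) / (s_hi - s_lo)))
  scores
}
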