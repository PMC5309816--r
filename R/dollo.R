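#' Dollo gain node of a gene family
#'
#' Under Dollo parsimony a family arises exactly once and can only be lost;
#' the unique most-recent single-origin point is the MRCA of the tips where
#' the family is present.
#'
#' @param tree Rooted `phylo` object.
#' @param present_tips Non-empty character vector of tip labels.
#' @return Node index (a tip index for a singleton).
#' @export
dollo_gain_node <- function(tree, present_tips) {
  idx <- match(present_tips, tree$tip.label)
  if (anyNA(idx)) {
    stop("unknown tip(s): ",
         paste(present_tips[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (length(idx) == 0) stop("present_tips must be non-empty", call. = FALSE)
  if (length(idx) == 1) return(idx)
  ape::getMRCA(tree, idx)
}

# Per-node count of present tips in the subtree, via one postorder pass.
subtree_present_counts <- function(tree, present_idx) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  cnt <- integer(nnode)
  cnt[present_idx] <- 1L
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(po))) {
    cnt[po[e, 1]] <- cnt[po[e, 1]] + cnt[po[e, 2]]
  }
  cnt
}

#' Minimal Dollo loss edges for one family
#'
#' Given the gain node, the minimal loss set puts one loss on every edge
#' whose child subtree contains no present tip while the parent lies on the
#' subtree spanning the gain node and the present tips (the shallowest edge
#' covering each maximal absent subtree).
#'
#' @param tree Rooted `phylo` object.
#' @param gain_node Node index from [dollo_gain_node()].
#' @param present_tips Tip labels where the family is present.
#' @return Integer vector of child node indices identifying the loss edges.
#' @export
dollo_losses <- function(tree, gain_node, present_tips) {
  present_idx <- match(present_tips, tree$tip.label)
  if (anyNA(present_idx)) {
    stop("unknown tip(s): ",
         paste(present_tips[is.na(present_idx)], collapse = ", "),
         call. = FALSE)
  }
  cnt <- subtree_present_counts(tree, present_idx)
  if (cnt[gain_node] != length(present_idx)) {
    stop("present tips are not all below the gain node", call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  if (gain_node <= ntip) return(integer(0))
  losses <- integer(0)
  stack <- gain_node
  while (length(stack) > 0) {  # walk only the occupied part of the subtree
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    for (k in kids) {
      if (cnt[k] == 0) {
        losses <- c(losses, k)
      } else if (k > ntip) {
        stack <- c(stack, k)
      }
    }
  }
  sort(losses)
}

#' Dollo gain/loss map over a presence/absence matrix
#'
#' Reconstructs every family's single gain and minimal loss edges and
#' aggregates counts per node: `gains` at the gain node, `losses` at the
#' child node of each loss edge, `net = gains - losses`. The total gain
#' count equals the number of families.
#'
#' @param tree Rooted `phylo` object.
#' @param presence Long presence tibble (`family_id`, `species`, `present`)
#'   as from [read_presence_matrix()]; species must be tree tips.
#' @return A `gain_loss_map` object: `nodes` tibble (`node`, `label`,
#'   `gains`, `losses`, `net`) and `events` tibble (`family_id`,
#'   `gain_node`, `n_losses`, `loss_nodes`).
#' @export
gain_loss_map <- function(tree, presence) {
  sp <- unique(presence$species)
  unknown <- setdiff(sp, tree$tip.label)
  if (length(unknown) > 0) {
    stop("presence matrix species not in tree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  gains <- integer(nnode)
  losses <- integer(nnode)
  fams <- split(presence, presence$family_id)
  events <- vector("list", length(fams))
  for (i in seq_along(fams)) {
    f <- fams[[i]]
    pres <- f$species[f$present]
    if (length(pres) == 0) {
      warning("family absent everywhere, skipped: ", f$family_id[1])
      next
    }
    g <- dollo_gain_node(tree, pres)
    l <- dollo_losses(tree, g, pres)
    gains[g] <- gains[g] + 1L
    losses[l] <- losses[l] + 1L
    events[[i]] <- tibble::tibble(
      family_id = f$family_id[1], gain_node = g, n_losses = length(l),
      loss_nodes = paste(l, collapse = ","))
  }
  labels <- c(tree$tip.label,
              paste0("node", (ntip + 1):nnode))
  out <- structure(list(
    nodes = tibble::tibble(node = seq_len(nnode), label = labels,
                           gains = gains, losses = losses,
                           net = gains - losses),
    events = dplyr::bind_rows(events),
    tree = tree
  ), class = "gain_loss_map")
  out
}
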