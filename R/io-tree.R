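#' Read a rooted Newick tree
#'
#' Parses a single Newick tree with `ape`. Missing branch lengths default to
#' zero with a warning; negative branch lengths are an error.
#'
#' @param path Path to a Newick file.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- tryCatch(
    ape::read.tree(path),
    error = function(e) stop("cannot parse Newick file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(tr)) stop("cannot parse Newick file: ", path, call. = FALSE)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1) {
      stop("expected a single tree, found ", length(tr), " in ", path,
           call. = FALSE)
    }
    tr <- tr[[1]]
  }
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) {
    stop("negative branch length(s) in ", path, call. = FALSE)
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip labels in ", path, call. = FALSE)
  }
  tr
}

#' Write a tree as Newick
#' @param tree A `phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
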