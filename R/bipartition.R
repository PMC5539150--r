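#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the tips in two; the bipartition is keyed by
#' the sorted tip labels of the side *not* containing the alphabetically
#' first tip, joined with `|`. Trivial splits (single tip on a side) are
#' dropped. Keys are named by the internal node subtending the split, so
#' supports can be attached back onto the tree.
#'
#' @param tree a `phylo` object.
#' @return named character vector of bipartition keys (names = internal
#'   node numbers).
#' @export
tree_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  anchor <- sort(labs)[1]
  keys <- character(0)
  for (k in seq_along(parts)) {
    side <- labs[parts[[k]]]
    canon <- if (anchor %in% side) setdiff(labs, side) else side
    if (length(canon) < 2 || length(canon) > ntip - 2) next
    key <- paste(sort(canon), collapse = "|")
    keys[as.character(ntip + k)] <- key
  }
  keys
}

#' Robinson-Foulds distance between two trees
#'
#' Count of non-trivial bipartitions present in exactly one of the two
#' trees, which must share an identical tip set.
#'
#' @param t1,t2 `phylo` objects on the same tips.
#' @return integer distance.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different tip sets")
  k1 <- tree_bipartitions(t1)
  k2 <- tree_bipartitions(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}
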