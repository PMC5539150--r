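#' Classify cassette transfer mode from three gene trees
#'
#' For each cassette, locates its LuxI, LuxR and concatenated (LuxI+LuxR)
#' sequences in the respective trees and finds each one's nearest
#' gram-negative partner (minimum patristic path length; ties resolved by
#' higher bootstrap support of the joining ancestor, then alphabetically).
#'
#' Modes are assigned from supported claims only:
#' \itemize{
#'   \item `simultaneous` - all three partners agree and each tree supports
#'     the tip/partner grouping (bootstrap support of their joining clade at
#'     least `min_support`): the whole cassette moved as one unit.
#'   \item `individual` - the LuxI and LuxR partners differ, the transferred
#'     gene's grouping is supported, and the other gene's tree contains a
#'     supported bipartition separating the cassette from that partner (a
#'     supported disagreement): the genes arrived separately.
#'   \item `unclear` - anything else: missing tips, unsupported groupings,
#'     or partial agreement (e.g. the concatenated placement contradicting
#'     both gene placements).
#' }
#'
#' @param luxi_tree,luxr_tree,concat_tree `phylo` trees with bootstrap
#'   supports in `$node.label`.
#' @param cassette_map data.frame with columns `cassette_id`, `luxi_tip`,
#'   `luxr_tip`, `concat_tip`.
#' @param metadata tip metadata supplying gram labels.
#' @param min_support bootstrap cutoff, percent (default 70).
#' @return data.frame: `cassette_id`, `mode`, `partner_luxi`,
#'   `partner_luxr`, `partner_concat`, `reason`.
#' @export
classify_transfer_mode <- function(luxi_tree, luxr_tree, concat_tree,
                                   cassette_map, metadata, min_support = 70) {
  metadata <- validate_tip_metadata(metadata)
  stopifnot(all(c("cassette_id", "luxi_tip", "luxr_tip", "concat_tip") %in%
                  names(cassette_map)))
  negatives <- metadata$tip_id[metadata$gram == "negative"]
  trees <- list(luxi = luxi_tree, luxr = luxr_tree, concat = concat_tree)
  tipcols <- c(luxi = "luxi_tip", luxr = "luxr_tip", concat = "concat_tip")

  rows <- lapply(seq_len(nrow(cassette_map)), function(k) {
    cs <- cassette_map[k, ]
    pl <- lapply(names(trees), function(nm)
      nearest_negative_partner(trees[[nm]], cs[[tipcols[[nm]]]],
                               negatives, min_support))
    names(pl) <- names(trees)
    missing <- names(pl)[vapply(pl, is.null, logical(1))]
    partners <- vapply(pl, function(p) if (is.null(p)) NA_character_ else p$partner,
                       character(1))
    if (length(missing)) {
      mode <- "unclear"
      reason <- paste("cassette absent from tree(s):",
                      paste(missing, collapse = ", "))
    } else {
      supported <- vapply(pl, `[[`, logical(1), "supported")
      agree <- partners[["luxi"]] == partners[["luxr"]] &&
        partners[["luxr"]] == partners[["concat"]]
      differ <- partners[["luxi"]] != partners[["luxr"]]
      split_i <- differ && supported[["luxi"]] &&
        separation_supported(trees$luxr, cs$luxr_tip, partners[["luxi"]],
                             min_support)
      split_r <- differ && supported[["luxr"]] &&
        separation_supported(trees$luxi, cs$luxi_tip, partners[["luxr"]],
                             min_support)
      if (agree && all(supported)) {
        mode <- "simultaneous"; reason <- ""
      } else if (split_i || split_r) {
        mode <- "individual"; reason <- ""
      } else if (agree || differ) {
        mode <- "unclear"
        reason <- "placements lack the bootstrap support the verdict needs"
      } else {
        mode <- "unclear"
        reason <- "concatenated placement disagrees with the gene placements"
      }
    }
    data.frame(cassette_id = cs$cassette_id, mode = mode,
               partner_luxi = partners[["luxi"]],
               partner_luxr = partners[["luxr"]],
               partner_concat = partners[["concat"]],
               reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# nearest gram-negative tip by patristic distance; NULL when tip absent.
# Support of a grouping is read off the tip/partner ancestor after
# re-rooting on the farthest tip outside the partner pool (edgelabel = TRUE
# keeps supports bound to edges), since the NJ root trifurcation is
# arbitrary.
nearest_negative_partner <- function(tree, tip, negatives, min_support) {
  if (is.na(tip) || !tip %in% tree$tip.label) return(NULL)
  negs <- intersect(tree$tip.label, setdiff(negatives, tip))
  if (length(negs) == 0) return(NULL)
  D <- ape::cophenetic.phylo(tree)
  d <- D[tip, negs]
  best <- negs[d - min(d) < 1e-12]
  pool <- setdiff(colnames(D), c(tip, negs))
  if (length(pool) == 0) pool <- setdiff(colnames(D), c(tip, best))
  if (length(pool) == 0) return(NULL)
  far <- D[tip, pool, drop = TRUE]
  root_tip <- pool[order(-far, pool)][1]
  tr <- ape::root(tree, outgroup = root_tip, edgelabel = TRUE)
  sup <- node_supports(tr)
  ntip <- length(tr$tip.label)
  anc_sup <- vapply(best, function(p) {
    node <- ape::getMRCA(tr, c(tip, p))
    s <- sup[node - ntip]
    if (is.na(s)) -1 else s
  }, numeric(1))
  ord <- order(-anc_sup, best)
  partner <- best[ord[1]]
  s <- anc_sup[ord[1]]
  list(partner = partner, support = if (s < 0) NA_real_ else s,
       supported = s >= min_support)
}

# TRUE when the tree holds a bipartition with support >= min_support that
# places `tip` and `other` on opposite sides
separation_supported <- function(tree, tip, other, min_support) {
  if (!all(c(tip, other) %in% tree$tip.label)) return(FALSE)
  keys <- tree_bipartitions(tree)
  if (length(keys) == 0) return(FALSE)
  sup <- node_supports(tree)
  ntip <- length(tree$tip.label)
  for (k in seq_along(keys)) {
    node <- as.integer(names(keys)[k])
    s <- sup[node - ntip]
    if (is.na(s) || s < min_support) next
    side <- strsplit(keys[k], "|", fixed = TRUE)[[1]]
    if (xor(tip %in% side, other %in% side)) return(TRUE)
  }
  FALSE
}
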