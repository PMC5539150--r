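#' Detect horizontal gene transfer from gram-mixed supported clades
#'
#' Scans every internal edge of the gene tree. For each edge, the smaller
#' side of its bipartition is examined; when that side mixes gram-positive
#' and gram-negative tips a call is emitted. The verdict is
#' `hgt_supported` when the edge also has bootstrap support at least
#' `min_support` **and** the mixed grouping contradicts the reference
#' (16S rRNA) tree; `candidate` when supported but not contradicting the
#' reference; `rejected` when support is missing or below the cutoff.
#' Shared ecological niche between cross-gram tips is annotated
#' (`niche_match`) as corroborating evidence but is not required.
#'
#' Reference incongruence is a bipartition test on the shared tips: the
#' reference tree must itself separate the gram labels (contain the
#' bipartition gram-positive vs gram-negative), in which case any
#' gram-mixed gene-tree clade that is not a clade of the reference
#' contradicts reference monophyly of the labels.
#'
#' @param gene_tree `phylo` with bootstrap supports in `$node.label`.
#' @param reference_tree `phylo`; the 16S rRNA (species) tree.
#' @param metadata tip metadata ([read_tip_metadata()]) covering the shared
#'   tips.
#' @param min_support bootstrap cutoff, percent (default 70).
#' @return data.frame with one row per gram-mixed edge: `clade_tips`
#'   (comma-separated), `n_tips`, `support`, `mixed`, `niche_match`,
#'   `reference_incongruent`, `verdict`.
#' @export
detect_hgt <- function(gene_tree, reference_tree, metadata, min_support = 70) {
  metadata <- validate_tip_metadata(metadata)
  shared <- intersect(gene_tree$tip.label, reference_tree$tip.label)
  if (length(shared) == 0) stop("trees share no tips")
  miss <- setdiff(shared, metadata$tip_id)
  if (length(miss))
    stop("tips without metadata: ", paste(miss, collapse = ", "))
  if (length(shared) < 4)
    stop("need at least 4 shared tips for bipartition comparison")
  gt <- ape::keep.tip(gene_tree, shared)
  rt <- ape::keep.tip(reference_tree, shared)
  gram <- setNames(metadata$gram, metadata$tip_id)
  niche <- setNames(metadata$niche, metadata$tip_id)

  ref_keys <- tree_bipartitions(rt)
  gp_tips <- shared[gram[shared] == "positive"]
  gn_tips <- shared[gram[shared] == "negative"]
  gram_key <- bipartition_key(gp_tips, shared)
  labels_monophyletic <- length(gp_tips) > 0 && length(gn_tips) > 0 &&
    (gram_key %in% ref_keys ||
       length(gp_tips) <= 1 || length(gn_tips) <= 1)

  ntip <- length(gt$tip.label)
  parts <- ape::prop.part(gt)
  labs <- attr(parts, "labels")
  sup <- node_supports(gt)
  calls <- list()
  for (k in seq_along(parts)) {
    node <- ntip + k
    clade <- labs[parts[[k]]]
    if (length(clade) == ntip) next  # root
    side <- if (2 * length(clade) <= ntip) clade else setdiff(labs, clade)
    g <- gram[side]
    mixed <- all(c("positive", "negative") %in% g)
    if (!mixed) next
    s <- sup[node - ntip]
    pos <- side[g == "positive"]; neg <- side[g == "negative"]
    nm <- any(outer(niche[pos], niche[neg], "=="), na.rm = TRUE)
    side_key <- bipartition_key(side, shared)
    incong <- labels_monophyletic && !(side_key %in% ref_keys)
    verdict <- if (!is.na(s) && s >= min_support) {
      if (incong) "hgt_supported" else "candidate"
    } else "rejected"
    calls[[length(calls) + 1]] <- data.frame(
      clade_tips = paste(sort(side), collapse = ","),
      n_tips = length(side), support = s, mixed = TRUE,
      niche_match = nm, reference_incongruent = incong,
      verdict = verdict, stringsAsFactors = FALSE)
  }
  if (!length(calls))
    return(data.frame(clade_tips = character(), n_tips = integer(),
                      support = numeric(), mixed = logical(),
                      niche_match = logical(),
                      reference_incongruent = logical(),
                      verdict = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  out <- out[order(-out$support, out$clade_tips), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# canonical bipartition key of a tip side within a full tip set
bipartition_key <- function(side, all_tips) {
  anchor <- sort(all_tips)[1]
  canon <- if (anchor %in% side) setdiff(all_tips, side) else side
  paste(sort(canon), collapse = "|")
}
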