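#' Bootstrap support for a distance-based tree
#'
#' Builds the tree on the full alignment, then resamples alignment columns
#' with replacement `n_reps` times, rebuilds with the same deterministic
#' builder, and attaches to each internal edge the percentage of replicate
#' trees containing the same bipartition. Seeded runs are reproducible
#' bit-for-bit.
#'
#' @param msa alignment (named character vector, matrix or `AAStringSet`).
#' @param builder function mapping an alignment matrix to a `phylo` tree;
#'   defaults to neighbor joining on Poisson-corrected distances.
#' @param n_reps number of pseudo-replicates (>= 1; 1000 for publication-
#'   grade supports, fewer for simulation studies).
#' @param seed optional integer seed applied locally (the caller's RNG
#'   state is untouched).
#' @param correction distance correction for the default builder.
#' @return the main-tree `phylo` with supports in `$node.label`
#'   (rounded percentages; `""` for the root) and `attr(, "n_reps")`.
#' @export
bootstrap_support <- function(msa, builder = NULL, n_reps = 1000, seed = NULL,
                              correction = c("poisson", "p")) {
  correction <- match.arg(correction)
  if (n_reps < 1) stop("n_reps must be >= 1")
  m <- as_msa_matrix(msa)
  if (is.null(builder))
    builder <- function(mm) neighbor_joining(protein_distance(mm, correction))
  main <- builder(m)
  keys <- tree_bipartitions(main)
  run <- function() {
    counts <- setNames(numeric(length(keys)), keys)
    for (rep in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      kk <- tree_bipartitions(builder(m[, cols, drop = FALSE]))
      hit <- keys %in% kk
      counts[hit] <- counts[hit] + 1
    }
    counts
  }
  counts <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  ntip <- length(main$tip.label)
  labels <- rep("", main$Nnode)
  node_of <- as.integer(names(keys))
  labels[node_of - ntip] <- as.character(round(100 * counts / n_reps))
  main$node.label <- labels
  attr(main, "n_reps") <- n_reps
  main
}
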