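#' Neighbor-joining tree reconstruction
#'
#' Standard Saitou-Nei neighbor joining with the Q-criterion. The pair to
#' agglomerate at each step is chosen deterministically: among all pairs
#' minimising Q, the pair whose (sorted) representative labels are
#' lexicographically smallest wins, where a cluster's representative label
#' is its alphabetically first tip. Negative branch lengths are clamped to
#' zero and counted in `attr(, "negative_branches_clamped")`.
#'
#' @param dm symmetric distance matrix with identical row/column names and
#'   zero diagonal; at least 3 tips.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  stopifnot(is.matrix(dm))
  if (is.null(rownames(dm)) || !identical(rownames(dm), colnames(dm)))
    stop("distance matrix needs identical row/column names")
  if (nrow(dm) < 3) stop("need at least 3 tips")
  if (any(!is.finite(dm))) stop("non-finite distances")
  if (max(abs(dm - t(dm))) > 1e-8) stop("non-symmetric distance matrix")
  if (any(abs(diag(dm)) > 1e-12)) stop("non-zero diagonal")

  n_clamped <- 0L
  clamp <- function(x) {
    neg <- x < 0
    n_clamped <<- n_clamped + sum(neg)
    x[neg] <- 0
    x
  }
  fmt <- function(x) sprintf("%.12g", x)

  # active clusters: newick fragments, representative labels for tie-breaks
  newick <- rownames(dm)
  rep_lab <- rownames(dm)
  D <- dm

  while (length(newick) > 3) {
    n <- length(newick)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    idx <- which(Q - qmin < 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    lo <- pmin(rep_lab[idx[, 1]], rep_lab[idx[, 2]])
    hi <- pmax(rep_lab[idx[, 1]], rep_lab[idx[, 2]])
    pick <- order(lo, hi)[1]
    i <- idx[pick, 1]; j <- idx[pick, 2]

    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    li <- clamp(li); lj <- clamp(lj)
    merged <- sprintf("(%s:%s,%s:%s)", newick[i], fmt(li), newick[j], fmt(lj))

    others <- setdiff(seq_len(n), c(i, j))
    dnew <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D <- rbind(cbind(D[others, others, drop = FALSE], dnew),
               c(dnew, 0))
    newick <- c(newick[others], merged)
    rep_lab <- c(rep_lab[others], min(rep_lab[c(i, j)]))
    dimnames(D) <- list(rep_lab, rep_lab)
  }

  # closed-form terminal join of the last three clusters
  lx <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  ly <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lz <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 newick[1], fmt(lx), newick[2], fmt(ly), newick[3], fmt(lz))
  tree <- ape::read.tree(text = txt)
  attr(tree, "negative_branches_clamped") <- n_clamped
  tree
}
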