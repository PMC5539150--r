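#' Global pairwise sequence identity
#'
#' Global Needleman-Wunsch alignment with match +1, mismatch 0 and linear
#' gap penalty -1 by default; identity is `matches / alignment length`
#' (switchable to the shorter-sequence denominator). The traceback tie-break
#' is fixed (diagonal, then gap-in-second, then gap-in-first), so the value
#' is deterministic and symmetric.
#'
#' @param a,b sequences: character scalars or single-row protein sets.
#' @param match,mismatch,gap alignment scores.
#' @param denominator `"alignment"` (default) or `"shorter"`.
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = 0, gap = -1,
                              denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  a <- as_sequence(a); b <- as_sequence(b)
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  st <- .nw_align_stats(a, b, match, mismatch, gap)
  den <- if (denominator == "alignment") st$length else min(nchar(a), nchar(b))
  st$matches / den
}

as_sequence <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1, !is.null(x$sequence))
    x <- x$sequence
  }
  stopifnot(is.character(x), length(x) == 1)
  toupper(x)
}

#' Greedy identity-threshold clustering (CD-HIT-style)
#'
#' Representative selection by the classic greedy scheme: sequences are
#' sorted by decreasing length (ties by id), and each joins the first
#' existing cluster whose representative it matches at `>= threshold`
#' identity, otherwise it founds a new cluster. Every representative is the
#' longest member of its cluster, and representatives are mutually below the
#' threshold. Full dynamic-programming identity is used throughout (no k-mer
#' pre-filter): inputs here are desk-scale.
#'
#' @param proteins a [as_protein_set()] table.
#' @param threshold identity fraction in `(0, 1]`; default 0.30.
#' @param denominator passed to [pairwise_identity()].
#' @return data.frame with one row per sequence: `representative_id`,
#'   `member_id`, `identity_to_rep`; `attr(, "threshold")` records the
#'   threshold.
#' @export
greedy_cluster <- function(proteins, threshold = 0.30,
                           denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  proteins <- as_protein_set(proteins)
  if (nrow(proteins) == 0) stop("need at least one protein")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  ord <- order(-nchar(proteins$sequence), proteins$id)
  proteins <- proteins[ord, , drop = FALSE]
  reps <- character(0)
  assign_rep <- character(nrow(proteins))
  assign_ident <- numeric(nrow(proteins))
  seqs <- setNames(proteins$sequence, proteins$id)
  for (i in seq_len(nrow(proteins))) {
    id <- proteins$id[i]
    placed <- FALSE
    for (r in reps) {
      ident <- pairwise_identity(seqs[[id]], seqs[[r]],
                                 denominator = denominator)
      if (ident >= threshold) {
        assign_rep[i] <- r
        assign_ident[i] <- ident
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      assign_rep[i] <- id
      assign_ident[i] <- 1
    }
  }
  out <- data.frame(representative_id = assign_rep,
                    member_id = proteins$id,
                    identity_to_rep = assign_ident,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$representative_id, reps),
                   out$member_id != out$representative_id,
                   out$member_id), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' @rdname greedy_cluster
#' @param clusters output of [greedy_cluster()].
#' @return `cluster_representatives()`: character vector of representative
#'   ids in founding order.
#' @export
cluster_representatives <- function(clusters) {
  unique(clusters$representative_id)
}
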