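#' Map alignment columns to ungapped reference positions
#'
#' Builds the monotone mapping from alignment columns to 1-based residue
#' positions of the (ungapped) reference sequence; columns where the
#' reference carries a gap map to nothing.
#'
#' @param msa alignment (named character vector, matrix or `AAStringSet`).
#' @param ref_id id of the reference row.
#' @return data.frame with columns `alignment_column`, `ref_position`.
#' @export
map_reference_positions <- function(msa, ref_id) {
  m <- as_msa_matrix(msa)
  if (!ref_id %in% rownames(m))
    stop("reference id not in alignment: ", ref_id)
  ref <- m[ref_id, ]
  nongap <- which(ref != "-")
  if (length(nongap) == 0) stop("reference row is all gaps")
  data.frame(alignment_column = nongap,
             ref_position = seq_along(nongap))
}

#' Reference-anchored per-position conservation
#'
#' For every ungapped position of the reference, reports the percentage of
#' non-reference sequences whose residue in that alignment column equals the
#' reference residue (gaps count as mismatches). A site is conserved when
#' that identity reaches `threshold_pct` (default 50, the smallest
#' consensus level at which reported invariant-residue lists still include
#' their weakest sites). Exact percentages are returned alongside an
#' integer-rounded convenience column.
#'
#' @inheritParams map_reference_positions
#' @param threshold_pct conservation call threshold, percent.
#' @return data.frame with one row per reference position: `ref_position`,
#'   `ref_residue`, `alignment_column`, `identity_pct` (exact),
#'   `identity_pct_int` (rounded), `conserved`.
#' @export
site_conservation <- function(msa, ref_id, threshold_pct = 50) {
  m <- as_msa_matrix(msa)
  if (nrow(m) < 2) stop("alignment needs at least 2 sequences")
  map <- map_reference_positions(m, ref_id)
  others <- m[setdiff(rownames(m), ref_id), , drop = FALSE]
  ref <- m[ref_id, ]
  pct <- vapply(map$alignment_column, function(col)
    100 * sum(others[, col] == ref[col]) / nrow(others), numeric(1))
  data.frame(ref_position = map$ref_position,
             ref_residue = ref[map$alignment_column],
             alignment_column = map$alignment_column,
             identity_pct = pct,
             identity_pct_int = as.integer(round(pct)),
             conserved = pct >= threshold_pct,
             row.names = NULL,
             stringsAsFactors = FALSE)
}
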