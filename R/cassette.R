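#' ORF length in residues from gene coordinates
#'
#' Gene coordinates are 1-based inclusive and include the stop codon, so a
#' span of `end - start + 1` nucleotides encodes `span/3 - 1` residues.
#' A span not divisible by 3 is an annotation error and is rejected with the
#' locus name; a lone stop codon (0 residues) triggers a warning.
#'
#' @param features a `gene_features` table (or any data.frame with `start`,
#'   `end` and optionally `locus_tag`).
#' @return integer vector of residue counts, one per feature.
#' @export
orf_length_aa <- function(features) {
  stopifnot(is.data.frame(features), all(c("start", "end") %in% names(features)))
  span <- features$end - features$start + 1
  tags <- features$locus_tag %||% as.character(seq_along(span))
  bad <- span %% 3 != 0
  if (any(bad))
    stop("gene span not divisible by 3 for locus: ",
         paste(tags[bad], collapse = ", "))
  res <- as.integer(span / 3 - 1)
  if (any(res == 0))
    warning("degenerate ORF (lone stop codon) at locus: ",
            paste(tags[res == 0], collapse = ", "))
  res
}

#' Pair luxI and luxR loci into candidate cassettes
#'
#' On each replicon, every luxI is paired with the nearest available luxR
#' whose intervening gap is at most `max_gap_bp` (bases strictly between the
#' two ORFs, `right start - left end - 1`). Each luxR is used at most once;
#' ties resolve to the smaller gap, then the leftmost pair. Overlapping
#' luxI/luxR intervals are paired with `gap_bp = 0`, flagged, and produce a
#' warning. Unpaired loci are reported as solos (the "LuxR solo" / orphan
#' situation). The result is invariant to input row order.
#'
#' The default `max_gap_bp` of 3400 is the distance criterion that admits
#' every reported canonical Gram-positive pair (the widest of which sits at
#' a 3258 bp gap); the stricter 3000 bp criterion is available by argument.
#'
#' @param features a `gene_features` table with `gene_class` assigned.
#' @param max_gap_bp distance criterion in bp (default 3400).
#' @return list with data.frames `pairs` (columns `replicon_id`,
#'   `luxI_locus`, `luxR_locus`, `luxI_start`, `luxI_end`, `luxI_strand`,
#'   `luxR_start`, `luxR_end`, `luxR_strand`, `gap_bp`, `overlapping`,
#'   `canonical`) and `solos` (unpaired luxI/luxR features).
#' @export
pair_cassettes <- function(features, max_gap_bp = 3400) {
  features <- as_gene_features(features)
  luxi <- features[features$gene_class == "luxI", , drop = FALSE]
  luxr <- features[features$gene_class == "luxR", , drop = FALSE]
  cand <- NULL
  if (nrow(luxi) && nrow(luxr)) {
    cand <- do.call(rbind, lapply(seq_len(nrow(luxi)), function(i) {
      ii <- luxi[i, ]
      rr <- luxr[luxr$replicon_id == ii$replicon_id, , drop = FALSE]
      if (nrow(rr) == 0) return(NULL)
      g <- feature_gap(ii, rr)
      keep <- g$gap <= max_gap_bp
      if (!any(keep)) return(NULL)
      data.frame(i = i, j = match(rr$locus_tag[keep], luxr$locus_tag),
                 gap = g$gap[keep], overlap = g$overlap[keep],
                 left_start = pmin(ii$start, rr$start[keep]),
                 stringsAsFactors = FALSE)
    }))
  }
  used_i <- logical(nrow(luxi)); used_j <- logical(nrow(luxr))
  pairs <- list()
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$gap, cand$left_start, luxi$locus_tag[cand$i],
                       luxr$locus_tag[cand$j]), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (used_i[i] || used_j[j]) next
      used_i[i] <- TRUE; used_j[j] <- TRUE
      ii <- luxi[i, ]; rr <- luxr[j, ]
      if (cand$overlap[k])
        warning("overlapping luxI/luxR intervals: ", ii$locus_tag, " / ",
                rr$locus_tag, " (gap set to 0)")
      pairs[[length(pairs) + 1]] <- data.frame(
        replicon_id = ii$replicon_id,
        luxI_locus = ii$locus_tag, luxR_locus = rr$locus_tag,
        luxI_start = ii$start, luxI_end = ii$end, luxI_strand = ii$strand,
        luxR_start = rr$start, luxR_end = rr$end, luxR_strand = rr$strand,
        gap_bp = cand$gap[k], overlapping = cand$overlap[k],
        canonical = TRUE, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else data.frame(
    replicon_id = character(), luxI_locus = character(),
    luxR_locus = character(), luxI_start = integer(), luxI_end = integer(),
    luxI_strand = character(), luxR_start = integer(), luxR_end = integer(),
    luxR_strand = character(), gap_bp = integer(), overlapping = logical(),
    canonical = logical(), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$replicon_id, pmin(pairs$luxI_start, pairs$luxR_start)), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  solos <- rbind(luxi[!used_i, , drop = FALSE], luxr[!used_j, , drop = FALSE])
  solos <- solos[order(solos$replicon_id, solos$start), , drop = FALSE]
  rownames(solos) <- NULL
  list(pairs = pairs, solos = solos)
}

# gap in bases strictly between two ORFs (0 when overlapping, flagged)
feature_gap <- function(a, b) {
  left_end <- ifelse(a$start <= b$start, a$end, b$end)
  right_start <- ifelse(a$start <= b$start, b$start, a$start)
  gap <- as.integer(right_start - left_end - 1L)
  overlap <- gap < 0L
  gap[overlap] <- 0L
  list(gap = gap, overlap = overlap)
}

#' Render a gene-topology pattern string
#'
#' The pattern grammar writes each gene as an arrow over its strand
#' (`R>` forward, `<R` reverse; likewise `I`) in left-to-right replicon
#' order, with `X(n)` for `n` intervening genes (bucketed to `X(>7)` above
#' 7, the convention used for crowded cassette neighbourhoods). Adjacent
#' genes concatenate without separator, e.g. `"R>I>"`, `"R><I"`,
#' `"<I X(2) R>"`, `"R> X(>7) <I"`.
#'
#' @param left_class,right_class `"luxI"` or `"luxR"` for the left/right gene.
#' @param left_strand,right_strand `"+"` or `"-"`.
#' @param n_intervening non-negative intervening gene count.
#' @return the canonical pattern string.
#' @export
render_topology <- function(left_class, left_strand,
                            right_class, right_strand, n_intervening) {
  stopifnot(n_intervening >= 0)
  letter <- c(luxI = "I", luxR = "R")
  tok <- function(cls, strand)
    if (strand == "+") paste0(letter[[cls]], ">") else paste0("<", letter[[cls]])
  l <- tok(left_class, left_strand)
  r <- tok(right_class, right_strand)
  if (n_intervening == 0) return(paste0(l, r))
  x <- if (n_intervening > 7) "X(>7)" else sprintf("X(%d)", n_intervening)
  paste(l, x, r)
}

#' Classify the topology of a luxI/luxR cassette pair
#'
#' Counts the other-class genes lying wholly inside the gap between the two
#' ORFs (any strand: the intervening-gene notation is strand-unqualified)
#' and renders the canonical pattern string.
#'
#' @param pair one row of `pair_cassettes()$pairs`.
#' @param features the `gene_features` table for the replicon.
#' @return list with `left_class`, `left_strand`, `right_class`,
#'   `right_strand`, `n_intervening`, `render`.
#' @export
classify_topology <- function(pair, features) {
  features <- as_gene_features(features)
  i_first <- pair$luxI_start <= pair$luxR_start
  left <- list(class = if (i_first) "luxI" else "luxR",
               strand = if (i_first) pair$luxI_strand else pair$luxR_strand,
               end = if (i_first) pair$luxI_end else pair$luxR_end)
  right <- list(class = if (i_first) "luxR" else "luxI",
                strand = if (i_first) pair$luxR_strand else pair$luxI_strand,
                start = if (i_first) pair$luxR_start else pair$luxI_start)
  inside <- features$replicon_id == pair$replicon_id &
    features$gene_class == "other" &
    features$start > left$end & features$end < right$start
  n <- sum(inside)
  list(left_class = left$class, left_strand = left$strand,
       right_class = right$class, right_strand = right$strand,
       n_intervening = n,
       render = render_topology(left$class, left$strand,
                                right$class, right$strand, n))
}

#' Pair and classify all cassettes on a feature table
#'
#' Convenience wrapper running [pair_cassettes()] then [classify_topology()]
#' on every pair.
#'
#' @inheritParams pair_cassettes
#' @return list with `pairs` (augmented with `n_intervening` and `pattern`
#'   columns) and `solos`.
#' @export
cassette_table <- function(features, max_gap_bp = 3400) {
  res <- pair_cassettes(features, max_gap_bp = max_gap_bp)
  if (nrow(res$pairs)) {
    cls <- lapply(seq_len(nrow(res$pairs)),
                  function(k) classify_topology(res$pairs[k, ], features))
    res$pairs$n_intervening <- vapply(cls, `[[`, integer(1), "n_intervening")
    res$pairs$pattern <- vapply(cls, `[[`, character(1), "render")
  } else {
    res$pairs$n_intervening <- integer(0)
    res$pairs$pattern <- character(0)
  }
  res
}
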