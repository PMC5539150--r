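#' Amino-acid composition profiles
#'
#' Computes the fraction of each of the 20 standard residues per sequence,
#' `Comp(x) = A_x / N` where `A_x` counts residues of type `x` and `N` is
#' the number of standard residues in the protein. `X` residues are excluded
#' from both numerator and denominator. Each profile sums to 1.
#'
#' @param x a [as_protein_set()] table or character vector of sequences
#'   (names used as ids when present).
#' @return numeric matrix, one row per sequence, columns the 20 residues.
#' @export
aa_composition <- function(x) {
  if (is.data.frame(x)) {
    seqs <- setNames(x$sequence, x$id)
  } else {
    stopifnot(is.character(x))
    seqs <- toupper(x)
    if (is.null(names(seqs))) names(seqs) <- seq_along(seqs)
  }
  if (length(seqs) == 0) stop("no sequences")
  prof <- t(vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    ch <- ch[ch != "X"]
    if (length(ch) == 0) stop("sequence has no standard residues")
    counts <- table(factor(ch, levels = AA20))
    as.numeric(counts) / length(ch)
  }, numeric(length(AA20))))
  colnames(prof) <- AA20
  prof
}

#' Two-group amino-acid composition comparison
#'
#' For each residue, compares per-sequence composition fractions between two
#' groups: reports group means, the fold change `group1 mean / group2 mean`
#' and a two-sided p-value (Welch's t-test by default, Mann-Whitney as the
#' rank alternative). A residue is significant when the fold change is
#' `<= 0.80` or `>= 1.20` **and** `p < 0.05` (raw p-values by default;
#' Benjamini-Hochberg correction is opt-in).
#'
#' A residue absent from the denominator group yields an infinite fold
#' change and is flagged via `fc_defined = FALSE`, never dropped.
#'
#' @param group1,group2 protein sets, character vectors of sequences, or
#'   precomputed profile matrices from [aa_composition()].
#' @param test `"welch"` (default; needs >= 2 sequences per group) or
#'   `"wilcoxon"`.
#' @param adjust apply Benjamini-Hochberg to the p-values (default `FALSE`).
#' @param pooled_fc compute the fold change from pooled residue counts
#'   (weighted by sequence length) instead of per-sequence means.
#' @param fc_low,fc_high,alpha significance thresholds.
#' @return data.frame with one row per residue: `residue`, `group1_mean`,
#'   `group2_mean`, `fold_change`, `p_value`, `significant`, `fc_defined`;
#'   attributes `test` and `adjusted`.
#' @export
compare_composition <- function(group1, group2,
                                test = c("welch", "wilcoxon"),
                                adjust = FALSE, pooled_fc = FALSE,
                                fc_low = 0.80, fc_high = 1.20, alpha = 0.05) {
  test <- match.arg(test)
  p1 <- as_profiles(group1); p2 <- as_profiles(group2)
  if (test == "welch" && (nrow(p1) < 2 || nrow(p2) < 2))
    stop("Welch's t-test needs >= 2 sequences per group; ",
         "use test = \"wilcoxon\" for smaller groups")
  m1 <- colMeans(p1); m2 <- colMeans(p2)
  if (pooled_fc) {
    w1 <- attr(p1, "n_residues"); w2 <- attr(p2, "n_residues")
    m1fc <- colSums(p1 * w1) / sum(w1)
    m2fc <- colSums(p2 * w2) / sum(w2)
  } else {
    m1fc <- m1; m2fc <- m2
  }
  fc <- ifelse(m2fc == 0, ifelse(m1fc == 0, NA_real_, Inf), m1fc / m2fc)
  pv <- vapply(AA20, function(aa) {
    x <- p1[, aa]; y <- p2[, aa]
    if (test == "welch") {
      tryCatch(t.test(x, y)$p.value, error = function(e) {
        # zero variance in both groups: identical means carry no signal,
        # perfectly separated constants are maximal signal
        if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
      })
    } else {
      suppressWarnings(wilcox.test(x, y)$p.value)
    }
  }, numeric(1))
  if (adjust) pv <- p.adjust(pv, method = "BH")
  sig <- !is.na(fc) & (fc <= fc_low | fc >= fc_high) & !is.na(pv) & pv < alpha
  out <- data.frame(residue = AA20, group1_mean = unname(m1),
                    group2_mean = unname(m2), fold_change = unname(fc),
                    p_value = unname(pv), significant = unname(sig),
                    fc_defined = is.finite(fc) | (is.na(fc) & FALSE),
                    stringsAsFactors = FALSE)
  out$fc_defined <- is.finite(out$fold_change)
  attr(out, "test") <- test
  attr(out, "adjusted") <- adjust
  out
}

as_profiles <- function(x) {
  if (is.matrix(x) && identical(colnames(x), AA20)) {
    if (is.null(attr(x, "n_residues")))
      attr(x, "n_residues") <- rep(1, nrow(x))
    return(x)
  }
  if (is.data.frame(x)) {
    prof <- aa_composition(x)
    attr(prof, "n_residues") <- nchar(gsub("X", "", x$sequence))
    return(prof)
  }
  stopifnot(is.character(x))
  prof <- aa_composition(x)
  attr(prof, "n_residues") <- nchar(gsub("X", "", toupper(x)))
  prof
}
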