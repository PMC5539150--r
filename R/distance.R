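#' Pairwise evolutionary distances from a protein alignment
#'
#' p-distance (`mismatches / comparable columns`, where a column is
#' comparable when both rows are non-gap) or its Poisson multiple-hit
#' correction `-ln(1 - p)`. Saturated pairs (`p -> 1`) yield infinite
#' corrected distances and are flagged in `attr(, "saturated")`.
#'
#' @param msa alignment (named character vector, matrix or `AAStringSet`)
#'   with at least 3 rows.
#' @param correction `"p"` or `"poisson"` (default `"p"`).
#' @return symmetric distance matrix with tip ids as dimnames; attributes
#'   `correction` and `saturated` (logical matrix).
#' @export
protein_distance <- function(msa, correction = c("p", "poisson")) {
  correction <- match.arg(correction)
  m <- as_msa_matrix(msa)
  n <- nrow(m)
  if (n < 3) stop("need at least 3 sequences")
  ids <- rownames(m)
  gap <- m == "-"
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- !gap[i, ] & !gap[j, ]
      nc <- sum(comp)
      if (nc == 0)
        stop("no comparable columns between ", ids[i], " and ", ids[j])
      p <- sum(m[i, comp] != m[j, comp]) / nc
      d[i, j] <- d[j, i] <- p
    }
  }
  sat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (correction == "poisson") {
    sat <- d >= 1
    d <- ifelse(sat, Inf, -log(1 - d))
    diag(d) <- 0
  }
  attr(d, "correction") <- correction
  attr(d, "saturated") <- sat
  d
}
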