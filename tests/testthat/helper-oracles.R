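# Independent oracles used to check package operations. Each is a separate,
# deliberately naive implementation of the same mathematical definition.

# plain-R Needleman-Wunsch (linear gap) with the same canonical traceback
# preference (diagonal, then up, then left); returns identity = matches /
# alignment length
nw_identity_oracle <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  m <- length(a); n <- length(b)
  F <- matrix(0, m + 1, n + 1)
  F[1, ] <- (0:n) * gap
  F[, 1] <- (0:m) * gap
  for (i in 1:m) for (j in 1:n) {
    s <- if (a[i] == b[j]) match else mismatch
    F[i + 1, j + 1] <- max(F[i, j] + s, F[i, j + 1] + gap, F[i + 1, j] + gap)
  }
  i <- m; j <- n; matches <- 0; len <- 0
  while (i > 0 || j > 0) {
    s <- if (i > 0 && j > 0 && a[i] == b[j]) match else mismatch
    if (i > 0 && j > 0 &&
        isTRUE(all.equal(F[i + 1, j + 1], F[i, j] + s))) {
      if (a[i] == b[j]) matches <- matches + 1
      i <- i - 1; j <- j - 1
    } else if (i > 0 && isTRUE(all.equal(F[i + 1, j + 1], F[i, j + 1] + gap))) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    len <- len + 1
  }
  matches / len
}

# greedy clustering replayed from a precomputed identity matrix (oracle
# route: full matrix first, then the same first-fit greedy rule)
greedy_cluster_oracle <- function(proteins, threshold) {
  ident <- function(x, y) nw_identity_oracle(x, y)
  ord <- order(-nchar(proteins$sequence), proteins$id)
  p <- proteins[ord, ]
  reps <- character(0)
  assign <- character(nrow(p))
  for (i in seq_len(nrow(p))) {
    placed <- FALSE
    for (r in reps) {
      if (ident(p$sequence[i], p$sequence[p$id == r]) >= threshold) {
        assign[i] <- r; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, p$id[i]); assign[i] <- p$id[i] }
  }
  setNames(assign, p$id)
}

# character-tally composition oracle
composition_oracle <- function(seq) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  ch <- strsplit(toupper(seq), "")[[1]]
  ch <- ch[ch != "X"]
  counts <- vapply(aa, function(x) sum(ch == x), numeric(1))
  counts / length(ch)
}

# exhaustive column-scan p-distance oracle
pdist_oracle <- function(msa) {
  m <- do.call(rbind, strsplit(msa, ""))
  rownames(m) <- names(msa)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    mm <- 0; nc <- 0
    for (k in seq_len(ncol(m))) {
      if (m[i, k] != "-" && m[j, k] != "-") {
        nc <- nc + 1
        if (m[i, k] != m[j, k]) mm <- mm + 1
      }
    }
    d[i, j] <- mm / nc
  }
  d
}

# exhaustive bipartition-set comparison for RF distance
rf_oracle <- function(t1, t2) {
  biparts <- function(tr) {
    tips <- sort(tr$tip.label)
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    keys <- character(0)
    for (p in pp) {
      side <- sort(labs[p])
      comp <- sort(setdiff(tips, side))
      if (length(side) < 2 || length(comp) < 2) next
      canon <- if (tips[1] %in% side) comp else side
      keys <- c(keys, paste(canon, collapse = "|"))
    }
    unique(keys)
  }
  k1 <- biparts(t1); k2 <- biparts(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# seeded random protein sets for round-trip and property tests
rand_protein_set <- function(n, len_range = c(30, 80), seed = 1,
                             prefix = "RND") {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  withr::with_seed(seed, {
    lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
    data.frame(
      id = sprintf("%s%03d", prefix, seq_len(n)),
      gram = sample(c("positive", "negative", "unknown"), n, replace = TRUE),
      sequence = vapply(lens, function(l)
        paste(sample(aa, l, replace = TRUE), collapse = ""), character(1)),
      stringsAsFactors = FALSE)
  })
}

# mirror a replicon: flip coordinates around L and reverse strands
mirror_features <- function(features, L) {
  out <- features
  out$start <- L - features$end + 1L
  out$end <- L - features$start + 1L
  out$strand <- ifelse(features$strand == "+", "-", "+")
  as_gene_features(as.data.frame(out))
}
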