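#' Validate and classify a protein table
#'
#' A protein set is a plain `data.frame` with one row per sequence and columns
#' `id`, `organism`, `gram`, `phylum`, `family`, `niche`, `sequence`. Ids must
#' be non-empty and unique; sequences must be non-empty and restricted to the
#' 20 standard amino-acid letters plus `X`.
#'
#' @param x a data.frame with at least `id` and `sequence` columns; missing
#'   metadata columns are filled with `"unknown"` (gram) or `NA`.
#' @return the validated data.frame with class `protein_set`.
#' @export
as_protein_set <- function(x) {
  stopifnot(is.data.frame(x))
  if (!all(c("id", "sequence") %in% names(x)))
    stop("protein set needs 'id' and 'sequence' columns")
  for (col in c("organism", "phylum", "family", "niche"))
    if (is.null(x[[col]])) x[[col]] <- rep(NA_character_, nrow(x))
  if (is.null(x[["gram"]])) x[["gram"]] <- rep("unknown", nrow(x))
  x$id <- as.character(x$id)
  x$sequence <- toupper(as.character(x$sequence))
  x$gram <- as.character(x$gram)
  if (any(!nzchar(x$id))) stop("empty protein id")
  dup <- x$id[duplicated(x$id)]
  if (length(dup))
    stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "))
  if (any(nchar(x$sequence) < 1)) stop("zero-length sequence")
  bad_gram <- setdiff(unique(x$gram), GRAM_LEVELS)
  if (length(bad_gram))
    stop("gram label must be one of ", paste(GRAM_LEVELS, collapse = "/"),
         "; got: ", paste(bad_gram, collapse = ", "))
  ok <- grepl(paste0("^[", paste(c(AA20, "X"), collapse = ""), "]+$"), x$sequence)
  if (any(!ok))
    stop("sequence with letters outside the amino-acid alphabet (20 letters + X): ",
         paste(x$id[!ok], collapse = ", "))
  x <- x[, c("id", "organism", "gram", "phylum", "family", "niche", "sequence")]
  rownames(x) <- NULL
  class(x) <- c("protein_set", "data.frame")
  x
}

empty_protein_set <- function() {
  as_protein_set(data.frame(id = character(), sequence = character(),
                            stringsAsFactors = FALSE))
}

#' Read protein FASTA with `key=value` header metadata
#'
#' Headers are parsed as `id [key=value]...` where recognised keys are
#' `organism`, `gram`, `phylum`, `family` and `niche`; unknown keys are
#' ignored. An empty file yields an empty set with a warning.
#'
#' @param path FASTA file.
#' @return a [as_protein_set()] data.frame.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) {
    warning("empty FASTA file: ", path)
    return(empty_protein_set())
  }
  headers <- names(seqs)
  meta_keys <- c("organism", "gram", "phylum", "family", "niche")
  rows <- lapply(headers, function(h) {
    tok <- strsplit(trimws(h), "\\s+")[[1]]
    rec <- list(id = tok[1])
    kv <- tok[-1][grepl("=", tok[-1], fixed = TRUE)]
    for (f in kv) {
      key <- sub("=.*$", "", f)
      if (key %in% meta_keys) rec[[key]] <- sub("^[^=]*=", "", f)
    }
    rec
  })
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(id = r$id,
               organism = r$organism %||% NA_character_,
               gram = r$gram %||% "unknown",
               phylum = r$phylum %||% NA_character_,
               family = r$family %||% NA_character_,
               niche = r$niche %||% NA_character_,
               stringsAsFactors = FALSE)))
  df$sequence <- as.character(seqs)
  as_protein_set(df)
}

#' Write a protein set as FASTA with metadata headers
#'
#' @param proteins a [as_protein_set()] data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  proteins <- as_protein_set(proteins)
  hdr <- vapply(seq_len(nrow(proteins)), function(i) {
    p <- proteins[i, ]
    kv <- character(0)
    if (!is.na(p$organism)) kv <- c(kv, paste0("organism=", p$organism))
    if (p$gram != "unknown") kv <- c(kv, paste0("gram=", p$gram))
    for (key in c("phylum", "family", "niche"))
      if (!is.na(p[[key]])) kv <- c(kv, paste0(key, "=", p[[key]]))
    paste(c(p$id, kv), collapse = " ")
  }, character(1))
  ss <- Biostrings::AAStringSet(proteins$sequence)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
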