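#' Read gene features from GFF3
#'
#' Reads `gene`/`CDS` features (1-based inclusive coordinates per the GFF3
#' standard) into a plain feature table sorted by `(replicon_id, start)`.
#' Locus tags come from the `locus_tag` attribute, falling back to `ID`.
#' `gene_class` is assigned from `class_map` and defaults to `"other"`.
#'
#' Lines whose start exceeds their end are rejected with the offending line
#' number; strand symbols other than `+`/`-` are rejected.
#'
#' @param path GFF3 file.
#' @param class_map optional mapping `locus_tag -> gene_class`: a named
#'   character vector, a data.frame with columns `locus_tag`/`gene_class`,
#'   or a path to such a TSV. Classes must be `luxI`, `luxR` or `other`.
#' @return data.frame with columns `replicon_id`, `locus_tag`, `start`,
#'   `end`, `strand`, `gene_class`, `protein_id`, class `gene_features`.
#' @export
read_gene_features <- function(path, class_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_data <- !grepl("^\\s*(#|$)", lines)
  # line-level validation so coordinate and strand errors carry line numbers
  for (i in which(is_data)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) stop("GFF3 line ", i, ": fewer than 8 fields")
    if (!f[3] %in% c("gene", "CDS")) next
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e)) stop("GFF3 line ", i, ": non-numeric coordinates")
    if (s < 1) stop("GFF3 line ", i, ": non-positive coordinate")
    if (s > e) stop("GFF3 line ", i, ": start ", s, " > end ", e)
    if (!f[7] %in% c("+", "-"))
      stop("GFF3 line ", i, ": unknown strand symbol '", f[7], "'")
  }
  if (!any(is_data)) return(empty_gene_features())
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("gene", "CDS")]
  if (length(gr) == 0) return(empty_gene_features())
  mc <- S4Vectors::mcols(gr)
  locus <- if ("locus_tag" %in% names(mc)) as.character(mc$locus_tag) else rep(NA, length(gr))
  fallback <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA, length(gr))
  locus <- ifelse(is.na(locus), fallback, locus)
  if (any(is.na(locus))) stop("feature without locus_tag or ID attribute")
  pid <- if ("protein_id" %in% names(mc)) as.character(mc$protein_id) else rep(NA_character_, length(gr))
  df <- data.frame(
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    locus_tag = locus,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    protein_id = pid,
    stringsAsFactors = FALSE)
  df$gene_class <- "other"
  as_gene_features(df, class_map = class_map)
}

empty_gene_features <- function() {
  as_gene_features(data.frame(
    replicon_id = character(), locus_tag = character(),
    start = integer(), end = integer(), strand = character(),
    gene_class = character(), protein_id = character(),
    stringsAsFactors = FALSE))
}

#' @rdname read_gene_features
#' @param features a feature data.frame built in code.
#' @export
as_gene_features <- function(features, class_map = NULL) {
  req <- c("replicon_id", "locus_tag", "start", "end", "strand")
  if (!all(req %in% names(features)))
    stop("gene features need columns: ", paste(req, collapse = ", "))
  if (is.null(features$gene_class)) features$gene_class <- "other"
  if (is.null(features$protein_id)) features$protein_id <- NA_character_
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (nrow(features)) {
    if (any(features$start < 1)) stop("non-positive coordinate")
    if (any(features$start > features$end))
      stop("start > end for locus: ",
           paste(features$locus_tag[features$start > features$end], collapse = ", "))
    if (any(!features$strand %in% c("+", "-")))
      stop("unknown strand symbol")
  }
  if (!is.null(class_map)) {
    cm <- normalize_class_map(class_map)
    hit <- features$locus_tag %in% names(cm)
    features$gene_class[hit] <- unname(cm[features$locus_tag[hit]])
  }
  bad <- setdiff(unique(features$gene_class), c("luxI", "luxR", "other"))
  if (length(bad)) stop("gene_class must be luxI/luxR/other; got: ",
                        paste(bad, collapse = ", "))
  dup <- duplicated(features[, c("replicon_id", "locus_tag")])
  if (any(dup))
    stop("duplicate locus_tag on a replicon: ",
         paste(unique(features$locus_tag[dup]), collapse = ", "))
  features <- features[order(features$replicon_id, features$start, features$end), ,
                       drop = FALSE]
  features <- features[, c("replicon_id", "locus_tag", "start", "end", "strand",
                           "gene_class", "protein_id")]
  rownames(features) <- NULL
  class(features) <- c("gene_features", "data.frame")
  features
}

normalize_class_map <- function(class_map) {
  if (is.character(class_map) && length(class_map) == 1 && file.exists(class_map))
    class_map <- read.delim(class_map, stringsAsFactors = FALSE)
  if (is.data.frame(class_map)) {
    stopifnot(all(c("locus_tag", "gene_class") %in% names(class_map)))
    class_map <- setNames(class_map$gene_class, class_map$locus_tag)
  }
  stopifnot(is.character(class_map), !is.null(names(class_map)))
  class_map
}

#' Write gene features as GFF3
#'
#' Coordinates are written exactly as stored (1-based inclusive); the locus
#' tag is emitted both as `ID` and `locus_tag` attributes.
#'
#' @param features a `gene_features` table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_features <- function(features, path) {
  features <- as_gene_features(features)
  if (nrow(features) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = features$replicon_id,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- features$locus_tag
  S4Vectors::mcols(gr)$locus_tag <- features$locus_tag
  S4Vectors::mcols(gr)$protein_id <- features$protein_id
  S4Vectors::mcols(gr)$source <- "luxcassette"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname read_gene_features
#' @param features a `gene_features` table whose classes should be exported.
#' @export
write_class_map <- function(features, path) {
  features <- as_gene_features(features)
  write.table(features[, c("locus_tag", "gene_class")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
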