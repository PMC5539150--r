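#' Read a domain-hit table
#'
#' Tab-separated with a mandatory header. Required columns: `protein_id`,
#' `domain_id`, `source` (one of `interpro`, `cdd`); optional: `start`, `end`,
#' `description` (1-based residue coordinates). When `proteins` is supplied,
#' every `protein_id` must resolve and coordinates must satisfy
#' `1 <= start <= end <= protein length`.
#'
#' @param path TSV file.
#' @param proteins optional [as_protein_set()] table for cross-validation.
#' @return data.frame of hits.
#' @export
read_domain_hits <- function(path, proteins = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_domain_hits(df, proteins)
}

#' @rdname read_domain_hits
#' @param hits a data.frame of domain hits (e.g. built in code).
#' @export
validate_domain_hits <- function(hits, proteins = NULL) {
  req <- c("protein_id", "domain_id", "source")
  if (!all(req %in% names(hits)))
    stop("domain-hit table must have columns: ", paste(req, collapse = ", "))
  if (is.null(hits$start)) hits$start <- rep(NA_integer_, nrow(hits))
  if (is.null(hits$end)) hits$end <- rep(NA_integer_, nrow(hits))
  if (is.null(hits$description))
    hits$description <- rep(NA_character_, nrow(hits))
  bad_src <- setdiff(unique(hits$source), c("interpro", "cdd"))
  if (length(bad_src))
    stop("unknown domain source(s): ", paste(bad_src, collapse = ", "))
  has_coord <- !is.na(hits$start) | !is.na(hits$end)
  if (any(has_coord & (is.na(hits$start) | is.na(hits$end))))
    stop("domain hit with only one of start/end")
  coords <- !is.na(hits$start)
  if (any(coords & (hits$start < 1 | hits$start > hits$end)))
    stop("domain hit violating 1 <= start <= end")
  if (!is.null(proteins)) {
    proteins <- as_protein_set(proteins)
    orphans <- setdiff(hits$protein_id, proteins$id)
    if (length(orphans))
      stop("domain hits for unknown protein id(s): ",
           paste(unique(orphans), collapse = ", "))
    len <- setNames(nchar(proteins$sequence), proteins$id)
    over <- coords & hits$end > len[hits$protein_id]
    if (any(over))
      stop("domain hit end beyond protein length for: ",
           paste(unique(hits$protein_id[over]), collapse = ", "))
  }
  hits[, c("protein_id", "domain_id", "source", "start", "end", "description")]
}

#' @rdname read_domain_hits
#' @export
write_domain_hits <- function(hits, path) {
  hits <- validate_domain_hits(hits)
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read tip metadata for phylogenetic analyses
#'
#' Sidecar TSV with columns `tip_id`, `gram` (`positive`/`negative`),
#' `taxonomy`, `niche`; one row per tree tip.
#'
#' @param path TSV file.
#' @return data.frame of tip metadata.
#' @export
read_tip_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_tip_metadata(df)
}

#' @rdname read_tip_metadata
#' @param metadata a metadata data.frame built in code.
#' @export
validate_tip_metadata <- function(metadata) {
  req <- c("tip_id", "gram", "taxonomy", "niche")
  if (!all(req %in% names(metadata)))
    stop("tip metadata must have columns: ", paste(req, collapse = ", "))
  dup <- metadata$tip_id[duplicated(metadata$tip_id)]
  if (length(dup))
    stop("duplicate tip_id(s): ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(metadata$gram), c("positive", "negative"))
  if (length(bad))
    stop("tip gram label must be positive/negative; got: ",
         paste(bad, collapse = ", "))
  metadata[, req]
}

#' @rdname read_tip_metadata
#' @export
write_tip_metadata <- function(metadata, path) {
  metadata <- validate_tip_metadata(metadata)
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
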