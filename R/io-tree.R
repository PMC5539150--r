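#' Read a Newick tree with bootstrap supports
#'
#' Reads a single Newick tree. Numeric internal node labels are interpreted
#' as bootstrap supports in `[0, 100]`; absent branch lengths default to 0.
#' Unbalanced parentheses are reported with the character offset of the
#' first imbalance.
#'
#' @param path Newick file.
#' @return an [ape::read.tree()] `phylo` object; supports stay in
#'   `$node.label`.
#' @export
read_support_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path), collapse = "")
  check_parens(txt)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse Newick tree in ", path)
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0, nrow(tree$edge))
  sup <- node_supports(tree)
  bad <- !is.na(sup) & (sup < 0 | sup > 100)
  if (any(bad)) stop("bootstrap support outside [0, 100]")
  tree
}

check_parens <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  neg <- which(depth < 0)
  if (length(neg))
    stop("unbalanced parentheses: unmatched ')' at character offset ", neg[1])
  if (length(depth) && depth[length(depth)] != 0)
    stop("unbalanced parentheses: ", depth[length(depth)],
         " '(' left open at end of input (offset ", length(depth), ")")
  invisible(TRUE)
}

#' @rdname read_support_tree
#' @param tree a `phylo` object.
#' @export
write_support_tree <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

# numeric bootstrap supports per internal node (NA where absent/non-numeric)
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup
}

#' Read/write an amino-acid multiple sequence alignment
#'
#' Alignments travel as named character vectors of equal-length aligned
#' sequences (gap `-`), read from / written to aligned FASTA.
#'
#' @param path aligned FASTA file.
#' @return named character vector.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0) stop("empty alignment: ", path)
  msa <- as.character(ss)
  names(msa) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(msa))) stop("duplicate sequence id in alignment")
  if (length(unique(nchar(msa))) != 1)
    stop("alignment rows differ in length")
  toupper(msa)
}

#' @rdname read_alignment
#' @param msa named character vector (or character matrix) of aligned rows.
#' @export
write_alignment <- function(msa, path) {
  m <- as_msa_matrix(msa)
  rows <- apply(m, 1, paste, collapse = "")
  ss <- Biostrings::AAStringSet(rows)
  names(ss) <- rownames(m)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# accept named character vector, character matrix, or AAStringSet/
# AAMultipleAlignment; return character matrix (rows = sequences)
as_msa_matrix <- function(msa) {
  if (is.matrix(msa)) {
    if (is.null(rownames(msa))) stop("alignment matrix needs rownames")
    return(msa)
  }
  if (methods::is(msa, "AAMultipleAlignment"))
    msa <- methods::as(msa, "AAStringSet")
  if (methods::is(msa, "XStringSet")) {
    v <- as.character(msa)
    names(v) <- names(msa)
    msa <- v
  }
  stopifnot(is.character(msa), !is.null(names(msa)))
  if (length(unique(nchar(msa))) != 1) stop("alignment rows differ in length")
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(m) <- names(msa)
  m
}
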