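#' Configuration for domain-based LuxI/LuxR candidate mining
#'
#' LuxI candidates carry the autoinducer-synthase domain (IPR001690). LuxR
#' candidates must carry both a C-terminal DNA-binding domain (IPR000792
#' LuxR-type HTH, or the winged HTH superfamily IPR011991) and an
#' autoinducer/ligand-binding-class domain. The ABD list is not standardised
#' across annotation pipelines, so it is an explicit, configurable set; the
#' default is a reconstruction covering the LuxR autoinducer-binding domain
#' (IPR005143), GAF-like ligand pockets (IPR029016) and the CheY-like
#' receiver domains that accept the signal in two-component systems
#' (IPR011006, IPR001789).
#'
#' Length windows: LuxR candidates are restricted to 200-300 residues (the
#' canonical regulator envelope); the LuxI window defaults to a permissive
#' 150-350 around the observed 191-292 synthase range.
#'
#' @param luxi_domains,luxr_dna_domains,luxr_abd_domains character vectors of
#'   domain ids.
#' @param luxr_min_len,luxr_max_len,luxi_min_len,luxi_max_len residue bounds.
#' @return a `mining_config` list.
#' @export
mining_config <- function(luxi_domains = "IPR001690",
                          luxr_dna_domains = c("IPR000792", "IPR011991"),
                          luxr_abd_domains = c("IPR005143", "IPR029016",
                                               "IPR011006", "IPR001789"),
                          luxr_min_len = 200, luxr_max_len = 300,
                          luxi_min_len = 150, luxi_max_len = 350) {
  if (length(luxi_domains) == 0 || length(luxr_dna_domains) == 0)
    stop("domain sets must be non-empty")
  if (luxi_min_len >= luxi_max_len || luxr_min_len >= luxr_max_len)
    stop("min length must be below max length")
  structure(list(luxi_domains = luxi_domains,
                 luxr_dna_domains = luxr_dna_domains,
                 luxr_abd_domains = luxr_abd_domains,
                 luxr_min_len = luxr_min_len, luxr_max_len = luxr_max_len,
                 luxi_min_len = luxi_min_len, luxi_max_len = luxi_max_len),
            class = "mining_config")
}

check_orphans <- function(proteins, hits) {
  orphans <- setdiff(hits$protein_id, proteins$id)
  if (length(orphans))
    stop("domain hits reference unknown protein id(s): ",
         paste(unique(orphans), collapse = ", "))
}

#' Select putative LuxI synthase candidates
#'
#' Keeps proteins with at least one hit in `cfg$luxi_domains` and a length
#' inside the LuxI window. Output order is stable by id.
#'
#' @param proteins a [as_protein_set()] table.
#' @param hits a domain-hit table ([read_domain_hits()]).
#' @param cfg a [mining_config()].
#' @return the selected subset of `proteins`.
#' @export
select_luxi <- function(proteins, hits, cfg = mining_config()) {
  proteins <- as_protein_set(proteins)
  hits <- validate_domain_hits(hits)
  check_orphans(proteins, hits)
  with_domain <- unique(hits$protein_id[hits$domain_id %in% cfg$luxi_domains])
  len <- nchar(proteins$sequence)
  keep <- proteins$id %in% with_domain &
    len >= cfg$luxi_min_len & len <= cfg$luxi_max_len
  out <- proteins[keep, , drop = FALSE]
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Select putative LuxR regulator candidates (two-domain filter)
#'
#' A candidate must carry a DNA-binding-class domain AND an
#' autoinducer/ligand-binding-class domain, and fall inside the LuxR length
#' window. Regulators with the HTH domain alone do not pass: the two-domain
#' requirement is what separates AHL-responsive LuxR-family proteins from
#' the broader HTH crowd.
#'
#' @inheritParams select_luxi
#' @return the selected subset of `proteins`.
#' @export
select_luxr <- function(proteins, hits, cfg = mining_config()) {
  proteins <- as_protein_set(proteins)
  hits <- validate_domain_hits(hits)
  check_orphans(proteins, hits)
  if (length(cfg$luxr_abd_domains) == 0)
    stop("luxr_abd_domains is empty: the LuxR two-domain filter needs an ",
         "explicit autoinducer/ligand-binding domain list")
  has_dna <- unique(hits$protein_id[hits$domain_id %in% cfg$luxr_dna_domains])
  has_abd <- unique(hits$protein_id[hits$domain_id %in% cfg$luxr_abd_domains])
  len <- nchar(proteins$sequence)
  keep <- proteins$id %in% has_dna & proteins$id %in% has_abd &
    len >= cfg$luxr_min_len & len <= cfg$luxr_max_len
  out <- proteins[keep, , drop = FALSE]
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Census of per-protein domain architectures
#'
#' Collapses each protein's hits to its unique domain set and counts
#' identical sets (architecture combinations), plus per-domain occurrence
#' counts (number of proteins carrying each domain). Both tallies are
#' invariant to input row order.
#'
#' @param hits a domain-hit table.
#' @return list with data.frames `combinations` (`combination`, `count`) and
#'   `domains` (`domain_id`, `count`), each sorted by decreasing count then
#'   name.
#' @export
domain_architecture_census <- function(hits) {
  hits <- validate_domain_hits(hits)
  if (nrow(hits) == 0)
    return(list(
      combinations = data.frame(combination = character(), count = integer()),
      domains = data.frame(domain_id = character(), count = integer())))
  sets <- lapply(split(hits$domain_id, hits$protein_id),
                 function(d) sort(unique(d)))
  combo <- vapply(sets, paste, character(1), collapse = "+")
  ctab <- table(combo)
  combinations <- data.frame(combination = names(ctab),
                             count = as.integer(ctab),
                             stringsAsFactors = FALSE)
  combinations <- combinations[order(-combinations$count,
                                     combinations$combination), ]
  dtab <- table(unlist(sets))
  domains <- data.frame(domain_id = names(dtab), count = as.integer(dtab),
                        stringsAsFactors = FALSE)
  domains <- domains[order(-domains$count, domains$domain_id), ]
  rownames(combinations) <- rownames(domains) <- NULL
  list(combinations = combinations, domains = domains)
}
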