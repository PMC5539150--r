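#' Parse a cassette topology pattern into a generator spec
#'
#' Accepts the canonical pattern grammar (see [render_topology()]), e.g.
#' `"R>I>"`, `"R><I"`, `"<I X(2) R>"`, `"R> X(>7) <I"`, plus the genomic
#' gap to plant between the two ORFs. For the `X(>7)` bucket the concrete
#' intervening count defaults to 8 and may be overridden.
#'
#' @param pattern pattern string.
#' @param gap_bp bases strictly between the two ORFs.
#' @param n_intervening optional explicit intervening-gene count (must be
#'   consistent with the pattern).
#' @return a `cassette_spec` list.
#' @export
cassette_spec <- function(pattern, gap_bp, n_intervening = NULL) {
  rx <- "^\\s*(<[IR]|[IR]>)\\s*(?:X\\((>?)([0-9]+)\\)\\s*)?(<[IR]|[IR]>)\\s*$"
  m <- regmatches(pattern, regexec(rx, pattern))[[1]]
  if (length(m) == 0) stop("cannot parse topology pattern: ", pattern)
  parse_tok <- function(tok) {
    cls <- if (grepl("I", tok)) "luxI" else "luxR"
    strand <- if (grepl(">$", tok)) "+" else "-"
    list(class = cls, strand = strand)
  }
  left <- parse_tok(m[2]); right <- parse_tok(m[5])
  if (left$class == right$class)
    stop("pattern must contain one I and one R: ", pattern)
  if (m[4] == "") {
    n <- 0L
  } else if (m[3] == ">") {
    bound <- as.integer(m[4])
    n <- if (is.null(n_intervening)) bound + 1L else as.integer(n_intervening)
    if (n <= bound) stop("pattern X(>", bound, ") needs n_intervening > ", bound)
  } else {
    n <- as.integer(m[4])
    if (!is.null(n_intervening) && n_intervening != n)
      stop("n_intervening disagrees with pattern: ", pattern)
  }
  if (is.null(n_intervening)) n_intervening <- n
  if (n_intervening != n && m[3] != ">")
    stop("n_intervening disagrees with pattern: ", pattern)
  structure(list(left = left, right = right, gap_bp = as.integer(gap_bp),
                 n_intervening = as.integer(n_intervening),
                 pattern = render_topology(left$class, left$strand,
                                           right$class, right$strand,
                                           as.integer(n_intervening))),
            class = "cassette_spec")
}

# SwissProt-wide average residue frequencies; the realistic background for
# i.i.d. protein sequence generation
swissprot_freqs <- function() {
  f <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.72, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.86, M = 2.41, N = 4.06,
         P = 4.73, Q = 3.93, R = 5.53, S = 6.61, T = 5.35, V = 6.86,
         W = 1.10, Y = 2.92)
  f <- f[AA20]
  f / sum(f)
}

#' Define a synthetic survey scenario
#'
#' Bundles every tunable of the synthetic-data generators with the default
#' study conditions: the four observed cassette topology classes at their
#' reported gaps, two decoy solo pairs beyond the 3400 bp distance
#' criterion, a planted alanine enrichment of 1.4x at 50 sequences per
#' group with lengths in the 200-300 residue regulator window, and an
#' 8 + 8 tip two-clade species tree with a long stem separating the gram
#' groups. A fixed seed makes every generator output reproducible
#' bit-for-bit.
#'
#' @param seed integer seed fixing all generator randomness.
#' @param cassette_specs list of [cassette_spec()] objects.
#' @param n_decoys decoy solo luxI/luxR pairs placed beyond `max_gap_bp`.
#' @param max_gap_bp distance criterion the decoys must exceed.
#' @param aac_shift named residue multipliers for group 2 (e.g. `c(A = 1.4)`).
#' @param group_sizes sequences per composition group.
#' @param seq_length_range uniform length range for generated proteins.
#' @param base_freqs residue frequencies for group 1 (default SwissProt-wide
#'   averages).
#' @param tree_spec list: `n_gp`, `n_gn` tips per gram clade, `clade_scale`
#'   (within-clade branch-length multiplier), `stem_length` (branch
#'   separating the clades, in expected substitutions/site).
#' @param hgt_events data.frame with columns `tip`, `donor`, `genes`
#'   (`"luxI"`, `"luxR"` or `"both"`), or `NULL` for no events.
#' @param msa_length simulated alignment columns.
#' @param substitution_rate global rate multiplier for sequence evolution.
#' @param donor_branch branch length attaching a transferred gene inside
#'   the donor clade.
#' @return a `qs_scenario` list.
#' @export
synthetic_scenario <- function(seed = 1,
                               cassette_specs = list(
                                 cassette_spec("R>I>", gap_bp = 222),
                                 cassette_spec("R><I", gap_bp = 162),
                                 cassette_spec("<I X(2) R>", gap_bp = 730),
                                 cassette_spec("R> X(>7) <I", gap_bp = 883,
                                               n_intervening = 8)),
                               n_decoys = 2,
                               max_gap_bp = 3400,
                               aac_shift = c(A = 1.4),
                               group_sizes = c(50, 50),
                               seq_length_range = c(200, 300),
                               base_freqs = swissprot_freqs(),
                               tree_spec = list(n_gp = 8, n_gn = 8,
                                                clade_scale = 0.2,
                                                stem_length = 0.5),
                               hgt_events = NULL,
                               msa_length = 200,
                               substitution_rate = 1,
                               donor_branch = 0.02) {
  stopifnot(length(group_sizes) == 2, length(seq_length_range) == 2)
  if (!is.null(hgt_events)) {
    stopifnot(is.data.frame(hgt_events),
              all(c("tip", "donor", "genes") %in% names(hgt_events)),
              all(hgt_events$genes %in% c("luxI", "luxR", "both")))
  }
  structure(list(seed = as.integer(seed), cassette_specs = cassette_specs,
                 n_decoys = n_decoys, max_gap_bp = max_gap_bp,
                 aac_shift = aac_shift, group_sizes = group_sizes,
                 seq_length_range = seq_length_range, base_freqs = base_freqs,
                 tree_spec = tree_spec, hgt_events = hgt_events,
                 msa_length = msa_length,
                 substitution_rate = substitution_rate,
                 donor_branch = donor_branch),
            class = "qs_scenario")
}

#' Generate annotated replicons with planted cassettes and decoys
#'
#' Emits one replicon per cassette spec, each carrying the requested
#' luxI/luxR pair at the requested gap with the requested number of
#' intervening `other` genes, plus decoy replicons holding solo luxI and
#' luxR loci separated by more than the distance criterion. The returned
#' truth table is sufficient to score [pair_cassettes()] /
#' [classify_topology()] with no other information.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir optional output directory; when given, writes
#'   `replicons.gff3`, `class_map.tsv` and `truth.tsv`.
#' @return list with `features` (a `gene_features` table), `class_map`
#'   (named vector), `truth` (data.frame) and `paths`.
#' @export
make_replicons <- function(scenario, dir = NULL) {
  stopifnot(inherits(scenario, "qs_scenario"))
  res <- withr::with_seed(scenario$seed, {
    rows <- list(); truth <- list()
    gene_len <- function(cls) {
      if (cls == "luxI") sample(seq(576, 879, by = 3), 1)
      else sample(seq(603, 903, by = 3), 1)
    }
    for (ci in seq_along(scenario$cassette_specs)) {
      spec <- scenario$cassette_specs[[ci]]
      rep_id <- sprintf("synth_rep%02d", ci)
      l_len <- gene_len(spec$left$class)
      l_start <- 101L; l_end <- l_start + l_len - 1L
      r_start <- l_end + spec$gap_bp + 1L
      r_len <- gene_len(spec$right$class)
      r_end <- r_start + r_len - 1L
      tag <- function(cls) if (cls == "luxI") "I" else "R"
      l_tag <- sprintf("SYN%02d_%s", ci, tag(spec$left$class))
      r_tag <- sprintf("SYN%02d_%s", ci, tag(spec$right$class))
      rows[[length(rows) + 1]] <- data.frame(
        replicon_id = rep_id,
        locus_tag = c(l_tag, r_tag),
        start = c(l_start, r_start), end = c(l_end, r_end),
        strand = c(spec$left$strand, spec$right$strand),
        gene_class = c(spec$left$class, spec$right$class),
        stringsAsFactors = FALSE)
      n <- spec$n_intervening
      if (n > 0) {
        unit <- spec$gap_bp %/% n
        glen <- 3L * ((unit - 4L) %/% 3L)
        if (glen < 30)
          stop("infeasible cassette spec: ", n, " intervening genes do not ",
               "fit in a ", spec$gap_bp, " bp gap")
        starts <- l_end + 1L + (seq_len(n) - 1L) * unit + 2L
        rows[[length(rows) + 1]] <- data.frame(
          replicon_id = rep_id,
          locus_tag = sprintf("SYN%02d_X%02d", ci, seq_len(n)),
          start = starts, end = starts + glen - 1L,
          strand = rep(c("+", "-"), length.out = n),
          gene_class = "other", stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1]] <- data.frame(
        replicon_id = rep_id,
        luxI_locus = if (spec$left$class == "luxI") l_tag else r_tag,
        luxR_locus = if (spec$left$class == "luxR") l_tag else r_tag,
        gap_bp = spec$gap_bp, n_intervening = n, pattern = spec$pattern,
        stringsAsFactors = FALSE)
    }
    for (d in seq_len(scenario$n_decoys)) {
      rep_id <- sprintf("synth_decoy%02d", d)
      i_len <- sample(seq(576, 879, by = 3), 1)
      r_len <- sample(seq(603, 903, by = 3), 1)
      i_start <- 101L; i_end <- i_start + i_len - 1L
      r_start <- i_end + scenario$max_gap_bp + 1000L
      rows[[length(rows) + 1]] <- data.frame(
        replicon_id = rep_id,
        locus_tag = sprintf("DEC%02d_%s", d, c("I", "R")),
        start = c(i_start, r_start), end = c(i_end, r_start + r_len - 1L),
        strand = c("+", "+"), gene_class = c("luxI", "luxR"),
        stringsAsFactors = FALSE)
    }
    features <- as_gene_features(do.call(rbind, rows))
    list(features = features, truth = do.call(rbind, truth))
  })
  class_map <- setNames(res$features$gene_class, res$features$locus_tag)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(gff = file.path(dir, "replicons.gff3"),
                  class_map = file.path(dir, "class_map.tsv"),
                  truth = file.path(dir, "truth.tsv"))
    write_gene_features(res$features, paths$gff)
    write_class_map(res$features, paths$class_map)
    write.table(res$truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(features = res$features, class_map = class_map, truth = res$truth,
       paths = paths)
}

#' Generate two composition groups with a planted residue shift
#'
#' Group 1 sequences are drawn i.i.d. from the scenario's base residue
#' frequencies, group 2 from the same frequencies multiplied by
#' `aac_shift` and renormalised; lengths are uniform over
#' `seq_length_range`. Group 1 carries the `gram=negative` label (the
#' reference group), group 2 `gram=positive`.
#'
#' @inheritParams make_replicons
#' @return list with `group1`, `group2` (protein sets) and `truth`
#'   (`shift`, `base_freqs`, `shifted_freqs`); plus `paths` when `dir` is
#'   given.
#' @export
make_aac_groups <- function(scenario, dir = NULL) {
  stopifnot(inherits(scenario, "qs_scenario"))
  base <- scenario$base_freqs[AA20]
  if (any(is.na(base)) || any(base < 0) || sum(base) <= 0)
    stop("base_freqs must be nonnegative over the 20 residues")
  base <- base / sum(base)
  mult <- setNames(rep(1, 20), AA20)
  if (length(scenario$aac_shift)) {
    bad <- setdiff(names(scenario$aac_shift), AA20)
    if (length(bad)) stop("aac_shift for unknown residue(s): ",
                          paste(bad, collapse = ", "))
    mult[names(scenario$aac_shift)] <- scenario$aac_shift
  }
  shifted <- base * mult
  if (sum(shifted) <= 0) stop("shift not renormalizable")
  shifted <- shifted / sum(shifted)
  lr <- scenario$seq_length_range
  out <- withr::with_seed(scenario$seed, {
    gen <- function(n, freqs, prefix, gram) {
      lens <- sample(seq(lr[1], lr[2]), n, replace = TRUE)
      seqs <- vapply(lens, function(l)
        paste(sample(AA20, l, replace = TRUE, prob = freqs), collapse = ""),
        character(1))
      as_protein_set(data.frame(id = sprintf("%s_%03d", prefix, seq_len(n)),
                                gram = gram, sequence = seqs,
                                stringsAsFactors = FALSE))
    }
    list(group1 = gen(scenario$group_sizes[1], base, "BASE", "negative"),
         group2 = gen(scenario$group_sizes[2], shifted, "SHIFT", "positive"))
  })
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(group1 = file.path(dir, "group1.fasta"),
                  group2 = file.path(dir, "group2.fasta"))
    write_protein_fasta(out$group1, paths$group1)
    write_protein_fasta(out$group2, paths$group2)
  }
  list(group1 = out$group1, group2 = out$group2,
       truth = list(shift = scenario$aac_shift, base_freqs = base,
                    shifted_freqs = shifted),
       paths = paths)
}

#' Evolve marker and gene alignments on a species tree with planted HGT
#'
#' Builds a random bifurcating species tree whose gram-positive (`GPxx`)
#' and gram-negative (`GNxx`) tips form monophyletic clades separated by a
#' long stem, evolves a 16S-like marker alignment on it under an
#' equal-rates (Poisson-style) amino-acid substitution process, and evolves
#' luxI/luxR gene alignments on per-gene trees in which each planted
#' transfer detaches the recipient tip and re-attaches it on the donor's
#' terminal branch — guaranteeing the gene-tree signal a transfer leaves.
#' The concatenated alignment is the column-wise join of the two genes.
#' Recipient and donor tips are given the same ecological niche.
#'
#' @inheritParams make_replicons
#' @return list: `species_tree`, `gene_trees` (per gene), `marker_msa`,
#'   `luxi_msa`, `luxr_msa`, `concat_msa`, `metadata`, `cassette_map`,
#'   `truth` (the planted events), and `paths` when `dir` is given.
#' @export
evolve_on_tree <- function(scenario, dir = NULL) {
  stopifnot(inherits(scenario, "qs_scenario"))
  ts <- scenario$tree_spec
  stopifnot(ts$n_gp >= 2, ts$n_gn >= 2)
  events <- scenario$hgt_events
  out <- withr::with_seed(scenario$seed, {
    clade <- function(n, prefix) {
      t <- ape::rtree(n, tip.label = sprintf("%s%02d", prefix, seq_len(n)))
      # branch lengths bounded away from zero so every split leaves a
      # resolvable signature at the simulated alignment lengths
      t$edge.length <- runif(length(t$edge.length), 0.3, 1) * ts$clade_scale
      t
    }
    t_gp <- clade(ts$n_gp, "GP")
    t_gn <- clade(ts$n_gn, "GN")
    strip <- function(t) sub(";$", "", ape::write.tree(t))
    species <- ape::read.tree(text = sprintf(
      "(%s:%.8f,%s:%.8f);", strip(t_gp), ts$stem_length,
      strip(t_gn), ts$stem_length))
    if (!is.null(events)) {
      # donor "auto" resolves to the deepest gram-negative tip: a donor
      # that is not also the recipient's vertically nearest relative, so
      # planted transfer signal stays distinguishable from vertical descent
      if (any(events$donor == "auto")) {
        depth <- ape::node.depth.edgelength(species)[seq_along(species$tip.label)]
        names(depth) <- species$tip.label
        gn <- grep("^GN", species$tip.label, value = TRUE)
        deepest <- gn[order(-depth[gn], gn)][1]
        events$donor[events$donor == "auto"] <- deepest
      }
      missing <- setdiff(c(events$tip, events$donor), species$tip.label)
      if (length(missing))
        stop("hgt tip(s) not in tree: ", paste(missing, collapse = ", "))
    }
    gene_tree <- function(gene) {
      tr <- species
      if (!is.null(events)) {
        for (k in seq_len(nrow(events))) {
          ev <- events[k, ]
          if (!(ev$genes %in% c(gene, "both"))) next
          tr <- regraft_tip(tr, ev$tip, ev$donor, scenario$donor_branch)
        }
      }
      tr
    }
    trees <- list(luxI = gene_tree("luxI"), luxR = gene_tree("luxR"))
    sim <- function(tr) {
      s <- phangorn::simSeq(tr, l = scenario$msa_length, type = "AA",
                            rate = scenario$substitution_rate)
      m <- as.character(s)
      setNames(apply(m, 1, paste, collapse = ""), rownames(m))
    }
    marker <- sim(species)
    luxi <- sim(trees$luxI)
    luxr <- sim(trees$luxR)
    list(species = species, trees = trees, marker = marker,
         luxi = luxi, luxr = luxr, events = events)
  })
  events <- out$events
  tips <- out$species$tip.label
  ord <- sort(tips)
  concat <- setNames(paste0(out$luxi[ord], out$luxr[ord]), ord)
  gram <- ifelse(grepl("^GP", ord), "positive", "negative")
  niche <- rep(c("aquatic", "host", "sediment"), length.out = length(ord))
  names(niche) <- ord
  if (!is.null(events)) {
    for (k in seq_len(nrow(events))) {
      niche[events$tip[k]] <- "soil"
      niche[events$donor[k]] <- "soil"
    }
  }
  metadata <- validate_tip_metadata(data.frame(
    tip_id = ord, gram = gram,
    taxonomy = ifelse(gram == "positive", "Actinobacteria", "Proteobacteria"),
    niche = unname(niche), stringsAsFactors = FALSE))
  gp <- ord[gram == "positive"]
  cassette_map <- data.frame(cassette_id = gp, luxi_tip = gp, luxr_tip = gp,
                             concat_tip = gp, stringsAsFactors = FALSE)
  truth <- if (is.null(events))
    data.frame(tip = character(), donor = character(), genes = character(),
               stringsAsFactors = FALSE) else events
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(species_tree = file.path(dir, "species_tree.nwk"),
                  marker_msa = file.path(dir, "marker.aln.fasta"),
                  luxi_msa = file.path(dir, "luxi.aln.fasta"),
                  luxr_msa = file.path(dir, "luxr.aln.fasta"),
                  concat_msa = file.path(dir, "concat.aln.fasta"),
                  metadata = file.path(dir, "tip_metadata.tsv"),
                  truth = file.path(dir, "hgt_truth.tsv"))
    write_support_tree(out$species, paths$species_tree)
    write_alignment(out$marker, paths$marker_msa)
    write_alignment(out$luxi, paths$luxi_msa)
    write_alignment(out$luxr, paths$luxr_msa)
    write_alignment(concat, paths$concat_msa)
    write_tip_metadata(metadata, paths$metadata)
    write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(species_tree = out$species, gene_trees = out$trees,
       marker_msa = out$marker, luxi_msa = out$luxi, luxr_msa = out$luxr,
       concat_msa = concat, metadata = metadata, cassette_map = cassette_map,
       truth = truth, paths = paths)
}

# detach a tip and re-attach it near the end of the donor's terminal
# branch, so the recipient/donor cherry is subtended by most of that
# branch and carries strong bootstrap signal
regraft_tip <- function(tree, tip, donor, branch) {
  if (!tip %in% tree$tip.label) stop("hgt tip not in tree: ", tip)
  if (!donor %in% tree$tip.label) stop("donor tip not in tree: ", donor)
  tr <- ape::drop.tip(tree, tip)
  didx <- which(tr$tip.label == donor)
  el <- tr$edge.length[tr$edge[, 2] == didx]
  phytools::bind.tip(tr, tip, edge.length = branch, where = didx,
                     position = el * 0.1)
}
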