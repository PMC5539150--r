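#' Configure a full survey run
#'
#' Inputs may be in-memory objects or file paths (FASTA/TSV/GFF3/Newick,
#' resolved with the package readers). Stages whose inputs are absent are
#' skipped; referenced files must exist.
#'
#' @param proteins protein set or FASTA path.
#' @param domain_hits domain-hit table or TSV path.
#' @param features gene features or GFF3 path.
#' @param class_map locus_tag to gene_class mapping (vector, data.frame or
#'   TSV path) applied when `features` is read from GFF3.
#' @param mining a [mining_config()].
#' @param redundancy_threshold identity threshold for representative
#'   selection.
#' @param max_gap_bp cassette distance criterion.
#' @param composition_test `"welch"` or `"wilcoxon"`.
#' @param msa,msa_ref alignment (object or aligned-FASTA path) and
#'   reference id for conservation scoring.
#' @param conservation_threshold conservation call threshold, percent.
#' @param luxi_msa,luxr_msa,marker_msa gene and marker alignments for the
#'   phylogenetic stage.
#' @param reference_tree reference (16S) `phylo` or Newick path; built by
#'   neighbor joining on `marker_msa` when absent.
#' @param tip_metadata tip metadata table or TSV path.
#' @param cassette_map cassette-to-tip map for co-transfer classification.
#' @param bootstrap_reps bootstrap pseudo-replicates per gene tree.
#' @param min_support bootstrap cutoff for HGT and co-transfer calls.
#' @param seed integer seed driving all stochastic stages.
#' @param outdir optional directory for per-stage artifacts and the JSON
#'   report.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(proteins = NULL, domain_hits = NULL,
                            features = NULL, class_map = NULL,
                            mining = mining_config(),
                            redundancy_threshold = 0.30,
                            max_gap_bp = 3400,
                            composition_test = "welch",
                            msa = NULL, msa_ref = NULL,
                            conservation_threshold = 50,
                            luxi_msa = NULL, luxr_msa = NULL,
                            marker_msa = NULL, reference_tree = NULL,
                            tip_metadata = NULL, cassette_map = NULL,
                            bootstrap_reps = 100, min_support = 70,
                            seed = 1, outdir = NULL) {
  cfg <- list(proteins = proteins, domain_hits = domain_hits,
              features = features, class_map = class_map, mining = mining,
              redundancy_threshold = redundancy_threshold,
              max_gap_bp = max_gap_bp, composition_test = composition_test,
              msa = msa, msa_ref = msa_ref,
              conservation_threshold = conservation_threshold,
              luxi_msa = luxi_msa, luxr_msa = luxr_msa,
              marker_msa = marker_msa, reference_tree = reference_tree,
              tip_metadata = tip_metadata, cassette_map = cassette_map,
              bootstrap_reps = bootstrap_reps, min_support = min_support,
              seed = as.integer(seed), outdir = outdir)
  for (f in c("proteins", "domain_hits", "features", "msa", "luxi_msa",
              "luxr_msa", "marker_msa", "reference_tree", "tip_metadata")) {
    x <- cfg[[f]]
    if (is.character(x) && length(x) == 1 && !file.exists(x))
      stop("config input '", f, "' points to a missing file: ", x)
  }
  structure(cfg, class = "pipeline_config")
}

resolve_input <- function(x, reader, ...) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1 && file.exists(x))
    return(reader(x, ...))
  x
}

#' Run the full LuxI/LuxR survey pipeline
#'
#' Executes, in order and when inputs allow: candidate mining, redundancy
#' reduction of LuxR candidates, cassette pairing and topology
#' classification, gram-group composition comparison, reference-anchored
#' conservation, bootstrapped gene-tree construction with HGT detection and
#' cassette co-transfer classification. Per-stage artifacts and a
#' versioned, machine-readable JSON report (stage counts mirroring the
#' survey flowchart) are written to `outdir` when given. Given the same
#' config and seed the run is idempotent; a stage failure aborts with the
#' stage name, preserving artifacts already written.
#'
#' @param config a [pipeline_config()].
#' @return the report, an invisible list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) if (is.null(outdir)) NULL else file.path(outdir, name)
  save_tsv <- function(df, name) {
    p <- art(name)
    if (!is.null(p)) write.table(df, p, sep = "\t", quote = FALSE,
                                 row.names = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  report <- list(schema_version = "1.0", seed = config$seed, stages = list())

  proteins <- resolve_input(config$proteins, read_protein_fasta)
  hits <- resolve_input(config$domain_hits, read_domain_hits)
  features <- resolve_input(config$features, read_gene_features,
                            class_map = config$class_map)
  if (!is.null(features) && !is.null(config$class_map))
    features <- as_gene_features(features, class_map = config$class_map)
  luxr_cand <- NULL

  if (!is.null(proteins) && !is.null(hits)) {
    res <- stage("mining", {
      luxi <- select_luxi(proteins, hits, config$mining)
      luxr <- select_luxr(proteins, hits, config$mining)
      list(luxi = luxi, luxr = luxr)
    })
    luxr_cand <- res$luxr
    lensum <- function(p) {
      n <- nchar(p$sequence)
      if (!length(n)) list(n = 0L) else
        list(n = nrow(p), min = min(n), mean = mean(n), max = max(n))
    }
    report$stages$mining <- list(n_proteins = nrow(proteins),
                                 luxi = lensum(res$luxi),
                                 luxr = lensum(res$luxr))
    message("mining: ", nrow(proteins), " proteins -> ", nrow(res$luxi),
            " LuxI / ", nrow(res$luxr), " LuxR candidates")
    if (!is.null(outdir)) {
      if (nrow(res$luxi)) write_protein_fasta(res$luxi, art("luxi_candidates.fasta"))
      if (nrow(res$luxr)) write_protein_fasta(res$luxr, art("luxr_candidates.fasta"))
    }
  }

  if (!is.null(luxr_cand) && nrow(luxr_cand) > 0) {
    clusters <- stage("redundancy",
                      greedy_cluster(luxr_cand, config$redundancy_threshold))
    reps <- cluster_representatives(clusters)
    report$stages$redundancy <- list(n_input = nrow(luxr_cand),
                                     n_representatives = length(reps),
                                     threshold = config$redundancy_threshold)
    message("redundancy: ", nrow(luxr_cand), " -> ", length(reps),
            " representatives")
    save_tsv(clusters, "luxr_clusters.tsv")
  }

  if (!is.null(features)) {
    cas <- stage("cassettes", cassette_table(features, config$max_gap_bp))
    pat <- table(cas$pairs$pattern)
    report$stages$cassettes <- list(
      n_pairs = nrow(cas$pairs), n_solos = nrow(cas$solos),
      max_gap_bp = config$max_gap_bp,
      patterns = as.list(setNames(as.integer(pat), names(pat))))
    message("cassettes: ", nrow(cas$pairs), " pairs, ", nrow(cas$solos),
            " solos")
    save_tsv(cas$pairs, "cassette_pairs.tsv")
    save_tsv(cas$solos, "cassette_solos.tsv")
  }

  if (!is.null(proteins) &&
      sum(proteins$gram == "positive") >= 2 &&
      sum(proteins$gram == "negative") >= 2) {
    comp <- stage("composition", compare_composition(
      proteins[proteins$gram == "positive", , drop = FALSE],
      proteins[proteins$gram == "negative", , drop = FALSE],
      test = config$composition_test))
    report$stages$composition <- list(
      test = config$composition_test,
      n_significant = sum(comp$significant),
      significant_residues = comp$residue[comp$significant])
    message("composition: ", sum(comp$significant), " significant residues")
    save_tsv(comp, "composition.tsv")
  }

  if (!is.null(config$msa) && !is.null(config$msa_ref)) {
    msa <- resolve_input(config$msa, read_alignment)
    cons <- stage("conservation", site_conservation(
      msa, config$msa_ref, config$conservation_threshold))
    report$stages$conservation <- list(
      reference = config$msa_ref, n_positions = nrow(cons),
      n_conserved = sum(cons$conserved),
      threshold_pct = config$conservation_threshold)
    message("conservation: ", sum(cons$conserved), " conserved sites")
    save_tsv(cons, "conservation.tsv")
  }

  if (!is.null(config$luxi_msa) && !is.null(config$tip_metadata) &&
      (!is.null(config$marker_msa) || !is.null(config$reference_tree))) {
    res <- stage("phylogenetics", {
      meta <- resolve_input(config$tip_metadata, read_tip_metadata)
      ref <- resolve_input(config$reference_tree, read_support_tree)
      if (is.null(ref)) {
        marker <- as_msa_matrix(resolve_input(config$marker_msa, read_alignment))
        ref <- neighbor_joining(protein_distance(marker, "poisson"))
      }
      gene_msas <- list(luxI = resolve_input(config$luxi_msa, read_alignment))
      if (!is.null(config$luxr_msa))
        gene_msas$luxR <- resolve_input(config$luxr_msa, read_alignment)
      trees <- lapply(seq_along(gene_msas), function(i)
        bootstrap_support(gene_msas[[i]], n_reps = config$bootstrap_reps,
                          seed = config$seed + i))
      names(trees) <- names(gene_msas)
      calls <- lapply(trees, detect_hgt, reference_tree = ref,
                      metadata = meta, min_support = config$min_support)
      modes <- NULL
      if (!is.null(config$cassette_map) && length(trees) == 2) {
        concat_rows <- vapply(names(gene_msas$luxI), function(id)
          paste0(gene_msas$luxI[[id]], gene_msas$luxR[[id]]), character(1))
        concat_tree <- bootstrap_support(concat_rows,
                                         n_reps = config$bootstrap_reps,
                                         seed = config$seed + 10L)
        modes <- classify_transfer_mode(trees$luxI, trees$luxR, concat_tree,
                                        config$cassette_map, meta,
                                        config$min_support)
      }
      list(trees = trees, ref = ref, calls = calls, modes = modes)
    })
    report$stages$phylogenetics <- list(
      bootstrap_reps = config$bootstrap_reps,
      min_support = config$min_support,
      n_hgt_supported = vapply(res$calls, function(d)
        sum(d$verdict == "hgt_supported"), integer(1)),
      transfer_modes = if (is.null(res$modes)) NULL else
        as.list(table(res$modes$mode)))
    message("phylogenetics: ",
            paste(names(res$calls), vapply(res$calls, function(d)
              sum(d$verdict == "hgt_supported"), integer(1)),
              sep = "=", collapse = ", "), " supported HGT calls")
    if (!is.null(outdir)) {
      for (nm in names(res$trees))
        write_support_tree(res$trees[[nm]],
                           art(paste0(tolower(nm), "_tree.nwk")))
      for (nm in names(res$calls))
        save_tsv(res$calls[[nm]], paste0(tolower(nm), "_hgt_calls.tsv"))
      if (!is.null(res$modes)) save_tsv(res$modes, "transfer_modes.tsv")
    }
  }

  validate_report(report)
  if (!is.null(outdir))
    jsonlite::write_json(report, art("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(report)
}

validate_report <- function(report) {
  stopifnot(is.list(report),
            identical(report$schema_version, "1.0"),
            is.integer(report$seed) || is.numeric(report$seed),
            is.list(report$stages))
  invisible(TRUE)
}
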