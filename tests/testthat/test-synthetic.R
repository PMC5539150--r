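test_that("pattern specs parse the full grammar and reject nonsense", {
  sp <- cassette_spec("R>I>", 222)
  expect_equal(sp$left$class, "luxR")
  expect_equal(sp$left$strand, "+")
  expect_equal(sp$n_intervening, 0L)
  sp2 <- cassette_spec("<I X(2) R>", 730)
  expect_equal(sp2$left$strand, "-")
  expect_equal(sp2$n_intervening, 2L)
  sp3 <- cassette_spec("R> X(>7) <I", 883)
  expect_equal(sp3$n_intervening, 8L)
  expect_error(cassette_spec("R>R>", 100), "one I and one R")
  expect_error(cassette_spec("R> X(>7) <I", 883, n_intervening = 3), "> 7")
  expect_error(cassette_spec("garbage", 100), "parse")
})

test_that("planted replicons are recovered by pairing and classification", {
  sc <- synthetic_scenario(seed = 91)
  rep <- make_replicons(sc)
  res <- cassette_table(rep$features, max_gap_bp = sc$max_gap_bp)
  expect_equal(nrow(res$pairs), nrow(rep$truth))
  m <- match(rep$truth$luxI_locus, res$pairs$luxI_locus)
  expect_false(anyNA(m))
  expect_identical(res$pairs$luxR_locus[m], rep$truth$luxR_locus)
  expect_identical(res$pairs$gap_bp[m], rep$truth$gap_bp)
  expect_identical(res$pairs$n_intervening[m], rep$truth$n_intervening)
  expect_identical(res$pairs$pattern[m], rep$truth$pattern)
  # decoy solos stay unpaired
  expect_equal(sum(grepl("^DEC", res$solos$locus_tag)), 2 * sc$n_decoys)
})

test_that("a decoy-only scenario yields zero pairs and all solos", {
  sc <- synthetic_scenario(seed = 92, cassette_specs = list(), n_decoys = 5)
  rep <- make_replicons(sc)
  res <- pair_cassettes(rep$features, max_gap_bp = sc$max_gap_bp)
  expect_equal(nrow(res$pairs), 0)
  expect_equal(nrow(res$solos), 10)
})

test_that("generator outputs are valid under the strict readers and seed-stable", {
  sc <- synthetic_scenario(seed = 93)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- make_replicons(sc, dir = d1)
  r2 <- make_replicons(sc, dir = d2)
  expect_identical(readLines(r1$paths$gff), readLines(r2$paths$gff))
  back <- read_gene_features(r1$paths$gff, class_map = r1$paths$class_map)
  expect_identical(back$start, r1$features$start)
  expect_identical(back$gene_class, r1$features$gene_class)
  g1 <- make_aac_groups(sc, dir = d1)
  g2 <- make_aac_groups(sc)
  expect_identical(g1$group2$sequence, g2$group2$sequence)
  expect_identical(read_protein_fasta(g1$paths$group1)$sequence,
                   g1$group1$sequence)
  e1 <- evolve_on_tree(sc, dir = d1)
  e2 <- evolve_on_tree(sc)
  expect_identical(e1$luxi_msa, e2$luxi_msa)
  expect_identical(ape::write.tree(e1$species_tree),
                   ape::write.tree(e2$species_tree))
  expect_identical(read_alignment(e1$paths$luxi_msa), e1$luxi_msa)
  expect_silent(validate_tip_metadata(read_tip_metadata(e1$paths$metadata)))
})

test_that("infeasible intervening-gene specs are rejected", {
  sc <- synthetic_scenario(seed = 94, cassette_specs = list(
    cassette_spec("R> X(>7) <I", gap_bp = 100, n_intervening = 8)))
  expect_error(make_replicons(sc), "infeasible")
})

test_that("null composition groups stay near the nominal false-positive rate", {
  nsig <- vapply(1:10, function(s) {
    g <- make_aac_groups(synthetic_scenario(seed = 900 + s,
                                            aac_shift = numeric(0)))
    sum(compare_composition(g$group2, g$group1)$significant)
  }, numeric(1))
  expect_lte(mean(nsig), 2)
})

test_that("evolution scenarios respect gram monophyly and planted events", {
  ev <- data.frame(tip = "GP02", donor = "GN03", genes = "both",
                   stringsAsFactors = FALSE)
  sim <- evolve_on_tree(synthetic_scenario(seed = 95, hgt_events = ev))
  expect_true(ape::is.monophyletic(sim$species_tree,
                                   grep("^GP", sim$species_tree$tip.label,
                                        value = TRUE)))
  # the recipient moved into the donor clade in both gene trees
  for (g in c("luxI", "luxR")) {
    gt <- sim$gene_trees[[g]]
    sib <- ape::cophenetic.phylo(gt)["GP02", ]
    sib <- sib[names(sib) != "GP02"]
    expect_equal(names(which.min(sib)), "GN03")
  }
  expect_equal(sim$truth$donor, "GN03")
  expect_equal(unique(nchar(sim$concat_msa)), 2 * 200)
  bad <- data.frame(tip = "GP99", donor = "GN01", genes = "both",
                    stringsAsFactors = FALSE)
  expect_error(evolve_on_tree(synthetic_scenario(seed = 96, hgt_events = bad)),
               "GP99")
})
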