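test_that("ORF length counts residues excluding the stop codon", {
  f <- grampos_cassette_features(with_intervening = FALSE)
  lens <- setNames(orf_length_aa(f), f$locus_tag)
  expect_equal(unname(lens["ADL19_05265"]), 191L)
  expect_equal(unname(lens["ADL14_01865"]), 191L)
  bad <- data.frame(locus_tag = "odd", start = 1, end = 5)
  expect_error(orf_length_aa(bad), "odd")
  expect_warning(orf_length_aa(data.frame(locus_tag = "stp", start = 1, end = 3)),
                 "degenerate")
})

test_that("gap arithmetic follows end-to-start minus one", {
  f <- as_gene_features(data.frame(
    replicon_id = "r", locus_tag = c("R", "I"),
    start = c(117, 3948), end = c(689, 4550),
    strand = c("+", "-"), gene_class = c("luxR", "luxI")))
  res <- pair_cassettes(f, 3400)
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$pairs$gap_bp, 3948 - 689 - 1)  # 3258
  # exceeding the criterion leaves two solos
  res2 <- pair_cassettes(f, 3000)
  expect_equal(nrow(res2$pairs), 0)
  expect_equal(nrow(res2$solos), 2)
})

test_that("overlapping luxI/luxR intervals pair with zero gap and a warning", {
  f <- as_gene_features(data.frame(
    replicon_id = "r", locus_tag = c("I", "R"),
    start = c(100, 400), end = c(500, 900),
    strand = c("+", "+"), gene_class = c("luxI", "luxR")))
  expect_warning(res <- pair_cassettes(f), "overlap")
  expect_equal(res$pairs$gap_bp, 0)
  expect_true(res$pairs$overlapping)
})

test_that("the six reported Gram-positive cassettes are reproduced row-for-row", {
  f <- grampos_cassette_features()
  res <- cassette_table(f, max_gap_bp = 3400)
  expect_equal(nrow(res$pairs), 6)
  expect_equal(nrow(res$solos), 0)
  truth <- grampos_cassette_patterns()
  got <- res$pairs[match(truth$luxI_locus, res$pairs$luxI_locus), ]
  expect_identical(got$luxR_locus, truth$luxR_locus)
  expect_identical(got$pattern, truth$pattern)
  # the 3000 bp criterion drops exactly the widest pair
  res3k <- cassette_table(f, max_gap_bp = 3000)
  expect_equal(nrow(res3k$pairs), 5)
  expect_false("ADL14_12710" %in% res3k$pairs$luxI_locus)
})

test_that("topology rendering covers all strand/intervening combinations", {
  expect_equal(render_topology("luxR", "+", "luxI", "+", 0), "R>I>")
  expect_equal(render_topology("luxR", "+", "luxI", "-", 0), "R><I")
  expect_equal(render_topology("luxI", "-", "luxR", "+", 2), "<I X(2) R>")
  expect_equal(render_topology("luxR", "+", "luxI", "-", 8), "R> X(>7) <I")
  expect_equal(render_topology("luxI", "+", "luxR", "-", 7), "I> X(7) <R")
})

test_that("pairing is invariant to feature input order", {
  f <- grampos_cassette_features()
  withr::with_seed(41, {
    for (k in 1:3) {
      shuf <- as_gene_features(as.data.frame(f)[sample(nrow(f)), ])
      expect_identical(cassette_table(shuf, 3400)$pairs,
                       cassette_table(f, 3400)$pairs)
    }
  })
})

test_that("mirroring a replicon mirrors the pattern and preserves gap and count", {
  f <- grampos_cassette_features()
  L <- 200000L
  mir <- mirror_features(f, L)
  res <- cassette_table(f, 3400)$pairs
  resm <- cassette_table(mir, 3400)$pairs
  expect_equal(nrow(resm), nrow(res))
  m <- match(res$luxI_locus, resm$luxI_locus)
  expect_identical(resm$gap_bp[m], res$gap_bp)
  expect_identical(resm$n_intervening[m], res$n_intervening)
  flip <- function(side) list(class = side$class,
                              strand = if (side$strand == "+") "-" else "+")
  for (k in seq_len(nrow(res))) {
    orig <- cassette_spec(res$pattern[k], res$gap_bp[k],
                          n_intervening = res$n_intervening[k])
    mirr <- cassette_spec(resm$pattern[m][k], resm$gap_bp[m][k],
                          n_intervening = resm$n_intervening[m][k])
    expect_identical(mirr$left, flip(orig$right))
    expect_identical(mirr$right, flip(orig$left))
    expect_identical(mirr$n_intervening, orig$n_intervening)
  }
})

test_that("nearest-luxR matching uses each luxR at most once, smallest gap first", {
  f <- as_gene_features(data.frame(
    replicon_id = "r",
    locus_tag = c("I1", "R1", "I2"),
    start = c(1001, 2501, 3601), end = c(2000, 3500, 4600),
    strand = "+", gene_class = c("luxI", "luxR", "luxI")))
  res <- pair_cassettes(f, 3400)
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$pairs$luxI_locus, "I2")  # gap 100 beats gap 500
  expect_equal(res$solos$locus_tag, "I1")
})
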