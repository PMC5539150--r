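test_that("p-distance and Poisson correction follow their closed forms", {
  msa <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA", c = "CCCCCAAAAA")
  d <- protein_distance(msa, "p")
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0.5)
  dp <- protein_distance(msa, "poisson")
  expect_equal(dp["a", "c"], -log(0.5))
  # saturated pair flagged infinite
  sat <- protein_distance(c(a = "AC", b = "CA", c = "AC"), "poisson")
  expect_true(is.infinite(sat["a", "b"]))
  expect_true(attr(sat, "saturated")["a", "b"])
})

test_that("distances equal an independent column-scan oracle on gapped alignments", {
  withr::with_seed(71, {
    for (k in 1:5) {
      msa <- vapply(1:5, function(i)
        paste(sample(c("A", "R", "N", "D", "-"), 30, TRUE,
                     prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = ""),
        character(1))
      names(msa) <- paste0("t", 1:5)
      expect_equal(unclass(protein_distance(msa, "p"))[1:5, 1:5],
                   pdist_oracle(msa), tolerance = 1e-12)
    }
  })
  expect_error(protein_distance(c(a = "A-", b = "-A", c = "AA")),
               "comparable")
})

test_that("three-taxon NJ matches the closed-form branch lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), (3 + 4 - 5) / 2)  # 1
  expect_equal(unname(bl["B"]), (3 + 5 - 4) / 2)  # 2
  expect_equal(unname(bl["C"]), (4 + 5 - 3) / 2)  # 3
})

test_that("NJ recovers random trees exactly from additive distances", {
  withr::with_seed(72, {
    for (k in 1:10) {
      n <- sample(6:10, 1)
      tr <- ape::rtree(n)
      dm <- ape::cophenetic.phylo(tr)
      nj <- neighbor_joining(dm)
      expect_equal(robinson_foulds(nj, tr), 0)
      # cross-check against the reference NJ implementation
      expect_equal(robinson_foulds(nj, ape::nj(dm)), 0)
    }
  })
})

test_that("NJ is deterministic under complete ties and validates input", {
  d <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(d) <- 0
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  bad <- d; bad[1, 2] <- 2
  expect_error(neighbor_joining(bad), "symmetric")
  expect_error(neighbor_joining(d[1:2, 1:2]), "3 tips")
})

test_that("Robinson-Foulds matches closed forms and the exhaustive oracle", {
  ta <- ape::read.tree(text = "((A,B),(C,D));")
  tb <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(robinson_foulds(ta, ta), 0)
  expect_equal(robinson_foulds(ta, tb), 2)
  expect_error(robinson_foulds(ta, ape::read.tree(text = "((A,B),(C,E));")),
               "tip sets")
  withr::with_seed(73, {
    for (k in 1:10) {
      n <- sample(5:9, 1)
      t1 <- ape::rtree(n); t2 <- ape::rtree(n)
      expect_equal(robinson_foulds(t1, t2), rf_oracle(t1, t2))
      expect_equal(robinson_foulds(t1, t2),
                   as.integer(phangorn::RF.dist(t1, t2)))
    }
  })
})

test_that("bootstrap supports are percentages, seed-reproducible, degenerate at 1 rep", {
  sim <- evolve_on_tree(synthetic_scenario(seed = 74,
                                           tree_spec = list(n_gp = 4, n_gn = 4,
                                                            clade_scale = 0.2,
                                                            stem_length = 0.5)))
  t1 <- bootstrap_support(sim$luxi_msa, n_reps = 50, seed = 7)
  t2 <- bootstrap_support(sim$luxi_msa, n_reps = 50, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  tone <- bootstrap_support(sim$luxi_msa, n_reps = 1, seed = 8)
  sup1 <- suppressWarnings(as.numeric(tone$node.label))
  expect_true(all(sup1[!is.na(sup1)] %in% c(0, 100)))
  expect_error(bootstrap_support(sim$luxi_msa, n_reps = 0), "n_reps")
})

test_that("a long internal branch earns high support for the separating edge", {
  sim <- evolve_on_tree(synthetic_scenario(seed = 75))
  tr <- bootstrap_support(sim$marker_msa, n_reps = 100, seed = 9)
  keys <- tree_bipartitions(tr)
  gp <- sort(grep("^GP", tr$tip.label, value = TRUE))
  gn <- sort(grep("^GN", tr$tip.label, value = TRUE))
  anchor <- sort(tr$tip.label)[1]
  gram_key <- paste(sort(if (anchor %in% gp) gn else gp), collapse = "|")
  node <- as.integer(names(keys)[keys == gram_key])
  expect_length(node, 1)
  sup <- as.numeric(tr$node.label[node - length(tr$tip.label)])
  expect_gte(sup, 95)
})

test_that("a planted transfer is detected and congruent trees stay silent", {
  ev <- data.frame(tip = "GP02", donor = "auto", genes = "luxI",
                   stringsAsFactors = FALSE)
  sim <- evolve_on_tree(synthetic_scenario(seed = 76, hgt_events = ev))
  gt <- bootstrap_support(sim$luxi_msa, n_reps = 100, seed = 10)
  ref <- neighbor_joining(protein_distance(sim$marker_msa, "poisson"))
  calls <- detect_hgt(gt, ref, sim$metadata)
  supported <- calls[calls$verdict == "hgt_supported", ]
  expect_gte(nrow(supported), 1)
  expect_true(any(grepl("GP02", supported$clade_tips)))
  expect_true(all(supported$mixed))
  expect_true(all(supported$reference_incongruent))
  # planted recipient and donor share the niche annotation
  expect_true(any(supported$niche_match))
  # congruent, label-monophyletic gene tree: no calls at all
  gt0 <- bootstrap_support(sim$marker_msa, n_reps = 100, seed = 11)
  expect_equal(nrow(detect_hgt(gt0, ref, sim$metadata)), 0)
})

test_that("detect_hgt validates shared tips and metadata coverage", {
  ta <- ape::read.tree(text = "((A,B),(C,D));")
  tb <- ape::read.tree(text = "((E,F),(G,H));")
  md <- data.frame(tip_id = LETTERS[1:8],
                   gram = rep(c("positive", "negative"), 4),
                   taxonomy = "t", niche = "n")
  expect_error(detect_hgt(ta, tb, md), "share no tips")
  expect_error(detect_hgt(ta, ta, md[md$tip_id != "A", ]), "metadata")
})

test_that("transfer modes separate joint, single-gene and unsupported cases", {
  mk <- function(seed, genes) {
    ev <- data.frame(tip = "GP03", donor = "auto", genes = genes,
                     stringsAsFactors = FALSE)
    sim <- evolve_on_tree(synthetic_scenario(seed = seed, hgt_events = ev))
    lt <- bootstrap_support(sim$luxi_msa, n_reps = 100, seed = seed + 1)
    rt <- bootstrap_support(sim$luxr_msa, n_reps = 100, seed = seed + 2)
    ct <- bootstrap_support(sim$concat_msa, n_reps = 100, seed = seed + 3)
    classify_transfer_mode(lt, rt, ct, sim$cassette_map, sim$metadata)
  }
  both <- mk(77, "both")
  expect_equal(both$mode[both$cassette_id == "GP03"], "simultaneous")
  single <- mk(78, "luxI")
  expect_equal(single$mode[single$cassette_id == "GP03"], "individual")
  # an unreachable support cutoff forces every cassette to unclear
  ev <- data.frame(tip = "GP03", donor = "auto", genes = "both",
                   stringsAsFactors = FALSE)
  sim <- evolve_on_tree(synthetic_scenario(seed = 79, hgt_events = ev))
  lt <- bootstrap_support(sim$luxi_msa, n_reps = 100, seed = 80)
  rt <- bootstrap_support(sim$luxr_msa, n_reps = 100, seed = 81)
  ct <- bootstrap_support(sim$concat_msa, n_reps = 100, seed = 82)
  res <- classify_transfer_mode(lt, rt, ct, sim$cassette_map, sim$metadata,
                                min_support = 101)
  expect_true(all(res$mode == "unclear"))
  # a cassette missing from a tree is reported unclear with its reason
  cm <- rbind(sim$cassette_map,
              data.frame(cassette_id = "ghost", luxi_tip = "ghost",
                         luxr_tip = "ghost", concat_tip = "ghost"))
  res2 <- classify_transfer_mode(lt, rt, ct, cm, sim$metadata)
  expect_equal(res2$mode[res2$cassette_id == "ghost"], "unclear")
  expect_match(res2$reason[res2$cassette_id == "ghost"], "absent")
})
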