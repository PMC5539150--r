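mk_prot <- function(id, len, gram = "positive") {
  data.frame(id = id, gram = gram, sequence = strrep("A", len),
             stringsAsFactors = FALSE)
}
mk_hit <- function(id, dom) {
  data.frame(protein_id = id, domain_id = dom, source = "interpro",
             stringsAsFactors = FALSE)
}

test_that("LuxI selection keeps synthase-domain proteins inside the length window", {
  prot <- as_protein_set(rbind(mk_prot("I1", 219), mk_prot("I2", 191),
                               mk_prot("N1", 219), mk_prot("S1", 100)))
  hits <- rbind(mk_hit("I1", "IPR001690"), mk_hit("I2", "IPR001690"),
                mk_hit("N1", "IPR016181"),   # acyltransferase only
                mk_hit("S1", "IPR001690"))   # too short
  out <- select_luxi(prot, hits)
  expect_equal(out$id, c("I1", "I2"))
})

test_that("planted LuxI mixture is recovered exactly (brute-force membership)", {
  withr::with_seed(21, {
    ids <- sprintf("P%02d", 1:10)
    planted <- sample(ids, 4)
    prot <- as_protein_set(do.call(rbind, lapply(ids, mk_prot, len = 250)))
    hits <- do.call(rbind, c(
      lapply(planted, mk_hit, dom = "IPR001690"),
      lapply(ids, mk_hit, dom = "IPR016181")))
    out <- select_luxi(prot, hits)
    expect_setequal(out$id, planted)
    # brute-force oracle: direct set membership
    oracle <- ids[ids %in% hits$protein_id[hits$domain_id == "IPR001690"]]
    expect_setequal(out$id, oracle)
  })
})

test_that("LuxR selection enforces the two-domain (DNA + ABD) filter", {
  prot <- as_protein_set(rbind(mk_prot("R1", 248), mk_prot("R2", 248),
                               mk_prot("R3", 350)))
  hits <- rbind(mk_hit("R1", "IPR000792"), mk_hit("R1", "IPR005143"),
                mk_hit("R2", "IPR000792"),              # HTH alone: a solo short-lister, rejected
                mk_hit("R3", "IPR000792"), mk_hit("R3", "IPR005143"))  # too long
  out <- select_luxr(prot, hits)
  expect_equal(out$id, "R1")
})

test_that("planted LuxR mixture of 20 with 7 passing is recovered exactly", {
  withr::with_seed(22, {
    ids <- sprintf("Q%02d", 1:20)
    pass <- sample(ids, 7)
    dna_only <- sample(setdiff(ids, pass), 5)
    prot <- as_protein_set(do.call(rbind, lapply(ids, mk_prot, len = 248)))
    hits <- do.call(rbind, c(
      lapply(pass, mk_hit, dom = "IPR000792"),
      lapply(pass, mk_hit, dom = "IPR011006"),
      lapply(dna_only, mk_hit, dom = "IPR000792"),
      lapply(ids, mk_hit, dom = "IPR029999")))
    out <- select_luxr(prot, hits)
    expect_setequal(out$id, pass)
    # invariant: output is a subset of DNA-binding-domain carriers
    dna <- hits$protein_id[hits$domain_id %in% c("IPR000792", "IPR011991")]
    expect_true(all(out$id %in% dna))
  })
})

test_that("mining rejects orphan hits and an empty ABD set", {
  prot <- as_protein_set(mk_prot("A1", 250))
  hits <- mk_hit("GHOST", "IPR001690")
  expect_error(select_luxi(prot, hits), "GHOST")
  cfg <- mining_config()
  cfg$luxr_abd_domains <- character(0)
  expect_error(select_luxr(prot, mk_hit("A1", "IPR000792"), cfg), "empty")
})

test_that("domain architecture census counts identical sets and is order-invariant", {
  hits <- rbind(mk_hit("p1", "A"), mk_hit("p1", "B"),
                mk_hit("p2", "B"), mk_hit("p2", "A"), mk_hit("p2", "A"),
                mk_hit("p3", "A"))
  cen <- domain_architecture_census(hits)
  expect_equal(cen$combinations$count[cen$combinations$combination == "A+B"], 2)
  expect_equal(cen$combinations$count[cen$combinations$combination == "A"], 1)
  expect_equal(cen$domains$count[cen$domains$domain_id == "A"], 3)
  shuffled <- hits[rev(seq_len(nrow(hits))), ]
  expect_identical(domain_architecture_census(shuffled), cen)
  empty <- domain_architecture_census(hits[0, ])
  expect_equal(nrow(empty$combinations), 0)
})

test_that("census equals an independent tally on a random fixture", {
  withr::with_seed(23, {
    doms <- sprintf("IPR%06d", 1:12)
    hits <- data.frame(
      protein_id = sample(sprintf("W%02d", 1:50), 300, replace = TRUE),
      domain_id = sample(doms, 300, replace = TRUE),
      source = "interpro", stringsAsFactors = FALSE)
    cen <- domain_architecture_census(hits)
    # independent tally via table() on pasted sorted unique sets
    key <- vapply(split(hits$domain_id, hits$protein_id),
                  function(d) paste(sort(unique(d)), collapse = "+"),
                  character(1))
    tab <- table(key)
    expect_equal(sum(cen$combinations$count), length(key))
    for (k in names(tab))
      expect_equal(cen$combinations$count[cen$combinations$combination == k],
                   unname(as.integer(tab[k])))
  })
})
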