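test_that("composition fractions are exact and exclude X", {
  prof <- aa_composition(c(a = "AAAA", b = "ACDE", c = "AXAX"))
  expect_equal(prof["a", "A"], 1.0)
  expect_equal(sum(prof["a", ] > 0), 1)
  expect_equal(unname(prof["b", c("A", "C", "D", "E")]), rep(0.25, 4))
  expect_equal(prof["c", "A"], 1.0)  # X never counts
  expect_equal(rowSums(prof), c(a = 1, b = 1, c = 1))
  expect_error(aa_composition("XX"), "standard")
})

test_that("profiles equal an independent counting oracle on random sequences", {
  ps <- rand_protein_set(100, len_range = c(50, 150), seed = 51)
  prof <- aa_composition(as_protein_set(ps))
  for (k in sample(100, 20)) {
    expect_equal(unname(prof[ps$id[k], ]),
                 unname(composition_oracle(ps$sequence[k])),
                 tolerance = 1e-12)
  }
})

test_that("identical groups give unit fold changes and no significance", {
  ps <- as_protein_set(rand_protein_set(10, seed = 52))
  cmp <- compare_composition(ps, ps)
  present <- !is.na(cmp$fold_change)
  expect_true(all(cmp$fold_change[present] == 1))
  expect_false(any(cmp$significant))
  # group means each sum to 1
  expect_equal(sum(cmp$group1_mean), 1)
  expect_equal(sum(cmp$group2_mean), 1)
})

test_that("a planted 1.4x alanine shift is flagged significant with FC near 1.4", {
  g <- make_aac_groups(synthetic_scenario(seed = 53, aac_shift = c(A = 1.4)))
  cmp <- compare_composition(g$group2, g$group1)
  rowA <- cmp[cmp$residue == "A", ]
  expect_true(rowA$significant)
  expect_gte(rowA$fold_change, 1.20)
  planted <- unname(g$truth$shifted_freqs["A"] / g$truth$base_freqs["A"])
  expect_lt(abs(rowA$fold_change - planted), 0.1)
  expect_lt(rowA$p_value, 0.05)
})

test_that("swapping groups inverts fold changes and preserves p-values", {
  g1 <- as_protein_set(rand_protein_set(8, seed = 54, prefix = "G1"))
  g2 <- as_protein_set(rand_protein_set(8, seed = 55, prefix = "G2"))
  a <- compare_composition(g1, g2)
  b <- compare_composition(g2, g1)
  fin <- is.finite(a$fold_change) & a$fold_change > 0
  expect_equal(b$fold_change[fin], 1 / a$fold_change[fin])
  expect_equal(a$p_value, b$p_value)
})

test_that("a residue absent from the denominator group is flagged, not dropped", {
  g1 <- as_protein_set(data.frame(id = c("a", "b"),
                                  sequence = c("WWAA", "WWCC")))
  g2 <- as_protein_set(data.frame(id = c("c", "d"),
                                  sequence = c("AACC", "AACC")))
  cmp <- compare_composition(g1, g2)
  rowW <- cmp[cmp$residue == "W", ]
  expect_true(is.infinite(rowW$fold_change))
  expect_false(rowW$fc_defined)
  expect_equal(nrow(cmp), 20)
})

test_that("the rank test runs where Welch cannot, and small groups error clearly", {
  one <- as_protein_set(data.frame(id = "a", sequence = "MKLV"))
  many <- as_protein_set(rand_protein_set(5, seed = 56))
  expect_error(compare_composition(one, many, test = "welch"), "wilcoxon")
  cmp <- compare_composition(one, many, test = "wilcoxon")
  expect_equal(nrow(cmp), 20)
})

test_that("Benjamini-Hochberg adjustment never increases the significant set", {
  g <- make_aac_groups(synthetic_scenario(seed = 57, aac_shift = c(A = 1.3)))
  raw <- compare_composition(g$group2, g$group1)
  adj <- compare_composition(g$group2, g$group1, adjust = TRUE)
  expect_true(all(adj$p_value >= raw$p_value - 1e-15))
  expect_lte(sum(adj$significant), sum(raw$significant))
})
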