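toy <- toy_substitution_matrix()

test_that("column profiles count residues and gaps exactly", {
  msa <- msa_from_strings(c("L", "L", "I", "-"))
  p <- column_profile(msa, 1)
  expect_equal(p$counts, c(I = 1L, L = 2L))
  expect_equal(p$gap_count, 1L)
  expect_equal(p$depth, 4L)
  expect_error(column_profile(msa, 0), "out of range")
  msa2 <- msa_from_strings(c("-", "-", "-"))
  p2 <- column_profile(msa2, 1)
  expect_equal(length(p2$counts), 0L)
  expect_equal(p2$gap_count, 3L)
})

test_that("most frequent symbol ties break alphabetically, gap loses ties", {
  prof <- function(seqs) column_profile(msa_from_strings(seqs), 1)
  expect_equal(most_frequent_symbol(prof(c("L", "L", "L", "I"))), "L")
  expect_equal(most_frequent_symbol(prof(c("L", "L", "-", "-", "-"))), "-")
  expect_equal(most_frequent_symbol(prof(c("L", "L", "I", "I"))), "I")
  expect_equal(most_frequent_symbol(prof(c("L", "L", "-", "-"))), "L")
})

test_that("similarity sets use strict score inequality", {
  expect_true("I" %in% similar_set("L", toy, 1))   # score 3 > 1
  expect_true("I" %in% similar_set("L", toy, 2))   # score 3 > 2
  expect_false("I" %in% similar_set("L", toy, 3))  # not > 3
  expect_false("L" %in% similar_set("L", toy, 1))  # never itself
  expect_false("F" %in% similar_set("L", toy, 1))  # score -2
  expect_error(similar_set("X", toy, 1), "unknown residue")
})

test_that("position conservation follows the identical-plus-similar rule", {
  # 7 L + 2 I (similar) + 1 gap: (7+2)/9 = 1 at threshold 1
  msa <- msa_from_strings(c(rep("L", 7), "I", "I", "-"))
  p <- column_profile(msa, 1)
  r1 <- position_conservation(p, toy, conservation_params(1, 0.9))
  expect_equal(r1$fraction, 1.0)
  expect_true(r1$conserved)
  # same column, threshold 3 drops the I matches: 7/9
  r2 <- position_conservation(p, toy, conservation_params(3, 0.9))
  expect_equal(r2$fraction, 7 / 9, tolerance = 1e-12)
  expect_false(r2$conserved)
  # gap-majority column scores 0 by definition
  msa3 <- msa_from_strings(c("L", "L", "-", "-", "-"))
  r3 <- position_conservation(column_profile(msa3, 1), toy)
  expect_equal(r3$fraction, 0)
  expect_false(r3$conserved)
})

test_that("the scan equals the brute-force per-column oracle", {
  for (seed in 1:5) {
    g <- gen_msa(n_sequences = 20,
                 design = sample(c("identical", "similar", "random"), 15,
                                 replace = TRUE),
                 gap_rate = 0.1, seed = seed)
    scan <- ortholog_conservation_scan(g$msa, toy)
    orc <- oracle_conservation(g$msa, toy)
    expect_equal(scan$fraction, unname(orc[, "fraction"]), tolerance = 1e-12)
    expect_equal(scan$conserved, unname(orc[, "conserved"]) == 1)
  }
})

test_that("degenerate alignments scan sensibly", {
  msa <- msa_from_strings(rep("ACDEF", 4))
  expect_true(all(ortholog_conservation_scan(msa, toy)$fraction == 1))
  one <- msa_from_strings("AC-EF")
  sc <- ortholog_conservation_scan(one, toy)
  expect_equal(sc$fraction, c(1, 1, 0, 1, 1))
})

test_that("representative removal and degapping keeps column provenance", {
  msa <- msa_from_strings(c("AC-EF", "AC-EF", "ACDEF", "A--EF", "AC-E-"),
                          ids = c("h1", "h2", "h3", "rep1", "rep2"))
  out <- strip_representatives_and_gaps(msa, c("rep1", "rep2"))
  expect_equal(out$msa$id, c("h1", "h2", "h3"))
  expect_equal(out$column_map, c(1L, 2L, 4L, 5L))  # column 3 gapped in h1/h2
  expect_equal(ncol(out$msa$ali), 4L)
  expect_error(strip_representatives_and_gaps(msa, "nope"), "unknown")
  allgap <- msa_from_strings(c("--", "--"), ids = c("a", "b"))
  expect_warning(strip_representatives_and_gaps(allgap, character(0)),
                 "all columns")
})

test_that("reference mapping skips the reference's gap columns", {
  msa <- msa_from_strings(c("A-C", "AGC"), ids = c("ref", "x"))
  expect_equal(map_to_reference(msa, "ref"), c(1L, NA, 2L))
  gapless <- msa_from_strings(c("ACDEF", "ACDEF"), ids = c("r", "x"))
  expect_equal(map_to_reference(gapless, "r"), 1:5)
  expect_error(map_to_reference(msa, "zz"), "unknown reference")
})

test_that("class-wide fraction is the plain conserved-receptor share", {
  expect_equal(classwide_fraction(c(rep(TRUE, 8), rep(FALSE, 3))), 8 / 11,
               tolerance = 1e-12)
  expect_equal(classwide_fraction(rep(TRUE, 5)), 1)
  expect_equal(classwide_fraction(rep(FALSE, 5)), 0)
  expect_error(classwide_fraction(logical(0)), "empty")
})

test_that("entropy divergence behaves like Shannon entropy in bits", {
  expect_equal(divergence_entropy(rep("L", 11)), 0)
  # closed form for 9 identical + 2 distinct singletons of 11
  h <- -(9 / 11 * log2(9 / 11) + 2 * (1 / 11) * log2(1 / 11))
  expect_equal(divergence_entropy(c(rep("L", 9), "F", "K")), h,
               tolerance = 1e-12)
  expect_error(divergence_entropy(character(0)), "empty")
  expect_error(divergence_entropy(c("L", "-")), "gap")
  # permutation invariance and the log2(n) ceiling
  set.seed(42)
  for (i in 1:10) {
    x <- sample(AA <- c("A", "C", "D", "E", "F"), 11, replace = TRUE)
    expect_equal(divergence_entropy(x), divergence_entropy(sample(x)))
    expect_lte(divergence_entropy(x), log2(11))
  }
})

test_that("selection rules pick the documented position classes", {
  g <- gen_panel(c("all_identical", "one_different", "two_different",
                   "similar_only"), seed = 3)
  panel <- g$panel
  expect_equal(select_positions(panel, selection_rule("entropy_zero"), toy),
               1L)
  expect_equal(select_positions(panel,
                                selection_rule("entropy_le",
                                               entropy_cutoff = 0.44), toy),
               c(1L, 2L))
  sim <- select_positions(panel,
                          selection_rule("similar_only",
                                         similarity_threshold = 2L), toy)
  expect_true(all(c(1L, 4L) %in% sim))
  expect_false(any(c(2L, 3L) %in% sim))
})

test_that("panel positions with a gap are never selected", {
  mf <- rbind(rep("L", 3), c("L", "-", "L"))
  cons <- matrix(TRUE, 2, 3)
  panel <- paralog_panel(mf, cons)
  expect_true(is.na(panel$entropy_bits[2]))
  expect_equal(select_positions(panel, selection_rule("entropy_zero"), toy),
               1L)
})

test_that("designed conserved columns are recovered with no false positives", {
  # parameter-recovery property at reduced width; the acceptance suite
  # runs the full 20-seed sweep
  g <- gen_msa(n_sequences = 50,
               design = rep(c("identical", "similar", "random"), each = 10),
               gap_rate = 0.05, seed = 11)
  scan <- ortholog_conservation_scan(g$msa, toy)
  designed <- g$truth$design != "random"
  expect_gte(mean(scan$conserved[designed]), 0.95)
  expect_equal(sum(scan$conserved[!designed]), 0L)
})
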