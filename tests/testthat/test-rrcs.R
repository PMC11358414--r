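single_atom_res <- function(resno, x, chain = "A", elety = "CB") {
  data.frame(chain = chain, resno = resno, insert = "", resid = "ALA",
             elety = elety, elesy = substr(elety, 1, 1),
             x = x, y = 0, z = 0, is_water = FALSE, is_ligand = FALSE,
             stringsAsFactors = FALSE)
}

test_that("the atom contact ramp has the documented breakpoints", {
  p <- rrcs_params()
  expect_equal(atom_contact_score(3.0, p), 1.0)
  expect_equal(atom_contact_score(3.23, p), 1.0)
  expect_equal(atom_contact_score(4.63, p), 0.0)
  expect_equal(atom_contact_score(3.93, p), 0.5, tolerance = 1e-12)
  expect_error(atom_contact_score(-1, p), "negative")
  # monotone non-increasing in distance
  d <- seq(0, 6, by = 0.01)
  expect_true(all(diff(atom_contact_score(d, p)) <= 1e-12))
})

test_that("residue-pair scores respect the near-sequence backbone policy", {
  p <- rrcs_params()
  expect_equal(residue_pair_rrcs(single_atom_res(1, 0),
                                 single_atom_res(10, 10), p), 0)
  expect_equal(residue_pair_rrcs(single_atom_res(1, 0),
                                 single_atom_res(10, 3), p), 1.0)
  # adjacent residues whose only proximal atoms are main chain score 0
  expect_equal(residue_pair_rrcs(single_atom_res(1, 0, elety = "CA"),
                                 single_atom_res(2, 3, elety = "N"), p), 0)
  # the same geometry far in sequence scores 1
  expect_equal(residue_pair_rrcs(single_atom_res(1, 0, elety = "CA"),
                                 single_atom_res(20, 3, elety = "N"), p), 1)
  expect_warning(sc <- residue_pair_rrcs(single_atom_res(1, 0)[0, ],
                                         single_atom_res(2, 3), p))
  expect_equal(sc, 0)
})

test_that("structure networks equal the exhaustive double-loop oracle", {
  p <- rrcs_params()
  for (seed in 1:20) {
    s <- random_toy_structure(n_residues = sample(10:50, 1), seed = seed)
    net <- structure_rrcs(s, params = p)
    orc <- oracle_rrcs(s, p)
    expect_equal(nrow(net), nrow(orc), info = paste("seed", seed))
    if (nrow(orc)) {
      key <- function(df) paste(df$key_i, df$key_j)
      expect_setequal(key(net), key(orc))
      m <- match(key(orc), key(net))
      expect_identical(net$score[m], orc$score)  # bit-for-bit
    }
  }
})

test_that("waters and ligands never enter the network", {
  s <- random_toy_structure(n_residues = 10, seed = 3, with_waters = 20)
  net <- structure_rrcs(s)
  expect_false(any(grepl("^W", c(net$key_i, net$key_j))))
  only_water <- s
  only_water$atom <- s$atom[s$atom$is_water, ]
  expect_equal(nrow(structure_rrcs(only_water)), 0L)
})

test_that("contact networks are invariant under rigid-body motion", {
  s <- random_toy_structure(n_residues = 25, seed = 5)
  net1 <- structure_rrcs(s)
  set.seed(99)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  moved <- s
  xyz <- as.matrix(s$atom[, c("x", "y", "z")]) %*% t(q)
  moved$atom$x <- xyz[, 1] + 11.3
  moved$atom$y <- xyz[, 2] - 4.2
  moved$atom$z <- xyz[, 3] + 0.7
  net2 <- structure_rrcs(moved)
  expect_equal(net1$score, net2$score, tolerance = 1e-9)
  expect_identical(net1$key_i, net2$key_i)
})

test_that("residue matching reports gaps and name mismatches non-fatally", {
  s <- random_toy_structure(n_residues = 12, seed = 8)
  m <- match_residues(s, s)
  expect_equal(length(m$matched), 12L)
  expect_equal(nrow(m$mismatched), 0L)
  trimmed <- s
  trimmed$atom <- s$atom[s$atom$resno != 5, ]
  m2 <- match_residues(s, trimmed)
  expect_true(res_key("A", 5) %in% m2$only_a)
  renamed <- s
  renamed$atom$resid[renamed$atom$resno == 2] <- "TRP"
  m3 <- match_residues(s, renamed)
  expect_true(res_key("A", 2) %in% m3$mismatched$key)
  expect_false(res_key("A", 2) %in% m3$matched)
})

test_that("delta networks are zero on identity and antisymmetric", {
  sA <- random_toy_structure(n_residues = 20, seed = 13)
  sB <- random_toy_structure(n_residues = 20, seed = 14)
  nA <- structure_rrcs(sA)
  nB <- structure_rrcs(sB)
  dAA <- delta_rrcs(nA, nA)
  expect_true(all(dAA$delta == 0))
  expect_true(all(dAA$provenance == "both"))
  dAB <- delta_rrcs(nA, nB)
  dBA <- delta_rrcs(nB, nA)
  key <- function(df) paste(df$key_i, df$key_j)
  m <- match(key(dAB), key(dBA))
  expect_equal(dAB$delta, -dBA$delta[m], tolerance = 1e-12)
  # pairs on one side only carry the full signed score
  solo <- dAB[dAB$provenance == "active_only", ]
  if (nrow(solo)) {
    ms <- match(key(solo), key(as.data.frame(nA)))
    expect_equal(solo$delta, nA$score[ms])
  }
})

test_that("delta refuses mismatched parameter sets", {
  s <- random_toy_structure(n_residues = 10, seed = 2)
  n1 <- structure_rrcs(s, params = rrcs_params())
  n2 <- structure_rrcs(s, params = rrcs_params(d_zero = 5.0))
  expect_error(delta_rrcs(n1, n2), "different RRCS parameters")
})

test_that("thresholding keeps exactly the pairs at or above min_abs", {
  sA <- random_toy_structure(n_residues = 20, seed = 21)
  sB <- random_toy_structure(n_residues = 20, seed = 22)
  d <- delta_rrcs(structure_rrcs(sA), structure_rrcs(sB))
  expect_equal(nrow(significant_changes(d, 0)), nrow(d))
  expect_equal(nrow(significant_changes(d, max(abs(d$delta)) + 1)), 0L)
  mid <- stats::median(abs(d$delta))
  kept <- significant_changes(d, mid)
  expect_true(all(abs(kept$delta) >= mid))
  expect_equal(nrow(kept), sum(abs(d$delta) >= mid))
})
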