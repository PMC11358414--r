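test_that("helix axes recover construction directions", {
  line <- cbind(0, 0, seq(0, 10, length.out = 8))
  ax <- helix_axis(line)
  expect_equal(abs(sum(ax$axis * c(0, 0, 1))), 1, tolerance = 1e-9)
  expect_error(helix_axis(line[1:3, ]), "at least 4")
  for (seed in 1:5) {
    h <- gen_helix(15, seed = seed)
    # recover the construction axis: transform z back through the fit
    ax <- helix_axis(h$ca)
    ends <- h$ca[15, ] - h$ca[1, ]
    expect_lt(acos(min(1, abs(sum(ax$axis * ends / sqrt(sum(ends^2)))))) *
                180 / pi, 5)
  }
})

test_that("kink angles match the planted bend across magnitudes", {
  for (seed in 1:5) {
    h0 <- gen_helix(21, 0, seed = seed)
    expect_lt(kink_angle(h0$ca, 11), 2)
  }
  for (ang in c(15, 30, 70, 90)) {
    h <- gen_helix(21, ang, 11, seed = ang)
    expect_lt(abs(kink_angle(h$ca, h$truth$pivot) - ang), 2)
  }
  h <- gen_helix(21, 30, 11, seed = 1)
  expect_error(kink_angle(h$ca, 2), "each side")
  expect_error(gen_helix(5, kink_angle = 30), ">= 8")
})

test_that("superposition recovers planted rigid transforms", {
  set.seed(7)
  x <- matrix(rnorm(30), ncol = 3)
  fit0 <- superpose(x, x)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  shifted <- sweep(x, 2, c(5, -3, 2), "+")
  expect_equal(superpose(shifted, x)$rmsd, 0, tolerance = 1e-9)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  rotated <- x %*% t(q)
  fit <- superpose(x, rotated)
  expect_equal(fit$rotation, q, tolerance = 1e-9)
  expect_error(superpose(x[1:2, ], x[1:2, ]), ">= 3")
})

test_that("tm opening recovers planted swing and tip displacement", {
  sp0 <- gen_state_pair(swing_angle = 0, seed = 2)
  op0 <- tm_opening(sp0$inactive, sp0$active, "A", sp0$truth$tm_range,
                    sp0$truth$pivot_resno, sp0$truth$anchor_resnos,
                    sp0$truth$tip_resno)
  expect_lt(op0$angle_deg, 0.5)
  expect_lt(op0$displacement, 0.1)
  sp <- gen_state_pair(swing_angle = 15, tip_shift = 4, seed = 3)
  op <- tm_opening(sp$inactive, sp$active, "A", sp$truth$tm_range,
                   sp$truth$pivot_resno, sp$truth$anchor_resnos,
                   sp$truth$tip_resno)
  expect_lt(abs(op$angle_deg - 15), 2)
  expect_lt(abs(op$displacement - 4), 0.3)
})

test_that("dihedrals follow the IUPAC sign convention", {
  # cis arrangement: 0 degrees; anti: 180
  expect_equal(dihedral4(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral4(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)),
               180)
  # build-then-measure at a planted angle
  a <- c(0, 0, 0); b <- c(1.5, 0, 0); cc <- c(2.1, 1.3, 0)
  for (tor in c(-135, -60, 60, 90, 179)) {
    d <- consnet:::place_atom(a, b, cc, 1.5, 111, tor)
    expect_equal(dihedral4(a, b, cc, d), tor, tolerance = 0.1)
  }
})

test_that("chi angles read planted rotamers and flag missing atoms", {
  sp <- gen_state_pair(seed = 5)
  ra <- sp$inactive$atom[sp$inactive$atom$resno == sp$truth$trp_resno, ]
  chi <- chi_dihedrals(ra)
  expect_equal(unname(chi["chi1"]), sp$truth$chi_inactive[1], tolerance = 0.2)
  expect_equal(unname(chi["chi2"]), sp$truth$chi_inactive[2], tolerance = 0.2)
  # a residue without the side-chain atoms yields NA, not an error
  ala <- sp$inactive$atom[sp$inactive$atom$resno == 101, ]
  expect_true(all(is.na(chi_dihedrals(ala)) |
                    ala$resid[1] %in% names(consnet:::CHI_ATOMS)))
  gly <- ala; gly$resid <- "GLY"
  expect_true(all(is.na(chi_dihedrals(gly))))
})

test_that("dihedral series track the planted two-rotamer trajectory", {
  g <- gen_two_state_frames(n_frames = 150, seed = 9)
  dh <- dihedral_series(g$frames, "A", 3)
  expect_equal(nrow(dh), 150L)
  for (st in 1:2) {
    idx <- g$truth$states == st
    expect_lt(circ_diff_deg(circ_mean_deg(dh$chi1[idx]),
                            g$truth$chi_means[[st]][1]), 5)
    expect_lt(circ_diff_deg(circ_mean_deg(dh$chi2[idx]),
                            g$truth$chi_means[[st]][2]), 5)
  }
  expect_error(dihedral_series(g$frames, "A", 99), "absent")
})

test_that("distance series are exact per frame", {
  g <- gen_two_state_frames(n_frames = 60, seed = 10)
  ds <- distance_series(g$frames, g$truth$probe$a, g$truth$probe$b)
  expect_equal(nrow(ds), 60L)
  expect_equal(ds$time_ps, (0:59) * 50)
  # recompute one frame by hand
  co <- matrix(g$frames$xyz[17, ], ncol = 3, byrow = TRUE)
  expect_equal(ds$distance[17], sqrt(sum((co[1, ] - co[2, ])^2)))
  expect_error(distance_series(g$frames, g$truth$probe$a,
                               list(chain = "A", resno = 9, elety = "CA")),
               "not found")
})

test_that("two-state classification labels the planted states", {
  cl <- classify_two_state(c(3, 3, 8, 8), "threshold", cutoff = 5)
  expect_equal(cl$states, c(1L, 1L, 2L, 2L))
  expect_equal(classify_two_state(rep(4, 10), "threshold", cutoff = 5)$states,
               rep(1L, 10))
  expect_error(classify_two_state(rep(4, 10), "kmeans2"), "degenerate")
  for (seed in 1:5) {
    g <- gen_two_state_frames(n_frames = 200, seed = seed)
    ds <- distance_series(g$frames, g$truth$probe$a, g$truth$probe$b)
    cl <- classify_two_state(ds$distance, "kmeans2")
    expect_gte(mean(cl$states == g$truth$states), 0.98)
    # deterministic and lower-mean-first
    cl2 <- classify_two_state(ds$distance, "kmeans2")
    expect_identical(cl$states, cl2$states)
    expect_lt(cl$means[1], cl$means[2])
  }
})

test_that("occupancy grids agree with the point-in-voxel oracle", {
  for (seed in 1:5) {
    g <- gen_two_state_frames(n_frames = 40, seed = seed,
                              water_occupancy = c(0.3, 0.7))
    sel <- which(g$frames$atom$is_water)
    grid <- occupancy_grid(g$frames, sel, spacing = 1.5)
    expect_true(all(grid$fraction >= 0 & grid$fraction <= 1))
    expect_equal(grid$fraction, oracle_occupancy(g$frames, sel, grid))
  }
})

test_that("grid masks use greater-or-equal threshold semantics", {
  g <- gen_two_state_frames(n_frames = 10, seed = 1,
                            water_occupancy = c(0.2, 0.1))
  sel <- which(g$frames$atom$is_water)
  grid <- occupancy_grid(g$frames, sel, spacing = 1)
  mk <- mask_grid(grid, 0.2)
  expect_equal(mk$voxels$fraction, 0.2)  # the 2-of-10 site survives
  expect_equal(mk$volume, 1)
  expect_equal(nrow(mask_grid(grid, 1.01 * max(grid$fraction))$voxels), 0L)
  all_visited <- mask_grid(grid, 1e-9)
  expect_equal(sum(all_visited$voxels$fraction > 0),
               nrow(all_visited$voxels))
})

test_that("angles are invariant under global rigid motion of the inputs", {
  h <- gen_helix(21, 30, 11, seed = 77)
  set.seed(78)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  moved <- sweep(h$ca %*% t(q), 2, c(3, -8, 12), "+")
  expect_equal(kink_angle(h$ca, 11), kink_angle(moved, 11),
               tolerance = 1e-6)
})
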