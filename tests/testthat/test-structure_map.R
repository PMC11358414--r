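placed_structure <- function(df) {
  structure(list(atom = df, source = "toy"), class = "mol_structure")
}

toy_with_water <- function(water_dist) {
  df <- rbind(
    data.frame(chain = "A", resno = 1L, insert = "", resid = "SER",
               elety = "CB", elesy = "C", x = 0, y = 0, z = 0,
               is_water = FALSE, is_ligand = FALSE),
    data.frame(chain = "A", resno = 50L, insert = "", resid = "HOH",
               elety = "O", elesy = "O", x = water_dist, y = 0, z = 0,
               is_water = TRUE, is_ligand = FALSE))
  placed_structure(df)
}

test_that("water adjacency applies the heavy-atom cutoff exactly", {
  expect_equal(water_adjacent_residues(toy_with_water(3.0), 3.5),
               res_key("A", 1))
  expect_equal(water_adjacent_residues(toy_with_water(4.0), 3.5),
               character(0))
  no_water <- toy_with_water(3)
  no_water$atom <- no_water$atom[!no_water$atom$is_water, ]
  expect_equal(water_adjacent_residues(no_water), character(0))
})

test_that("water and ligand adjacency are monotone in the cutoff", {
  s <- random_toy_structure(n_residues = 20, seed = 31, with_waters = 10)
  cuts <- c(2, 3.5, 5, 8)
  sets <- lapply(cuts, function(ct) water_adjacent_residues(s, ct))
  for (i in seq_len(length(cuts) - 1))
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("ligand contacts honour the cutoff and warn when absent", {
  df <- rbind(
    data.frame(chain = "A", resno = 1L, insert = "", resid = "PHE",
               elety = "CB", elesy = "C", x = 0, y = 0, z = 0,
               is_water = FALSE, is_ligand = FALSE),
    data.frame(chain = "A", resno = 90L, insert = "", resid = "CHS",
               elety = "C1", elesy = "C", x = 4.0, y = 0, z = 0,
               is_water = FALSE, is_ligand = TRUE))
  s <- placed_structure(df)
  expect_equal(ligand_contact_residues(s, "CHS", 4.5), res_key("A", 1))
  s$atom$x[2] <- 5.0
  expect_equal(ligand_contact_residues(s, "CHS", 4.5), character(0))
  expect_warning(ligand_contact_residues(s, "XYZ"), "no ligand")
})

test_that("surface detection separates a buried centre from its shell", {
  # one residue at the origin surrounded by 24 residues within 10 A
  n <- 24L
  set.seed(4)
  ang <- seq(0, 2 * pi, length.out = n + 1L)[-1L]
  shell <- data.frame(
    chain = "A", resno = 2L + seq_len(n), insert = "",
    resid = "LEU", elety = "CA", elesy = "C",
    x = 6 * cos(ang), y = 6 * sin(ang), z = rep(c(-2, 2), length.out = n),
    is_water = FALSE, is_ligand = FALSE)
  centre <- data.frame(chain = "A", resno = 1L, insert = "", resid = "LEU",
                       elety = "CA", elesy = "C", x = 0, y = 0, z = 0,
                       is_water = FALSE, is_ligand = FALSE)
  s <- placed_structure(rbind(centre, shell))
  surf <- surface_residues(s, patch_params(surface_burial_max = 20))
  expect_false(res_key("A", 1) %in% surf)      # 24 neighbours
  expect_true(all(res_key("A", shell$resno) %in% surf))
  # an isolated helix is all surface
  h <- gen_helix(12, seed = 1)
  iso <- placed_structure(data.frame(
    chain = "A", resno = 1:12, insert = "", resid = "ALA", elety = "CA",
    elesy = "C", x = h$ca[, 1], y = h$ca[, 2], z = h$ca[, 3],
    is_water = FALSE, is_ligand = FALSE))
  expect_equal(length(surface_residues(iso)), 12L)
})

test_that("patches partition conserved surface residues into components", {
  b <- gen_bundle(seed = 9)
  patches <- conserved_surface_patches(b$structure, b$truth$patch)
  expect_length(patches, 1L)
  expect_setequal(patches[[1]]$members, b$truth$patch)
  expect_equal(patches[[1]]$aromatic_count, 5L)
  # adding far-apart conserved singletons must not create patches
  far <- c(b$truth$patch, res_key("A", c(101L, 523L)))
  p2 <- conserved_surface_patches(b$structure, far)
  expect_length(p2, 1L)
  all_members <- unlist(lapply(p2, `[[`, "members"))
  expect_false(any(duplicated(all_members)))
})

test_that("the water-base selection is the three-way intersection", {
  sp <- gen_state_pair(swing_angle = 15, tip_shift = 4, seed = 4)
  net_i <- structure_rrcs(sp$inactive)
  net_a <- structure_rrcs(sp$active)
  delta <- significant_changes(
    delta_rrcs(net_a, net_i, match_residues(sp$active, sp$inactive)), 0.1)
  wset <- water_adjacent_residues(sp$inactive)
  sel <- select_positions(sp$panel, selection_rule("entropy_zero"))
  lab <- sp$panel$labels[sel]
  cons <- res_key(sp$generic_map$chain[sp$generic_map$label %in% lab],
                  sp$generic_map$resno[sp$generic_map$label %in% lab])
  picked <- activation_network_near_water(delta, cons, wset)
  expect_setequal(picked, sp$truth$water_base)
  # subset property against the component sets
  expect_true(all(picked %in% network_residues(delta)))
  expect_true(all(picked %in% cons))
  expect_true(all(picked %in% wset))
  # removing any one requirement must not shrink the selection
  expect_gte(length(intersect(network_residues(delta), wset)),
             length(picked))
})

test_that("annotation joins all flags and keys patches only on surface", {
  b <- gen_bundle(seed = 6)
  sp <- gen_state_pair(seed = 6)
  ann <- annotate(b$structure, b$panel, NULL, b$generic_map,
                  rule = selection_rule("entropy_zero"),
                  matrix = toy_substitution_matrix())
  expect_equal(nrow(ann), nrow(structure_residues(b$structure)))
  expect_setequal(ann$key[ann$conserved], b$truth$conserved)
  expect_setequal(ann$key[ann$water_adjacent], b$truth$water_adjacent)
  expect_true(all(is.na(ann$patch_id) | ann$surface))
  expect_true(all(ann$classwide_fraction[ann$conserved] == 1))
  # empty inputs give all-false flags
  ann0 <- annotate(b$structure)
  expect_false(any(ann0$conserved))
  expect_false(any(ann0$in_delta_network))
  expect_true(all(is.na(ann0$generic_label)))
})
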