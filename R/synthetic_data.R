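# Deterministic seeded generators for every input class of the pipeline,
# each with planted ground truth: designed alignments, paralog panels,
# ideal helices and 7-helix bundles with waters / sterol-like ligand /
# aromatic surface patch, two-state frame series, and inactive/active
# structure pairs with a swung helix and a flipped tryptophan rotamer.
#
# Geometry constants are textbook alpha-helix values (1.5 Angstrom rise,
# 100 degree twist, 2.3 Angstrom Calpha radius); nothing is physically
# minimised, the point is recorded ground truth.

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")
AA3to1 <- stats::setNames(names(AA3), AA3)

#' Toy substitution matrix for tests and fixtures
#'
#' A deliberately simple matrix with six similarity groups
#' (ILVM, FYW, KR, DE, ST, NQ): 6 on the diagonal, 3 within a group,
#' -2 otherwise. Group members score above both similarity thresholds in
#' use (>1 and >2), so fixtures do not depend on any published BLOSUM
#' scaling.
#'
#' @return 20x20 integer matrix.
#' @export
toy_substitution_matrix <- function() {
  m <- matrix(-2L, 20L, 20L, dimnames = list(AA1, AA1))
  groups <- list(c("I", "L", "V", "M"), c("F", "Y", "W"), c("K", "R"),
                 c("D", "E"), c("S", "T"), c("N", "Q"))
  for (g in groups) m[g, g] <- 3L
  diag(m) <- 6L
  m
}

toy_similarity_groups <- function() {
  list(c("I", "L", "V", "M"), c("F", "Y", "W"), c("K", "R"),
       c("D", "E"), c("S", "T"), c("N", "Q"))
}

#' Generate a designed ortholog alignment
#'
#' Emulates an ortholog MSA with known per-column structure:
#' `identical` columns carry a single residue (up to gap noise),
#' `similar` columns draw from one similarity group of the toy matrix,
#' `random` columns draw uniformly over the 20 residues. Gaps are
#' injected independently per cell at `gap_rate`.
#'
#' @param n_sequences number of sequences (default 50).
#' @param design character vector over columns, each `"identical"`,
#'   `"similar"` or `"random"`.
#' @param gap_rate per-cell gap probability in `[0, 0.2]`.
#' @param seed integer seed; the generator is bit-reproducible given
#'   (design, seed).
#' @return list with `msa` (an `msa` object) and `truth` (data frame
#'   `position`, `design`, `base_residue`).
#' @export
gen_msa <- function(n_sequences = 50L, design, gap_rate = 0.05, seed = 1L) {
  stopifnot(gap_rate >= 0, gap_rate <= 0.2, length(design) >= 1L,
            all(design %in% c("identical", "similar", "random")))
  set.seed(seed)
  groups <- toy_similarity_groups()
  ali <- matrix("", nrow = n_sequences, ncol = length(design))
  base <- character(length(design))
  for (p in seq_along(design)) {
    col <- switch(design[p],
      identical = {
        base[p] <- sample(AA1, 1L)
        rep(base[p], n_sequences)
      },
      similar = {
        g <- groups[[sample(length(groups), 1L)]]
        base[p] <- g[1L]
        sample(g, n_sequences, replace = TRUE)
      },
      random = {
        base[p] <- NA_character_
        sample(AA1, n_sequences, replace = TRUE)
      })
    ali[, p] <- col
  }
  if (gap_rate > 0) {
    gaps <- matrix(stats::runif(length(ali)) < gap_rate, nrow = n_sequences)
    ali[gaps] <- "-"
  }
  ids <- sprintf("ortholog_%03d", seq_len(n_sequences))
  msa <- new_msa(ids, apply(ali, 1L, paste, collapse = ""))
  list(msa = msa,
       truth = data.frame(position = seq_along(design), design = design,
                          base_residue = base, stringsAsFactors = FALSE))
}

#' Generate a cross-paralog panel with designed divergence
#'
#' Emulates the class-wide panel (11 paralogs by default) with known
#' per-position divergence: `all_identical` positions have 0 entropy,
#' `one_different` positions have 0.44 bits at n = 11, `two_different`
#' positions carry two deviating singletons, and `similar_only` positions
#' vary only within one similarity group of the toy matrix.
#'
#' @param patterns character vector over positions, each `"all_identical"`,
#'   `"one_different"`, `"two_different"` or `"similar_only"`.
#' @param n_receptors panel width (default 11).
#' @param n_conserved integer vector: how many receptors carry a
#'   within-ortholog-conserved flag at each position (default: all).
#' @param labels optional generic labels per position.
#' @param seed integer seed.
#' @return list with `panel` (a `paralog_panel`) and `truth` (data frame
#'   `position`, `pattern`, `n_conserved`).
#' @export
gen_panel <- function(patterns, n_receptors = 11L,
                      n_conserved = rep(n_receptors, length(patterns)),
                      labels = NULL, seed = 1L) {
  stopifnot(all(patterns %in% c("all_identical", "one_different",
                                "two_different", "similar_only")),
            all(n_conserved <= n_receptors), all(n_conserved >= 0))
  set.seed(seed)
  groups <- toy_similarity_groups()
  grouped <- unlist(groups)
  mf <- matrix("", nrow = length(patterns), ncol = n_receptors,
               dimnames = list(NULL, sprintf("receptor_%02d",
                                             seq_len(n_receptors))))
  dissimilar_to <- function(aa) {
    g <- Filter(function(x) aa %in% x, groups)
    excl <- if (length(g)) c(aa, g[[1L]]) else aa
    sample(setdiff(AA1, excl), 1L)
  }
  for (p in seq_along(patterns)) {
    base <- sample(AA1, 1L)
    row <- rep(base, n_receptors)
    if (patterns[p] == "one_different") {
      row[sample(n_receptors, 1L)] <- dissimilar_to(base)
    } else if (patterns[p] == "two_different") {
      i <- sample(n_receptors, 2L)
      row[i[1L]] <- dissimilar_to(base)
      row[i[2L]] <- dissimilar_to(base)
    } else if (patterns[p] == "similar_only") {
      g <- groups[[sample(length(groups), 1L)]]
      row <- sample(g, n_receptors, replace = TRUE)
      if (length(unique(row)) < 2L)
        row[sample(n_receptors, 1L)] <- setdiff(g, row[1L])[1L]
    }
    mf[p, ] <- row
  }
  conserved <- matrix(FALSE, nrow = length(patterns), ncol = n_receptors)
  for (p in seq_along(patterns))
    conserved[p, sample(n_receptors, n_conserved[p])] <- TRUE
  panel <- paralog_panel(mf, conserved, labels = labels)
  list(panel = panel,
       truth = data.frame(position = seq_along(patterns), pattern = patterns,
                          n_conserved = n_conserved, stringsAsFactors = FALSE))
}

rodrigues <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  k <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3L, 3L)
  diag(3L) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

random_rigid_transform <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  list(rot = q, trans = stats::runif(3L, -20, 20))
}

apply_rigid <- function(points, tf) {
  sweep(as.matrix(points) %*% t(tf$rot), 2L, tf$trans, "+")
}

ideal_helix_ca <- function(n_res, rise = 1.5, twist = 100, radius = 2.3,
                           phase = 0) {
  k <- seq_len(n_res) - 1L
  ang <- (phase + k * twist) * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), k * rise)
}

#' Generate an ideal alpha-helix Calpha trace with an optional kink
#'
#' A straight ideal helix (1.5 Angstrom rise, 100 degree twist,
#' 2.3 Angstrom radius) built along z, with the segment past the pivot
#' bent by `kink_angle` about an axis through the helix axis at the pivot
#' height, then placed at a random rigid-body orientation (seeded).
#'
#' @param n_res number of residues (>= 8 when kinked).
#' @param kink_angle bend in degrees (0 for a straight helix).
#' @param pivot pivot residue index (needs >= 4 residues on each side).
#' @param seed integer seed for the random placement.
#' @return list with `ca` (n x 3 matrix) and `truth`
#'   (`kink_angle`, `pivot`).
#' @export
gen_helix <- function(n_res, kink_angle = 0, pivot = NULL, seed = 1L) {
  if (kink_angle > 0) {
    if (n_res < 8L) stop("kinked helix needs >= 8 residues")
    if (is.null(pivot)) pivot <- ceiling(n_res / 2)
    if (pivot - 1L < 4L || n_res - pivot < 4L)
      stop("pivot too close to the helix ends")
  }
  set.seed(seed)
  ca <- ideal_helix_ca(n_res, phase = stats::runif(1L, 0, 360))
  if (kink_angle > 0) {
    centre <- c(0, 0, (pivot - 1L) * 1.5)
    rot <- rodrigues(c(1, 0, 0), kink_angle)
    after <- (pivot + 1L):n_res
    ca[after, ] <- sweep(sweep(ca[after, , drop = FALSE], 2L, centre) %*%
                           t(rot), 2L, centre, "+")
  }
  tf <- random_rigid_transform()
  list(ca = apply_rigid(ca, tf),
       truth = list(kink_angle = kink_angle, pivot = pivot))
}

# --- bundle construction ----------------------------------------------------

# One chain, n_helices vertical ideal helices on a ring. Residue numbers:
# helix h residue k -> resno = 100 * h + k. Atoms N, CA, C, O, CB per
# residue (no GLY used). CB points radially outward from the helix axis,
# which is what water / ligand placement keys on.
build_bundle_atoms <- function(n_helices, n_res, ring_radius, phases,
                               residue_names) {
  rows <- vector("list", n_helices * n_res)
  idx <- 0L
  for (h in seq_len(n_helices)) {
    centre_ang <- 2 * pi * (h - 1L) / n_helices
    axis_xy <- ring_radius * c(cos(centre_ang), sin(centre_ang))
    ca <- ideal_helix_ca(n_res, phase = phases[h])
    ca[, 1L] <- ca[, 1L] + axis_xy[1L]
    ca[, 2L] <- ca[, 2L] + axis_xy[2L]
    for (k in seq_len(n_res)) {
      p <- ca[k, ]
      radial <- c(p[1L] - axis_xy[1L], p[2L] - axis_xy[2L], 0)
      radial <- radial / sqrt(sum(radial^2))
      tang <- c(-radial[2L], radial[1L], 0)
      nm <- residue_names[k, h]
      at_names <- c("N", "CA", "C", "O", "CB")
      at_xyz <- rbind(p + c(0, 0, -1.16) + 0.87 * tang,
                      p,
                      p + c(0, 0, 1.16) - 0.87 * tang,
                      p + c(0, 0, 2.39) - 0.87 * tang,
                      p + 1.53 * radial)
      at_ele <- c("N", "C", "C", "O", "C")
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        chain = "A", resno = 100L * h + k, insert = "", resid = nm,
        elety = at_names, elesy = at_ele,
        x = at_xyz[, 1L], y = at_xyz[, 2L], z = at_xyz[, 3L],
        is_water = FALSE, is_ligand = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

bundle_radial <- function(atom, resno) {
  # outward unit vector (from the residue's helix axis) at a residue's CB
  ca <- atom[atom$resno == resno & atom$elety == "CA", ]
  cb <- atom[atom$resno == resno & atom$elety == "CB", ]
  v <- c(cb$x - ca$x, cb$y - ca$y, cb$z - ca$z)
  v / sqrt(sum(v^2))
}

# NeRF atom placement: position d with |c-d| = bond, angle(b,c,d) = angle
# and torsion(a,b,c,d) = torsion (degrees)
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  rot <- cbind(bc, m, n)
  as.numeric(c + rot %*% d_local)
}

trp_side_chain <- function(atom, resno, chi1, chi2) {
  get <- function(el) {
    r <- atom[atom$resno == resno & atom$elety == el, ]
    c(r$x, r$y, r$z)
  }
  n <- get("N"); ca <- get("CA"); cb <- get("CB")
  cg <- place_atom(n, ca, cb, 1.52, 114, chi1)
  cd1 <- place_atom(ca, cb, cg, 1.43, 127, chi2)
  template <- atom[atom$resno == resno & atom$elety == "CB", ]
  add <- template[c(1L, 1L), ]
  add$elety <- c("CG", "CD1")
  add$elesy <- "C"
  add$x <- c(cg[1L], cd1[1L]); add$y <- c(cg[2L], cd1[2L])
  add$z <- c(cg[3L], cd1[3L])
  add
}

default_bundle_names <- function(n_res, n_helices) {
  pool <- c("LEU", "ALA", "VAL", "ILE", "THR", "SER", "MET", "ASN",
            "GLU", "LYS", "GLN", "ASP")
  matrix(rep_len(pool, n_res * n_helices), nrow = n_res)
}

#' Generate a toy 7-helix bundle with planted features
#'
#' Builds a single-chain bundle of vertical ideal helices on a ring
#' (helix `h`, residue `k` is residue number `100 * h + k`) and plants,
#' with recorded ground truth: water oxygens 3 Angstrom off the CB of
#' designated residues, a sterol-like ligand (residue name CHS) whose
#' atoms sit 4 Angstrom off the CB of a designated aromatic surface
#' patch, and a cross-paralog panel in which exactly the patch (and any
#' extra conserved residues requested) has zero entropy while all other
#' positions are strongly diverged.
#'
#' @param n_helices number of helices (default 7).
#' @param n_res residues per helix (default 24).
#' @param ring_radius helix-axis ring radius in Angstrom (default 13).
#' @param water_resnos residue numbers receiving a planted water
#'   (default: three interior-facing residues of helix 6).
#' @param patch_resnos residue numbers forming the aromatic surface patch
#'   (default: five residues spanning helices 2 and 3). `NULL` for none.
#' @param with_ligand place the sterol-like ligand along the patch.
#' @param seed integer seed (helix phases and panel assembly).
#' @return list with `structure` (a `mol_structure`), `panel`
#'   (a `paralog_panel` keyed by generic labels `h.k`), `generic_map`,
#'   and `truth` (lists of residue keys: `water_adjacent`,
#'   `ligand_contacts`, `patch`, `conserved`).
#' @export
gen_bundle <- function(n_helices = 7L, n_res = 24L, ring_radius = 11,
                       water_resnos = NULL, patch_resnos = NULL,
                       with_ligand = TRUE, seed = 1L) {
  set.seed(seed)
  phases <- stats::runif(n_helices, 0, 360)
  # outward-facing surface stripe of a helix: residues k0, k0+4, k0+7,
  # k0+11, k0+14 stay within +-40 degrees of one face (100 degrees per
  # residue); the default patch and water sites live on such stripes so
  # that planted decorations point away from the rest of the bundle
  outward_deg <- function(h) (h - 1L) * 360 / n_helices
  if (is.null(patch_resnos)) {
    patch_resnos <- 300L + c(6L, 10L, 13L, 17L, 20L)
    phases[3L] <- outward_deg(3L) - 12L * 100  # residue 13 faces outward
  }
  if (is.null(water_resnos)) {
    water_resnos <- 600L + c(6L, 10L, 13L)
    phases[6L] <- outward_deg(6L) - 9L * 100   # residue 10 faces outward
  }
  names_mat <- default_bundle_names(n_res, n_helices)
  patch_names <- c("PHE", "TYR", "TRP", "PHE", "HIS")
  for (i in seq_along(patch_resnos)) {
    h <- patch_resnos[i] %/% 100L; k <- patch_resnos[i] %% 100L
    names_mat[k, h] <- patch_names[((i - 1L) %% 5L) + 1L]
  }
  atom <- build_bundle_atoms(n_helices, n_res, ring_radius, phases,
                             names_mat)
  waters <- do.call(rbind, lapply(seq_along(water_resnos), function(i) {
    r <- water_resnos[i]
    cb <- atom[atom$resno == r & atom$elety == "CB", ]
    u <- bundle_radial(atom, r)
    data.frame(chain = "A", resno = 900L + i, insert = "", resid = "HOH",
               elety = "O", elesy = "O",
               x = cb$x + 3 * u[1L], y = cb$y + 3 * u[2L],
               z = cb$z + 3 * u[3L],
               is_water = TRUE, is_ligand = FALSE, stringsAsFactors = FALSE)
  }))
  ligand <- NULL
  if (with_ligand && length(patch_resnos)) {
    ligand <- do.call(rbind, lapply(seq_along(patch_resnos), function(i) {
      r <- patch_resnos[i]
      cb <- atom[atom$resno == r & atom$elety == "CB", ]
      u <- bundle_radial(atom, r)
      data.frame(chain = "A", resno = 950L, insert = "", resid = "CHS",
                 elety = paste0("C", i), elesy = "C",
                 x = cb$x + 4 * u[1L], y = cb$y + 4 * u[2L],
                 z = cb$z + 4 * u[3L],
                 is_water = FALSE, is_ligand = TRUE,
                 stringsAsFactors = FALSE)
    }))
  }
  atom <- rbind(atom, waters, ligand)
  rownames(atom) <- NULL
  struct <- structure(list(atom = atom, source = "synthetic bundle"),
                      class = "mol_structure")
  # panel keyed by generic labels "h.k": conserved (zero-entropy) exactly
  # at the patch and water residues, strong divergence everywhere else
  res <- structure_residues(struct)
  labels <- sprintf("%d.%d", res$resno %/% 100L, res$resno %% 100L)
  conserved_resnos <- sort(unique(c(patch_resnos, water_resnos)))
  pat <- ifelse(res$resno %in% conserved_resnos, "all_identical",
                "two_different")
  mf <- matrix("", nrow = nrow(res), ncol = 11L)
  for (p in seq_len(nrow(res))) {
    if (pat[p] == "all_identical") {
      mf[p, ] <- rep(AA3to1[[res$resid[p]]], 11L)
    } else {
      picks <- sample(c("A", "G", "P", "C", "H", "W"), 4L)
      mf[p, ] <- c(rep(picks[1L], 5L), rep(picks[2L], 3L), rep(picks[3L], 2L),
                   picks[4L])
    }
  }
  conserved <- matrix(pat == "all_identical", nrow = nrow(res), ncol = 11L)
  panel <- paralog_panel(mf, conserved,
                         receptor_ids = sprintf("receptor_%02d", 1:11),
                         labels = labels)
  gmap <- new_generic_map(res$chain, res$resno, labels)
  truth <- list(
    water_adjacent = res_key("A", water_resnos),
    ligand_contacts = if (with_ligand) res_key("A", patch_resnos)
                      else character(0),
    patch = res_key("A", patch_resnos),
    conserved = res_key("A", conserved_resnos))
  list(structure = struct, panel = panel, generic_map = gmap, truth = truth)
}

#' Write a bundle (or any structure) as PDB and minimal mmCIF fixtures
#'
#' Emits the same synthetic structure in both coordinate dialects so the
#' two readers can be checked against each other. The mmCIF emitted here
#' is a minimal atom_site loop intended only for fixtures.
#'
#' @param structure a `mol_structure`.
#' @param dir output directory.
#' @param stem file stem (default `"synthetic"`).
#' @return named character vector of the two paths.
#' @export
write_structure_fixtures <- function(structure, dir, stem = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, paste0(stem, ".pdb"))
  cif <- file.path(dir, paste0(stem, ".cif"))
  write_structure_pdb(structure, pdb)
  a <- structure$atom
  grp <- ifelse(a$is_water | a$is_ligand, "HETATM", "ATOM")
  header <- c("data_synthetic", "#", "loop_",
              paste0("_atom_site.",
                     c("group_PDB", "id", "type_symbol", "label_atom_id",
                       "label_alt_id", "label_comp_id", "label_asym_id",
                       "label_entity_id", "label_seq_id",
                       "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                       "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
                       "auth_seq_id", "auth_comp_id", "auth_asym_id",
                       "auth_atom_id", "pdbx_PDB_model_num")))
  lines <- sprintf(
    "%-6s %-5d %-2s %-4s . %-3s A 1 %-4d %s %8.3f %8.3f %8.3f 1.00 0.00 ? %-4d %-3s %s %-4s 1",
    grp, seq_len(nrow(a)), a$elesy, a$elety, a$resid, seq_len(nrow(a)),
    ifelse(a$insert == "", "?", a$insert), a$x, a$y, a$z, a$resno, a$resid,
    a$chain, a$elety)
  writeLines(c(header, lines, "#"), cif)
  c(pdb = pdb, cif = cif)
}

#' Generate an inactive/active structure pair with planted activation
#'
#' Starts from the synthetic bundle (with waters at designated helix-6
#' residues and a tryptophan with a built side chain on helix 7) and
#' produces the active state by (a) swinging the intracellular segment of
#' helix 6 outward by `swing_angle` about a pivot placed so the tip
#' Calpha moves by exactly `tip_shift`, and (b) flipping the planted
#' tryptophan between two chi1/chi2 rotamers. The contact-change network
#' of the pair is therefore confined to helix 6 and the tryptophan, and
#' the planted water-base residues are the only ones that are conserved,
#' water-adjacent and contact-rewired at once.
#'
#' @param swing_angle helix swing in degrees (0 to 90).
#' @param tip_shift tip Calpha displacement in Angstrom.
#' @param seed integer seed.
#' @param n_res residues per helix (default 24).
#' @return list with `inactive`, `active` (`mol_structure`s), `panel`,
#'   `generic_map`, and `truth` (`swing_angle`, `tip_shift`, `chain`,
#'   `tm_range`, `pivot_resno`, `tip_resno`, `anchor_resnos`,
#'   `water_base` keys, `trp_resno`, `chi_inactive`, `chi_active`).
#' @export
gen_state_pair <- function(swing_angle = 15, tip_shift = 4, seed = 1L,
                           n_res = 24L) {
  if (swing_angle < 0 || swing_angle > 90) stop("swing angle must be 0..90")
  base <- gen_bundle(n_res = n_res, with_ligand = FALSE,
                     patch_resnos = integer(0), water_resnos = integer(0),
                     seed = seed)
  atom <- base$structure$atom
  # planted tryptophan with explicit side chain on helix 7
  trp_resno <- 712L
  atom$resid[atom$resno == trp_resno] <- "TRP"
  chi_inactive <- c(-60, 90)
  chi_active <- c(180, -90)
  tip_resno <- 601L
  tm_range <- 601:(600L + n_res)
  lever <- if (swing_angle > 0)
    tip_shift / (2 * sin(swing_angle * pi / 360)) else 15
  max_lever <- (n_res - 6L) * 1.5
  if (lever < 13.5 || lever > max_lever)
    stop("infeasible swing/shift combination (lever arm ", round(lever, 1),
         " Angstrom outside 13.5..", max_lever, ")")
  moving_res <- tm_range[(tm_range - 601L) * 1.5 < lever - 1e-9]
  # water-base residues: swinging helix-6 residues that carry inter-helix
  # contacts (CB within contact range of a neighbouring helix) and sit
  # well below the pivot, so the swing is guaranteed to rewire them
  other <- atom[!atom$resno %in% tm_range, c("x", "y", "z")]
  facing <- Filter(function(r) {
    cb <- atom[atom$resno == r & atom$elety == "CB", ]
    d2 <- (other$x - cb$x)^2 + (other$y - cb$y)^2 + (other$z - cb$z)^2
    min(d2) < 4.5^2
  }, tm_range[(tm_range - 601L) * 1.5 < lever - 4.5])
  water_resnos <- utils::head(unlist(facing), 3L)
  if (length(water_resnos) < 2L)
    stop("bundle geometry yielded fewer than 2 contact-bearing helix-6 ",
         "residues below the pivot")
  waters <- do.call(rbind, lapply(seq_along(water_resnos), function(i) {
    r <- water_resnos[i]
    cb <- atom[atom$resno == r & atom$elety == "CB", ]
    data.frame(chain = "A", resno = 900L + i, insert = "", resid = "HOH",
               elety = "O", elesy = "O", x = cb$x, y = cb$y, z = cb$z + 3,
               is_water = TRUE, is_ligand = FALSE, stringsAsFactors = FALSE)
  }))
  atom <- rbind(atom, waters)
  atom_inact <- rbind(atom, trp_side_chain(atom, trp_resno,
                                           chi_inactive[1L], chi_inactive[2L]))
  atom_act <- rbind(atom, trp_side_chain(atom, trp_resno,
                                         chi_active[1L], chi_active[2L]))
  ord <- order(atom_inact$resno, match(atom_inact$elety,
               c("N", "CA", "C", "O", "CB", "CG", "CD1")))
  atom_inact <- atom_inact[ord, ]; atom_act <- atom_act[ord, ]
  if (swing_angle > 0) {
    tip_ca <- atom[atom$resno == tip_resno & atom$elety == "CA", ]
    centre <- c(tip_ca$x, tip_ca$y, tip_ca$z + lever)
    axis <- bundle_radial(atom, tip_resno)
    rot <- rodrigues(axis, swing_angle)
    mv <- atom_act$resno %in% moving_res
    xyz <- as.matrix(atom_act[mv, c("x", "y", "z")])
    atom_act[mv, c("x", "y", "z")] <-
      sweep(sweep(xyz, 2L, centre) %*% t(rot), 2L, centre, "+")
  }
  pivot_resno <- max(moving_res)
  inactive <- structure(list(atom = atom_inact, source = "synthetic inactive"),
                        class = "mol_structure")
  active <- structure(list(atom = atom_act, source = "synthetic active"),
                      class = "mol_structure")
  # regenerate panel/map including the TRP rename
  res <- structure_residues(inactive)
  labels <- sprintf("%d.%d", res$resno %/% 100L, res$resno %% 100L)
  water_base <- res_key("A", water_resnos)
  conserved_resnos <- water_resnos
  pat <- ifelse(res$resno %in% conserved_resnos, "all_identical",
                "two_different")
  set.seed(seed + 1L)
  mf <- matrix("", nrow = nrow(res), ncol = 11L)
  for (p in seq_len(nrow(res))) {
    if (pat[p] == "all_identical") {
      mf[p, ] <- rep(AA3to1[[res$resid[p]]], 11L)
    } else {
      picks <- sample(c("A", "G", "P", "C", "H", "W"), 4L)
      mf[p, ] <- c(rep(picks[1L], 5L), rep(picks[2L], 3L), rep(picks[3L], 2L),
                   picks[4L])
    }
  }
  conserved <- matrix(pat == "all_identical", nrow = nrow(res), ncol = 11L)
  panel <- paralog_panel(mf, conserved,
                         receptor_ids = sprintf("receptor_%02d", 1:11),
                         labels = labels)
  gmap <- new_generic_map(res$chain, res$resno, labels)
  list(inactive = inactive, active = active, panel = panel,
       generic_map = gmap,
       truth = list(swing_angle = swing_angle, tip_shift = tip_shift,
                    chain = "A", tm_range = tm_range,
                    pivot_resno = pivot_resno, tip_resno = tip_resno,
                    anchor_resnos = c(101:(100L + n_res), 201:(200L + n_res),
                                      301:(300L + n_res), 401:(400L + n_res)),
                    water_base = water_base, trp_resno = trp_resno,
                    chi_inactive = chi_inactive, chi_active = chi_active))
}

# wrapped von Mises sampler (Best & Fisher rejection scheme)
rvonmises <- function(n, mu_deg, kappa) {
  if (kappa <= 0) return(stats::runif(n, -180, 180))
  mu <- mu_deg * pi / 180
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3L)
      z <- cos(pi * u[1L])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (c_ * (2 - c_) - u[2L] > 0 || log(c_ / u[2L]) + 1 - c_ >= 0) break
    }
    out[i] <- mu + sign(u[3L] - 0.5) * acos(f)
  }
  deg <- out * 180 / pi
  ((deg + 180) %% 360) - 180
}

#' Generate a two-state frame series with planted dynamics
#'
#' Emulates desk-scale trajectory behaviour: a probe atom pair whose
#' distance alternates between two states with geometric dwell times and
#' Gaussian within-state spread, a tryptophan whose chi1/chi2 rotamer
#' follows the same state sequence (von Mises spread around per-state
#' means), and water sites occupied in an exact, recorded fraction of
#' frames (absent frames park the water far from the site, keeping the
#' topology constant).
#'
#' @param n_frames number of frames (>= 2).
#' @param frame_interval frame spacing in ps (default 50).
#' @param state_means,state_sds distance means / SDs per state (Angstrom),
#'   length 2 (defaults 4, 9 and 0.3, 0.3).
#' @param dwell mean dwell time in frames (default 25).
#' @param chi_means list of two `c(chi1, chi2)` rotamer means (degrees).
#' @param chi_kappa von Mises concentration of the rotamer spread.
#' @param water_occupancy numeric vector of target occupancy fractions,
#'   one planted water site each.
#' @param seed integer seed.
#' @return list with `frames` (a `frame_series`) and `truth` (`states`,
#'   `state_means`, `chi_means`, `water_occupancy` with achieved exact
#'   fractions, `water_sites` coordinates, `trp` = chain/resno of the
#'   tryptophan, `probe` = the two distance atoms).
#' @export
gen_two_state_frames <- function(n_frames = 200L, frame_interval = 50,
                                 state_means = c(4, 9),
                                 state_sds = c(0.3, 0.3), dwell = 25,
                                 chi_means = list(c(-60, 90), c(180, -90)),
                                 chi_kappa = 200, water_occupancy = 0.5,
                                 seed = 1L) {
  stopifnot(n_frames >= 2L, all(state_sds > 0),
            state_means[1L] != state_means[2L])
  set.seed(seed)
  states <- integer(0)
  s <- 1L
  while (length(states) < n_frames) {
    states <- c(states, rep(s, stats::rgeom(1L, 1 / dwell) + 1L))
    s <- 3L - s
  }
  states <- states[seq_len(n_frames)]
  dist <- stats::rnorm(n_frames, state_means[states], state_sds[states])
  chi1 <- chi2 <- numeric(n_frames)
  for (st in 1:2) {
    idx <- which(states == st)
    chi1[idx] <- rvonmises(length(idx), chi_means[[st]][1L], chi_kappa)
    chi2[idx] <- rvonmises(length(idx), chi_means[[st]][2L], chi_kappa)
  }
  sites <- lapply(seq_along(water_occupancy), function(i)
    c(10 * i, -10, 0.5))
  present <- lapply(water_occupancy, function(f) {
    k <- round(f * n_frames)
    sort(sample.int(n_frames, k))
  })
  # fixed topology: probe CA pair, TRP with side chain, one O per site
  trp_base <- list(n = c(20, 0, 0), ca = c(21.46, 0, 0), cb = c(22, 1.4, 0))
  topo <- data.frame(
    chain = "A",
    resno = c(1L, 2L, rep(3L, 5L), 100L + seq_along(sites)),
    insert = "",
    resid = c("ALA", "ALA", rep("TRP", 5L), rep("HOH", length(sites))),
    elety = c("CA", "CA", "N", "CA", "CB", "CG", "CD1",
              rep("O", length(sites))),
    elesy = c("C", "C", "N", "C", "C", "C", "C", rep("O", length(sites))),
    x = 0, y = 0, z = 0,
    is_water = c(rep(FALSE, 7L), rep(TRUE, length(sites))),
    is_ligand = FALSE, stringsAsFactors = FALSE)
  nat <- nrow(topo)
  xyz <- matrix(0, nrow = n_frames, ncol = 3L * nat)
  for (f in seq_len(n_frames)) {
    cg <- place_atom(trp_base$n, trp_base$ca, trp_base$cb, 1.52, 114,
                     chi1[f])
    cd1 <- place_atom(trp_base$ca, trp_base$cb, cg, 1.43, 127, chi2[f])
    # absent frames park the water in a frame-specific far voxel so no
    # parked position ever accumulates occupancy
    wpos <- lapply(seq_along(sites), function(i) {
      if (f %in% present[[i]]) sites[[i]]
      else sites[[i]] + c(0, 0, 50 + 5 * f)
    })
    co <- rbind(c(0, 0, 0), c(dist[f], 0, 0),
                trp_base$n, trp_base$ca, trp_base$cb, cg, cd1,
                do.call(rbind, wpos))
    xyz[f, ] <- as.numeric(t(co))
  }
  topo[, c("x", "y", "z")] <- matrix(xyz[1L, ], ncol = 3L, byrow = TRUE)
  frames <- structure(list(atom = topo, xyz = xyz,
                           frame_interval = frame_interval),
                      class = "frame_series")
  list(frames = frames,
       truth = list(states = states, state_means = state_means,
                    chi_means = chi_means,
                    water_occupancy = vapply(present, length, 0L) / n_frames,
                    water_sites = sites,
                    trp = list(chain = "A", resno = 3L),
                    probe = list(a = list(chain = "A", resno = 1L,
                                          elety = "CA"),
                                 b = list(chain = "A", resno = 2L,
                                          elety = "CA"))))
}
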