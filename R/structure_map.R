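# Mapping conservation and contact-change results onto structures:
# water-adjacent residues, the water-pocket-base subsection of the
# activation network, and conserved surface patches (sterol-site logic).

#' Surface-patch parameters
#'
#' @param neighbor_radius Calpha-Calpha distance (Angstrom) under which two
#'   residues are "structurally continuous" (default 8.0).
#' @param surface_burial_max a residue is on the surface when its Calpha
#'   has at most this many neighbouring Calpha within 10 Angstrom
#'   (default 20, calibrated on the synthetic 7-helix bundle).
#' @param water_cutoff heavy-atom to water-oxygen distance (Angstrom) for
#'   water adjacency (default 3.5, a hydrogen-bond heavy-atom distance).
#' @param ligand_cutoff heavy-atom distance for ligand contact
#'   (default 4.5, hydrophobic-contact range).
#' @param min_patch_size smallest surface patch reported (default 3).
#' @return list of class `patch_params`.
#' @export
patch_params <- function(neighbor_radius = 8.0, surface_burial_max = 20L,
                         water_cutoff = 3.5, ligand_cutoff = 4.5,
                         min_patch_size = 3L) {
  stopifnot(neighbor_radius > 0, surface_burial_max > 0, water_cutoff > 0,
            ligand_cutoff > 0, min_patch_size > 0)
  structure(list(neighbor_radius = neighbor_radius,
                 surface_burial_max = as.integer(surface_burial_max),
                 water_cutoff = water_cutoff, ligand_cutoff = ligand_cutoff,
                 min_patch_size = as.integer(min_patch_size)),
            class = "patch_params")
}

# minimum distance from each residue's heavy atoms to a set of points
residues_within <- function(structure, points, cutoff) {
  a <- structure$atom
  a <- a[!a$is_water & !a$is_ligand, , drop = FALSE]
  if (nrow(a) == 0L || nrow(points) == 0L) return(character(0))
  x <- as.matrix(a[, c("x", "y", "z")])
  d2 <- outer(rowSums(x^2), rowSums(points^2), "+") - 2 * tcrossprod(x, points)
  near <- sqrt(pmax(apply(d2, 1L, min), 0)) <= cutoff
  unique(res_key(a$chain, a$resno, a$insert)[near])
}

#' Residues adjacent to water
#'
#' @param structure a `mol_structure` (may contain zero waters).
#' @param water_cutoff distance cutoff in Angstrom (default 3.5).
#' @return character vector of residue keys with at least one heavy atom
#'   within `water_cutoff` of a water oxygen.
#' @export
water_adjacent_residues <- function(structure, water_cutoff = 3.5) {
  w <- structure$atom[structure$atom$is_water &
                        structure$atom$elesy == "O", , drop = FALSE]
  if (nrow(w) == 0L) return(character(0))
  residues_within(structure, as.matrix(w[, c("x", "y", "z")]), water_cutoff)
}

#' Residues in contact with a named ligand
#'
#' @param structure a `mol_structure`.
#' @param ligand_names residue names of the ligand(s), e.g.
#'   `c("CHS", "CLR")` for cholesterol hemisuccinate / cholesterol.
#' @param cutoff heavy-atom distance cutoff (default 4.5 Angstrom).
#' @return character vector of residue keys; empty (with a warning) when
#'   no ligand of the given names is present.
#' @export
ligand_contact_residues <- function(structure, ligand_names = c("CHS", "CLR"),
                                    cutoff = 4.5) {
  stopifnot(cutoff > 0)
  lg <- structure$atom[structure$atom$is_ligand &
                         structure$atom$resid %in% ligand_names, , drop = FALSE]
  if (nrow(lg) == 0L) {
    warning("no ligand named ", paste(ligand_names, collapse = "/"),
            " in structure")
    return(character(0))
  }
  residues_within(structure, as.matrix(lg[, c("x", "y", "z")]), cutoff)
}

#' Water-pocket-base subsection of the activation network
#'
#' The intersection of three residue sets: residues participating in at
#' least one contact-change edge, residues at class-wide conserved
#' positions, and residues adjacent to water.
#'
#' @param delta a `delta_network` (already thresholded as desired).
#' @param conserved_residues character vector of residue keys at conserved
#'   positions.
#' @param water_set character vector of water-adjacent residue keys (from
#'   [water_adjacent_residues()]).
#' @return sorted character vector of residue keys.
#' @export
activation_network_near_water <- function(delta, conserved_residues,
                                          water_set) {
  in_delta <- network_residues(delta)
  sort(intersect(intersect(in_delta, conserved_residues), water_set))
}

ca_table <- function(structure) {
  a <- structure$atom
  ca <- a[!a$is_water & !a$is_ligand & a$elety == "CA", , drop = FALSE]
  all_res <- structure_residues(structure)
  missing <- setdiff(all_res$key, res_key(ca$chain, ca$resno, ca$insert))
  if (length(missing))
    warning(length(missing), " residue(s) without CA excluded from ",
            "surface/patch analysis")
  ca
}

#' Surface residues by Calpha burial count
#'
#' A coordination-number proxy for solvent exposure: a residue counts as
#' surface when its Calpha has at most `surface_burial_max` other Calpha
#' within 10 Angstrom. Residues without a Calpha are excluded with a
#' warning.
#'
#' @param structure a `mol_structure`.
#' @param params a [patch_params()] list.
#' @return character vector of surface residue keys.
#' @export
surface_residues <- function(structure, params = patch_params()) {
  ca <- ca_table(structure)
  if (nrow(ca) == 0L) return(character(0))
  x <- as.matrix(ca[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(x))
  nb <- rowSums(d <= 10.0) - 1L
  res_key(ca$chain, ca$resno, ca$insert)[nb <= params$surface_burial_max]
}

#' Conserved, structurally continuous surface patches
#'
#' Builds the graph whose vertices are residues that are both conserved
#' and on the surface, with edges between Calpha pairs within
#' `neighbor_radius`, and reports its connected components of at least
#' `min_patch_size` residues. Each patch carries its aromatic count
#' (F/Y/W/H), the enrichment signature of the sterol-binding face.
#'
#' @param structure a `mol_structure`.
#' @param conserved_residues character vector of conserved residue keys.
#' @param params a [patch_params()] list.
#' @param surface optional precomputed surface set (keys); computed from
#'   the structure when `NULL`.
#' @return list of patches, each a list with `members` (sorted keys),
#'   `size`, `aromatic_count`; ordered by decreasing aromatic count then
#'   size.
#' @export
conserved_surface_patches <- function(structure, conserved_residues,
                                      params = patch_params(),
                                      surface = NULL) {
  if (is.null(surface)) surface <- surface_residues(structure, params)
  ca <- ca_table(structure)
  ca$key <- res_key(ca$chain, ca$resno, ca$insert)
  cand <- ca[ca$key %in% intersect(conserved_residues, surface), ,
             drop = FALSE]
  if (nrow(cand) == 0L) return(list())
  x <- as.matrix(cand[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(x))
  adj <- d <= params$neighbor_radius
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  patches <- lapply(split(seq_len(nrow(cand)), comp), function(idx) {
    members <- sort(cand$key[idx])
    list(members = members, size = length(members),
         aromatic_count = sum(cand$resid[idx] %in%
                                c("PHE", "TYR", "TRP", "HIS")))
  })
  patches <- Filter(function(p) p$size >= params$min_patch_size, patches)
  ord <- order(-vapply(patches, `[[`, 0L, "aromatic_count"),
               -vapply(patches, `[[`, 0L, "size"))
  unname(patches[ord])
}

#' Annotate every residue of a structure
#'
#' The pipeline join: one row per (non-water, non-ligand) residue carrying
#' its generic label, panel-derived conservation, water adjacency,
#' membership in the contact-change network, surface status and patch id.
#' Panel positions are keyed to residues through the generic-number map
#' and the panel's position labels; residues without a label (or whose
#' label is absent from the panel) get `NA` conservation fields.
#'
#' @param structure a `mol_structure`.
#' @param panel a `paralog_panel` with `labels` set (or `NULL`).
#' @param delta a `delta_network` (or `NULL`).
#' @param generic_map a `generic_map` (or `NULL`).
#' @param params a [patch_params()] list.
#' @param rule a [selection_rule()] defining "conserved" for the patch
#'   analysis.
#' @param matrix substitution matrix for `similar_only` rules.
#' @return data frame of class `residue_annotation` with columns `key`,
#'   `chain`, `resno`, `resid`, `generic_label`, `conserved`,
#'   `classwide_fraction`, `entropy_bits`, `water_adjacent`,
#'   `in_delta_network`, `surface`, `patch_id`.
#' @export
annotate <- function(structure, panel = NULL, delta = NULL,
                     generic_map = NULL, params = patch_params(),
                     rule = selection_rule("entropy_zero"),
                     matrix = blosum80()) {
  res <- structure_residues(structure)
  lab <- if (is.null(generic_map)) rep(NA_character_, nrow(res)) else
    generic_label(generic_map, res$chain, res$resno)
  conserved <- rep(FALSE, nrow(res))
  cw <- ent <- rep(NA_real_, nrow(res))
  if (!is.null(panel) && !is.null(panel$labels)) {
    pos <- match(lab, panel$labels)
    hit <- !is.na(pos)
    cw[hit] <- panel$classwide_fraction[pos[hit]]
    ent[hit] <- panel$entropy_bits[pos[hit]]
    selected <- select_positions(panel, rule, matrix)
    conserved[hit] <- pos[hit] %in% selected
  }
  wset <- water_adjacent_residues(structure, params$water_cutoff)
  dset <- if (is.null(delta)) character(0) else network_residues(delta)
  surf <- surface_residues(structure, params)
  out <- data.frame(key = res$key, chain = res$chain, resno = res$resno,
                    resid = res$resid, generic_label = lab,
                    conserved = conserved, classwide_fraction = cw,
                    entropy_bits = ent,
                    water_adjacent = res$key %in% wset,
                    in_delta_network = res$key %in% dset,
                    surface = res$key %in% surf,
                    patch_id = NA_integer_, stringsAsFactors = FALSE)
  patches <- conserved_surface_patches(structure, out$key[out$conserved],
                                       params, surface = surf)
  for (i in seq_along(patches))
    out$patch_id[out$key %in% patches[[i]]$members] <- i
  class(out) <- c("residue_annotation", "data.frame")
  out
}
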