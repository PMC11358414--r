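# Residue-residue contact scores (RRCS) and activation-difference networks.
#
# Each residue pair scores the sum over its heavy-atom pairs of a linear
# distance ramp: 1 at or below the contact cutoff, 0 at or beyond the zero
# cutoff. For sequence-near pairs (same chain, |i - j| <= 4) the main-chain
# atoms of both residues are excluded so that trivial backbone adjacency
# does not dominate the network. The activation network is the signed
# difference score_active - score_inactive over matched residues, a pair
# missing on one side contributing 0 there.

MAIN_CHAIN_ATOMS <- c("N", "CA", "C", "O")

#' RRCS parameters
#'
#' @param d_contact full-contact distance in Angstrom: atom pairs at or
#'   below it score 1 (default 3.23).
#' @param d_zero zero-contact distance: pairs at or beyond it score 0
#'   (default 4.63); between the two cutoffs the score ramps linearly.
#' @param near_sequence_separation residue-number separation at or below
#'   which (same chain) the main-chain atoms N, CA, C, O of both residues
#'   are excluded (default 4).
#' @return list of class `rrcs_params`.
#' @export
rrcs_params <- function(d_contact = 3.23, d_zero = 4.63,
                        near_sequence_separation = 4L) {
  stopifnot(d_contact > 0, d_zero > d_contact)
  structure(list(d_contact = d_contact, d_zero = d_zero,
                 near_sequence_separation = as.integer(near_sequence_separation)),
            class = "rrcs_params")
}

#' Atom-pair contact score
#'
#' @param d distance(s) in Angstrom, non-negative.
#' @param params an [rrcs_params()] list.
#' @return score(s) in `[0, 1]`: 1 for `d <= d_contact`, 0 for
#'   `d >= d_zero`, linear in between.
#' @export
atom_contact_score <- function(d, params = rrcs_params()) {
  if (any(d < 0)) stop("negative distance")
  s <- (params$d_zero - d) / (params$d_zero - params$d_contact)
  pmin(1, pmax(0, s))
}

# atoms_i, atoms_j: data frames with elety, x, y, z for one residue each
pair_score_atoms <- function(atoms_i, atoms_j, params, exclude_main_chain) {
  if (exclude_main_chain) {
    atoms_i <- atoms_i[!atoms_i$elety %in% MAIN_CHAIN_ATOMS, , drop = FALSE]
    atoms_j <- atoms_j[!atoms_j$elety %in% MAIN_CHAIN_ATOMS, , drop = FALSE]
  }
  if (nrow(atoms_i) == 0L || nrow(atoms_j) == 0L) return(0)
  dx <- outer(atoms_i$x, atoms_j$x, "-")
  dy <- outer(atoms_i$y, atoms_j$y, "-")
  dz <- outer(atoms_i$z, atoms_j$z, "-")
  d <- sqrt(dx * dx + dy * dy + dz * dz)
  sum(atom_contact_score(as.numeric(t(d)), params))
}

#' RRCS of one residue pair
#'
#' @param res_i,res_j data frames of heavy atoms (`chain`, `resno`,
#'   `insert`, `elety`, `x`, `y`, `z`), each belonging to one residue.
#' @param params an [rrcs_params()] list.
#' @return non-negative score: sum of [atom_contact_score()] over the
#'   eligible heavy-atom pairs. Residues on the same chain within
#'   `near_sequence_separation` contribute side-chain/side-chain and
#'   side-chain/backbone-free contacts only (main-chain atoms of both are
#'   excluded). A residue with no heavy atoms scores 0 with a warning.
#' @export
residue_pair_rrcs <- function(res_i, res_j, params = rrcs_params()) {
  if (nrow(res_i) == 0L || nrow(res_j) == 0L) {
    warning("residue with zero heavy atoms; score 0")
    return(0)
  }
  near <- res_i$chain[1L] == res_j$chain[1L] &&
    abs(res_i$resno[1L] - res_j$resno[1L]) <= params$near_sequence_separation
  pair_score_atoms(res_i, res_j, params, exclude_main_chain = near)
}

#' Residue-residue contact network of a structure
#'
#' Computes RRCS for every residue pair of the selection and keeps pairs
#' with a positive score. Waters and ligands are excluded by default; the
#' network is a single-molecule one, so inter-chain pairs are off unless
#' requested. A bounding-sphere prefilter skips residue pairs that cannot
#' contribute; the result is identical to the exhaustive all-pairs loop.
#'
#' @param structure a `mol_structure`.
#' @param selection optional character vector of residue keys
#'   (see [res_key()]) restricting the network.
#' @param params an [rrcs_params()] list.
#' @param inter_chain include residue pairs on different chains.
#' @return object of class `contact_network`: data frame with `key_i`,
#'   `key_j`, `name_i`, `name_j`, `score` (pairs ordered so that residue i
#'   precedes residue j by chain then number), with the parameter set in
#'   `attr(, "params")`.
#' @export
structure_rrcs <- function(structure, selection = NULL,
                           params = rrcs_params(), inter_chain = FALSE) {
  a <- structure$atom
  a <- a[!a$is_water & !a$is_ligand, , drop = FALSE]
  a$key <- res_key(a$chain, a$resno, a$insert)
  if (!is.null(selection)) {
    if (length(selection) == 0L) stop("empty selection")
    a <- a[a$key %in% selection, , drop = FALSE]
  }
  keys <- unique(a$key)
  if (length(keys) == 0L)
    return(empty_contact_network(params))
  info <- split_res_key(keys)
  ord <- order(info$chain, info$resno, info$insert)
  keys <- keys[ord]; info <- info[ord, , drop = FALSE]
  atoms_by_res <- split(a, factor(a$key, levels = keys))
  names_by_res <- unname(vapply(atoms_by_res, function(r) r$resid[1L], ""))
  centroids <- t(vapply(atoms_by_res, function(r)
    colMeans(as.matrix(r[, c("x", "y", "z")])), numeric(3L)))
  radii <- vapply(seq_along(keys), function(i) {
    x <- as.matrix(atoms_by_res[[i]][, c("x", "y", "z")])
    sqrt(max(rowSums(sweep(x, 2L, centroids[i, ])^2)))
  }, 0)
  n <- length(keys)
  out <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    if (!inter_chain) js <- js[info$chain[js] == info$chain[i]]
    if (!length(js)) next
    cd <- sqrt(colSums((t(centroids[js, , drop = FALSE]) - centroids[i, ])^2))
    js <- js[cd <= radii[i] + radii[js] + params$d_zero]
    if (!length(js)) next
    sc <- vapply(js, function(j)
      residue_pair_rrcs(atoms_by_res[[i]], atoms_by_res[[j]], params), 0)
    pos <- sc > 0
    if (any(pos)) {
      out[[i]] <- data.frame(key_i = keys[i], key_j = keys[js[pos]],
                             name_i = names_by_res[i],
                             name_j = names_by_res[js[pos]],
                             score = sc[pos], stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(df)) return(empty_contact_network(params))
  rownames(df) <- NULL
  structure(df, params = params, class = c("contact_network", "data.frame"))
}

empty_contact_network <- function(params) {
  structure(data.frame(key_i = character(), key_j = character(),
                       name_i = character(), name_j = character(),
                       score = numeric(), stringsAsFactors = FALSE),
            params = params, class = c("contact_network", "data.frame"))
}

#' Residue correspondence between two structures
#'
#' Residues are matched by (chain, number, insertion code); a residue
#' present in both structures but under a different name (e.g. a point
#' mutation) is reported as a mismatch, and residues present on one side
#' only (e.g. a disordered loop) are listed unmatched. Nothing is fatal.
#'
#' @param structure_a,structure_b `mol_structure` objects.
#' @return list with `matched` (character vector of residue keys present
#'   in both with equal names), `mismatched` (data frame `key`, `name_a`,
#'   `name_b`), `only_a`, `only_b` (key vectors).
#' @export
match_residues <- function(structure_a, structure_b) {
  ra <- structure_residues(structure_a)
  rb <- structure_residues(structure_b)
  common <- intersect(ra$key, rb$key)
  na <- ra$resid[match(common, ra$key)]
  nb <- rb$resid[match(common, rb$key)]
  same <- na == nb
  list(matched = common[same],
       mismatched = data.frame(key = common[!same], name_a = na[!same],
                               name_b = nb[!same], stringsAsFactors = FALSE),
       only_a = setdiff(ra$key, rb$key),
       only_b = setdiff(rb$key, ra$key))
}

#' Activation difference network (delta RRCS)
#'
#' Signed change of the contact network between two states: for every
#' residue pair seen in either network (restricted to matched residues),
#' `delta = score_active - score_inactive`, a side on which the pair is
#' absent contributing 0. Both networks must have been computed with the
#' same parameters.
#'
#' @param active,inactive `contact_network` objects.
#' @param correspondence output of [match_residues()] (active vs
#'   inactive); `NULL` keeps every pair.
#' @return object of class `delta_network`: data frame `key_i`, `key_j`,
#'   `name_i`, `name_j`, `delta`, `provenance`
#'   (`"both"`/`"active_only"`/`"inactive_only"`).
#' @export
delta_rrcs <- function(active, inactive, correspondence = NULL) {
  pa <- attr(active, "params"); pi_ <- attr(inactive, "params")
  if (!identical(unclass(pa), unclass(pi_)))
    stop("networks computed with different RRCS parameters; refusing to subtract")
  keep <- function(net) {
    if (is.null(correspondence)) return(net)
    net[net$key_i %in% correspondence$matched &
        net$key_j %in% correspondence$matched, , drop = FALSE]
  }
  act <- keep(as.data.frame(active)); ina <- keep(as.data.frame(inactive))
  pk <- function(net) paste(net$key_i, net$key_j, sep = " ~ ")
  all_pairs <- union(pk(act), pk(ina))
  ia <- match(all_pairs, pk(act)); ii <- match(all_pairs, pk(ina))
  sa <- ifelse(is.na(ia), 0, act$score[ia])
  si <- ifelse(is.na(ii), 0, ina$score[ii])
  src <- ifelse(is.na(ia), "inactive_only",
                ifelse(is.na(ii), "active_only", "both"))
  take <- function(col) ifelse(is.na(ia), ina[[col]][ii], act[[col]][ia])
  df <- data.frame(key_i = take("key_i"), key_j = take("key_j"),
                   name_i = take("name_i"), name_j = take("name_j"),
                   delta = sa - si, provenance = src,
                   stringsAsFactors = FALSE)
  ki <- split_res_key(df$key_i)
  df <- df[order(ki$chain, ki$resno, ki$insert, df$key_j), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, params = pa, class = c("delta_network", "data.frame"))
}

#' Filter a delta network by absolute change
#'
#' No significance threshold is built in; callers state the magnitude of
#' change they consider meaningful.
#'
#' @param delta a `delta_network`.
#' @param min_abs_delta minimum `|delta|` to keep (>= 0).
#' @return filtered `delta_network`.
#' @export
significant_changes <- function(delta, min_abs_delta) {
  stopifnot(min_abs_delta >= 0)
  out <- delta[abs(delta$delta) >= min_abs_delta, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, params = attr(delta, "params"),
            class = c("delta_network", "data.frame"))
}

#' Residues participating in a network
#' @param network a `contact_network` or `delta_network`.
#' @return character vector of residue keys.
#' @export
network_residues <- function(network) {
  unique(c(network$key_i, network$key_j))
}
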