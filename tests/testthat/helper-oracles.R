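# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (plain loops, no shared code with the package
# internals beyond exported constructors) so they can arbitrate.

# per-column conservation, recomputed from the raw characters
oracle_conservation <- function(msa, matrix, similarity_threshold = 1L,
                                conserved_fraction = 0.90) {
  t(vapply(seq_len(ncol(msa$ali)), function(p) {
    col <- msa$ali[, p]
    res <- col[col != "-"]
    n_gap <- sum(col == "-")
    if (length(res) == 0L || n_gap > max(table(res)))
      return(c(fraction = 0, conserved = 0))
    tab <- table(res)
    mfa <- sort(names(tab)[tab == max(tab)])[1L]
    sim <- setdiff(colnames(matrix)[matrix[mfa, ] > similarity_threshold],
                   mfa)
    fr <- sum(tab[names(tab) %in% c(mfa, sim)]) / length(res)
    c(fraction = fr, conserved = as.numeric(fr >= conserved_fraction - 1e-9))
  }, c(fraction = 0, conserved = 0)))
}

# exhaustive all-pairs double-loop RRCS
oracle_rrcs <- function(structure, params = rrcs_params()) {
  a <- structure$atom
  a <- a[!a$is_water & !a$is_ligand, , drop = FALSE]
  a$key <- res_key(a$chain, a$resno, a$insert)
  keys <- unique(a$key)
  info <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  ord <- order(info[, 1L], as.integer(info[, 2L]))
  keys <- keys[ord]
  out <- list()
  for (i in seq_along(keys)) {
    for (j in seq_along(keys)) {
      if (j <= i) next
      ri <- a[a$key == keys[i], ]
      rj <- a[a$key == keys[j], ]
      if (ri$chain[1L] != rj$chain[1L]) next
      near <- abs(ri$resno[1L] - rj$resno[1L]) <=
        params$near_sequence_separation
      if (near) {
        ri <- ri[!ri$elety %in% c("N", "CA", "C", "O"), ]
        rj <- rj[!rj$elety %in% c("N", "CA", "C", "O"), ]
      }
      scores <- numeric(0)
      for (ai in seq_len(nrow(ri))) {
        for (aj in seq_len(nrow(rj))) {
          d <- sqrt((ri$x[ai] - rj$x[aj])^2 + (ri$y[ai] - rj$y[aj])^2 +
                      (ri$z[ai] - rj$z[aj])^2)
          scores <- c(scores, min(1, max(0, (params$d_zero - d) /
                                          (params$d_zero - params$d_contact))))
        }
      }
      s <- sum(scores)
      if (s > 0)
        out[[length(out) + 1L]] <- data.frame(key_i = keys[i],
                                              key_j = keys[j], score = s)
    }
  }
  if (!length(out))
    return(data.frame(key_i = character(), key_j = character(),
                      score = numeric()))
  do.call(rbind, out)
}

# per-voxel occupancy recomputed point by point
oracle_occupancy <- function(frames, selection, grid) {
  counts <- array(0L, dim = grid$dims)
  for (f in seq_len(nrow(frames$xyz))) {
    co <- matrix(frames$xyz[f, ], ncol = 3L, byrow = TRUE)[selection, ,
                                                           drop = FALSE]
    seen <- character(0)
    for (r in seq_len(nrow(co))) {
      idx <- floor((co[r, ] - grid$origin) / grid$spacing) + 1L
      if (all(idx >= 1L) && all(idx <= grid$dims)) {
        tag <- paste(idx, collapse = ",")
        if (!tag %in% seen) {
          counts[idx[1L], idx[2L], idx[3L]] <-
            counts[idx[1L], idx[2L], idx[3L]] + 1L
          seen <- c(seen, tag)
        }
      }
    }
  }
  counts / nrow(frames$xyz)
}

# random toy structure: a couple of chains of residues with 1-5 heavy
# atoms scattered in a box, waters sprinkled in
random_toy_structure <- function(n_residues = 30L, seed = 1L,
                                 box = 18, with_waters = 0L) {
  set.seed(seed)
  atom_names <- c("N", "CA", "C", "O", "CB", "CG", "CD1")
  rows <- lapply(seq_len(n_residues), function(r) {
    ch <- if (r <= ceiling(n_residues / 2)) "A" else "B"
    nat <- sample(5L, 1L)
    nm <- sample(atom_names, nat)
    centre <- runif(3L, 0, box)
    data.frame(chain = ch, resno = r, insert = "",
               resid = sample(c("LEU", "SER", "PHE", "GLY"), 1L),
               elety = nm, elesy = substr(nm, 1L, 1L),
               x = centre[1L] + rnorm(nat, sd = 0.8),
               y = centre[2L] + rnorm(nat, sd = 0.8),
               z = centre[3L] + rnorm(nat, sd = 0.8),
               is_water = FALSE, is_ligand = FALSE,
               stringsAsFactors = FALSE)
  })
  if (with_waters > 0L) {
    rows <- c(rows, list(data.frame(
      chain = "W", resno = 1000L + seq_len(with_waters), insert = "",
      resid = "HOH", elety = "O", elesy = "O",
      x = runif(with_waters, 0, box), y = runif(with_waters, 0, box),
      z = runif(with_waters, 0, box),
      is_water = TRUE, is_ligand = FALSE, stringsAsFactors = FALSE)))
  }
  structure(list(atom = do.call(rbind, rows), source = "toy"),
            class = "mol_structure")
}

msa_from_strings <- function(seqs, ids = sprintf("seq%02d", seq_along(seqs))) {
  tf <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), tf)
  on.exit(unlink(tf))
  read_fasta_alignment(tf)
}

circ_mean_deg <- function(x) {
  atan2(mean(sin(x * pi / 180)), mean(cos(x * pi / 180))) * 180 / pi
}

circ_diff_deg <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  abs(d)
}
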