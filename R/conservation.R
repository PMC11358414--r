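# Ortholog conservation, cross-paralog conservation and entropy divergence.
#
# The per-column score follows the most-frequent-residue convention: the
# column's modal residue plus every residue similar to it (substitution
# score strictly above a threshold) counts as a match, and the fraction is
# taken over the non-gap rows only. A column whose modal symbol is the gap
# scores 0 by definition.

#' The BLOSUM80 substitution matrix
#'
#' Returns the BLOSUM80 scores shipped with Biostrings, restricted to the
#' 20 standard amino acids. Published BLOSUM80 tables exist in more than
#' one scaling; analyses that depend on a particular variant should pass
#' their own matrix (any symmetric 20x20 integer matrix with amino-acid
#' dimnames works wherever a `matrix` argument is accepted).
#'
#' @return 20x20 integer matrix with dimnames over the standard residues.
#' @export
blosum80 <- function() {
  e <- new.env()
  utils::data("BLOSUM80", package = "Biostrings", envir = e)
  m <- e$BLOSUM80[AA1, AA1]
  storage.mode(m) <- "integer"
  m
}

check_subst_matrix <- function(matrix) {
  if (!is.matrix(matrix) || is.null(dimnames(matrix)))
    stop("substitution matrix must be a named square matrix")
  if (!all(AA1 %in% rownames(matrix)) || !all(AA1 %in% colnames(matrix)))
    stop("substitution matrix must cover the 20 standard amino acids")
  m <- matrix[AA1, AA1]
  if (!isTRUE(all.equal(m, t(m)))) stop("substitution matrix must be symmetric")
  m
}

#' Conservation parameters
#'
#' @param similarity_threshold integer score a residue pair must strictly
#'   exceed to count as similar (default 1, i.e. score > 1).
#' @param conserved_fraction minimum fraction of identical-plus-similar
#'   matches for a column to be labelled conserved (default 0.90, applied
#'   as greater-or-equal).
#' @return list of class `conservation_params`.
#' @export
conservation_params <- function(similarity_threshold = 1L,
                                conserved_fraction = 0.90) {
  stopifnot(conserved_fraction >= 0, conserved_fraction <= 1)
  structure(list(similarity_threshold = as.integer(similarity_threshold),
                 conserved_fraction = conserved_fraction),
            class = "conservation_params")
}

#' Residue counts of one alignment column
#'
#' @param msa an `msa` object.
#' @param position 1-based column index.
#' @return list of class `column_profile`: `position`, `counts` (named
#'   integer vector over observed residues), `gap_count`, `depth`.
#' @export
column_profile <- function(msa, position) {
  if (position < 1L || position > ncol(msa$ali))
    stop("position ", position, " out of range 1..", ncol(msa$ali))
  col <- msa$ali[, position]
  gap_count <- sum(col == "-")
  res <- col[col != "-"]
  counts <- if (length(res)) table(res) else integer(0)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(position = position, counts = counts,
                 gap_count = gap_count, depth = length(col)),
            class = "column_profile")
}

#' Most frequent symbol of a column profile
#'
#' Ties among residues are broken alphabetically; the gap loses any tie
#' against a residue and wins only on strict majority of counts.
#'
#' @param profile a `column_profile`.
#' @return single character: a residue letter or `"-"`.
#' @export
most_frequent_symbol <- function(profile) {
  counts <- profile$counts
  if (length(counts) == 0L) return("-")
  best <- max(counts)
  if (profile$gap_count > best) return("-")
  sort(names(counts)[counts == best])[1L]
}

#' Residues similar to a given residue
#'
#' @param aa single residue letter.
#' @param matrix substitution matrix (see [blosum80()]).
#' @param threshold integer score that must be strictly exceeded.
#' @return character vector of residues `b != aa` with
#'   `score(aa, b) > threshold`.
#' @export
similar_set <- function(aa, matrix = blosum80(), threshold = 1L) {
  m <- check_subst_matrix(matrix)
  if (!aa %in% AA1) stop("unknown residue letter: ", aa)
  others <- setdiff(AA1, aa)
  others[m[aa, others] > threshold]
}

#' Conservation of one alignment column
#'
#' If the column's most frequent symbol is the gap, the column scores 0
#' and is not conserved. Otherwise the fraction is
#' `(count of modal residue + counts of residues similar to it) /
#' (non-gap depth)`, and the column is conserved when the fraction reaches
#' `params$conserved_fraction` (greater-or-equal, compared with a 1e-9
#' tolerance).
#'
#' @param profile a `column_profile`.
#' @param matrix substitution matrix.
#' @param params a [conservation_params()] list.
#' @return list of class `conservation_record`: `position`,
#'   `most_frequent`, `fraction`, `conserved`.
#' @export
position_conservation <- function(profile, matrix = blosum80(),
                                  params = conservation_params()) {
  mfa <- most_frequent_symbol(profile)
  if (mfa == "-") {
    rec <- list(position = profile$position, most_frequent = "-",
                fraction = 0, conserved = FALSE)
    return(structure(rec, class = "conservation_record"))
  }
  sim <- similar_set(mfa, matrix, params$similarity_threshold)
  counts <- profile$counts
  matches <- counts[mfa] + sum(counts[names(counts) %in% sim])
  nongap <- profile$depth - profile$gap_count
  fraction <- as.numeric(matches) / nongap
  structure(list(position = profile$position, most_frequent = mfa,
                 fraction = fraction,
                 conserved = fraction >= params$conserved_fraction - 1e-9),
            class = "conservation_record")
}

#' Per-column ortholog conservation scan
#'
#' @param msa an `msa` object.
#' @param matrix substitution matrix.
#' @param params a [conservation_params()] list.
#' @return data frame with one row per column: `position`, `most_frequent`,
#'   `fraction`, `conserved`, `gap_count`, `depth`.
#' @export
ortholog_conservation_scan <- function(msa, matrix = blosum80(),
                                       params = conservation_params()) {
  m <- check_subst_matrix(matrix)
  if (length(msa$id) == 0L) stop("empty alignment")
  recs <- lapply(seq_len(ncol(msa$ali)), function(p) {
    prof <- column_profile(msa, p)
    r <- position_conservation(prof, m, params)
    data.frame(position = p, most_frequent = r$most_frequent,
               fraction = r$fraction, conserved = r$conserved,
               gap_count = prof$gap_count, depth = prof$depth,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Remove representative sequences, then drop all gapped columns
#'
#' After removal of the named records, every column in which any remaining
#' record carries a gap is deleted, yielding a gapless alignment. The map
#' from kept columns back to original column indices is returned so that
#' positions remain traceable.
#'
#' @param msa an `msa` object.
#' @param representative_ids ids to remove (must all be present).
#' @return list with `msa` (degapped alignment) and `column_map` (integer
#'   vector: new column -> original column index).
#' @export
strip_representatives_and_gaps <- function(msa, representative_ids) {
  unknown <- setdiff(representative_ids, msa$id)
  if (length(unknown)) stop("unknown representative id(s): ",
                            paste(unknown, collapse = ", "))
  keep_rows <- !msa$id %in% representative_ids
  ali <- msa$ali[keep_rows, , drop = FALSE]
  keep_cols <- colSums(ali == "-") == 0L
  if (!any(keep_cols)) warning("all columns contain gaps; empty alignment")
  ali <- ali[, keep_cols, drop = FALSE]
  ids <- msa$id[keep_rows]
  out <- structure(list(id = ids, ali = ali,
                        reference_id = if (!is.null(msa$reference_id) &&
                                           msa$reference_id %in% ids)
                          msa$reference_id else NULL),
                   class = "msa")
  list(msa = out, column_map = which(keep_cols))
}

#' Map alignment columns to reference residue numbers
#'
#' Columns where the reference sequence has a residue map to that
#' residue's 1-based ungapped index; gap columns of the reference are
#' unmapped (`NA`).
#'
#' @param msa an `msa` object.
#' @param reference_id id of the reference record.
#' @return integer vector of length `ncol(msa$ali)`; `NA` for unmapped
#'   columns.
#' @export
map_to_reference <- function(msa, reference_id = msa$reference_id) {
  if (is.null(reference_id) || !reference_id %in% msa$id)
    stop("unknown reference id: ", reference_id)
  ref <- msa$ali[match(reference_id, msa$id), ]
  idx <- rep(NA_integer_, length(ref))
  nongap <- ref != "-"
  idx[nongap] <- seq_len(sum(nongap))
  idx
}

#' Fraction of receptors conserved at a position
#'
#' @param conserved_flags logical vector, one flag per receptor.
#' @return fraction in `[0, 1]`.
#' @export
classwide_fraction <- function(conserved_flags) {
  if (length(conserved_flags) == 0L) stop("empty receptor panel")
  mean(as.logical(conserved_flags))
}

#' Shannon-entropy divergence of the per-receptor modal residues
#'
#' Entropy in bits of the empirical distribution of the supplied residues:
#' `H = -sum_r p_r log2 p_r`. With 11 receptors, an all-identical position
#' gives 0 bits and a one-receptor-different position gives 0.44 bits.
#'
#' @param residues character vector of modal residues (no gaps).
#' @return entropy in bits.
#' @export
divergence_entropy <- function(residues) {
  if (length(residues) == 0L) stop("empty residue vector")
  if (any(residues == "-")) stop("gap symbols not allowed in entropy input")
  p <- as.numeric(table(residues)) / length(residues)
  -sum(p * log2(p))
}

#' Assemble a cross-paralog conservation panel
#'
#' @param most_frequent character matrix, positions x receptors: the modal
#'   residue of each receptor's ortholog alignment at each shared
#'   position (`"-"` where the receptor has a gap).
#' @param conserved logical matrix of the same shape: whether the position
#'   is conserved within that receptor's orthologs.
#' @param receptor_ids receptor names (default: matrix column names).
#' @param labels optional per-position generic labels (e.g. `"6.32"`),
#'   used to key panel positions to structure residues.
#' @return object of class `paralog_panel`: list with `receptor_ids`,
#'   `most_frequent`, `conserved`, `classwide_fraction` (per position),
#'   `entropy_bits` (per position; `NA` where any receptor shows a gap)
#'   and `labels`.
#' @export
paralog_panel <- function(most_frequent, conserved,
                          receptor_ids = colnames(most_frequent),
                          labels = NULL) {
  stopifnot(is.matrix(most_frequent), is.matrix(conserved),
            all(dim(most_frequent) == dim(conserved)))
  if (is.null(receptor_ids))
    receptor_ids <- paste0("receptor_", seq_len(ncol(most_frequent)))
  if (!is.null(labels)) stopifnot(length(labels) == nrow(most_frequent))
  cw <- apply(conserved, 1L, classwide_fraction)
  ent <- apply(most_frequent, 1L, function(r) {
    if (any(r == "-")) NA_real_ else divergence_entropy(r)
  })
  structure(list(receptor_ids = receptor_ids, most_frequent = most_frequent,
                 conserved = conserved, classwide_fraction = cw,
                 entropy_bits = ent, labels = labels),
            class = "paralog_panel")
}

#' @export
print.paralog_panel <- function(x, ...) {
  cat("paralog_panel:", nrow(x$most_frequent), "positions x",
      length(x$receptor_ids), "receptors\n")
  invisible(x)
}

#' Position selection rules over a paralog panel
#'
#' Three modes cover the selections used for the water-network and
#' sterol-site analyses: `entropy_zero` keeps positions where every
#' receptor shows the same modal residue; `entropy_le` keeps positions
#' with entropy up to a cutoff (0.44 bits admits one deviating receptor
#' out of 11); `similar_only` keeps positions where every pair of distinct
#' modal residues scores strictly above a similarity threshold (default 2).
#'
#' @param mode one of `"entropy_zero"`, `"entropy_le"`, `"similar_only"`.
#' @param entropy_cutoff bits, for `entropy_le` (default 0.44).
#' @param similarity_threshold integer score, for `similar_only`
#'   (default 2).
#' @return list of class `selection_rule`.
#' @export
selection_rule <- function(mode = c("entropy_zero", "entropy_le",
                                    "similar_only"),
                           entropy_cutoff = 0.44,
                           similarity_threshold = 2L) {
  mode <- match.arg(mode)
  stopifnot(entropy_cutoff >= 0)
  structure(list(mode = mode, entropy_cutoff = entropy_cutoff,
                 similarity_threshold = as.integer(similarity_threshold)),
            class = "selection_rule")
}

#' Select panel positions by a divergence rule
#'
#' @param panel a `paralog_panel`.
#' @param rule a [selection_rule()].
#' @param matrix substitution matrix (needed for `similar_only`).
#' @return integer vector of selected positions (sorted). Positions with
#'   undefined entropy (a gap in some receptor) are never selected.
#' @export
select_positions <- function(panel, rule, matrix = blosum80()) {
  stopifnot(inherits(panel, "paralog_panel"), inherits(rule, "selection_rule"))
  ent <- panel$entropy_bits
  defined <- !is.na(ent)
  sel <- switch(rule$mode,
    entropy_zero = defined & ent <= 1e-9,
    entropy_le   = defined & ent <= rule$entropy_cutoff + 1e-9,
    similar_only = {
      m <- check_subst_matrix(matrix)
      thr <- rule$similarity_threshold
      defined & vapply(seq_len(nrow(panel$most_frequent)), function(i) {
        r <- unique(panel$most_frequent[i, ])
        if (length(r) < 2L) return(TRUE)
        prs <- utils::combn(r, 2L)
        all(m[cbind(prs[1L, ], prs[2L, ])] > thr)
      }, TRUE)
    })
  which(sel)
}

#' Panel summary table
#'
#' @param panel a `paralog_panel`.
#' @return data frame: `position`, `label`, `classwide_fraction`,
#'   `entropy_bits`, `consensus` (modal residue across receptors).
#' @export
panel_table <- function(panel) {
  consensus <- apply(panel$most_frequent, 1L, function(r) {
    r <- r[r != "-"]
    if (!length(r)) return("-")
    tab <- table(r)
    sort(names(tab)[tab == max(tab)])[1L]
  })
  data.frame(position = seq_len(nrow(panel$most_frequent)),
             label = if (is.null(panel$labels)) NA_character_ else panel$labels,
             classwide_fraction = panel$classwide_fraction,
             entropy_bits = panel$entropy_bits,
             consensus = consensus, stringsAsFactors = FALSE)
}
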