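#' @keywords internal
"_PACKAGE"

# Shared conventions: coordinates in Angstrom, residue numbering as in the
# source file (1-based), alignment columns 1-based, gap symbol "-".

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

WATER_NAMES <- c("HOH", "WAT", "TIP3", "SOL", "H2O")

#' Residue keys
#'
#' A residue key is the string `chain|resno|insert` identifying a residue
#' uniquely within a structure; the insertion-code field is empty for the
#' common case.
#'
#' @param chain,resno,insert chain id, residue number, insertion code.
#' @return character vector of keys.
#' @export
res_key <- function(chain, resno, insert = "") {
  insert <- ifelse(is.na(insert) | insert == "?", "", insert)
  paste(chain, resno, insert, sep = "|")
}

split_res_key <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(
    chain = vapply(parts, `[`, "", 1L),
    resno = as.integer(vapply(parts, `[`, "", 2L)),
    insert = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "", ""),
    stringsAsFactors = FALSE
  )
}

#' Read a gapped FASTA multiple sequence alignment
#'
#' Sequences are upper-cased and `.` gap characters are normalised to `-`.
#' All records must have equal length (it is an alignment, not a sequence
#' set); a ragged record is reported by id.
#'
#' @param path path to a FASTA file.
#' @param reference_id optional id of the reference sequence (must be
#'   present among the records).
#' @return an object of class `msa`: a list with `id` (character vector),
#'   `ali` (character matrix, one row per record, one column per alignment
#'   position) and `reference_id`.
#' @export
read_fasta_alignment <- function(path, reference_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("not FASTA: no '>' header found in ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, "", 1L)
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
  }, "")
  seqs <- toupper(gsub(".", "-", gsub("[[:space:]]", "", seqs), fixed = TRUE))
  new_msa(ids, seqs, reference_id = reference_id)
}

new_msa <- function(ids, seqs, reference_id = NULL) {
  if (anyDuplicated(ids)) stop("duplicate sequence ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  widths <- nchar(seqs)
  if (length(widths) == 0L || widths[1L] < 1L) stop("empty alignment")
  if (length(unique(widths)) != 1L) {
    bad <- ids[widths != widths[1L]][1L]
    stop("ragged alignment: record '", bad, "' has length ",
         widths[ids == bad][1L], ", expected ", widths[1L])
  }
  if (!is.null(reference_id) && !reference_id %in% ids)
    stop("reference id '", reference_id, "' not among records")
  ali <- do.call(rbind, strsplit(seqs, ""))
  rownames(ali) <- ids
  structure(list(id = ids, ali = ali, reference_id = reference_id),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", length(x$id), "sequences x", ncol(x$ali), "columns\n")
  invisible(x)
}

#' Number of alignment columns
#' @param msa an `msa` object.
#' @return integer alignment width.
#' @export
alignment_width <- function(msa) ncol(msa$ali)

#' Read a coordinate file into a heavy-atom structure table
#'
#' Both PDB and mmCIF dialects are supported (parsed with bio3d).
#' Hydrogens (and deuteriums) are dropped: all downstream scoring follows
#' the heavy-atom convention. Alternate locations are resolved to the
#' highest-occupancy conformer, ties broken by alphabetical altloc id.
#' Waters and hetero-compound ligands are flagged rather than removed.
#'
#' @param path coordinate file.
#' @param dialect `"pdb"`, `"mmcif"` or `"auto"` (by file extension).
#' @param model model number to extract from a multi-model file (default 1).
#' @return an object of class `mol_structure`: a list with an `atom`
#'   data frame (`chain`, `resno`, `insert`, `resid`, `elety`, `elesy`,
#'   `x`, `y`, `z`, `is_water`, `is_ligand`) and `source` (the path).
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif"),
                           model = 1L) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (dialect == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE,
                                          verbose = FALSE)),
    error = function(e) stop("cannot parse ", dialect, " file ", path, ": ",
                             conditionMessage(e))
  )
  atom <- pdb$atom
  if (is.null(atom) || nrow(atom) == 0L) stop("empty structure: ", path)
  if (model > 1L) {
    xyz <- pdb$xyz
    if (is.matrix(xyz) && nrow(xyz) >= model) {
      atom[, c("x", "y", "z")] <- matrix(xyz[model, ], ncol = 3L, byrow = TRUE)
    } else stop("model ", model, " not present in ", path)
  }
  structure_from_bio3d(atom, source = path)
}

structure_from_bio3d <- function(atom, source = NA_character_) {
  insert <- atom$insert
  insert[is.na(insert) | insert == "?"] <- ""
  alt <- atom$alt
  alt[is.na(alt) | alt %in% c(".", "?")] <- ""
  occ <- atom$o
  occ[is.na(occ)] <- 1
  elesy <- atom$elesy
  miss <- is.na(elesy) | elesy == ""
  # infer element from the atom-name convention when the column is blank
  elesy[miss] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", atom$elety[miss])
  elesy <- toupper(trimws(elesy))
  df <- data.frame(
    chain = as.character(atom$chain), resno = as.integer(atom$resno),
    insert = insert, resid = toupper(as.character(atom$resid)),
    elety = as.character(atom$elety), elesy = elesy,
    x = atom$x, y = atom$y, z = atom$z,
    alt = alt, occ = occ, hetatm = atom$type == "HETATM",
    stringsAsFactors = FALSE
  )
  df <- df[!df$elesy %in% c("H", "D"), , drop = FALSE]
  if (nrow(df) == 0L) stop("empty structure (no heavy atoms): ", source)
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates in ", source)
  # altloc resolution: per (residue, atom name) keep highest occupancy,
  # ties broken by alphabetical altloc id
  akey <- paste(res_key(df$chain, df$resno, df$insert), df$elety)
  if (anyDuplicated(akey)) {
    ord <- order(akey, -df$occ, df$alt)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(akey[ord]), , drop = FALSE]
    df <- df[order(as.integer(rownames(df))), , drop = FALSE]
  }
  df$is_water <- df$resid %in% WATER_NAMES
  df$is_ligand <- df$hetatm & !df$is_water
  df$alt <- df$occ <- df$hetatm <- NULL
  rownames(df) <- NULL
  structure(list(atom = df, source = source), class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  a <- x$atom
  cat("mol_structure:", nrow(a), "heavy atoms,",
      length(unique(res_key(a$chain, a$resno, a$insert))), "residues (",
      sum(a$is_water), "water atoms,", sum(a$is_ligand), "ligand atoms )\n")
  invisible(x)
}

#' Residue table of a structure
#'
#' @param structure a `mol_structure`.
#' @param include_water,include_ligand keep water / ligand residues.
#' @return data frame with one row per residue: `key`, `chain`, `resno`,
#'   `insert`, `resid`, `is_water`, `is_ligand`, in file order.
#' @export
structure_residues <- function(structure, include_water = FALSE,
                               include_ligand = FALSE) {
  a <- structure$atom
  keep <- (!a$is_water | include_water) & (!a$is_ligand | include_ligand)
  a <- a[keep, , drop = FALSE]
  key <- res_key(a$chain, a$resno, a$insert)
  first <- !duplicated(key)
  data.frame(key = key[first], chain = a$chain[first], resno = a$resno[first],
             insert = a$insert[first], resid = a$resid[first],
             is_water = a$is_water[first], is_ligand = a$is_ligand[first],
             stringsAsFactors = FALSE)
}

#' Read an ordered series of coordinate frames
#'
#' Accepts a multi-model PDB file (MODEL/ENDMDL records) or a single-model
#' file, which yields a valid one-frame series. All frames must share one
#' atom topology; a frame with a deviating atom count is reported by its
#' 1-based frame index.
#'
#' @param path multi-model PDB file.
#' @param frame_interval frame spacing in picoseconds (metadata only).
#' @return an object of class `frame_series`: list with `atom` (topology
#'   data frame as in [read_structure()], coordinates of frame 1), `xyz`
#'   (numeric matrix, one row per frame, columns x1,y1,z1,x2,...) and
#'   `frame_interval` (ps).
#' @export
read_frames <- function(path, frame_interval = 50) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) {
    s <- read_structure(path, dialect = "pdb")
    return(frame_series_from_structures(list(s), frame_interval))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts)) stop("unbalanced MODEL/ENDMDL in ", path)
  frames <- lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    block <- block[grepl("^(ATOM  |HETATM)", block)]
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf), add = TRUE)
    writeLines(c(block, "END"), tf)
    read_structure(tf, dialect = "pdb")
  })
  frame_series_from_structures(frames, frame_interval)
}

frame_series_from_structures <- function(frames, frame_interval = 50) {
  stopifnot(length(frames) >= 1L)
  ref <- frames[[1L]]$atom
  sig <- function(a) paste(res_key(a$chain, a$resno, a$insert), a$elety)
  ref_sig <- sig(ref)
  xyz <- matrix(NA_real_, nrow = length(frames), ncol = 3L * nrow(ref))
  for (i in seq_along(frames)) {
    a <- frames[[i]]$atom
    if (nrow(a) != nrow(ref) || !identical(sig(a), ref_sig))
      stop("topology mismatch at frame ", i, ": ", nrow(a),
           " atoms, expected ", nrow(ref))
    xyz[i, ] <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  }
  structure(list(atom = ref, xyz = xyz, frame_interval = frame_interval),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat("frame_series:", nrow(x$xyz), "frames x", nrow(x$atom), "atoms (",
      x$frame_interval, "ps / frame )\n")
  invisible(x)
}

#' Number of frames in a series
#' @param frames a `frame_series`.
#' @return integer frame count.
#' @export
n_frames <- function(frames) nrow(frames$xyz)

frame_coords <- function(frames, i) {
  matrix(frames$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Write a frame series as a multi-model PDB file
#'
#' @param frames a `frame_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  a <- frames$atom
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(frames))) {
    co <- frame_coords(frames, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(pdb_atom_lines(a, co), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

pdb_atom_lines <- function(a, co = as.matrix(a[, c("x", "y", "z")])) {
  rec <- ifelse(a$is_water | a$is_ligand, "HETATM", "ATOM  ")
  name <- ifelse(nchar(a$elety) <= 3L, sprintf(" %-3s", a$elety),
                 sprintf("%-4s", a$elety))
  sprintf("%s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, seq_len(nrow(a)) %% 100000L, name, a$resid,
          substr(a$chain, 1L, 1L), a$resno,
          ifelse(a$insert == "", " ", a$insert),
          co[, 1L], co[, 2L], co[, 3L], 1, 0, a$elesy)
}

#' Write a structure as a PDB file
#'
#' @param structure a `mol_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  writeLines(c(pdb_atom_lines(structure$atom), "END"), path)
  invisible(path)
}

#' Read a residue-to-generic-number table
#'
#' The table assigns transmembrane-relative generic labels of the form
#' `helix.position` (Ballesteros-Weinstein style, e.g. `6.32`) to residues.
#' The mapping must be a bijection on the mapped residues.
#'
#' @param path TSV file with columns `chain`, `residue_number`,
#'   `generic_label`.
#' @return an object of class `generic_map`: data frame with `chain`,
#'   `resno`, `label`.
#' @export
read_generic_numbers <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("chain", "residue_number", "generic_label")
  if (!all(need %in% names(df)))
    stop("generic-number table must have columns: ", paste(need, collapse = ", "))
  new_generic_map(df$chain, as.integer(df$residue_number), df$generic_label)
}

new_generic_map <- function(chain, resno, label) {
  bad <- !grepl("^[0-9]+\\.[0-9]+$", label)
  if (any(bad)) stop("malformed generic label(s): ",
                     paste(unique(label[bad]), collapse = ", "))
  rk <- res_key(chain, resno)
  if (anyDuplicated(rk)) stop("duplicate residue in generic map: ",
                              rk[duplicated(rk)][1L])
  if (anyDuplicated(label)) stop("duplicate generic label: ",
                                 label[duplicated(label)][1L])
  structure(data.frame(chain = chain, resno = resno, label = label,
                       stringsAsFactors = FALSE),
            class = c("generic_map", "data.frame"))
}

#' Look up the generic label of a residue
#' @param map a `generic_map`.
#' @param chain,resno residue identity.
#' @return label string, or `NA` if unmapped.
#' @export
generic_label <- function(map, chain, resno) {
  i <- match(res_key(chain, resno), res_key(map$chain, map$resno))
  map$label[i]
}

#' Inverse lookup: residue carrying a generic label
#' @param map a `generic_map`.
#' @param label generic label string (e.g. `"7.55"`).
#' @return one-row data frame (`chain`, `resno`), or zero rows if absent.
#' @export
generic_residue <- function(map, label) {
  map[match(label, map$label), c("chain", "resno"), drop = FALSE]
}

#' Write a results table as TSV
#'
#' Plain UTF-8 TSV with a header row, `.` as the decimal separator and the
#' column order of the input; numeric values survive a read-back to at
#' least 6 significant digits.
#'
#' @param records a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  ok <- tryCatch({
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a TSV written by [write_table()]
#' @param path TSV file.
#' @return data frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
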