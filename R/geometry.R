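# Structure and frame-series geometry: helix axes and kink angles,
# two-state TM opening, side-chain chi1/chi2 dihedrals, distance series
# with two-state classification, and water-occupancy voxel grids.

#' Principal axis of a helix segment
#'
#' Fits the dominant direction of the Calpha trace. For segments of six or
#' more residues the trace is first smoothed with a 4-residue running mean
#' (which nearly cancels the helical wobble of the Calpha spiral), then
#' the principal axis of the centred points is taken; short segments use
#' the raw points. The axis is oriented N-terminus to C-terminus.
#'
#' @param ca_coords numeric matrix (n x 3) of Calpha coordinates in chain
#'   order, n >= 4.
#' @return list with `axis` (unit vector) and `centroid`.
#' @export
helix_axis <- function(ca_coords) {
  ca_coords <- as.matrix(ca_coords)
  n <- nrow(ca_coords)
  if (n < 4L) stop("need at least 4 Calpha positions, got ", n)
  pts <- if (n >= 6L) {
    t(vapply(seq_len(n - 3L), function(i)
      colMeans(ca_coords[i:(i + 3L), , drop = FALSE]), numeric(3L)))
  } else ca_coords
  centroid <- colMeans(ca_coords)
  centred <- sweep(pts, 2L, colMeans(pts))
  if (max(abs(centred)) < 1e-12) stop("degenerate (coincident) points")
  axis <- svd(centred, nu = 0L, nv = 3L)$v[, 1L]
  if (sum(axis * (ca_coords[n, ] - ca_coords[1L, ])) < 0) axis <- -axis
  list(axis = axis / sqrt(sum(axis^2)), centroid = centroid)
}

angle_between <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Kink angle of a helix at a pivot residue
#'
#' Angle between the axes of the sub-helices preceding and following the
#' pivot; 0 for a straight helix, up to 180 degrees.
#'
#' @param ca_coords numeric matrix (n x 3) of Calpha coordinates.
#' @param pivot 1-based index of the pivot residue; at least 4 Calpha are
#'   required on each side (the pivot itself belongs to neither flank).
#' @return kink angle in degrees, in `[0, 180]`.
#' @export
kink_angle <- function(ca_coords, pivot) {
  ca_coords <- as.matrix(ca_coords)
  n <- nrow(ca_coords)
  if (pivot - 1L < 4L || n - pivot < 4L)
    stop("need >= 4 Calpha on each side of the pivot (pivot ", pivot,
         " of ", n, ")")
  pre <- helix_axis(ca_coords[seq_len(pivot - 1L), , drop = FALSE])
  post <- helix_axis(ca_coords[(pivot + 1L):n, , drop = FALSE])
  angle_between(pre$axis, post$axis)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' @param mobile,reference numeric matrices (n x 3) of matched points,
#'   n >= 3.
#' @return list with `rotation` (3x3), `translation` (length 3; the fitted
#'   transform is `x %*% t(rotation) + translation`), `rmsd` and
#'   `transform(points)` applying the fit.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) < 3L || nrow(mobile) != nrow(reference))
    stop("need >= 3 matched atom pairs")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  h <- crossprod(sweep(mobile, 2L, cm), sweep(reference, 2L, cr))
  s <- svd(h)
  d <- sign(det(tcrossprod(s$v, s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cr - as.numeric(rot %*% cm)
  transform <- function(points)
    sweep(as.matrix(points) %*% t(rot), 2L, trans, "+")
  fitted <- transform(mobile)
  list(rotation = rot, translation = trans,
       rmsd = sqrt(mean(rowSums((fitted - reference)^2))),
       transform = transform)
}

residue_ca_coords <- function(structure, chain, resnos) {
  a <- structure$atom
  sel <- a$elety == "CA" & a$chain == chain & a$resno %in% resnos &
    !a$is_water & !a$is_ligand
  a <- a[sel, , drop = FALSE]
  a <- a[order(a$resno), , drop = FALSE]
  missing <- setdiff(resnos, a$resno)
  if (length(missing))
    stop("missing Calpha for residue(s) ", paste(missing, collapse = ", "),
         " in chain ", chain)
  as.matrix(a[, c("x", "y", "z")])
}

#' Opening of a transmembrane helix between two states
#'
#' Measures how far the intracellular half of a helix (typically TM6)
#' swings out upon activation. The active structure is first superposed
#' onto the inactive one using an anchor selection (by convention the
#' Calpha of helices that do not move, e.g. TM1-TM4); the opening angle is
#' the angle between the axes of the intracellular sub-segment (pivot to
#' cytoplasmic end) in the two states, and the displacement is the
#' distance between the two positions of a tip atom (by convention the
#' Calpha of the 6.32-equivalent residue at the helix end).
#'
#' @param inactive,active `mol_structure` objects.
#' @param chain chain id holding the helix.
#' @param tm_range integer vector of residue numbers of the helix, ordered
#'   extracellular to intracellular.
#' @param pivot residue number at which the helix pivots.
#' @param anchor_resnos residue numbers (same chain) used for
#'   superposition.
#' @param tip_resno residue whose Calpha displacement is reported
#'   (default: last residue of `tm_range`).
#' @return list with `angle_deg` and `displacement` (Angstrom).
#' @export
tm_opening <- function(inactive, active, chain, tm_range, pivot,
                       anchor_resnos, tip_resno = tm_range[length(tm_range)]) {
  anch_i <- residue_ca_coords(inactive, chain, anchor_resnos)
  anch_a <- residue_ca_coords(active, chain, anchor_resnos)
  fit <- superpose(anch_a, anch_i)
  sub <- tm_range[tm_range >= min(pivot, tip_resno) &
                    tm_range <= max(pivot, tip_resno)]
  if (length(sub) < 5L) stop("fewer than 4 residues between pivot and tip")
  ca_i <- residue_ca_coords(inactive, chain, sub)
  ca_a <- fit$transform(residue_ca_coords(active, chain, sub))
  ax_i <- helix_axis(ca_i)$axis
  ax_a <- helix_axis(ca_a)$axis
  tip_i <- residue_ca_coords(inactive, chain, tip_resno)
  tip_a <- fit$transform(residue_ca_coords(active, chain, tip_resno))
  list(angle_deg = angle_between(ax_i, ax_a),
       displacement = sqrt(sum((tip_a - tip_i)^2)))
}

#' Signed dihedral angle of four points
#'
#' IUPAC convention: right-handed, in `(-180, 180]`, 0 for cis and 180
#' for anti arrangements.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates.
#' @return angle in degrees.
#' @export
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb2 <- sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2) / nb2, sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# fourth atom of chi1 / chi2 per residue type (standard side-chain
# torsion definitions)
CHI_ATOMS <- list(
  ARG = c("CG", "CD"), ASN = c("CG", "OD1"), ASP = c("CG", "OD1"),
  CYS = c("SG", NA), GLN = c("CG", "CD"), GLU = c("CG", "CD"),
  HIS = c("CG", "ND1"), ILE = c("CG1", "CD1"), LEU = c("CG", "CD1"),
  LYS = c("CG", "CD"), MET = c("CG", "SD"), PHE = c("CG", "CD1"),
  PRO = c("CG", "CD"), SER = c("OG", NA), THR = c("OG1", NA),
  TRP = c("CG", "CD1"), TYR = c("CG", "CD1"), VAL = c("CG1", NA)
)

#' Side-chain chi1 and chi2 dihedrals of a residue
#'
#' chi1 is N-CA-CB-G and chi2 is CA-CB-G-D with the G/D atoms taken from
#' the standard per-residue torsion definitions (e.g. CG and CD1 for Trp).
#' A missing atom leaves the corresponding angle `NA` rather than failing.
#'
#' @param residue_atoms data frame of one residue's heavy atoms (`resid`,
#'   `elety`, `x`, `y`, `z`).
#' @return named numeric vector `c(chi1 = , chi2 = )` in `(-180, 180]`
#'   degrees, `NA` where undefined (e.g. Gly/Ala).
#' @export
chi_dihedrals <- function(residue_atoms) {
  resname <- residue_atoms$resid[1L]
  def <- CHI_ATOMS[[resname]]
  out <- c(chi1 = NA_real_, chi2 = NA_real_)
  if (is.null(def)) return(out)
  get <- function(name) {
    i <- match(name, residue_atoms$elety)
    if (is.na(i)) return(NULL)
    as.numeric(residue_atoms[i, c("x", "y", "z")])
  }
  n <- get("N"); ca <- get("CA"); cb <- get("CB"); g <- get(def[1L])
  if (!is.null(n) && !is.null(ca) && !is.null(cb) && !is.null(g))
    out["chi1"] <- dihedral4(n, ca, cb, g)
  if (!is.na(def[2L])) {
    d <- get(def[2L])
    if (!is.null(ca) && !is.null(cb) && !is.null(g) && !is.null(d))
      out["chi2"] <- dihedral4(ca, cb, g, d)
  }
  out
}

frame_residue_atoms <- function(frames, chain, resno, frame) {
  idx <- which(frames$atom$chain == chain & frames$atom$resno == resno)
  a <- frames$atom[idx, , drop = FALSE]
  co <- frame_coords(frames, frame)[idx, , drop = FALSE]
  a$x <- co[, 1L]; a$y <- co[, 2L]; a$z <- co[, 3L]
  a
}

#' chi1/chi2 series over a frame series
#'
#' @param frames a `frame_series`.
#' @param chain,resno residue to follow.
#' @return data frame of class `dihedral_series`: `frame`, `time_ps`,
#'   `chi1`, `chi2` (degrees; `NA` where undefined).
#' @export
dihedral_series <- function(frames, chain, resno) {
  if (!any(frames$atom$chain == chain & frames$atom$resno == resno))
    stop("residue ", chain, " ", resno, " absent from topology")
  nf <- n_frames(frames)
  vals <- t(vapply(seq_len(nf), function(f)
    chi_dihedrals(frame_residue_atoms(frames, chain, resno, f)),
    c(chi1 = 0, chi2 = 0)))
  out <- data.frame(frame = seq_len(nf),
                    time_ps = (seq_len(nf) - 1L) * frames$frame_interval,
                    chi1 = vals[, "chi1"], chi2 = vals[, "chi2"])
  class(out) <- c("dihedral_series", "data.frame")
  out
}

#' Inter-atomic distance series over a frame series
#'
#' @param frames a `frame_series`.
#' @param atom_a,atom_b atom specs: lists `list(chain=, resno=, elety=)`.
#' @return data frame of class `distance_series`: `frame`, `time_ps`,
#'   `distance` (Angstrom).
#' @export
distance_series <- function(frames, atom_a, atom_b) {
  locate <- function(spec) {
    i <- which(frames$atom$chain == spec$chain &
                 frames$atom$resno == spec$resno &
                 frames$atom$elety == spec$elety)
    if (length(i) != 1L)
      stop("atom ", spec$chain, " ", spec$resno, " ", spec$elety,
           if (length(i)) " ambiguous" else " not found", " in topology")
    i
  }
  ia <- locate(atom_a); ib <- locate(atom_b)
  nf <- n_frames(frames)
  d <- vapply(seq_len(nf), function(f) {
    co <- frame_coords(frames, f)
    sqrt(sum((co[ia, ] - co[ib, ])^2))
  }, 0)
  out <- data.frame(frame = seq_len(nf),
                    time_ps = (seq_len(nf) - 1L) * frames$frame_interval,
                    distance = d)
  class(out) <- c("distance_series", "data.frame")
  out
}

#' Two-state classification of a scalar series
#'
#' Used to separate the two bottleneck sub-conformations seen in distance
#' series. `threshold` mode assigns state 1 below a fixed cutoff;
#' `kmeans2` mode runs one-dimensional 2-means with deterministic
#' initialisation at the 10th and 90th percentiles, then labels the
#' lower-mean cluster state 1.
#'
#' @param values numeric vector (>= 2 values).
#' @param method `"threshold"` or `"kmeans2"`.
#' @param cutoff threshold for `threshold` mode.
#' @return list of class `state_series`: `states` (integer vector of 1/2),
#'   `method`, `cutoff` (threshold used or fitted cluster boundary),
#'   `means` (per-state means).
#' @export
classify_two_state <- function(values, method = c("threshold", "kmeans2"),
                               cutoff = NULL) {
  method <- match.arg(method)
  if (length(values) < 2L) stop("need at least 2 frames")
  if (method == "threshold") {
    if (is.null(cutoff)) stop("threshold mode requires a cutoff")
    states <- ifelse(values < cutoff, 1L, 2L)
  } else {
    q <- stats::quantile(values, c(0.1, 0.9), names = FALSE)
    if (diff(q) < 1e-12)
      stop("degenerate clustering: series is (nearly) constant")
    km <- stats::kmeans(values, centers = matrix(q, ncol = 1L))
    lower <- which.min(km$centers)
    states <- ifelse(km$cluster == lower, 1L, 2L)
    cutoff <- mean(km$centers)
  }
  means <- c(mean(values[states == 1L]), mean(values[states == 2L]))
  structure(list(states = states, method = method, cutoff = cutoff,
                 means = means), class = "state_series")
}

#' Occupancy grid of selected atoms over a frame series
#'
#' Divides a region into cubic voxels and records, per voxel, the fraction
#' of frames in which at least one selected atom centre falls inside it.
#' Voxels are half-open intervals `[low, high)` per axis and the grid
#' origin is snapped down to a multiple of the spacing, so grids computed
#' over different regions align.
#'
#' @param frames a `frame_series`.
#' @param selection integer vector of atom indices into `frames$atom`
#'   (e.g. water oxygens: `which(frames$atom$resid == "HOH")`).
#' @param spacing voxel edge length in Angstrom (default 1.0).
#' @param region optional list `list(min = c(x,y,z), max = c(x,y,z))`;
#'   default is the bounding box of the selection over all frames.
#' @return object of class `occupancy_grid`: list with `origin`,
#'   `spacing`, `dims`, `fraction` (3-d array in `[0, 1]`), `n_frames`.
#' @export
occupancy_grid <- function(frames, selection, spacing = 1.0, region = NULL) {
  nf <- n_frames(frames)
  if (nf < 1L) stop("zero frames")
  stopifnot(length(selection) >= 1L, spacing > 0)
  coords <- lapply(seq_len(nf), function(f)
    frame_coords(frames, f)[selection, , drop = FALSE])
  if (is.null(region)) {
    allc <- do.call(rbind, coords)
    region <- list(min = apply(allc, 2L, min), max = apply(allc, 2L, max))
  }
  origin <- floor(region$min / spacing) * spacing
  dims <- pmax(1L, as.integer(floor((region$max - origin) / spacing)) + 1L)
  counts <- array(0L, dim = dims)
  for (f in seq_len(nf)) {
    idx <- floor(sweep(coords[[f]], 2L, origin) / spacing) + 1L
    ok <- idx[, 1L] >= 1L & idx[, 1L] <= dims[1L] &
      idx[, 2L] >= 1L & idx[, 2L] <= dims[2L] &
      idx[, 3L] >= 1L & idx[, 3L] <= dims[3L]
    idx <- unique(idx[ok, , drop = FALSE])
    if (nrow(idx)) counts[idx] <- counts[idx] + 1L
  }
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 fraction = counts / nf, n_frames = nf),
            class = "occupancy_grid")
}

#' Threshold mask of an occupancy grid
#'
#' @param grid an `occupancy_grid`.
#' @param threshold occupancy fraction in `[0, 1]`; voxels with fraction
#'   greater-or-equal are retained (so a 20 percent threshold keeps a
#'   voxel visited in exactly 2 of 10 frames).
#' @return list with `voxels` (data frame `ix`, `iy`, `iz`, `x`, `y`, `z`
#'   voxel-centre coordinates, `fraction`) and `volume` (Angstrom^3).
#' @export
mask_grid <- function(grid, threshold = 0.2) {
  stopifnot(threshold >= 0, threshold <= 1)
  keep <- which(grid$fraction >= threshold - 1e-12, arr.ind = TRUE)
  df <- data.frame(ix = keep[, 1L], iy = keep[, 2L], iz = keep[, 3L])
  df$x <- grid$origin[1L] + (df$ix - 0.5) * grid$spacing
  df$y <- grid$origin[2L] + (df$iy - 0.5) * grid$spacing
  df$z <- grid$origin[3L] + (df$iz - 0.5) * grid$spacing
  df$fraction <- grid$fraction[keep]
  list(voxels = df, volume = nrow(df) * grid$spacing^3)
}

#' Write an occupancy grid as OpenDX-style volumetric text
#'
#' @param grid an `occupancy_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid_dx <- function(grid, path) {
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.4f 0 0", grid$spacing),
    sprintf("delta 0 %.4f 0", grid$spacing),
    sprintf("delta 0 0 %.4f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # dx convention: z varies fastest
  vals <- as.numeric(grid$fraction[cbind(
    rep(seq_len(d[1]), each = d[2] * d[3]),
    rep(rep(seq_len(d[2]), each = d[3]), times = d[1]),
    rep(seq_len(d[3]), times = d[1] * d[2]))])
  lines <- tapply(vals, (seq_along(vals) - 1L) %/% 3L,
                  function(v) paste(sprintf("%.6f", v), collapse = " "))
  writeLines(unname(lines), con)
  invisible(path)
}
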