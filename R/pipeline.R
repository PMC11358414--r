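# End-to-end analyses: the water-network pipeline (conservation panel +
# contact-change network + water adjacency) and the sterol-site pipeline
# (conserved surface patches + ligand-contact overlap), with provenance.
#
# Configuration is a plain named list; run_config() validates keys and
# fills defaults. Both runs are deterministic given config inputs. The
# package functions themselves are the scripting interface; the analyses
# below are the two canonical compositions.

#' Build and validate a run configuration
#'
#' Unknown keys are rejected so silently ignored typos cannot change a
#' run. Structures, panels and maps may be given as file paths or as
#' in-memory objects.
#'
#' @param ... configuration entries. Recognised keys:
#'   `inactive_structure`, `active_structure`, `structure` (path or
#'   `mol_structure`), `panel` (`paralog_panel`), `generic_map`
#'   (path or `generic_map`), `rule` (a [selection_rule()]),
#'   `matrix` (substitution matrix), `rrcs` (an [rrcs_params()]),
#'   `patch` (a [patch_params()]), `min_abs_delta` (numeric, required by
#'   the water-network analysis), `water_source` (`"inactive"` or
#'   `"active"`), `ligand_names`, `out_dir` (directory for TSV reports,
#'   `NULL` for none).
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  known <- c("inactive_structure", "active_structure", "structure", "panel",
             "generic_map", "rule", "matrix", "rrcs", "patch",
             "min_abs_delta", "water_source", "ligand_names", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  defaults <- list(rule = selection_rule("entropy_le", entropy_cutoff = 0.44),
                   matrix = NULL, rrcs = rrcs_params(),
                   patch = patch_params(), water_source = "inactive",
                   ligand_names = c("CHS", "CLR"), out_dir = NULL)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = "run_config")
}

load_structure_arg <- function(x, what) {
  if (is.null(x)) stop("config is missing the ", what)
  if (inherits(x, "mol_structure")) return(x)
  read_structure(x)
}

load_map_arg <- function(x) {
  if (is.null(x) || inherits(x, "generic_map")) return(x)
  read_generic_numbers(x)
}

config_matrix <- function(cfg) {
  if (is.null(cfg$matrix)) blosum80() else cfg$matrix
}

#' Water-network activation analysis
#'
#' The composition behind the water-pocket-base residue selection:
#' contact networks of the inactive and active structures are subtracted
#' into a contact-change (delta RRCS) network, thresholded at
#' `min_abs_delta`; class-wide conserved positions are selected from the
#' paralog panel under the configured rule (by default entropy up to
#' 0.44 bits, i.e. at most one deviating receptor out of 11); water
#' adjacency is measured on the configured structure; and the reported
#' residue set is the three-way intersection.
#'
#' @param config a [run_config()] with `inactive_structure`,
#'   `active_structure`, `panel`, `generic_map` and `min_abs_delta`.
#' @return list of class `water_network_report`: `residues` (selected
#'   keys), `labels` (their generic labels), `annotations` (full residue
#'   table), `delta` (thresholded network), `n_conserved_positions`,
#'   `provenance`.
#' @export
run_water_network_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$min_abs_delta))
    stop("water-network analysis requires an explicit min_abs_delta")
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  inact <- stage("read inactive", load_structure_arg(config$inactive_structure,
                                                     "inactive structure"))
  act <- stage("read active", load_structure_arg(config$active_structure,
                                                 "active structure"))
  gmap <- stage("generic map", load_map_arg(config$generic_map))
  if (is.null(gmap)) warning("no generic-number map; labels will be blank")
  mat <- config_matrix(config)
  net_i <- stage("rrcs inactive", structure_rrcs(inact, params = config$rrcs))
  net_a <- stage("rrcs active", structure_rrcs(act, params = config$rrcs))
  corr <- match_residues(act, inact)
  delta <- stage("delta", significant_changes(
    delta_rrcs(net_a, net_i, corr), config$min_abs_delta))
  water_struct <- if (config$water_source == "active") act else inact
  wset <- stage("water adjacency",
                water_adjacent_residues(water_struct,
                                        config$patch$water_cutoff))
  conserved_keys <- character(0)
  n_cons <- 0L
  if (!is.null(config$panel)) {
    sel <- stage("conservation", select_positions(config$panel, config$rule,
                                                  mat))
    n_cons <- length(sel)
    if (!is.null(gmap) && !is.null(config$panel$labels)) {
      lab <- config$panel$labels[sel]
      hit <- gmap[gmap$label %in% lab, , drop = FALSE]
      conserved_keys <- res_key(hit$chain, hit$resno)
    }
  }
  residues <- stage("intersection",
                    activation_network_near_water(delta, conserved_keys,
                                                  wset))
  ann <- stage("annotate",
               annotate(water_struct, config$panel, delta, gmap,
                        config$patch, config$rule, mat))
  labels <- if (is.null(gmap)) rep(NA_character_, length(residues)) else {
    sk <- split_res_key(residues)
    generic_label(gmap, sk$chain, sk$resno)
  }
  report <- list(residues = residues, labels = labels, annotations = ann,
                 delta = delta, n_conserved_positions = n_cons,
                 provenance = version_and_provenance(config))
  class(report) <- "water_network_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(ann, file.path(config$out_dir, "annotations.tsv"))
    write_table(as.data.frame(delta), file.path(config$out_dir, "delta.tsv"))
    write_table(data.frame(key = residues, label = labels),
                file.path(config$out_dir, "water_network_residues.tsv"))
  }
  report
}

#' @export
print.water_network_report <- function(x, ...) {
  cat("water-network analysis:", length(x$residues),
      "residues at the water-pocket base\n")
  if (length(x$residues))
    cat(paste0("  ", x$residues, "  [", x$labels, "]", collapse = "\n"),
        "\n")
  invisible(x)
}

#' Conserved sterol-site (cholesterol) surface analysis
#'
#' Selects class-wide conserved panel positions under the union of the
#' zero-entropy rule and the similar-only rule (variation allowed only
#' between residues scoring strictly above 2), maps them onto the
#' structure, extracts conserved structurally continuous surface patches
#' ranked by aromatic enrichment, and, when a sterol-like ligand is
#' present, reports the overlap of the top patch with the ligand-contact
#' residues.
#'
#' @param config a [run_config()] with `structure`, `panel`,
#'   `generic_map`.
#' @return list of class `cholesterol_site_report`: `patches`,
#'   `top_patch`, `ligand_contacts`, `overlap`, `annotations`,
#'   `provenance`.
#' @export
run_cholesterol_site_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  struct <- load_structure_arg(config$structure, "structure")
  gmap <- load_map_arg(config$generic_map)
  mat <- config_matrix(config)
  sel <- integer(0)
  if (!is.null(config$panel)) {
    sel <- sort(union(
      select_positions(config$panel, selection_rule("entropy_zero"), mat),
      select_positions(config$panel,
                       selection_rule("similar_only",
                                      similarity_threshold = 2L), mat)))
  }
  conserved_keys <- character(0)
  if (length(sel) && !is.null(gmap) && !is.null(config$panel$labels)) {
    lab <- config$panel$labels[sel]
    hit <- gmap[gmap$label %in% lab, , drop = FALSE]
    conserved_keys <- res_key(hit$chain, hit$resno)
  }
  patches <- conserved_surface_patches(struct, conserved_keys, config$patch)
  has_ligand <- any(struct$atom$is_ligand &
                      struct$atom$resid %in% config$ligand_names)
  contacts <- if (has_ligand)
    ligand_contact_residues(struct, config$ligand_names,
                            config$patch$ligand_cutoff) else character(0)
  top <- if (length(patches)) patches[[1L]] else NULL
  overlap <- if (has_ligand && !is.null(top))
    sort(intersect(top$members, contacts)) else character(0)
  ann <- annotate(struct, config$panel, NULL, gmap, config$patch,
                  selection_rule("entropy_zero"), mat)
  report <- list(patches = patches, top_patch = top,
                 ligand_contacts = sort(contacts), overlap = overlap,
                 annotations = ann,
                 provenance = version_and_provenance(config))
  class(report) <- "cholesterol_site_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(ann, file.path(config$out_dir, "annotations.tsv"))
    pt <- do.call(rbind, lapply(seq_along(patches), function(i)
      data.frame(patch_id = i, key = patches[[i]]$members,
                 aromatic_count = patches[[i]]$aromatic_count,
                 stringsAsFactors = FALSE)))
    if (is.null(pt)) pt <- data.frame(patch_id = integer(),
                                      key = character(),
                                      aromatic_count = integer())
    write_table(pt, file.path(config$out_dir, "patches.tsv"))
  }
  report
}

#' @export
print.cholesterol_site_report <- function(x, ...) {
  cat("sterol-site analysis:", length(x$patches),
      "conserved surface patch(es)\n")
  if (!is.null(x$top_patch))
    cat("  top patch:", length(x$top_patch$members), "residues,",
        x$top_patch$aromatic_count, "aromatic\n")
  if (length(x$ligand_contacts))
    cat("  ligand contacts:", paste(x$ligand_contacts, collapse = ", "),
        "\n  overlap with top patch:", length(x$overlap), "residues\n")
  invisible(x)
}

#' Run manifest: version, configuration hash, input checksums
#'
#' @param config a [run_config()].
#' @return list with `package_version`, `r_version`, `config_hash` (MD5
#'   of the deparsed parameter set, file inputs represented by their
#'   checksums), `input_checksums` (named MD5s, `NA` for missing files),
#'   `parameters`, `timestamp`.
#' @export
version_and_provenance <- function(config) {
  is_path <- vapply(config, function(x)
    is.character(x) && length(x) == 1L && grepl("[/.]", x), TRUE)
  checksums <- vapply(which(is_path), function(i) {
    p <- config[[i]]
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_
  }, "")
  params <- config
  params[which(is_path)] <- ifelse(is.na(checksums), "missing", checksums)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(params[order(names(params))]), tf)
  list(package_version = as.character(utils::packageVersion("consnet")),
       r_version = as.character(getRversion()),
       config_hash = unname(tools::md5sum(tf)),
       input_checksums = checksums,
       parameters = params,
       timestamp = format(Sys.time(), tz = "UTC"))
}
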