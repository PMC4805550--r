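# Experiment container: a plain-text, directory-based bundle holding raw
# sweeps, cell metadata, planted truths and derived product tables, plus
# the YAML pipeline configuration. Sample arrays are serialized with 17
# significant digits so a write/read round trip is lossless.

.SCHEMA_VERSION <- "1.0"

#' Construct an experiment bundle
#'
#' @param recordings named list of [CellRecording-class].
#' @param cells per-cell metadata data.frame (built from the recordings
#'   when omitted).
#' @param derived named list of derived products.
#' @param provenance list recording config, seed and versions.
#' @return an [ExperimentBundle-class].
#' @export
experimentBundle <- function(recordings, cells = NULL, derived = list(),
                             provenance = list()) {
  if (is.null(names(recordings)))
    names(recordings) <- vapply(recordings, function(r) r@cellId,
                                character(1))
  if (is.null(cells)) {
    cells <- do.call(rbind, lapply(recordings, function(r) {
      data.frame(cell_id = r@cellId,
                 type = if (!is.null(r@meta$type)) r@meta$type else "PC",
                 band = if (!is.null(r@meta$band)) r@meta$band
                        else NA_character_,
                 soma_um = r@geometry@midlineOffset)
    }))
    rownames(cells) <- NULL
  }
  provenance$schema_version <- .SCHEMA_VERSION
  new("ExperimentBundle", cells = cells, recordings = recordings,
      derived = derived, provenance = provenance)
}

#' Number of cells in a bundle
#'
#' @param bundle an [ExperimentBundle-class].
#' @return integer.
#' @export
nCells <- function(bundle) length(bundle@recordings)

#' Write an experiment bundle to disk
#'
#' The on-disk layout is a directory: \code{manifest.json} (schema version,
#' provenance, per-cell sampling metadata and geometry),
#' \code{cells.csv}, and per cell \code{sites_<id>.csv},
#' \code{traces_<id>.csv} (long format, currents printed with 17
#' significant digits for lossless round trips) and, for synthetic cells,
#' a \code{truth_<id>.csv} sidecar (site, count, expected charge,
#' archetype). Derived tables go under \code{derived/} as CSV.
#'
#' @param bundle an [ExperimentBundle-class].
#' @param path target directory (created; must not be a file).
#' @return \code{path}, invisibly.
#' @export
writeBundle <- function(bundle, path) {
  stopifnot(is(bundle, "ExperimentBundle"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cellMeta <- lapply(bundle@recordings, function(r) {
    g <- r@geometry
    list(cell_id = r@cellId, dt = r@dt, stim_onset_ms = r@stimOnset,
         n_sites = dim(r@traces)[1], n_trials = dim(r@traces)[2],
         n_samples = dim(r@traces)[3],
         geometry = list(half_extent_um = g@halfExtent, step_um = g@step,
                         n_depth_rows = g@nDepthRows,
                         midline_offset_um = g@midlineOffset),
         meta = r@meta, has_truth = is(r@truth, "GroundTruthMap"))
  })
  manifest <- list(schema_version = .SCHEMA_VERSION,
                   provenance = bundle@provenance, cells = cellMeta)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(bundle@cells, file.path(path, "cells.csv"),
                   row.names = FALSE)
  for (r in bundle@recordings) {
    id <- r@cellId
    utils::write.csv(r@sites, file.path(path, sprintf("sites_%s.csv", id)),
                     row.names = FALSE)
    d <- dim(r@traces)
    long <- data.table::data.table(
      site = rep(seq_len(d[1]), times = d[2] * d[3]),
      trial = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
      sample = rep(seq_len(d[3]), each = d[1] * d[2]),
      i_pa = sprintf("%.17g", as.vector(r@traces)))
    data.table::fwrite(long, file.path(path, sprintf("traces_%s.csv", id)))
    if (is(r@truth, "GroundTruthMap")) {
      tt <- r@truth@sites
      tt$expected_charge_pC <- expectedCharge(r@truth)
      tt$archetype_id <- r@truth@archetypeId
      utils::write.csv(tt, file.path(path, sprintf("truth_%s.csv", id)),
                       row.names = FALSE)
    }
  }
  if (length(bundle@derived)) {
    dir.create(file.path(path, "derived"), showWarnings = FALSE)
    for (nm in names(bundle@derived)) {
      obj <- bundle@derived[[nm]]
      if (is.data.frame(obj))
        utils::write.csv(obj, file.path(path, "derived",
                                        paste0(nm, ".csv")),
                         row.names = FALSE)
    }
  }
  invisible(path)
}

#' Read an experiment bundle from disk
#'
#' Restores the sample arrays, metadata and truths written by
#' [writeBundle()]; derived tables come back as data.frames under
#' \code{derived}. Unknown schema versions and missing required attributes
#' raise explicit errors.
#'
#' @param path bundle directory.
#' @return an [ExperimentBundle-class].
#' @export
readBundle <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a bundle: missing manifest.json",
                             call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  ver <- manifest$schema_version
  if (is.null(ver) || !identical(ver, .SCHEMA_VERSION))
    stop(sprintf("unknown bundle schema version: found '%s', expected '%s'",
                 if (is.null(ver)) "<none>" else ver, .SCHEMA_VERSION),
         call. = FALSE)
  cells <- utils::read.csv(file.path(path, "cells.csv"),
                           stringsAsFactors = FALSE)
  recs <- list()
  for (cm in manifest$cells) {
    id <- cm$cell_id
    for (attr in c("dt", "stim_onset_ms", "n_sites", "n_trials",
                   "n_samples")) {
      if (is.null(cm[[attr]]))
        stop(sprintf("schema error: cell '%s' is missing required attribute '%s'",
                     id, attr), call. = FALSE)
    }
    g <- cm$geometry
    geom <- gridGeometry(g$half_extent_um, g$step_um, g$n_depth_rows,
                         g$midline_offset_um)
    sites <- utils::read.csv(file.path(path, sprintf("sites_%s.csv", id)),
                             stringsAsFactors = FALSE)
    long <- data.table::fread(file.path(path, sprintf("traces_%s.csv", id)))
    arr <- array(as.numeric(long$i_pa),
                 dim = c(cm$n_sites, cm$n_trials, cm$n_samples))
    truth <- NULL
    if (isTRUE(cm$has_truth)) {
      tt <- utils::read.csv(file.path(path, sprintf("truth_%s.csv", id)),
                            stringsAsFactors = FALSE)
      truth <- new("GroundTruthMap",
                   sites = tt[, c("site", "ml_um", "depth_row", "count",
                                  "q_u", "burst")],
                   hotspots = data.frame(center_um = numeric(),
                                         halfwidth_um = numeric(),
                                         strength = numeric()),
                   archetypeId = as.character(tt$archetype_id[1]))
    }
    recs[[id]] <- new("CellRecording", cellId = id, traces = arr,
                      dt = cm$dt, stimOnset = cm$stim_onset_ms,
                      sites = sites, geometry = geom,
                      meta = lapply(cm$meta, identity), truth = truth)
  }
  derived <- list()
  dDir <- file.path(path, "derived")
  if (dir.exists(dDir)) {
    for (f in list.files(dDir, pattern = "\\.csv$")) {
      derived[[sub("\\.csv$", "", f)]] <-
        utils::read.csv(file.path(dDir, f), stringsAsFactors = FALSE)
    }
  }
  new("ExperimentBundle", cells = cells, recordings = recs,
      derived = derived,
      provenance = lapply(manifest$provenance, identity))
}

setMethod("show", "ExperimentBundle", function(object) {
  cat(sprintf("ExperimentBundle: %d cell(s), %d derived product(s)\n",
              length(object@recordings), length(object@derived)))
  if (!is.null(object@provenance$seed))
    cat("  root seed:", object@provenance$seed, "\n")
})
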