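# End-to-end orchestration: configuration, stage logging, pipeline run.

#' Default pipeline configuration
#'
#' A nested list holding every numeric default of the analysis in one
#' place; [readConfig()] merges a YAML file over these values.
#'
#' @return named list with sections \code{geometry}, \code{noise},
#'   \code{synth}, \code{analysis} and \code{plasticity}.
#' @export
defaultConfig <- function() {
  list(
    geometry = list(half_extent_um = 332, step_um = 41.5, n_depth_rows = 2),
    noise = list(sd_pa = 150, duration_ms = 1000, sampling_khz = 20,
                 stim_onset_ms = 200),
    synth = list(n_cells = 12, n_repeats = 3, archetypes = "default",
                 n_hotspots = 3, center_jitter_sd_um = 10,
                 strength_jitter_sd = 0.15),
    analysis = list(threshold = 3.09, kernel_halfwidth_um = 18,
                    window_um = 100, shift_um = 10, min_members = 1,
                    corr_step_um = 10, k = "auto", k_range = 2:8),
    plasticity = list(threshold = 3.09)
  )
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file.
#' @param config a configuration list.
#' @return \code{readConfig}: the configuration merged over
#'   [defaultConfig()]; \code{writeConfig}: \code{path}, invisibly.
#' @export
readConfig <- function(path) {
  user <- yaml::read_yaml(path)
  .mergeConfig(defaultConfig(), user)
}

#' @rdname readConfig
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

.stage <- function(name, cell, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed%s: %s", name,
                 if (is.null(cell)) "" else paste0(" for ", cell),
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full mapping pipeline
#'
#' Orchestrates the analysis in its natural order: charge integration and
#' noise modelling, per-site Z-scores, significance classification,
#' depth-maximum patterns, sliding-window median groups, the correlation
#' matrix and its co-clustering. Given no input bundle, a synthetic
#' population is generated first per the configuration. Every stage logs
#' its counts; any error aborts with the stage name and offending cell.
#'
#' @param config configuration list (see [defaultConfig()]).
#' @param seed integer root seed (mandatory; all randomness, including the
#'   k-means refinement of co-clustering, derives from it).
#' @param bundle optional [ExperimentBundle-class] of recordings to analyse
#'   instead of simulating.
#' @param outDir optional directory: the resulting bundle and its derived
#'   CSV tables are written there.
#' @param verbose emit stage logs via \code{message()}.
#' @return the [ExperimentBundle-class] with \code{derived} populated:
#'   \code{maps}, \code{patterns}, \code{groups}, \code{matrix},
#'   \code{clusters} (objects) and the corresponding \code{*_table}
#'   data.frames.
#' @export
runPipeline <- function(config = defaultConfig(), seed, bundle = NULL,
                        outDir = NULL, verbose = TRUE) {
  seed <- .requireSeed(seed)
  log <- function(...) if (verbose) message(sprintf(...))
  an <- config$analysis
  if (is.null(bundle)) {
    g <- config$geometry; nz <- config$noise; sy <- config$synth
    arch <- if (identical(sy$archetypes, "independent")) NULL
            else defaultArchetypes(sy$center_jitter_sd_um,
                                   sy$strength_jitter_sd)
    bundle <- .stage("simulate", NULL,
      simulatePopulation(nCells = sy$n_cells, archetypes = arch,
                         nHotspots = sy$n_hotspots,
                         halfExtent = g$half_extent_um, step = g$step_um,
                         nDepthRows = g$n_depth_rows,
                         noise = noiseSpec(nz$sd_pa, nz$duration_ms,
                                           nz$sampling_khz,
                                           nz$stim_onset_ms),
                         nRepeats = sy$n_repeats, seed = seed))
    log("simulate: %d cells generated", nCells(bundle))
  }
  bundle@provenance$seed <- seed
  bundle@provenance$config <- config
  bundle@provenance$config_hash <- digestConfig(config)

  maps <- list()
  for (id in names(bundle@recordings)) {
    r <- bundle@recordings[[id]]
    type <- if (!is.null(r@meta$type)) r@meta$type else "PC"
    maps[[id]] <- .stage("map", id, switch(type,
      GoC = computeMap(r, statistic = "charge", removeDC = TRUE),
      MLI = computeMap(r, statistic = "events"),
      computeMap(r, statistic = "charge")))
  }
  nSig <- sum(vapply(maps, function(m)
    sum(m@sites$z > an$threshold), numeric(1)))
  log("map: %d cells, %d sites, %d significant (Z > %g)",
      length(maps), sum(vapply(maps, function(m) nrow(m@sites),
                               numeric(1))), nSig, an$threshold)

  patterns <- lapply(names(maps), function(id)
    .stage("pattern", id,
           toPattern(maps[[id]], kernelHalfwidth = an$kernel_halfwidth_um)))
  names(patterns) <- names(maps)
  log("pattern: %d mediolateral patterns (kernel %g um)",
      length(patterns), an$kernel_halfwidth_um)

  groups <- .stage("groups", NULL,
    medianPatterns(patterns, windowUm = an$window_um,
                   shiftUm = an$shift_um, minMembers = an$min_members))
  log("groups: %d median-pattern groups (window %g um, shift %g um)",
      length(groups), an$window_um, an$shift_um)

  cmat <- NULL; assign <- NULL
  if (length(groups) >= 3) {
    cmat <- .stage("matrix", NULL,
                   correlationMatrix(groups, by = an$corr_step_um))
    assign <- .stage("cluster", NULL,
      spectralCocluster(cmat, k = an$k, kRange = an$k_range,
                        seed = .childSeed(seed, 999)))
    log("cluster: k = %d, contiguous clusters: %d of %d", assign@k,
        sum(assign@contiguous), assign@k)
  } else {
    log("matrix/cluster skipped: fewer than 3 groups")
  }

  bundle@derived <- c(list(maps = maps, patterns = patterns,
                           groups = groups, matrix = cmat,
                           clusters = assign),
                      .derivedTables(maps, patterns, groups, cmat, assign))
  if (!is.null(outDir)) {
    b2 <- bundle
    b2@derived <- Filter(is.data.frame, bundle@derived)
    writeBundle(b2, outDir)
    log("wrote bundle to %s", outDir)
  }
  bundle
}

#' Stable hash of a configuration
#'
#' Provenance helper: a deterministic hex digest of the serialized
#' configuration so derived products can record exactly which inputs
#' produced them.
#'
#' @param config configuration list.
#' @return character(1) hex digest.
#' @export
digestConfig <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(s))
  h <- c(17, 31)
  for (b in bytes) {
    h[1] <- (h[1] * 131 + b) %% 2147483647
    h[2] <- (h[2] * 137 + b) %% 2147483629
  }
  sprintf("%08x%08x", as.integer(h[1]), as.integer(h[2]))
}

.derivedTables <- function(maps, patterns, groups, cmat, assign) {
  mapTab <- do.call(rbind, lapply(maps, function(m) {
    s <- m@sites
    s$cell_id <- m@cellId
    s$label <- as.character(classifySites(m))
    s
  }))
  rownames(mapTab) <- NULL
  patTab <- do.call(rbind, lapply(patterns, function(p)
    data.frame(cell_id = p@cellId, position_um = p@positions,
               z = p@values)))
  rownames(patTab) <- NULL
  out <- list(maps_table = mapTab, patterns_table = patTab)
  if (length(groups)) {
    out$groups_table <- do.call(rbind, lapply(groups, function(g)
      data.frame(center_um = g@center, n_members = length(g@members))))
  }
  if (!is.null(cmat)) {
    n <- nrow(cmat@r)
    out$matrix_table <- data.frame(
      row_center_um = rep(cmat@centers, times = n),
      col_center_um = rep(cmat@centers, each = n),
      r = as.vector(cmat@r))
  }
  if (!is.null(assign)) {
    out$clusters_table <- data.frame(center_um = assign@centers,
                                     cluster = assign@clusters)
  }
  out
}
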