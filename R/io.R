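# File I/O: TIFF stacks, localization tables, run configuration.

#' Read a multi-page TIFF stack
#'
#' Frames are returned in page order as integer-valued count matrices
#' (16-bit unsigned values are read as raw counts, not rescaled).
#'
#' @param path TIFF file.
#' @return list of 2D numeric matrices.
#' @export
readStack <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop(sprintf("cannot read TIFF '%s': %s", path,
                                   conditionMessage(e)), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  if (!length(pages)) stop(sprintf("TIFF '%s' contains no pages", path))
  lapply(seq_along(pages), function(p) {
    m <- pages[[p]]
    if (length(dim(m)) != 2L)
      stop(sprintf("page %d of '%s' is not a single-channel image", p, path))
    m * 1.0
  })
}

#' Write a stack of frames as a 16-bit multi-page TIFF
#'
#' Counts are clamped to `[0, 65535]` and rounded (camera data are
#' unsigned).
#'
#' @param frames list of 2D count matrices.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeStack <- function(frames, path) {
  scaled <- lapply(frames, function(f)
    pmin(pmax(round(f), 0), 65535) / 65535)
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write / read a localization table
#'
#' CSV with the fixed header `frame, x_px, y_px, x_nm, y_nm, z_nm,
#' intensity, background, crlb_x, crlb_y, crlb_z, iterations,
#' termination`; write/read round-trips losslessly (an empty result
#' produces a header-only file).
#'
#' @param localizations data.frame as produced by [fitFrame()].
#' @param path CSV file.
#' @return `writeLocalizations`: `path` invisibly; `readLocalizations`:
#'   the data.frame.
#' @export
writeLocalizations <- function(localizations, path) {
  cols <- names(emptyLocalizations())
  missing <- setdiff(cols, names(localizations))
  for (m in missing) localizations[[m]] <- NA
  utils::write.csv(localizations[, cols, drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname writeLocalizations
#' @export
readLocalizations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(frame = "integer", iterations = "integer",
                                 termination = "character"))
}

#' Read and validate a run configuration
#'
#' YAML with unit-suffixed keys. Recognized keys (defaults in
#' parentheses): `calibration` (path, required for analysis),
#' `window_px` (9), `dxy_px` (0.1), `rxy_px` (4), `dz_nm` (25), `rz_nm`
#' (1000), `threshold_counts` (required), `suppression_radius_px`
#' (window), `bg_window_px` (11), `max_iterations` (5), `tol` (1e-3),
#' `pixel_size_nm` (100), `controller` (`count_threshold`,
#' `streak_length`, `power_step_mw`, `power_max_mw`).
#'
#' @param path YAML file.
#' @return validated configuration list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg configuration list.
#' @export
validateRunConfig <- function(cfg) {
  defaults <- list(window_px = 9L, dxy_px = 0.1, rxy_px = 4, dz_nm = 25,
                   rz_nm = 1000, bg_window_px = 11L, max_iterations = 5L,
                   tol = 1e-3, pixel_size_nm = 100)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.null(cfg$suppression_radius_px))
    cfg$suppression_radius_px <- cfg$window_px
  if (is.null(cfg$threshold_counts))
    stop("configuration error: 'threshold_counts' is required")
  num <- c("dxy_px", "rxy_px", "dz_nm", "rz_nm", "tol", "pixel_size_nm",
           "threshold_counts")
  for (k in num)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] <= 0)
      stop(sprintf("configuration error: '%s' must be a positive number", k))
  if (cfg$window_px < 5L || cfg$window_px %% 2L != 1L)
    stop("configuration error: 'window_px' must be odd and >= 5")
  # fails early if the grid is inconsistent
  lookupTableSpec(cfg$window_px, cfg$dxy_px, cfg$rxy_px, cfg$dz_nm, cfg$rz_nm)
  cc <- cfg$controller
  if (!is.null(cc)) {
    cdef <- list(count_threshold = 25, streak_length = 5L, power_step_mw = 5,
                 power_max_mw = 50)
    for (k in names(cdef)) if (is.null(cc[[k]])) cc[[k]] <- cdef[[k]]
    controllerState(cc$count_threshold, cc$streak_length, cc$power_step_mw,
                    cc$power_max_mw)
    cfg$controller <- cc
  }
  cfg
}

#' Write a run manifest
#'
#' Echoes the configuration, seeds and package version next to the run
#' outputs so the run can be reproduced exactly.
#'
#' @param cfg configuration list.
#' @param path output YAML file.
#' @param seed integer seed(s) used.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(cfg, path, seed = NA_integer_) {
  manifest <- list(
    package = "lutSMLM",
    version = as.character(utils::packageVersion("lutSMLM")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = cfg)
  yaml::write_yaml(manifest, path)
  invisible(path)
}
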