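# File I/O: image stacks (multi-page TIFF), trajectory CSVs, geometry YAML.

#' Read an image stack from a multi-page TIFF
#'
#' @param path Path to a multi-page TIFF of integer photon counts.
#' @return Integer array `rows x cols x frames`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) {
    stop("expected a multi-page TIFF time series (frames x rows x cols); ",
         "got a single 2-D image", call. = FALSE)
  }
  dims <- dim(pages[[1]])
  if (length(dims) != 2L) {
    stop("expected single-channel integer frames; got array of rank ",
         length(dims), call. = FALSE)
  }
  for (p in pages) {
    if (!identical(dim(p), dims)) stop("frame dimensions differ across pages",
                                       call. = FALSE)
    if (any(p != trunc(p)) || any(p < 0)) {
      stop("expected nonnegative integer photon counts", call. = FALSE)
    }
  }
  stack <- array(0L, dim = c(dims[1], dims[2], length(pages)))
  for (i in seq_along(pages)) stack[, , i] <- as.integer(pages[[i]])
  stack
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' @param stack Integer array `rows x cols x frames`, values in 0..65535.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3L)
  if (any(stack < 0) || any(stack > 65535)) {
    stop("counts must fit 16-bit (0..65535)", call. = FALSE)
  }
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(f) stack[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read pre-tracked trajectories from CSV
#'
#' Expects columns `trajectory_id`, `frame`, `row_px`, `col_px`,
#' `intensity`. Rows are grouped by trajectory and frame-sorted; duplicate
#' `(trajectory_id, frame)` rows are an integrity error.
#'
#' @param path CSV path.
#' @return Tibble sorted by `trajectory_id`, `frame`.
#' @export
read_trajectories_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("trajectory_id", "frame", "row_px", "col_px", "intensity")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("trajectory CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df[, c("trajectory_id", "frame")]) > 0L) {
    stop("duplicate (trajectory_id, frame) rows in ", path, call. = FALSE)
  }
  dplyr::arrange(df, .data$trajectory_id, .data$frame)
}

#' Read a per-frame incident-intensity series
#'
#' Two-column CSV `(frame, i0)`.
#' @param path CSV path.
#' @return Numeric vector of i0 values in frame order.
#' @export
read_i0_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("frame", "i0") %in% names(df))) {
    stop("i0 CSV needs columns frame, i0", call. = FALSE)
  }
  df <- dplyr::arrange(df, .data$frame)
  df$i0
}

#' Read the geometry/beam/ring configuration from YAML
#'
#' Expected keys: `detector` (`pitch_mm`, `rows`, `cols`, `center`,
#' `distance_mm`, `frame_interval_s`, optional `masks` as a list of
#' `[row0, row1, col0, col1]`), `beam` (`energy_keV`, `bandwidth`, `mode`),
#' `phases` (list of `{name, system, a, c}`), `rings` (list of
#' `{phase, hkl, half_width_px}`).
#'
#' @param path YAML path.
#' @return List with `geom` ([detector_geometry()]), `beam` ([beam_spec()]),
#'   `phases` (named list of [crystal_phase()]), `rois` (named list of ring
#'   ROIs, built when `rings` is present).
#' @export
read_geometry_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  det <- cfg$detector
  if (is.null(det)) stop("config missing `detector` block", call. = FALSE)
  masks <- lapply(det$masks %||% list(), function(m) {
    list(row0 = m[[1]], row1 = m[[2]], col0 = m[[3]], col1 = m[[4]])
  })
  geom <- detector_geometry(det$rows, det$cols, det$pitch_mm,
                            unlist(det$center), det$distance_mm,
                            det$frame_interval_s, masks)
  bm <- cfg$beam
  if (is.null(bm)) stop("config missing `beam` block", call. = FALSE)
  if (is.null(bm$energy_keV)) {
    stop("config must state beam energy_keV explicitly", call. = FALSE)
  }
  beam <- beam_spec(bm$energy_keV, bm$bandwidth %||% 0, bm$mode %||% "mono")
  phases <- list()
  for (p in cfg$phases %||% list()) {
    phases[[p$name]] <- crystal_phase(p$name, p$system, p$a, p$c)
  }
  rois <- list()
  for (r in cfg$rings %||% list()) {
    ph <- phases[[r$phase]]
    if (is.null(ph)) stop("ring references unknown phase ", r$phase,
                          call. = FALSE)
    roi <- build_ring_roi(ph, unlist(r$hkl), beam, geom,
                          r$half_width_px %||% 2)
    rois[[roi$label]] <- roi
  }
  list(geom = geom, beam = beam, phases = phases, rois = rois)
}

#' Write per-pixel fits to CSV
#'
#' @param fits A [dxb_fit_pixels()] tibble.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_pixel_fits_csv <- function(fits, path) {
  readr::write_csv(as.data.frame(fits), path)
  invisible(path)
}
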