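# Diffraction geometry: crystal phases, beam, detector, ring prediction and ROIs.
#
# Pixel convention: 0-based (row, col); a pixel's center sits at integer
# coordinates and radii are measured to pixel centers.

#' Crystal phase (lattice) description
#'
#' Holds the lattice parameters of one nanocrystal probe phase, from which
#' d-spacings of its reflections are predicted. Gold probes are face-centered
#' cubic (a = 4.08 Å); zinc oxide probes are hexagonal wurtzite
#' (a = 3.25 Å, c = 5.2 Å).
#'
#' @param name Text label, e.g. `"Au"` or `"ZnO"`.
#' @param system Crystal system, `"cubic"` or `"hexagonal"`.
#' @param a Lattice constant a in Ångström (> 0).
#' @param c Lattice constant c in Ångström; required for hexagonal phases and
#'   must be absent (`NULL`) for cubic ones.
#' @return An object of class `crystal_phase`.
#' @examples
#' crystal_phase("Au", "cubic", a = 4.08)
#' crystal_phase("ZnO", "hexagonal", a = 3.25, c = 5.2)
#' @export
crystal_phase <- function(name, system = c("cubic", "hexagonal"), a, c = NULL) {
  system <- match.arg(system)
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(a) || length(a) != 1L || a <= 0) {
    stop("lattice constant `a` must be a single positive number", call. = FALSE)
  }
  if (system == "hexagonal") {
    if (is.null(c) || !is.numeric(c) || length(c) != 1L || c <= 0) {
      stop("hexagonal phase `", name, "` needs a positive lattice constant `c`",
           call. = FALSE)
    }
  } else if (!is.null(c)) {
    stop("cubic phase `", name, "` must not carry a `c` lattice constant",
         call. = FALSE)
  }
  structure(list(name = name, system = system, a = a, c = c),
            class = "crystal_phase")
}

#' @export
print.crystal_phase <- function(x, ...) {
  cat(sprintf("<crystal_phase> %s (%s), a = %g Å%s\n", x$name, x$system,
              x$a, if (is.null(x$c)) "" else sprintf(", c = %g Å", x$c)))
  invisible(x)
}

#' X-ray beam description
#'
#' @param energy_keV Photon energy (peak energy for pink beam), keV.
#' @param bandwidth Fractional energy bandwidth dE/E (0 for monochromatic).
#' @param mode `"mono"` or `"pink"`. Pink (broad-bandwidth) beams produce Laue
#'   spots for tracking; monochromatic beams produce powder rings for blinking
#'   analysis.
#' @return An object of class `beam_spec`.
#' @examples
#' beam_spec(17.7, bandwidth = 0.1, mode = "pink")
#' @export
beam_spec <- function(energy_keV, bandwidth = 0, mode = c("mono", "pink")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(energy_keV), length(energy_keV) == 1L)
  if (energy_keV <= 0) stop("energy_keV must be > 0", call. = FALSE)
  if (bandwidth < 0) stop("bandwidth must be >= 0", call. = FALSE)
  if (mode == "pink" && bandwidth <= 0) {
    stop("pink beam requires bandwidth > 0", call. = FALSE)
  }
  structure(list(energy_keV = energy_keV, bandwidth = bandwidth, mode = mode),
            class = "beam_spec")
}

#' Flat 2-D detector geometry
#'
#' Describes the photon-counting detector and its placement. The default
#' template matches a PILATUS-100K-style detector (195 x 487 pixels of
#' 172 µm) with no intermodule gap; masked rectangles (e.g. intermodule
#' regions) are supplied explicitly because their placement is
#' installation-specific.
#'
#' @param n_rows,n_cols Pixel counts.
#' @param pixel_pitch_mm Pixel edge length, mm.
#' @param beam_center_px Length-2 numeric `(row, col)` of the direct-beam
#'   position, fractional 0-based pixels.
#' @param distance_mm Sample-to-detector distance, mm.
#' @param frame_interval_s Seconds per frame.
#' @param mask_rects List of masked rectangles, each a list/vector with fields
#'   `row0`, `row1`, `col0`, `col1` (inclusive 0-based bounds) lying inside the
#'   detector.
#' @return An object of class `detector_geometry`.
#' @examples
#' detector_geometry(beam_center_px = c(97, 243), distance_mm = 50,
#'                   frame_interval_s = 0.1)
#' @export
detector_geometry <- function(n_rows = 195, n_cols = 487, pixel_pitch_mm = 0.172,
                              beam_center_px, distance_mm, frame_interval_s,
                              mask_rects = list()) {
  stopifnot(length(beam_center_px) == 2L)
  if (pixel_pitch_mm <= 0) stop("pixel_pitch_mm must be > 0", call. = FALSE)
  if (distance_mm <= 0) stop("distance_mm must be > 0", call. = FALSE)
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0", call. = FALSE)
  mask_rects <- lapply(mask_rects, function(m) {
    m <- as.list(m)
    need <- c("row0", "row1", "col0", "col1")
    if (!all(need %in% names(m))) {
      stop("mask rectangles need fields row0, row1, col0, col1", call. = FALSE)
    }
    m <- m[need]
    if (m$row0 > m$row1 || m$col0 > m$col1 ||
        m$row0 < 0 || m$col0 < 0 || m$row1 > n_rows - 1L || m$col1 > n_cols - 1L) {
      stop("mask rectangle out of detector bounds", call. = FALSE)
    }
    m
  })
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pixel_pitch_mm = pixel_pitch_mm,
                 beam_center_px = as.numeric(beam_center_px),
                 distance_mm = distance_mm,
                 frame_interval_s = frame_interval_s,
                 mask_rects = mask_rects),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "<detector_geometry> %d x %d px, pitch %g mm, center (%g, %g), %g mm, %g s/frame, %d mask(s)\n",
    x$n_rows, x$n_cols, x$pixel_pitch_mm, x$beam_center_px[1],
    x$beam_center_px[2], x$distance_mm, x$frame_interval_s, length(x$mask_rects)))
  invisible(x)
}

#' Convert photon energy to wavelength
#'
#' Standard X-ray conversion lambda\[Å\] = 12.3984 / E\[keV\].
#'
#' @param energy_keV Photon energy, keV (> 0).
#' @return Wavelength in Ångström.
#' @examples
#' wavelength_from_energy(17.7)
#' @export
wavelength_from_energy <- function(energy_keV) {
  if (!is.numeric(energy_keV) || any(energy_keV <= 0)) {
    stop("energy_keV must be positive", call. = FALSE)
  }
  12.3984 / energy_keV
}

#' Interplanar d-spacing of a reflection
#'
#' Cubic: d = a / sqrt(h^2 + k^2 + l^2). Hexagonal:
#' 1/d^2 = (4/3)(h^2 + hk + k^2)/a^2 + l^2/c^2.
#'
#' @param phase A [crystal_phase()].
#' @param hkl Integer Miller index triple, not all zero.
#' @return d-spacing in Ångström.
#' @examples
#' d_spacing(crystal_phase("Au", "cubic", a = 4.08), c(1, 1, 1))
#' @export
d_spacing <- function(phase, hkl) {
  stopifnot(inherits(phase, "crystal_phase"), length(hkl) == 3L)
  h <- hkl[1]; k <- hkl[2]; l <- hkl[3]
  if (all(hkl == 0)) stop("hkl (0,0,0) has no d-spacing", call. = FALSE)
  if (phase$system == "cubic") {
    phase$a / sqrt(h^2 + k^2 + l^2)
  } else {
    if (is.null(phase$c)) stop("hexagonal phase without c lattice constant",
                               call. = FALSE)
    inv_d2 <- (4 / 3) * (h^2 + h * k + k^2) / phase$a^2 + l^2 / phase$c^2
    1 / sqrt(inv_d2)
  }
}

#' Predicted ring radius on the detector
#'
#' Bragg's law plus flat-detector projection:
#' `theta_B = asin(lambda / 2d)`, `radius_px = distance * tan(2 theta_B) / pitch`.
#' No polarization or solid-angle correction is applied.
#'
#' @param d d-spacing, Ångström.
#' @param beam A [beam_spec()].
#' @param geom A [detector_geometry()].
#' @return Ring radius in pixels.
#' @examples
#' geom <- detector_geometry(beam_center_px = c(97, 243), distance_mm = 95,
#'                           frame_interval_s = 0.0125)
#' ring_radius(2.3556, beam_spec(17.7, 0.1, "pink"), geom)
#' @export
ring_radius <- function(d, beam, geom) {
  stopifnot(inherits(beam, "beam_spec"), inherits(geom, "detector_geometry"))
  lambda <- wavelength_from_energy(beam$energy_keV)
  s <- lambda / (2 * d)
  if (s >= 1) {
    stop(sprintf("no reflection: lambda/2d = %.3f >= 1 (Bragg condition unreachable)", s),
         call. = FALSE)
  }
  theta_b <- asin(s)
  geom$distance_mm * tan(2 * theta_b) / geom$pixel_pitch_mm
}

#' Ring radius band under a finite bandwidth
#'
#' For a pink beam the Bragg condition is met over an energy band; a Laue spot
#' from a given reflection may land anywhere between the radii predicted at
#' the band edges `E (1 + bw/2)` and `E (1 - bw/2)`.
#'
#' @inheritParams ring_radius
#' @return Numeric length-2 `c(min, max)` radius in pixels.
#' @export
ring_radius_band <- function(d, beam, geom) {
  if (beam$bandwidth <= 0) {
    r <- ring_radius(d, beam, geom)
    return(c(r, r))
  }
  hi <- beam_spec(beam$energy_keV * (1 + beam$bandwidth / 2), 0, "mono")
  lo <- beam_spec(beam$energy_keV * (1 - beam$bandwidth / 2), 0, "mono")
  sort(c(ring_radius(d, lo, geom), ring_radius(d, hi, geom)))
}

pixel_radius_grid <- function(geom) {
  rows <- 0:(geom$n_rows - 1L)
  cols <- 0:(geom$n_cols - 1L)
  dr <- rows - geom$beam_center_px[1]
  dc <- cols - geom$beam_center_px[2]
  sqrt(outer(dr^2, dc^2, "+"))
}

in_any_mask <- function(row, col, mask_rects) {
  if (length(mask_rects) == 0L) return(rep(FALSE, length(row)))
  hit <- rep(FALSE, length(row))
  for (m in mask_rects) {
    hit <- hit | (row >= m$row0 & row <= m$row1 & col >= m$col0 & col <= m$col1)
  }
  hit
}

#' Build an annular ring region of interest
#'
#' Selects detector pixels whose center-to-beam-center distance lies within
#' `half_width_px` of the predicted ring radius, excluding masked rectangles
#' (e.g. the intermodule region of a modular detector).
#'
#' @param phase A [crystal_phase()].
#' @param hkl Miller index triple.
#' @param beam A [beam_spec()].
#' @param geom A [detector_geometry()] (its `mask_rects` are applied).
#' @param half_width_px Radial half-width of the annulus, pixels (> 0).
#'   The default of 2 px keeps the annulus on the ring crest for typical
#'   powder-ring widths.
#' @return An object of class `ring_roi`: list with `phase`, `hkl`, `label`
#'   (e.g. `"Au(111)"`), `d_spacing_A`, `radius_px`, `half_width_px`, and
#'   `pixels`, a tibble with 0-based `row`, `col` and each pixel's `radius_px`.
#' @examples
#' geom <- detector_geometry(64, 64, 1, c(32, 32), 100, 0.1)
#' roi <- build_ring_roi(crystal_phase("Au", "cubic", a = 4.08), c(1, 1, 1),
#'                       beam_spec(12.3984), geom, half_width_px = 2)
#' @export
build_ring_roi <- function(phase, hkl, beam, geom, half_width_px = 2) {
  if (half_width_px <= 0) stop("half_width_px must be > 0", call. = FALSE)
  d <- d_spacing(phase, hkl)
  radius <- ring_radius(d, beam, geom)
  rg <- pixel_radius_grid(geom)
  sel <- which(abs(rg - radius) <= half_width_px, arr.ind = TRUE)
  row <- sel[, 1] - 1L
  col <- sel[, 2] - 1L
  keep <- !in_any_mask(row, col, geom$mask_rects)
  row <- row[keep]; col <- col[keep]
  if (length(row) == 0L) {
    stop(sprintf("empty ROI for %s(%s): no unmasked pixels within %g px of radius %.2f px",
                 phase$name, paste(hkl, collapse = ""), half_width_px, radius),
         call. = FALSE)
  }
  ord <- order(row, col)  # deterministic row-major order
  pixels <- tibble::tibble(
    row = row[ord], col = col[ord],
    radius_px = sqrt((row[ord] - geom$beam_center_px[1])^2 +
                     (col[ord] - geom$beam_center_px[2])^2))
  structure(list(phase = phase$name, hkl = as.integer(hkl),
                 label = sprintf("%s(%s)", phase$name, paste(hkl, collapse = "")),
                 d_spacing_A = d, radius_px = radius,
                 half_width_px = half_width_px, pixels = pixels),
            class = "ring_roi")
}

#' @export
print.ring_roi <- function(x, ...) {
  cat(sprintf("<ring_roi> %s: d = %.4f Å, radius = %.2f px ± %g, %d pixels\n",
              x$label, x$d_spacing_A, x$radius_px, x$half_width_px,
              nrow(x$pixels)))
  invisible(x)
}

#' Route an observed radius to a unique candidate ring
#'
#' The dual-probe separation step: a spot (or pixel) at a given radius is
#' assigned to the one candidate ring whose predicted radius lies within
#' `tolerance_px`. Ambiguity is an error, never a silent choice.
#'
#' @param observed_radius_px Observed radius, pixels.
#' @param candidate_rois Nonempty list of [build_ring_roi()] objects.
#' @param tolerance_px Matching tolerance, pixels (> 0).
#' @param beam Optional [beam_spec()]; if supplied and the beam is pink, each
#'   candidate's acceptance interval is widened to its bandwidth radius band
#'   (see [ring_radius_band()]) rather than a fixed radius. Requires `geom`.
#' @param geom Optional [detector_geometry()], needed with `beam`.
#' @return The matching candidate's `label`, or `NA_character_` when no
#'   candidate matches (unassigned).
#' @export
assign_ring <- function(observed_radius_px, candidate_rois, tolerance_px,
                        beam = NULL, geom = NULL) {
  if (length(candidate_rois) == 0L) stop("no candidate rings", call. = FALSE)
  if (tolerance_px <= 0) stop("tolerance_px must be > 0", call. = FALSE)
  hits <- vapply(candidate_rois, function(roi) {
    if (!is.null(beam) && beam$mode == "pink") {
      stopifnot(!is.null(geom))
      band <- ring_radius_band(roi$d_spacing_A, beam, geom)
      observed_radius_px >= band[1] - tolerance_px &&
        observed_radius_px <= band[2] + tolerance_px
    } else {
      abs(roi$radius_px - observed_radius_px) <= tolerance_px
    }
  }, logical(1))
  n <- sum(hits)
  if (n == 0L) return(NA_character_)
  if (n > 1L) {
    labs <- vapply(candidate_rois[hits], `[[`, character(1), "label")
    stop(sprintf("ambiguous ring assignment at radius %.2f px: %s",
                 observed_radius_px, paste(labs, collapse = ", ")),
         call. = FALSE)
  }
  candidate_rois[[which(hits)]]$label
}

#' Export a ring ROI as JSON for audit
#'
#' @param roi A [build_ring_roi()] object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(roi, path) {
  stopifnot(inherits(roi, "ring_roi"))
  obj <- list(label = roi$label, phase = roi$phase, hkl = roi$hkl,
              d_spacing_A = roi$d_spacing_A, radius_px = roi$radius_px,
              half_width_px = roi$half_width_px,
              pixels = as.data.frame(roi$pixels[, c("row", "col")]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' The standard dual-probe phases
#'
#' Convenience constructors for the gold and zinc-oxide probe lattices
#' (Au fcc a = 4.08 Å; ZnO wurtzite a = 3.25 Å, c = 5.2 Å).
#' @return A [crystal_phase()].
#' @export
phase_au <- function() crystal_phase("Au", "cubic", a = 4.08)

#' @rdname phase_au
#' @export
phase_zno <- function() crystal_phase("ZnO", "hexagonal", a = 3.25, c = 5.2)

#' The six indexed dual-probe rings
#'
#' The ring set used for dual-probe work: Au (111), (200) and ZnO (100),
#' (002), (101), (102).
#'
#' @param beam A [beam_spec()].
#' @param geom A [detector_geometry()].
#' @param half_width_px Annulus half-width passed to [build_ring_roi()].
#' @return Named list of `ring_roi` objects keyed by label.
#' @export
standard_ring_set <- function(beam, geom, half_width_px = 2) {
  au <- phase_au(); zno <- phase_zno()
  specs <- list(list(au, c(1, 1, 1)), list(au, c(2, 0, 0)),
                list(zno, c(1, 0, 0)), list(zno, c(0, 0, 2)),
                list(zno, c(1, 0, 1)), list(zno, c(1, 0, 2)))
  rois <- lapply(specs, function(s) {
    build_ring_roi(s[[1]], s[[2]], beam, geom, half_width_px)
  })
  names(rois) <- vapply(rois, `[[`, character(1), "label")
  rois
}
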