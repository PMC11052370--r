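# Laue-spot detection and frame-to-frame linking (the tracking observable).

#' Calibrate a movie by the incident-beam intensity
#'
#' Scales each frame by `mean(i0) / i0[frame]`, removing per-frame
#' incident-flux variation while preserving the grand mean of the stack.
#'
#' @param stack Numeric array `rows x cols x frames`.
#' @param i0 Numeric vector of per-frame incident intensities, one per
#'   frame, all > 0.
#' @return Numeric array of the same shape.
#' @export
normalize_i0 <- function(stack, i0) {
  d <- dim(stack)
  if (length(d) != 3L || d[3] != length(i0)) {
    stop("i0 length must equal the frame count", call. = FALSE)
  }
  if (any(!is.finite(i0)) || any(i0 <= 0)) {
    stop("all i0 values must be positive", call. = FALSE)
  }
  scale <- mean(i0) / i0
  out <- stack * rep(scale, each = d[1] * d[2])
  out
}

#' Detect diffraction spots in one frame
#'
#' Local maxima of the background-subtracted frame above a threshold,
#' refined to sub-pixel position by an intensity-weighted centroid in a
#' window. Maxima closer than `min_separation_px` are suppressed in favor of
#' the brighter one.
#'
#' @param frame Nonnegative numeric matrix (one detector frame).
#' @param geom A [detector_geometry()] (for the beam center).
#' @param background Background estimator: `"median"` (per-frame median) or
#'   `"none"`.
#' @param min_intensity Detection threshold on the background-subtracted
#'   peak pixel.
#' @param min_separation_px Minimum distance between detections.
#' @param centroid_halfwidth Half-width of the centroid window, pixels.
#' @return Tibble with `row_px`, `col_px` (0-based, sub-pixel), `intensity`
#'   (windowed background-subtracted sum), `radius_px`, `azimuth_deg`
#'   relative to the beam center. Empty when nothing is found.
#' @export
detect_spots <- function(frame, geom, background = c("median", "none"),
                         min_intensity = 5, min_separation_px = 3,
                         centroid_halfwidth = 3L) {
  background <- match.arg(background)
  if (any(frame < 0)) stop("frame must be nonnegative", call. = FALSE)
  bg <- if (background == "median") stats::median(frame) else 0
  sub <- frame - bg
  nr <- nrow(frame); nc <- ncol(frame)
  empty <- tibble::tibble(row_px = numeric(0), col_px = numeric(0),
                          intensity = numeric(0), radius_px = numeric(0),
                          azimuth_deg = numeric(0))
  if (nr < 3L || nc < 3L) return(empty)
  # 8-neighborhood local maxima on the interior
  core <- sub[2:(nr - 1), 2:(nc - 1)]
  is_max <- core >= min_intensity
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & core >= sub[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  r1 <- cand[, 1] + 1L; c1 <- cand[, 2] + 1L   # 1-based in full frame
  peak <- sub[cbind(r1, c1)]
  ord <- order(-peak, r1, c1)
  r1 <- r1[ord]; c1 <- c1[ord]; peak <- peak[ord]
  # greedy non-maximum suppression
  keep <- logical(length(r1))
  for (i in seq_along(r1)) {
    if (i == 1L) { keep[1] <- TRUE; next }
    kept <- which(keep)
    d2 <- (r1[kept] - r1[i])^2 + (c1[kept] - c1[i])^2
    keep[i] <- all(d2 >= min_separation_px^2)
  }
  r1 <- r1[keep]; c1 <- c1[keep]
  w <- centroid_halfwidth
  res <- purrr::map2(r1, c1, function(r, c) {
    rows <- max(1L, r - w):min(nr, r + w)
    cols <- max(1L, c - w):min(nc, c + w)
    win <- pmax(sub[rows, cols, drop = FALSE], 0)
    tot <- sum(win)
    if (tot <= 0) return(NULL)
    rr <- sum(win * (rows - 1L)) / tot       # 0-based centroid
    cc <- sum(t(win) * (cols - 1L)) / tot
    tibble::tibble(row_px = rr, col_px = cc, intensity = tot)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) return(empty)
  # second suppression pass on the refined centroids: shoulder-noise maxima
  # a few pixels from a bright peak centroid onto the same spot and must be
  # merged, keeping the brighter detection
  ord2 <- order(-out$intensity)
  out <- out[ord2, ]
  keep2 <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    if (i == 1L) { keep2[1] <- TRUE; next }
    kept <- which(keep2)
    d2 <- (out$row_px[kept] - out$row_px[i])^2 +
          (out$col_px[kept] - out$col_px[i])^2
    keep2[i] <- all(d2 >= min_separation_px^2)
  }
  out <- out[keep2, ]
  dr <- out$row_px - geom$beam_center_px[1]
  dc <- out$col_px - geom$beam_center_px[2]
  out$radius_px <- sqrt(dr^2 + dc^2)
  out$azimuth_deg <- atan2(dr, dc) * 180 / pi
  out
}

#' Detect spots in every frame of a stack
#'
#' @param stack Numeric array `rows x cols x frames`.
#' @inheritParams detect_spots
#' @param ... Passed to [detect_spots()].
#' @return Tibble of per-frame detections with a `frame` column (0-based).
#' @export
detect_spots_stack <- function(stack, geom, ...) {
  n <- dim(stack)[3]
  res <- purrr::map(seq_len(n), function(f) {
    sp <- detect_spots(stack[, , f], geom, ...)
    if (nrow(sp) > 0) sp$frame <- f - 1L
    sp
  })
  dplyr::bind_rows(res)
}

# Pipeline routing: an ambiguous assignment leaves the trajectory
# unassigned (NA, tallied upstream) instead of aborting the run.
route_radius <- function(r, rois, tolerance_px, beam = NULL, geom = NULL) {
  tryCatch(assign_ring(r, rois, tolerance_px, beam = beam, geom = geom),
           error = function(e) NA_character_)
}

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbor frame-to-frame assignment: at each frame, the
#' closest (track, detection) pairs are linked in order of increasing
#' displacement, rejecting links farther than `max_disp_px`; a track
#' survives gaps up to `memory_frames` missed frames; unmatched detections
#' start new tracks. Each trajectory is optionally routed to a ring via
#' [assign_ring()] on its mean radius.
#'
#' @param detections Tibble with columns `frame`, `row_px`, `col_px` and
#'   optionally `intensity` (e.g. from [detect_spots_stack()]).
#' @param geom A [detector_geometry()].
#' @param max_disp_px Maximum per-link displacement, pixels.
#' @param memory_frames Number of consecutive missed frames a track survives.
#' @param rois Optional list of [build_ring_roi()] candidates for ring
#'   routing.
#' @param tolerance_px Ring-assignment tolerance, pixels.
#' @param beam Optional [beam_spec()] for bandwidth-widened assignment.
#' @return Tibble with `trajectory_id`, `frame`, `row_px`, `col_px`,
#'   `intensity`, `radius_px`, `azimuth_deg` and (when `rois` given)
#'   `ring_label`, sorted by trajectory and frame.
#' @export
link_spots <- function(detections, geom, max_disp_px = 5, memory_frames = 2L,
                       rois = NULL, tolerance_px = 2, beam = NULL) {
  need <- c("frame", "row_px", "col_px")
  if (!all(need %in% names(detections))) {
    stop("detections need columns frame, row_px, col_px", call. = FALSE)
  }
  det <- dplyr::arrange(detections, .data$frame)
  if (!"intensity" %in% names(det)) det$intensity <- NA_real_
  frames <- sort(unique(det$frame))
  # active tracks: id, last row/col, last frame
  act_id <- integer(0); act_r <- numeric(0); act_c <- numeric(0)
  act_f <- integer(0)
  next_id <- 1L
  out_id <- integer(nrow(det))
  rows_by_frame <- split(seq_len(nrow(det)), det$frame)
  for (f in frames) {
    ii <- rows_by_frame[[as.character(f)]]
    # drop tracks that exceeded the gap memory
    live <- act_f >= f - memory_frames - 1L
    act_id <- act_id[live]; act_r <- act_r[live]; act_c <- act_c[live]
    act_f <- act_f[live]
    dr <- det$row_px[ii]; dc <- det$col_px[ii]
    assigned <- rep(NA_integer_, length(ii))
    if (length(act_id) > 0L && length(ii) > 0L) {
      dist <- sqrt(outer(act_r, dr, "-")^2 + outer(act_c, dc, "-")^2)
      dist[dist > max_disp_px] <- NA_real_
      while (any(is.finite(dist))) {
        k <- arrayInd(which.min(dist), dim(dist))
        ti <- k[1]; di <- k[2]
        assigned[di] <- ti
        dist[ti, ] <- NA_real_; dist[, di] <- NA_real_
      }
    }
    for (j in seq_along(ii)) {
      if (is.na(assigned[j])) {
        out_id[ii[j]] <- next_id
        act_id <- c(act_id, next_id)
        act_r <- c(act_r, dr[j]); act_c <- c(act_c, dc[j])
        act_f <- c(act_f, f)
        next_id <- next_id + 1L
      } else {
        ti <- assigned[j]
        out_id[ii[j]] <- act_id[ti]
        act_r[ti] <- dr[j]; act_c[ti] <- dc[j]; act_f[ti] <- f
      }
    }
  }
  det$trajectory_id <- out_id
  dr <- det$row_px - geom$beam_center_px[1]
  dc <- det$col_px - geom$beam_center_px[2]
  det$radius_px <- sqrt(dr^2 + dc^2)
  det$azimuth_deg <- atan2(dr, dc) * 180 / pi
  det <- dplyr::arrange(det, .data$trajectory_id, .data$frame)
  if (!is.null(rois)) {
    lab <- det |>
      dplyr::group_by(.data$trajectory_id) |>
      dplyr::summarise(mean_radius = mean(.data$radius_px)) |>
      dplyr::mutate(ring_label = vapply(.data$mean_radius, route_radius,
                                        character(1), rois = rois,
                                        tolerance_px = tolerance_px,
                                        beam = beam, geom = geom))
    det <- dplyr::left_join(det,
                            lab[, c("trajectory_id", "ring_label")],
                            by = "trajectory_id")
  }
  det[, c("trajectory_id", "frame", "row_px", "col_px", "intensity",
          "radius_px", "azimuth_deg",
          intersect("ring_label", names(det)))]
}
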