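# Two-dimensional theta-chi motion maps: histograms, projections, peaks,
# FWHM, subtraction maps and hotspot superposition.

#' Per-trajectory motion statistics for the theta-chi map
#'
#' Reduces each angular trajectory to one `(S_chi, S_theta)` point. The
#' default statistic is the base-10 log of the temporal MSD at a fixed lag,
#' per axis; alternatives are the net angular displacement and the fitted
#' anomalous-diffusion constant.
#'
#' @param ang Output of [to_angular()].
#' @param axis_statistic `"log10_msd"`, `"net_disp"` or `"d_alpha"`.
#' @param lag_frames Lag (in frames) for the MSD statistic.
#' @param min_frames Trajectories shorter than this are dropped.
#' @return Tibble `trajectory_id`, `s_chi`, `s_theta` (+ `ring_label` when
#'   present), with attributes `axis_statistic`, `lag_frames`, `units`.
#' @export
motion_statistics <- function(ang,
                              axis_statistic = c("log10_msd", "net_disp",
                                                 "d_alpha"),
                              lag_frames = 1L, min_frames = 5L) {
  axis_statistic <- match.arg(axis_statistic)
  stat_one <- function(g) {
    f <- switch(axis_statistic,
      log10_msd = function(x) {
        m <- mean(diff(x, lag = lag_frames)^2)
        log10(max(m, 1e-12))
      },
      net_disp = function(x) x[length(x)] - x[1],
      d_alpha = function(x) {
        cv <- compute_msd(tibble::tibble(time_s = g$time_s, chi_deg = x,
                                         theta_deg = x), "chi")
        fit_msd(cv)$D_alpha
      })
    c(f(g$chi_deg), f(g$theta_deg))
  }
  out <- ang |>
    dplyr::group_by(.data$trajectory_id) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < max(min_frames, lag_frames + 1L)) return(tibble::tibble())
      s <- stat_one(dplyr::arrange(g, .data$frame))
      res <- tibble::tibble(s_chi = s[1], s_theta = s[2])
      if ("ring_label" %in% names(g)) res$ring_label <- g$ring_label[1]
      res
    }) |>
    dplyr::ungroup()
  attr(out, "axis_statistic") <- axis_statistic
  attr(out, "lag_frames") <- lag_frames
  attr(out, "units") <- switch(axis_statistic,
                               log10_msd = "log10(deg^2)",
                               net_disp = "deg",
                               d_alpha = "deg^2/s^alpha")
  out
}

#' Shared histogram edges over pooled motion statistics
#'
#' Default binning covers the 1st--99th percentile range of the pooled
#' per-trajectory statistics with `bins` equal-width bins per axis. Fixed,
#' shared edges are required for any histogram comparison.
#'
#' @param stats_list List of [motion_statistics()] tibbles to pool.
#' @param bins Bins per axis.
#' @return List with `chi_edges`, `theta_edges`.
#' @export
motion_hist_edges <- function(stats_list, bins = 50L) {
  if (!is.data.frame(stats_list[[1]])) stats_list <- list(stats_list)
  pooled <- dplyr::bind_rows(stats_list)
  rng <- function(x) {
    q <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
    if (q[1] == q[2]) q <- q + c(-0.5, 0.5)
    q
  }
  qc <- rng(pooled$s_chi); qt <- rng(pooled$s_theta)
  list(chi_edges = seq(qc[1], qc[2], length.out = bins + 1L),
       theta_edges = seq(qt[1], qt[2], length.out = bins + 1L))
}

#' Build a 2-D theta-chi motion histogram with 1-D projections
#'
#' Bins one point per trajectory at `(S_chi, S_theta)`; the density is the
#' count array normalized to unit sum. Points outside the edge range are
#' dropped (use shared pooled edges when comparing conditions).
#'
#' @param ang Output of [to_angular()], or a precomputed
#'   [motion_statistics()] tibble.
#' @param edges Optional list with `chi_edges`, `theta_edges`; defaults to
#'   [motion_hist_edges()] of this input alone.
#' @param bins Bins per axis when `edges` is not given.
#' @inheritParams motion_statistics
#' @return Object of class `motion_hist2d`: `chi_edges`, `theta_edges`,
#'   `counts` (chi x theta matrix), `density`, `chi_proj` and `theta_proj`
#'   (tibbles `center`, `count`, `density`), `n_points`, `metadata`.
#' @export
build_motion_hist <- function(ang, edges = NULL, bins = 50L,
                              axis_statistic = "log10_msd", lag_frames = 1L,
                              min_frames = 5L) {
  st <- if (all(c("s_chi", "s_theta") %in% names(ang))) ang
        else motion_statistics(ang, axis_statistic, lag_frames, min_frames)
  if (nrow(st) == 0L) stop("no trajectories to bin", call. = FALSE)
  if (is.null(edges)) edges <- motion_hist_edges(st, bins)
  ce <- edges$chi_edges; te <- edges$theta_edges
  ic <- findInterval(st$s_chi, ce, rightmost.closed = TRUE)
  it <- findInterval(st$s_theta, te, rightmost.closed = TRUE)
  ok <- ic >= 1 & ic <= length(ce) - 1 & it >= 1 & it <= length(te) - 1
  counts <- matrix(0L, length(ce) - 1L, length(te) - 1L)
  for (j in which(ok)) counts[ic[j], it[j]] <- counts[ic[j], it[j]] + 1L
  total <- sum(counts)
  if (total == 0L) stop("all points fell outside the histogram edges",
                        call. = FALSE)
  density <- counts / total
  centers <- function(e) (e[-1] + e[-length(e)]) / 2
  structure(list(
    chi_edges = ce, theta_edges = te, counts = counts, density = density,
    chi_proj = tibble::tibble(center = centers(ce),
                              count = rowSums(counts),
                              density = rowSums(density)),
    theta_proj = tibble::tibble(center = centers(te),
                                count = colSums(counts),
                                density = colSums(density)),
    n_points = total, n_dropped = sum(!ok),
    metadata = list(axis_statistic = attr(st, "axis_statistic"),
                    lag_frames = attr(st, "lag_frames"),
                    units = attr(st, "units"),
                    angular_convention = "dchi = d(azimuth); dtheta = 0.5 d(2theta)")),
    class = "motion_hist2d")
}

#' @export
print.motion_hist2d <- function(x, ...) {
  cat(sprintf("<motion_hist2d> %d x %d bins, %d trajectories (%d outside range), statistic %s\n",
              nrow(x$counts), ncol(x$counts), x$n_points, x$n_dropped,
              x$metadata$axis_statistic %||% "?"))
  invisible(x)
}

same_edges <- function(a, b, tol = 1e-12) {
  length(a$chi_edges) == length(b$chi_edges) &&
    length(a$theta_edges) == length(b$theta_edges) &&
    max(abs(a$chi_edges - b$chi_edges)) <= tol &&
    max(abs(a$theta_edges - b$theta_edges)) <= tol
}

#' Peak position and FWHM of a 1-D histogram
#'
#' The peak is the center of the maximal bin refined by three-point
#' parabolic interpolation; the FWHM comes from linear interpolation of the
#' half-maximum crossings on each side. A plateau maximum resolves to the
#' leftmost maximal bin (with a warning); a single occupied bin reports one
#' bin width.
#'
#' @param hist_1d Tibble with `center` and a value column (`density` or
#'   `count`), at least 3 bins.
#' @return One-row tibble `peak`, `fwhm`.
#' @export
peak_and_fwhm <- function(hist_1d) {
  stopifnot(all(c("center") %in% names(hist_1d)), nrow(hist_1d) >= 3L)
  val_col <- intersect(c("density", "count"), names(hist_1d))[1]
  if (is.na(val_col)) stop("need a density or count column", call. = FALSE)
  x <- hist_1d$center; y <- hist_1d[[val_col]]
  if (all(y == 0)) stop("histogram has no counts", call. = FALSE)
  imax <- which(y == max(y))
  plateau <- length(imax) > 1L
  if (plateau) {
    warning("plateau maximum: using leftmost maximal bin")
  }
  i <- imax[1]
  bw <- x[2] - x[1]
  peak <- x[i]
  if (!plateau && i > 1L && i < length(y)) {
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (denom < 0) peak <- x[i] + 0.5 * bw * (y[i - 1] - y[i + 1]) / denom
  }
  if (sum(y > 0) == 1L) {
    return(tibble::tibble(peak = peak, fwhm = bw))
  }
  half <- max(y) / 2
  left <- NA_real_; right <- NA_real_
  for (j in seq_len(i - 1)) {      # last upward crossing left of the peak
    if (y[j] < half && y[j + 1] >= half) {
      left <- x[j] + bw * (half - y[j]) / (y[j + 1] - y[j])
    }
  }
  for (j in i:(length(y) - 1)) {   # first downward crossing right of the peak
    if (y[j] >= half && y[j + 1] < half) {
      right <- x[j] + bw * (half - y[j]) / (y[j + 1] - y[j])
      break
    }
  }
  if (is.na(left)) left <- x[1] - bw / 2
  if (is.na(right)) right <- x[length(x)] + bw / 2
  tibble::tibble(peak = peak, fwhm = right - left)
}

#' Subtract two motion histograms
#'
#' Per-bin difference of the unit-normalized densities (`a - b`); the total
#' therefore sums to 0, and positive mass marks enrichment under condition
#' a. Bin edges must be identical; no resampling is attempted.
#'
#' @param hist_a,hist_b [build_motion_hist()] objects with identical edges.
#' @return Object of class `motion_diff2d`: `chi_edges`, `theta_edges`,
#'   `diff` (matrix), `chi_proj`/`theta_proj` difference projections.
#' @export
subtract_hists <- function(hist_a, hist_b) {
  stopifnot(inherits(hist_a, "motion_hist2d"), inherits(hist_b, "motion_hist2d"))
  if (!same_edges(hist_a, hist_b)) {
    stop("histogram edges differ: rebuild both with shared edges",
         call. = FALSE)
  }
  d <- hist_a$density - hist_b$density
  structure(list(chi_edges = hist_a$chi_edges,
                 theta_edges = hist_a$theta_edges, diff = d,
                 chi_proj = tibble::tibble(center = hist_a$chi_proj$center,
                                           diff = rowSums(d)),
                 theta_proj = tibble::tibble(center = hist_a$theta_proj$center,
                                             diff = colSums(d)),
                 metadata = hist_a$metadata),
            class = "motion_diff2d")
}

#' Hotspot superposition across conditions
#'
#' For each condition, selects the occupied bins whose density reaches the
#' given quantile (computed over occupied bins; quantile 0 selects every
#' occupied bin), reports the density-weighted hotspot centroid, and the
#' pairwise centroid displacements between conditions.
#'
#' @param hists Named list of [build_motion_hist()] objects sharing edges.
#' @param quantile Density quantile defining a hotspot bin.
#' @return List of class `hotspot_report`: `hotspots` (tibble `condition`,
#'   `chi`, `theta`, `density`), `centroids` (tibble `condition`, `chi`,
#'   `theta`), `displacements` (tibble `from`, `to`, `d_chi`, `d_theta`).
#' @export
superpose_hotspots <- function(hists, quantile = 0.90) {
  stopifnot(length(hists) >= 1L)
  if (is.null(names(hists)) || any(names(hists) == "")) {
    names(hists) <- paste0("condition_", seq_along(hists))
  }
  ref <- hists[[1]]
  for (h in hists) {
    if (!same_edges(ref, h)) stop("histogram edges differ", call. = FALSE)
  }
  centers <- function(e) (e[-1] + e[-length(e)]) / 2
  cc <- centers(ref$chi_edges); tc <- centers(ref$theta_edges)
  hot <- purrr::imap(hists, function(h, nm) {
    dens <- h$density
    occ <- dens > 0
    thr <- stats::quantile(dens[occ], quantile, names = FALSE)
    sel <- which(occ & dens >= thr, arr.ind = TRUE)
    tibble::tibble(condition = nm, chi = cc[sel[, 1]], theta = tc[sel[, 2]],
                   density = dens[sel])
  })
  hot <- dplyr::bind_rows(hot)
  cent <- hot |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(chi = sum(.data$chi * .data$density) / sum(.data$density),
                     theta = sum(.data$theta * .data$density) / sum(.data$density))
  nm <- cent$condition
  pairs <- if (length(nm) > 1L) {
    idx <- utils::combn(length(nm), 2)
    tibble::tibble(from = nm[idx[1, ]], to = nm[idx[2, ]],
                   d_chi = cent$chi[idx[2, ]] - cent$chi[idx[1, ]],
                   d_theta = cent$theta[idx[2, ]] - cent$theta[idx[1, ]])
  } else tibble::tibble(from = character(0), to = character(0),
                        d_chi = numeric(0), d_theta = numeric(0))
  structure(list(hotspots = hot, centroids = cent, displacements = pairs),
            class = "hotspot_report")
}
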