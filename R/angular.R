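# Angular (twisting/bending) trajectories and anomalous-diffusion MSD fits.

wrap_deg <- function(x) ((x + 180) %% 360) - 180

#' Decompose spot trajectories into twisting and bending angles
#'
#' Per step, the twisting increment is the signed azimuthal displacement
#' about the beam axis (`d chi = d azimuth`, wrapped to (-180, 180]); the
#' bending increment is half the change of the scattering angle
#' (`d theta = 0.5 * d(2 theta)`, with
#' `2 theta = atan(radius_mm / distance_mm)`), reflecting that a crystal
#' tilt of delta deflects the Bragg-reflected ray by 2 delta. Both are
#' accumulated from 0 at the trajectory start, in degrees.
#'
#' @param trajectories Tibble with `frame`, `row_px`, `col_px` and
#'   optionally `trajectory_id` (one trajectory assumed when absent); other
#'   columns such as `ring_label` are carried through.
#' @param geom A [detector_geometry()] (beam center, distance, pixel pitch,
#'   frame interval).
#' @return Tibble with `trajectory_id`, `frame`, `time_s` (from trajectory
#'   start), `chi_deg`, `theta_deg`, plus any carried ring label.
#' @export
to_angular <- function(trajectories, geom) {
  tr <- trajectories
  if (!"trajectory_id" %in% names(tr)) tr$trajectory_id <- 1L
  stopifnot(all(c("frame", "row_px", "col_px") %in% names(tr)))
  dr <- tr$row_px - geom$beam_center_px[1]
  dc <- tr$col_px - geom$beam_center_px[2]
  radius <- sqrt(dr^2 + dc^2)
  if (any(radius <= 0)) {
    stop("spot at zero radius: azimuth undefined", call. = FALSE)
  }
  azim <- atan2(dr, dc) * 180 / pi
  two_theta <- atan(radius * geom$pixel_pitch_mm / geom$distance_mm) * 180 / pi
  tr$..azim <- azim; tr$..tth <- two_theta
  keep_lab <- intersect("ring_label", names(tr))
  out <- tr |>
    dplyr::group_by(.data$trajectory_id) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 2L) {
        stop("trajectory shorter than 2 frames has no angular decomposition",
             call. = FALSE)
      }
      g <- dplyr::arrange(g, .data$frame)
      dchi <- wrap_deg(diff(g$..azim))
      dtheta <- 0.5 * diff(g$..tth)
      res <- tibble::tibble(frame = g$frame,
                            time_s = (g$frame - g$frame[1]) * geom$frame_interval_s,
                            chi_deg = c(0, cumsum(dchi)),
                            theta_deg = c(0, cumsum(dtheta)))
      for (cl in keep_lab) res[[cl]] <- g[[cl]]
      res
    }) |>
    dplyr::ungroup()
  out
}

#' Filter trajectories by on-detector lifetime
#'
#' Lifetime filtering separates fast- and slow-moving populations by the
#' duration of their diffraction spots. Lifetime is counted in frames from
#' appearance to disappearance (inclusive).
#'
#' @param trajectories Tibble with `trajectory_id` and `frame`.
#' @param min_frames,max_frames Inclusive lifetime bounds
#'   (`min_frames <= max_frames`).
#' @return The surviving rows; attribute `lifetime_counts` holds
#'   `c(total, kept, dropped)` trajectory counts.
#' @export
filter_by_lifetime <- function(trajectories, min_frames = 0, max_frames = Inf) {
  if (min_frames > max_frames) stop("min_frames > max_frames", call. = FALSE)
  lt <- trajectories |>
    dplyr::group_by(.data$trajectory_id) |>
    dplyr::summarise(lifetime = max(.data$frame) - min(.data$frame) + 1L)
  keep_ids <- lt$trajectory_id[lt$lifetime >= min_frames &
                               lt$lifetime <= max_frames]
  out <- trajectories[trajectories$trajectory_id %in% keep_ids, ]
  attr(out, "lifetime_counts") <- c(total = nrow(lt), kept = length(keep_ids),
                                    dropped = nrow(lt) - length(keep_ids))
  out
}

#' Trajectory lifetimes
#'
#' @param trajectories Tibble with `trajectory_id` and `frame`.
#' @return Tibble `trajectory_id`, `lifetime` (frames).
#' @export
trajectory_lifetimes <- function(trajectories) {
  trajectories |>
    dplyr::group_by(.data$trajectory_id) |>
    dplyr::summarise(lifetime = max(.data$frame) - min(.data$frame) + 1L) |>
    dplyr::ungroup()
}

msd_series <- function(x, max_lag) {
  n <- length(x)
  vapply(seq_len(max_lag), function(m) {
    mean((x[(1 + m):n] - x[1:(n - m)])^2)
  }, numeric(1))
}

#' Temporal mean squared displacement of one angular trajectory
#'
#' Time-averaged single-trajectory MSD:
#' `delta^2(m dt) = mean_t [x(t + m dt) - x(t)]^2` for lags
#' `m = 1 ... floor(n/4)` (longer lags are pair-starved).
#'
#' @param ang Tibble for a single trajectory with `time_s`, `chi_deg`,
#'   `theta_deg` (length >= 3), regularly sampled.
#' @param axis `"chi"`, `"theta"`, or `"both"` (sum of the per-axis squared
#'   displacements).
#' @param max_lag_frames Largest lag; default `floor(n/4)`.
#' @return Tibble of class `msd_curve` with `lag_s`, `msd` (deg^2),
#'   `n_pairs`.
#' @export
compute_msd <- function(ang, axis = c("chi", "theta", "both"),
                        max_lag_frames = NULL) {
  axis <- match.arg(axis)
  n <- nrow(ang)
  if (n < 3L) stop("trajectory too short for an MSD (need >= 3 points)",
                   call. = FALSE)
  if (is.null(max_lag_frames)) max_lag_frames <- max(1L, n %/% 4L)
  max_lag_frames <- min(as.integer(max_lag_frames), n - 1L)
  dt <- (ang$time_s[n] - ang$time_s[1]) / (n - 1)
  msd <- switch(axis,
    chi = msd_series(ang$chi_deg, max_lag_frames),
    theta = msd_series(ang$theta_deg, max_lag_frames),
    both = msd_series(ang$chi_deg, max_lag_frames) +
           msd_series(ang$theta_deg, max_lag_frames))
  structure(tibble::tibble(lag_s = seq_len(max_lag_frames) * dt, msd = msd,
                           n_pairs = n - seq_len(max_lag_frames)),
            class = c("msd_curve", "tbl_df", "tbl", "data.frame"))
}

#' Fit the anomalous-diffusion model to an MSD curve
#'
#' Least squares of `delta^2(t) = D_alpha t^alpha + 2 beta^2` with
#' `D_alpha >= 0` and `beta^2 >= 0`; `beta` is a measurement-error term. The
#' regime is subdiffusion for `alpha < 1`, superdiffusion for `alpha > 1`;
#' estimates within `regime_tol` of 1 are labeled `"normal"`.
#'
#' @param curve A [compute_msd()] result (>= 4 points).
#' @param regime_tol Classification half-width around `alpha = 1`.
#' @return Object of class `msd_fit`: `D_alpha` (deg^2/s^alpha), `alpha`,
#'   `beta` (deg), `regime`, `converged` (non-convergence is flagged, not
#'   raised), `residual_norm`.
#' @export
fit_msd <- function(curve, regime_tol = 0.05) {
  if (nrow(curve) < 4L) stop("need at least 4 MSD points", call. = FALSE)
  lag <- curve$lag_s; y <- curve$msd
  if (all(y <= 0)) {
    # stationary trajectory: zero displacement at every lag
    return(structure(list(D_alpha = 0, alpha = NA_real_, beta = 0,
                          regime = "stationary", converged = TRUE,
                          residual_norm = 0, curve = curve),
                     class = "msd_fit"))
  }
  # log-log initialisation on the positive early lags
  pos <- y > 0
  lf <- stats::lm(log(y[pos]) ~ log(lag[pos]))
  a0 <- min(max(stats::coef(lf)[2], 0.1), 3)
  d0 <- max(exp(stats::coef(lf)[1]), 1e-12)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ D * lag^alpha + 2 * beta2,
                      start = list(D = d0, alpha = a0, beta2 = 0),
                      lower = c(0, 1e-3, 0), upper = c(Inf, 5, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(D_alpha = NA_real_, alpha = NA_real_,
                          beta = NA_real_, regime = NA_character_,
                          converged = FALSE, residual_norm = NA_real_,
                          curve = curve),
                     class = "msd_fit"))
  }
  cf <- stats::coef(fit)
  alpha <- cf[["alpha"]]
  regime <- if (abs(alpha - 1) <= regime_tol) "normal"
            else if (alpha < 1) "subdiffusion" else "superdiffusion"
  structure(list(D_alpha = cf[["D"]], alpha = alpha,
                 beta = sqrt(cf[["beta2"]]), regime = regime,
                 converged = TRUE,
                 residual_norm = sqrt(mean(stats::residuals(fit)^2)),
                 curve = curve),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("<msd_fit> D_alpha = %.4g deg^2/s^a, alpha = %.3f, beta = %.4g deg [%s]\n",
              x$D_alpha, x$alpha, x$beta, x$regime))
  invisible(x)
}

#' Ensemble-averaged MSD over many trajectories
#'
#' Averages the temporal MSD curves of all trajectories long enough to
#' contribute every requested lag (equal weight per trajectory). The
#' ensemble curve is far less noisy than any single-trajectory curve and is
#' the robust route to an ensemble diffusion constant.
#'
#' @param ang Output of [to_angular()] (many trajectories).
#' @param axis Axis passed to [compute_msd()].
#' @param max_lag_frames Largest lag, frames.
#' @return An `msd_curve` tibble (`lag_s`, `msd`, `n_pairs` = number of
#'   contributing trajectories), fit-ready via [fit_msd()].
#' @export
ensemble_msd <- function(ang, axis = c("chi", "theta", "both"),
                         max_lag_frames = 100L) {
  axis <- match.arg(axis)
  curves <- ang |>
    dplyr::group_by(.data$trajectory_id) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) <= max_lag_frames) return(NULL)
      compute_msd(g, axis, max_lag_frames)
    })
  curves <- purrr::compact(curves)
  if (length(curves) == 0L) {
    stop("no trajectory long enough for the requested lags", call. = FALSE)
  }
  m <- rowMeans(vapply(curves, function(cv) cv$msd,
                       numeric(max_lag_frames)))
  structure(tibble::tibble(lag_s = curves[[1]]$lag_s, msd = m,
                           n_pairs = length(curves)),
            class = c("msd_curve", "tbl_df", "tbl", "data.frame"))
}

#' Per-trajectory MSD fits for a set of angular trajectories
#'
#' @param ang Output of [to_angular()] (many trajectories).
#' @param axis Axis passed to [compute_msd()].
#' @param min_frames Trajectories shorter than this are skipped.
#' @param max_lag_frames Passed to [compute_msd()].
#' @return Tibble with one row per fitted trajectory: `trajectory_id`,
#'   `ring_label` (if present), `n_frames`, `D_alpha`, `alpha`, `beta`,
#'   `regime`, `converged`.
#' @export
fit_msd_trajectories <- function(ang, axis = c("chi", "theta", "both"),
                                 min_frames = 8L, max_lag_frames = NULL) {
  axis <- match.arg(axis)
  ang |>
    dplyr::group_by(.data$trajectory_id) |>
    dplyr::group_modify(function(g, key) {
      # the anomalous-diffusion fit needs >= 4 MSD lags, i.e. >= 16 frames
      if (nrow(g) < max(min_frames, 16L)) return(tibble::tibble())
      ft <- fit_msd(compute_msd(g, axis, max_lag_frames))
      res <- tibble::tibble(n_frames = nrow(g), D_alpha = ft$D_alpha,
                            alpha = ft$alpha, beta = ft$beta,
                            regime = ft$regime, converged = ft$converged)
      if ("ring_label" %in% names(g)) res$ring_label <- g$ring_label[1]
      res
    }) |>
    dplyr::ungroup()
}
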