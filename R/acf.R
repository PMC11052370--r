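# Per-pixel intensity autocorrelation analysis (the blinking observable).

#' Extract per-pixel intensity traces from an image stack
#'
#' @param stack Integer array `rows x cols x frames` of photon counts.
#' @param roi A [build_ring_roi()] whose pixels to extract (0-based indices).
#' @return A tibble, one row per ROI pixel in row-major order, with columns
#'   `row`, `col` and the list-column `intensity` (integer vector per pixel,
#'   length = number of frames).
#' @export
extract_pixel_traces <- function(stack, roi) {
  stopifnot(inherits(roi, "ring_roi"))
  d <- dim(stack)
  if (length(d) != 3L) stop("stack must be a rows x cols x frames array",
                            call. = FALSE)
  if (d[3] < 2L) stop("stack needs at least 2 frames", call. = FALSE)
  px <- roi$pixels
  if (any(px$row > d[1] - 1L) || any(px$col > d[2] - 1L)) {
    stop(sprintf("ROI exceeds stack dimensions (%d x %d)", d[1], d[2]),
         call. = FALSE)
  }
  traces <- purrr::map2(px$row, px$col,
                        function(r, c) as.numeric(stack[r + 1L, c + 1L, ]))
  tibble::tibble(row = px$row, col = px$col, intensity = traces)
}

#' Intensity autocorrelation function of one pixel trace
#'
#' Computes `ACF(tau) = <I(t) I(t + tau)> / <I(t)^2>` on a photon-count
#' trace: for lag `m` the numerator averages the `n - m` available products
#' while the denominator is the full-trace mean of `I^2`, so `ACF(0) = 1`
#' exactly for any nonzero trace.
#'
#' @param intensity Numeric vector of photon counts (length >= 2, not
#'   identically zero).
#' @param frame_interval_s Seconds per frame (converts lags to seconds).
#' @param max_lag_frames Largest lag in frames; defaults to `n %/% 4`
#'   (longer lags are pair-starved).
#' @return A tibble of class `acf_curve` with columns `lag_s`, `acf`,
#'   `n_pairs`, including the lag-0 row.
#' @export
compute_acf <- function(intensity, frame_interval_s, max_lag_frames = NULL) {
  n <- length(intensity)
  if (n < 2L) stop("trace too short for an ACF", call. = FALSE)
  if (all(intensity == 0)) {
    stop("degenerate all-zero trace: ACF undefined", call. = FALSE)
  }
  if (is.null(max_lag_frames)) max_lag_frames <- n %/% 4L
  max_lag_frames <- as.integer(max_lag_frames)
  if (max_lag_frames < 1L || max_lag_frames >= n) {
    stop("max_lag_frames must be in [1, length - 1]", call. = FALSE)
  }
  denom <- mean(intensity^2)
  vals <- vapply(0:max_lag_frames, function(m) {
    if (m == 0L) return(1)
    mean(intensity[1:(n - m)] * intensity[(1 + m):n]) / denom
  }, numeric(1))
  structure(tibble::tibble(lag_s = (0:max_lag_frames) * frame_interval_s,
                           acf = vals,
                           n_pairs = n - (0:max_lag_frames)),
            class = c("acf_curve", "tbl_df", "tbl", "data.frame"))
}

new_acf_fit <- function(k, A, T, converged, residual_norm, curve = NULL,
                        weighted = FALSE, mean_curve = NULL) {
  accepted <- isTRUE(converged) && is.finite(k) && is.finite(A) &&
    is.finite(T) && k > 0 && A > 0 && T > 0
  structure(list(k = k, A = A, T = T, accepted = accepted,
                 converged = converged, residual_norm = residual_norm,
                 curve = curve, weighted = weighted, mean_curve = mean_curve),
            class = "acf_fit")
}

#' @export
print.acf_fit <- function(x, ...) {
  cat(sprintf("<acf_fit%s> k = %.4g, A = %.4g, T = %.4g /s [%s]\n",
              if (x$weighted) " (weighted mean curve)" else "",
              x$k, x$A, x$T,
              if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

acf_fit_starts <- function(lag, val) {
  k0 <- min(val)
  a0 <- max(val[1] - k0, 1e-6)
  target <- k0 + a0 / exp(1)
  below <- which(val <= target)
  t0 <- if (length(below) > 0) 1 / lag[below[1]] else 2 / (lag[1] + lag[length(lag)])
  if (!is.finite(t0) || t0 <= 0) t0 <- 1 / stats::median(lag)
  # deterministic multi-start: jitter the decay-rate guess over two decades
  lapply(c(1, 0.3, 3, 0.1, 10), function(f) c(k = k0, A = a0, T = t0 * f))
}

fit_exp_curve <- function(lag, val, weights = NULL) {
  starts <- acf_fit_starts(lag, val)
  w <- if (is.null(weights)) rep(1, length(lag)) else weights
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(val ~ k + A * exp(-T * lag),
                        start = as.list(st), weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  best
}

#' Fit a single-exponential decay to an ACF curve
#'
#' Nonlinear least squares of `ACF = k + A exp(-T t)` over the positive lags
#' (the lag-0 point, 1 by construction, is excluded). A fit is `accepted`
#' only when it converged with `k > 0`, `A > 0` and `T > 0`; failures are
#' encoded in the flags, never raised.
#'
#' @param curve An [compute_acf()] result (or any data frame with `lag_s`
#'   and `acf` columns; needs at least 4 positive lags).
#' @return An object of class `acf_fit` with elements `k`, `A`, `T` (1/s),
#'   `accepted`, `converged`, `residual_norm`.
#' @export
fit_acf_exponential <- function(curve) {
  pos <- curve$lag_s > 0
  lag <- curve$lag_s[pos]; val <- curve$acf[pos]
  if (length(lag) < 4L) stop("need at least 4 positive lags", call. = FALSE)
  best <- fit_exp_curve(lag, val)
  if (is.null(best)) {
    return(new_acf_fit(NA_real_, NA_real_, NA_real_, FALSE, NA_real_, curve))
  }
  cf <- stats::coef(best$fit)
  new_acf_fit(cf[["k"]], cf[["A"]], cf[["T"]], TRUE,
              sqrt(mean(stats::residuals(best$fit)^2)), curve)
}

#' Weighted exponential fit of the pixel-averaged ACF
#'
#' Averages the accepted per-pixel ACF curves lag by lag and fits the
#' exponential by weighted least squares, with weights `1 / SE^2` from the
#' across-pixel standard error at each lag (lags with zero SE receive the
#' largest finite weight present).
#'
#' @param curves List of [compute_acf()] results sharing the same lag grid
#'   (at least 2).
#' @return An `acf_fit` whose `mean_curve` element is a tibble with `lag_s`,
#'   `mean_acf`, `se`, `weight`.
#' @export
fit_averaged_acf <- function(curves) {
  if (length(curves) < 2L) {
    stop("need at least 2 accepted curves to average", call. = FALSE)
  }
  lag <- curves[[1]]$lag_s
  for (cv in curves) {
    if (length(cv$lag_s) != length(lag) || any(cv$lag_s != lag)) {
      stop("curves must share one lag grid", call. = FALSE)
    }
  }
  vals <- vapply(curves, function(cv) cv$acf, numeric(length(lag)))
  m <- rowMeans(vals)
  se <- apply(vals, 1, stats::sd) / sqrt(length(curves))
  w <- ifelse(se > 0, 1 / se^2, NA_real_)
  if (all(is.na(w))) {
    w <- rep(1, length(lag))
  } else if (any(is.na(w))) {
    w[is.na(w)] <- max(w, na.rm = TRUE)
  }
  pos <- lag > 0
  best <- fit_exp_curve(lag[pos], m[pos], w[pos])
  mean_curve <- tibble::tibble(lag_s = lag, mean_acf = m, se = se, weight = w)
  if (is.null(best)) {
    return(new_acf_fit(NA_real_, NA_real_, NA_real_, FALSE, NA_real_,
                       weighted = TRUE, mean_curve = mean_curve))
  }
  cf <- stats::coef(best$fit)
  new_acf_fit(cf[["k"]], cf[["A"]], cf[["T"]], TRUE,
              sqrt(mean(stats::residuals(best$fit)^2)),
              weighted = TRUE, mean_curve = mean_curve)
}

#' Per-pixel ACF decay constants over a ring ROI
#'
#' The blinking workhorse: extracts every ROI pixel trace, computes its ACF
#' and exponential fit, and tallies exclusions. All-zero (degenerate) pixels
#' are excluded and counted, never fitted.
#'
#' @param stack Integer array `rows x cols x frames`.
#' @param roi A [build_ring_roi()].
#' @param frame_interval_s Seconds per frame.
#' @param max_lag_frames Passed to [compute_acf()].
#' @return A tibble of class `dxb_pixel_fits`, one row per ROI pixel:
#'   `row`, `col`, `ring_label`, `k`, `A`, `T`, `accepted`, `residual_norm`,
#'   `degenerate`. Attribute `counts` holds
#'   `c(attempted, accepted, rejected, degenerate)` (accepted + rejected +
#'   degenerate = attempted).
#' @export
dxb_fit_pixels <- function(stack, roi, frame_interval_s,
                           max_lag_frames = NULL) {
  traces <- extract_pixel_traces(stack, roi)
  rows <- purrr::pmap(traces, function(row, col, intensity) {
    if (all(intensity == 0)) {
      return(tibble::tibble(row = row, col = col, ring_label = roi$label,
                            k = NA_real_, A = NA_real_, T = NA_real_,
                            accepted = FALSE, residual_norm = NA_real_,
                            degenerate = TRUE))
    }
    cv <- compute_acf(intensity, frame_interval_s, max_lag_frames)
    ft <- fit_acf_exponential(cv)
    tibble::tibble(row = row, col = col, ring_label = roi$label,
                   k = ft$k, A = ft$A, T = ft$T, accepted = ft$accepted,
                   residual_norm = ft$residual_norm, degenerate = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  counts <- c(attempted = nrow(out), accepted = sum(out$accepted),
              rejected = sum(!out$accepted & !out$degenerate),
              degenerate = sum(out$degenerate))
  attr(out, "counts") <- counts
  class(out) <- c("dxb_pixel_fits", class(out))
  out
}
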