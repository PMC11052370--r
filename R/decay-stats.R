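# Decay-constant distribution statistics: box summaries, two-Gaussian
# mobility decomposition, rank-sum comparisons, radiation-damage check.

decay_values <- function(sample) {
  v <- if (is.data.frame(sample)) {
    col <- intersect(c("value", "T"), names(sample))[1]
    if (is.na(col)) stop("sample needs a `value` (or `T`) column", call. = FALSE)
    sample[[col]]
  } else as.numeric(sample)
  v <- v[is.finite(v)]
  v
}

#' Five-number summary of a decay-constant sample
#'
#' Minimum, 25th, 50th and 75th percentiles and maximum, with quantiles by
#' linear interpolation between order statistics (type 7).
#'
#' @param sample Numeric vector of decay constants (1/s), or a data frame
#'   with a `value` (or `T`) column.
#' @return One-row tibble with `min`, `q25`, `median`, `q75`, `max`, `n`.
#' @export
decay_stats <- function(sample) {
  v <- decay_values(sample)
  if (length(v) == 0L) stop("empty decay sample", call. = FALSE)
  q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  tibble::tibble(min = q[1], q25 = q[2], median = q[3], q75 = q[4],
                 max = q[5], n = length(v))
}

fd_bins <- function(v) {
  bw <- 2 * stats::IQR(v) / length(v)^(1 / 3)
  if (bw <= 0) return(10L)
  max(5L, ceiling(diff(range(v)) / bw))
}

#' Two-Gaussian decomposition of a decay-constant histogram
#'
#' Bins the decay constants and fits the bin counts with the sum of two
#' Gaussian curves by least squares (deterministic multi-start). The
#' components are ordered so component 1 is the low-mobility group (smaller
#' mean); the percentage of the total fitted area in each component comes
#' from the analytic areas `amplitude * sd * sqrt(2 pi)`.
#'
#' @param sample Numeric vector (or data frame with `value` column) of decay
#'   constants; needs at least 50 values.
#' @param n_bins Number of histogram bins; default Freedman--Diaconis.
#' @return An object of class `gaussian_pair`: list with `mu`, `sigma`,
#'   `amplitude` (length-2, ordered), `pct` (area percentages summing to
#'   100), `converged`, `histogram` (tibble `center`, `count`), and
#'   `fitted` (tibble `center`, `fit`, `fit1`, `fit2` for overlay).
#' @export
fit_two_gaussians <- function(sample, n_bins = NULL) {
  v <- decay_values(sample)
  if (length(v) < 50L) stop("need at least 50 values for a mixture fit",
                            call. = FALSE)
  if (is.null(n_bins)) n_bins <- fd_bins(v)
  breaks <- seq(min(v), max(v), length.out = n_bins + 1L)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  x <- h$mids; y <- h$counts
  # multi-start: split the sample at several quantiles for initial guesses
  starts <- lapply(c(0.5, 0.3, 0.7, 0.4, 0.6), function(q) {
    cut <- stats::quantile(v, q)
    lo <- v[v <= cut]; hi <- v[v > cut]
    if (length(lo) < 2L || length(hi) < 2L) return(NULL)
    list(a1 = max(y) * 0.8, m1 = mean(lo), s1 = max(stats::sd(lo), 1e-6),
         a2 = max(y) * 0.8, m2 = mean(hi), s2 = max(stats::sd(hi), 1e-6))
  })
  best <- NULL
  for (st in starts) {
    if (is.null(st)) next
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)) +
            a2 * exp(-(x - m2)^2 / (2 * s2^2)),
        start = st,
        lower = c(0, min(x), 1e-8, 0, min(x), 1e-8),
        upper = c(Inf, max(x), diff(range(x)), Inf, max(x), diff(range(x))),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("two-Gaussian fit failed to converge from any start (n = ",
         length(v), ", bins = ", n_bins, ")", call. = FALSE)
  }
  cf <- stats::coef(best$fit)
  ord <- order(c(cf[["m1"]], cf[["m2"]]))
  mu <- c(cf[["m1"]], cf[["m2"]])[ord]
  sigma <- c(cf[["s1"]], cf[["s2"]])[ord]
  amp <- c(cf[["a1"]], cf[["a2"]])[ord]
  area <- amp * sigma * sqrt(2 * pi)
  pct <- 100 * area / sum(area)
  comp <- function(i, xx) amp[i] * exp(-(xx - mu[i])^2 / (2 * sigma[i]^2))
  structure(list(mu = mu, sigma = sigma, amplitude = amp, pct = pct,
                 converged = TRUE,
                 histogram = tibble::tibble(center = x, count = y),
                 fitted = tibble::tibble(center = x,
                                         fit1 = comp(1, x), fit2 = comp(2, x),
                                         fit = comp(1, x) + comp(2, x)),
                 n = length(v), n_bins = n_bins),
            class = "gaussian_pair")
}

#' @export
print.gaussian_pair <- function(x, ...) {
  cat(sprintf(
    "<gaussian_pair> group-I: %.1f%% (mu %.4g, sd %.4g); group-II: %.1f%% (mu %.4g, sd %.4g)\n",
    x$pct[1], x$mu[1], x$sigma[1], x$pct[2], x$mu[2], x$sigma[2]))
  invisible(x)
}

significance_tier <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "n.s."
}

rank_sum_exact_p <- function(ranks, n_a, w_obs) {
  idx <- utils::combn(length(ranks), n_a)
  sums <- colSums(matrix(ranks[idx], nrow = n_a))
  e_w <- n_a * mean(ranks) # = n_a (N+1)/2 without ties
  mean(abs(sums - e_w) >= abs(w_obs - e_w) - 1e-9)
}

#' Wilcoxon rank-sum comparison of two decay-constant samples
#'
#' Two-sided rank-sum test with midrank ties: exact enumeration of all rank
#' assignments when `n_a + n_b <= max_exact`, normal approximation with tie
#' correction otherwise. The significance tier uses `***` for p < 0.001
#' (the reporting threshold), `**` for p < 0.01, `*` for p < 0.05, else
#' `n.s.`.
#'
#' @param sample_a,sample_b Numeric vectors (or data frames with a `value`
#'   column); both nonempty.
#' @param max_exact Size bound for exact enumeration (default 12).
#' @return One-row tibble of class `ranksum_test` with `statistic` (rank sum
#'   of sample a), `p_value`, `method`, `tier`, `n_a`, `n_b`.
#' @export
compare_distributions <- function(sample_a, sample_b, max_exact = 12L) {
  a <- decay_values(sample_a); b <- decay_values(sample_b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  ranks <- rank(c(a, b))          # midranks for ties
  w <- sum(ranks[seq_len(n_a)])
  if (n <= max_exact) {
    p <- rank_sum_exact_p(ranks, n_a, w)
    method <- "exact"
  } else {
    e_w <- n_a * (n + 1) / 2
    ties <- table(c(a, b))
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v_w <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (v_w <= 0) {
      p <- 1
    } else {
      z <- (w - e_w) / sqrt(v_w)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  structure(tibble::tibble(statistic = w, p_value = p, method = method,
                           tier = significance_tier(p), n_a = n_a, n_b = n_b),
            class = c("ranksum_test", "tbl_df", "tbl", "data.frame"))
}

#' First-half vs second-half radiation-damage check
#'
#' Splits the movie at the midpoint (first `ceiling(n/2)` frames vs the
#' rest), runs the full ACF -> exponential-fit chain on each half over the
#' same ROI, and compares the two accepted decay-constant distributions with
#' the rank-sum test. The `damaged` flag is raised when p < 0.001.
#'
#' @param stack Integer array `rows x cols x frames` (>= 4 frames).
#' @param roi A [build_ring_roi()].
#' @param frame_interval_s Seconds per frame.
#' @param max_lag_frames Passed to [compute_acf()] (per half).
#' @param alpha Damage threshold on the p-value.
#' @return List of class `damage_check`: `first` and `second` (accepted T
#'   tibbles), `test` (the [compare_distributions()] row), `damaged`.
#' @export
radiation_damage_check <- function(stack, roi, frame_interval_s,
                                   max_lag_frames = NULL, alpha = 0.001) {
  n <- dim(stack)[3]
  if (is.na(n) || n < 4L) stop("need at least 4 frames to split", call. = FALSE)
  cut <- ceiling(n / 2)
  first <- stack[, , seq_len(cut), drop = FALSE]
  second <- stack[, , (cut + 1L):n, drop = FALSE]
  f1 <- dxb_fit_pixels(first, roi, frame_interval_s, max_lag_frames)
  f2 <- dxb_fit_pixels(second, roi, frame_interval_s, max_lag_frames)
  t1 <- f1$T[f1$accepted]; t2 <- f2$T[f2$accepted]
  if (length(t1) == 0L || length(t2) == 0L) {
    stop("no accepted fits in one movie half", call. = FALSE)
  }
  test <- compare_distributions(t1, t2)
  structure(list(first = tibble::tibble(value = t1),
                 second = tibble::tibble(value = t2),
                 test = test, damaged = test$p_value < alpha),
            class = "damage_check")
}

#' @export
print.damage_check <- function(x, ...) {
  cat(sprintf(
    "<damage_check> first half n = %d (median %.4g), second half n = %d (median %.4g), p = %.3g -> %s\n",
    nrow(x$first), stats::median(x$first$value), nrow(x$second),
    stats::median(x$second$value), x$test$p_value,
    if (x$damaged) "DAMAGED" else "ok"))
  invisible(x)
}
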