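# broom-style tidiers for the fitted-object classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ACF exponential fit
#'
#' @param x An `acf_fit` from [fit_acf_exponential()] or
#'   [fit_averaged_acf()].
#' @param ... Unused.
#' @return Tibble with one row per parameter (`k`, `A`, `T`).
#' @export
tidy.acf_fit <- function(x, ...) {
  tibble::tibble(term = c("k", "A", "T"),
                 estimate = c(x$k, x$A, x$T),
                 unit = c("", "", "1/s"))
}

#' @rdname tidy.acf_fit
#' @return For `glance()`: one-row tibble with `accepted`, `converged`,
#'   `residual_norm`, `weighted`.
#' @export
glance.acf_fit <- function(x, ...) {
  tibble::tibble(accepted = x$accepted, converged = x$converged,
                 residual_norm = x$residual_norm, weighted = x$weighted)
}

#' Tidy a two-Gaussian mobility decomposition
#'
#' @param x A `gaussian_pair` from [fit_two_gaussians()].
#' @param ... Unused.
#' @return Tibble with one row per component: `component` (`"group-I"` is
#'   the low-mobility group), `mean`, `sd`, `amplitude`, `pct` of the total
#'   fitted area.
#' @export
tidy.gaussian_pair <- function(x, ...) {
  tibble::tibble(component = c("group-I", "group-II"),
                 mean = x$mu, sd = x$sigma, amplitude = x$amplitude,
                 pct = x$pct)
}

#' @rdname tidy.gaussian_pair
#' @export
glance.gaussian_pair <- function(x, ...) {
  tibble::tibble(pct1 = x$pct[1], pct2 = x$pct[2], converged = x$converged,
                 n = x$n, n_bins = x$n_bins)
}

#' Tidy an anomalous-diffusion MSD fit
#'
#' @param x An `msd_fit` from [fit_msd()].
#' @param ... Unused.
#' @return Tibble with one row per parameter.
#' @export
tidy.msd_fit <- function(x, ...) {
  tibble::tibble(term = c("D_alpha", "alpha", "beta"),
                 estimate = c(x$D_alpha, x$alpha, x$beta),
                 unit = c("deg^2/s^alpha", "", "deg"))
}

#' @rdname tidy.msd_fit
#' @export
glance.msd_fit <- function(x, ...) {
  tibble::tibble(regime = x$regime, converged = x$converged,
                 residual_norm = x$residual_norm)
}
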