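# The two published dual-probe workflows, run end to end per ring and per
# condition, with a reconciling run report.

ring_groups <- function(rois, pool_zno = TRUE) {
  phases <- vapply(rois, `[[`, character(1), "phase")
  if (length(unique(phases)) < 2L) {
    stop("dual workflow requires rings from at least 2 distinct phases",
         call. = FALSE)
  }
  if (!pool_zno) {
    groups <- as.list(names(rois))
    names(groups) <- names(rois)
    return(groups)
  }
  groups <- list()
  for (ph in unique(phases)) {
    labs <- names(rois)[phases == ph]
    nm <- if (length(labs) == 1L) labs else {
      sprintf("%s(%s)", ph, paste(vapply(rois[labs], function(r) {
        paste(r$hkl, collapse = "")
      }, character(1)), collapse = "+"))
    }
    groups[[nm]] <- labs
  }
  groups
}

#' Run the dual-probe blinking (DXB) workflow
#'
#' For each condition movie and each ring group (by default the Au ring(s)
#' and the pooled ZnO rings are analyzed separately, so the two probe
#' domains stay independent), runs extract -> ACF -> exponential fit ->
#' distribution statistics -> two-Gaussian decomposition, then compares each
#' condition against the baseline with the rank-sum test.
#'
#' @param stacks Named list of integer arrays `rows x cols x frames`, one
#'   per condition; the first name is the baseline (e.g. ligand-free).
#' @param config List with `geom`, `rois` (and optionally `beam`), e.g. from
#'   [read_geometry_config()]; needs rings from two distinct phases.
#' @param pool_zno Pool the ZnO rings into one sample (the default for
#'   blinking analysis) or analyze each ring separately.
#' @param max_lag_frames Passed to [compute_acf()].
#' @param mixture_min_n Minimum accepted-fit count for a mixture fit.
#' @return Object of class `dxb_run`: `fits` (per-pixel tibble with
#'   `condition` and `group`), `samples` (accepted decay constants),
#'   `stats` (five-number summaries per condition x group), `mixtures`
#'   (named list of [fit_two_gaussians()] results or NULL), `comparisons`
#'   (rank-sum rows vs baseline per group), `report`.
#' @export
run_dual_dxb <- function(stacks, config, pool_zno = TRUE,
                         max_lag_frames = NULL, mixture_min_n = 50L) {
  stopifnot(is.list(stacks), length(stacks) >= 1L, !is.null(names(stacks)))
  geom <- config$geom; rois <- config$rois
  if (length(rois) < 2L) stop("config must name at least 2 rings", call. = FALSE)
  groups <- ring_groups(rois, pool_zno)
  conditions <- names(stacks)
  fits <- list(); counts <- list()
  for (cond in conditions) {
    for (g in names(groups)) {
      for (lab in groups[[g]]) {
        ft <- dxb_fit_pixels(stacks[[cond]], rois[[lab]],
                             geom$frame_interval_s, max_lag_frames)
        cnt <- attr(ft, "counts")
        ft$condition <- cond; ft$group <- g
        fits[[length(fits) + 1L]] <- ft
        counts[[length(counts) + 1L]] <- tibble::tibble(
          condition = cond, group = g, ring_label = lab,
          attempted = cnt[["attempted"]], accepted = cnt[["accepted"]],
          rejected = cnt[["rejected"]], degenerate = cnt[["degenerate"]])
      }
    }
  }
  fits <- dplyr::bind_rows(fits)
  samples <- fits |>
    dplyr::filter(.data$accepted) |>
    dplyr::select(value = "T", "condition", "group")
  stats <- samples |>
    dplyr::group_by(.data$condition, .data$group) |>
    dplyr::group_modify(function(g, key) decay_stats(g$value)) |>
    dplyr::ungroup()
  mixtures <- list()
  for (cond in conditions) for (g in names(groups)) {
    v <- samples$value[samples$condition == cond & samples$group == g]
    key <- paste(cond, g, sep = " / ")
    mixtures[[key]] <- if (length(v) >= mixture_min_n) {
      tryCatch(fit_two_gaussians(v), error = function(e) NULL)
    } else NULL
  }
  baseline <- conditions[1]
  comparisons <- list()
  for (cond in setdiff(conditions, baseline)) for (g in names(groups)) {
    a <- samples$value[samples$condition == baseline & samples$group == g]
    b <- samples$value[samples$condition == cond & samples$group == g]
    if (length(a) == 0L || length(b) == 0L) next
    cmp <- compare_distributions(a, b)
    cmp$group <- g; cmp$baseline <- baseline; cmp$condition <- cond
    comparisons[[length(comparisons) + 1L]] <- cmp
  }
  report <- list(counts = dplyr::bind_rows(counts),
                 groups = groups, baseline = baseline,
                 frame_interval_s = geom$frame_interval_s)
  structure(list(fits = fits, samples = samples, stats = stats,
                 mixtures = mixtures,
                 comparisons = dplyr::bind_rows(comparisons),
                 report = report),
            class = "dxb_run")
}

#' @export
print.dxb_run <- function(x, ...) {
  cat(sprintf("<dxb_run> %d conditions x %d groups, %d pixel fits (%d accepted)\n",
              length(unique(x$fits$condition)),
              length(x$report$groups), nrow(x$fits), sum(x$fits$accepted)))
  invisible(x)
}

#' Run the dual-probe tracking (DXT) workflow
#'
#' Per condition: spot trajectories (pre-tracked tibbles, or detected and
#' linked from a stack) are routed to rings, decomposed into
#' twisting/bending angles, lifetime-filtered, MSD-fitted, and binned into
#' theta-chi motion maps on edges shared across all conditions and rings;
#' each non-baseline condition gets a subtraction map against the baseline,
#' plus the pairwise map between the two last conditions (e.g. treatment vs
#' treatment + antagonist), and a hotspot superposition report per ring.
#'
#' @param inputs Named list, one entry per condition: either a trajectory
#'   tibble (`trajectory_id`, `frame`, `row_px`, `col_px`, `intensity`) or
#'   an image stack array. First name = baseline condition.
#' @param config List with `geom`, `beam`, `rois` (two probe phases).
#' @param i0 Optional named list of per-frame incident-intensity vectors
#'   (stack inputs only).
#' @param min_life,max_life Lifetime filter bounds, frames.
#' @param lag_frames Lag for the motion-map statistic.
#' @param bins Motion-map bins per axis.
#' @param tolerance_px Ring-assignment tolerance.
#' @param max_disp_px,memory_frames Linker parameters (stack inputs).
#' @param min_intensity Detection threshold (stack inputs).
#' @return Object of class `dxt_run`: `trajectories`, `angular`, `msd_fits`
#'   (tibbles with `condition`), `hists` (per ring: named list of
#'   [build_motion_hist()] per condition), `subtractions` (per ring: named
#'   list of [subtract_hists()] maps), `hotspots` (per ring), `report`.
#' @export
run_dual_dxt <- function(inputs, config, i0 = NULL, min_life = 5L,
                         max_life = Inf, lag_frames = 1L, bins = 50L,
                         tolerance_px = 2, max_disp_px = 5,
                         memory_frames = 2L, min_intensity = 5) {
  stopifnot(is.list(inputs), length(inputs) >= 1L, !is.null(names(inputs)))
  geom <- config$geom; rois <- config$rois; beam <- config$beam
  phases <- unique(vapply(rois, `[[`, character(1), "phase"))
  if (length(phases) < 2L) {
    stop("dual workflow requires rings from 2 distinct phases", call. = FALSE)
  }
  conditions <- names(inputs)
  if (!is.null(i0)) {
    for (cond in names(i0)) {
      if (!is.data.frame(inputs[[cond]]) && is.null(i0[[cond]])) {
        stop("missing i0 series for condition ", cond, call. = FALSE)
      }
    }
  }
  trajs <- list(); angs <- list(); msds <- list(); counts <- list()
  for (cond in conditions) {
    inp <- inputs[[cond]]
    tr <- if (is.data.frame(inp)) {
      det <- inp
      dr <- det$row_px - geom$beam_center_px[1]
      dc <- det$col_px - geom$beam_center_px[2]
      det$radius_px <- sqrt(dr^2 + dc^2)
      det$azimuth_deg <- atan2(dr, dc) * 180 / pi
      lab <- det |>
        dplyr::group_by(.data$trajectory_id) |>
        dplyr::summarise(mean_radius = mean(.data$radius_px)) |>
        dplyr::mutate(ring_label = vapply(.data$mean_radius, route_radius,
                                          character(1), rois = rois,
                                          tolerance_px = tolerance_px,
                                          beam = beam, geom = geom))
      dplyr::left_join(det, lab[, c("trajectory_id", "ring_label")],
                       by = "trajectory_id")
    } else {
      stk <- inp
      if (!is.null(i0[[cond]])) stk <- normalize_i0(stk, i0[[cond]])
      det <- detect_spots_stack(stk, geom, min_intensity = min_intensity)
      link_spots(det, geom, max_disp_px, memory_frames, rois = rois,
                 tolerance_px = tolerance_px, beam = beam)
    }
    n_total <- length(unique(tr$trajectory_id))
    tr <- tr[!is.na(tr$ring_label), ]
    n_routed <- length(unique(tr$trajectory_id))
    tr <- filter_by_lifetime(tr, min_life, max_life)
    lc <- attr(tr, "lifetime_counts")
    ang <- to_angular(tr, geom)   # carries ring_label through
    mf <- fit_msd_trajectories(ang, "both")
    tr$condition <- cond; ang$condition <- cond
    if (nrow(mf) > 0) mf$condition <- cond
    trajs[[cond]] <- tr; angs[[cond]] <- ang; msds[[cond]] <- mf
    counts[[cond]] <- tibble::tibble(
      condition = cond, tracked = n_total, routed = n_routed,
      unassigned = n_total - n_routed, kept = lc[["kept"]],
      lifetime_dropped = lc[["dropped"]])
  }
  angular <- dplyr::bind_rows(angs)
  # shared motion-map edges per ring over all conditions
  ring_labels <- sort(unique(angular$ring_label))
  hists <- list(); subtractions <- list(); hotspots <- list()
  baseline <- conditions[1]
  for (rl in ring_labels) {
    stats_by_cond <- purrr::map(conditions, function(cond) {
      a <- angular[angular$condition == cond & angular$ring_label == rl, ]
      if (nrow(a) == 0L) return(NULL)
      motion_statistics(a, lag_frames = lag_frames)
    })
    names(stats_by_cond) <- conditions
    stats_by_cond <- purrr::compact(stats_by_cond)
    if (length(stats_by_cond) == 0L) next
    edges <- motion_hist_edges(stats_by_cond, bins)
    hists[[rl]] <- purrr::map(stats_by_cond, build_motion_hist, edges = edges)
    subs <- list()
    for (cond in setdiff(names(hists[[rl]]), baseline)) {
      subs[[paste(cond, "minus", baseline)]] <-
        subtract_hists(hists[[rl]][[cond]], hists[[rl]][[baseline]])
    }
    extra <- setdiff(names(hists[[rl]]), baseline)
    if (length(extra) >= 2L) {
      a <- extra[length(extra) - 1L]; b <- extra[length(extra)]
      subs[[paste(a, "minus", b)]] <-
        subtract_hists(hists[[rl]][[a]], hists[[rl]][[b]])
    }
    subtractions[[rl]] <- subs
    hotspots[[rl]] <- superpose_hotspots(hists[[rl]])
  }
  structure(list(trajectories = dplyr::bind_rows(trajs),
                 angular = angular, msd_fits = dplyr::bind_rows(msds),
                 hists = hists, subtractions = subtractions,
                 hotspots = hotspots,
                 report = list(counts = dplyr::bind_rows(counts),
                               baseline = baseline,
                               lag_frames = lag_frames,
                               lifetime_bounds = c(min_life, max_life))),
            class = "dxt_run")
}

#' @export
print.dxt_run <- function(x, ...) {
  cat(sprintf("<dxt_run> %d conditions, %d rings mapped, %d trajectories kept\n",
              length(unique(x$trajectories$condition)), length(x$hists),
              length(unique(paste(x$trajectories$condition,
                                  x$trajectories$trajectory_id)))))
  invisible(x)
}
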