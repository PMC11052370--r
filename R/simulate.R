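# Synthetic-data generators with known ground truth for every pipeline stage.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic nanocrystal-motion generators.
#' Defaults emulate the blinking (DXB) recording protocol: 100 ms frames,
#' 2000 frames per movie.
#'
#' @param seed RNG seed (integer).
#' @param n_frames Number of frames.
#' @param frame_interval_s Seconds per frame.
#' @param d_rot Rotational diffusion coefficient, rad^2/s.
#' @param rocking_width_deg Gaussian half-width of the Bragg acceptance
#'   (rocking-curve proxy), degrees. Together with `d_rot` it sets the
#'   blinking correlation time (roughly `rocking_width^2 / d_rot`).
#' @param mean_photons Expected photon counts per frame at the exact Bragg
#'   condition.
#' @param background_photons Flat background expectation per pixel per frame.
#' @param n_crystals Number of simulated nanocrystals.
#' @param lifetime_mean_frames Mean trajectory lifetime in frames (geometric
#'   law; `Inf` = spots survive the whole movie). DXT mode only.
#' @param mixture Optional two-population spec,
#'   `list(d_rot = c(d1, d2), w = c(w1, w2))` with `w1 + w2 = 1`; crystals are
#'   split between the two rotational-diffusion coefficients.
#' @param relax_s Orientation mean-reversion time, seconds. `NULL` gives a
#'   pure Brownian orientation walk; a finite value gives an
#'   Ornstein--Uhlenbeck walk whose stationary tilt spread is
#'   `sqrt(d_rot * relax_s)` radians, so the blinking process is stationary;
#'   `"auto"` sets each crystal's relaxation time to
#'   `rocking_width^2 / d_rot` (stationary tilt spread = rocking width, so
#'   the blinking correlation time scales as `1 / d_rot`).
#' @param drift_deg_s Optional per-axis deterministic drift, degrees/s
#'   (superdiffusive control for tracking simulations).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_frames = 2000L, frame_interval_s = 0.1,
                       d_rot = 0.1, rocking_width_deg = 30,
                       mean_photons = 20, background_photons = 0.5,
                       n_crystals = 200L, lifetime_mean_frames = Inf,
                       mixture = NULL, relax_s = NULL, drift_deg_s = 0) {
  stopifnot(n_frames >= 2, frame_interval_s > 0, d_rot >= 0,
            rocking_width_deg > 0, mean_photons > 0, background_photons >= 0,
            n_crystals >= 1, lifetime_mean_frames > 0)
  if (!is.null(mixture)) {
    stopifnot(length(mixture$d_rot) == 2L, length(mixture$w) == 2L)
    if (abs(sum(mixture$w) - 1) > 1e-9) {
      stop("mixture weights must sum to 1", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 frame_interval_s = frame_interval_s, d_rot = d_rot,
                 rocking_width_deg = rocking_width_deg,
                 mean_photons = mean_photons,
                 background_photons = background_photons,
                 n_crystals = as.integer(n_crystals),
                 lifetime_mean_frames = lifetime_mean_frames,
                 mixture = mixture, relax_s = relax_s,
                 drift_deg_s = drift_deg_s),
            class = "sim_config")
}

# per-crystal relaxation times as a list (NULL entries = pure Brownian)
crystal_relax_s <- function(cfg, drot) {
  if (is.null(cfg$relax_s)) return(vector("list", length(drot)))
  if (identical(cfg$relax_s, "auto")) {
    sw <- cfg$rocking_width_deg * pi / 180
    return(as.list(sw^2 / drot))
  }
  rep(list(cfg$relax_s), length(drot))
}

per_crystal_d_rot <- function(cfg) {
  if (is.null(cfg$mixture)) return(rep(cfg$d_rot, cfg$n_crystals))
  n1 <- round(cfg$mixture$w[1] * cfg$n_crystals)
  c(rep(cfg$mixture$d_rot[1], n1), rep(cfg$mixture$d_rot[2], cfg$n_crystals - n1))
}

# One axis of an orientation walk, in radians. Pure Brownian when relax_s is
# NULL (increment variance 2*d_rot*dt); OU with stationary start otherwise.
walk_axis <- function(n, dt, d_rot, relax_s = NULL, drift_rad_s = 0) {
  if (is.null(relax_s)) {
    steps <- stats::rnorm(n - 1, mean = drift_rad_s * dt,
                          sd = sqrt(2 * d_rot * dt))
    c(0, cumsum(steps))
  } else {
    phi <- exp(-dt / relax_s)
    s_stat <- sqrt(d_rot * relax_s)
    x <- numeric(n)
    x[1] <- stats::rnorm(1, 0, s_stat)
    innov <- stats::rnorm(n - 1, 0, s_stat * sqrt(1 - phi^2))
    for (i in 2:n) x[i] <- phi * x[i - 1] + innov[i - 1]
    x + drift_rad_s * dt * (seq_len(n) - 1)
  }
}

#' Simulate nanocrystal orientation walks
#'
#' Each crystal performs independent angular random walks on two axes
#' (tilt: diffraction-angle axis; azimuth: twist about the beam axis) with
#' Gaussian per-step increments of variance `2 * d_rot * frame_interval`
#' (small-angle planar approximation). With `cfg$relax_s` set, the tilt and
#' azimuth relax toward zero (Ornstein--Uhlenbeck), giving a stationary
#' blinking process.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `crystal`, `frame` (0-based), `tilt_deg`,
#'   `azimuth_deg` and `d_rot` (the crystal's own coefficient, rad^2/s).
#' @export
simulate_orientation_walks <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(cfg$seed, {
    rad2deg <- 180 / pi
    drot <- per_crystal_d_rot(cfg)
    drift <- cfg$drift_deg_s / rad2deg
    relax <- crystal_relax_s(cfg, drot)
    out <- purrr::map(seq_len(cfg$n_crystals), function(i) {
      tilt <- walk_axis(cfg$n_frames, cfg$frame_interval_s, drot[i],
                        relax[[i]], drift)
      azim <- walk_axis(cfg$n_frames, cfg$frame_interval_s, drot[i],
                        relax[[i]], drift)
      tibble::tibble(crystal = i, frame = 0:(cfg$n_frames - 1L),
                     tilt_deg = tilt * rad2deg, azimuth_deg = azim * rad2deg,
                     d_rot = drot[i])
    })
    dplyr::bind_rows(out)
  })
}

#' Convenience detector geometry for blinking simulations
#'
#' A small square detector whose sample distance is chosen so that the
#' Au(111) ring falls at `radius_px` at the given beam energy. Keeps
#' simulated movies small while preserving realistic pixel pitch and frame
#' timing.
#'
#' @param n_px Detector edge length in pixels.
#' @param radius_px Desired Au(111) ring radius, pixels.
#' @param energy_keV Beam energy, keV.
#' @param frame_interval_s Seconds per frame.
#' @return A [detector_geometry()].
#' @export
dxb_sim_geometry <- function(n_px = 64, radius_px = 20, energy_keV = 17.7,
                             frame_interval_s = 0.1) {
  pitch <- 0.172
  d111 <- d_spacing(phase_au(), c(1, 1, 1))
  lambda <- wavelength_from_energy(energy_keV)
  two_theta <- 2 * asin(lambda / (2 * d111))
  dist <- radius_px * pitch / tan(two_theta)
  ctr <- (n_px - 1) / 2
  detector_geometry(n_px, n_px, pitch, c(ctr, ctr), dist, frame_interval_s)
}

#' Render a blinking (DXB) movie from orientation walks
#'
#' Each crystal illuminates the ring pixel nearest its initial azimuth. The
#' expected count is `mean_photons * exp(-tilt^2 / (2 * rocking_width^2))`
#' plus a flat background, Poisson-sampled per frame; the intensity
#' correlation time is therefore controlled by the rotational diffusion
#' coefficient of the walks.
#'
#' @param walks Output of [simulate_orientation_walks()].
#' @param roi A [build_ring_roi()] the crystals diffract onto.
#' @param cfg The [sim_config()] used for the walks.
#' @param geom The [detector_geometry()].
#' @param pixel_map `"azimuth"`: each crystal sits at a uniform random
#'   azimuth on the ring (offset by its own twist walk) and illuminates the
#'   nearest ROI pixel, so pixel occupancy is Poisson-like; `"one_per_pixel"`:
#'   crystals are dealt round-robin over the ROI pixels (one pixel per
#'   crystal when `n_crystals <=` pixel count), giving clean per-pixel
#'   statistics.
#' @return An object of class `dxb_movie`: list with `stack` (integer array
#'   rows x cols x frames), `pixel_map` (tibble crystal -> row, col),
#'   `noiseless` (matrix frames x crystals of expected signal counts, no
#'   background), `cfg`, `geom`, `roi_label`.
#' @export
render_dxb_movie <- function(walks, roi, cfg, geom,
                             pixel_map = c("azimuth", "one_per_pixel")) {
  stopifnot(inherits(roi, "ring_roi"), inherits(cfg, "sim_config"),
            inherits(geom, "detector_geometry"))
  pixel_map <- match.arg(pixel_map)
  n_frames <- cfg$n_frames
  tilt <- matrix(walks$tilt_deg, nrow = n_frames)     # frames x crystals
  az0 <- walks$azimuth_deg[walks$frame == 0]
  # noiseless expected signal per crystal
  lam <- cfg$mean_photons * exp(-tilt^2 / (2 * cfg$rocking_width_deg^2))
  px <- roi$pixels
  if (pixel_map == "one_per_pixel") {
    idx <- (seq_len(cfg$n_crystals) - 1L) %% nrow(px) + 1L
  } else {
    # uniform ring placement plus the crystal's own twist offset
    ring_az <- with_local_seed(cfg$seed + 3L,
                               stats::runif(cfg$n_crystals, 0, 360))
    px_az <- atan2(px$row - geom$beam_center_px[1],
                   px$col - geom$beam_center_px[2]) * 180 / pi
    idx <- vapply((ring_az + az0) %% 360, function(a) {
      d <- abs(((px_az - a + 180) %% 360) - 180)
      which.min(d)
    }, integer(1))
  }
  with_local_seed(cfg$seed + 1L, {
    stack <- array(0L, dim = c(geom$n_rows, geom$n_cols, n_frames))
    # accumulate expected counts per occupied pixel, then Poisson-sample
    for (p in unique(idx)) {
      crystals <- which(idx == p)
      lam_p <- rowSums(lam[, crystals, drop = FALSE]) + cfg$background_photons
      counts <- stats::rpois(n_frames, lam_p)
      stack[px$row[p] + 1L, px$col[p] + 1L, ] <- counts
    }
    if (cfg$background_photons > 0) {
      unocc <- setdiff(seq_len(nrow(px)), unique(idx))
      for (p in unocc) {
        stack[px$row[p] + 1L, px$col[p] + 1L, ] <-
          stats::rpois(n_frames, cfg$background_photons)
      }
    }
    structure(list(stack = stack,
                   pixel_map = tibble::tibble(crystal = seq_along(idx),
                                              row = px$row[idx],
                                              col = px$col[idx]),
                   noiseless = lam, cfg = cfg, geom = geom,
                   roi_label = roi$label),
              class = "dxb_movie")
  })
}

#' Simulate a blinking movie in one call
#'
#' Wraps [simulate_orientation_walks()] and [render_dxb_movie()].
#' @inheritParams render_dxb_movie
#' @return A `dxb_movie` (see [render_dxb_movie()]); the walks are attached
#'   as `$walks`.
#' @export
simulate_dxb_movie <- function(cfg, roi, geom,
                               pixel_map = c("azimuth", "one_per_pixel")) {
  walks <- simulate_orientation_walks(cfg)
  mv <- render_dxb_movie(walks, roi, cfg, geom, pixel_map)
  mv$walks <- walks
  mv
}

#' Theoretical intensity ACF of the stationary blinking model
#'
#' Closed-form autocorrelation of the generator's stationary blinking
#' process: an Ornstein--Uhlenbeck tilt with stationary variance
#' `s^2 = d_rot * relax_s` viewed through the Gaussian rocking transfer of
#' width `sigma = rocking_width`. With `a = s^2 / sigma^2` and
#' `rho = exp(-tau / relax_s)`,
#' `ACF(tau) = sqrt(1 + 2a) / sqrt((1 + a)^2 - a^2 rho^2)`,
#' normalized as `<I(t) I(t+tau)> / <I(t)^2>` for the noiseless intensity
#' (Poisson counting noise rescales the positive-lag curve by a constant and
#' leaves the decay constant untouched).
#'
#' @param tau_s Lag times, seconds.
#' @param cfg A [sim_config()] with `relax_s` set.
#' @return Numeric vector of ACF values.
#' @export
dxb_theoretical_acf <- function(tau_s, cfg) {
  stopifnot(inherits(cfg, "sim_config"), !is.null(cfg$relax_s))
  sw <- cfg$rocking_width_deg * pi / 180
  relax <- if (identical(cfg$relax_s, "auto")) sw^2 / cfg$d_rot else cfg$relax_s
  a <- cfg$d_rot * relax / sw^2
  rho2 <- exp(-2 * tau_s / relax)
  sqrt(1 + 2 * a) / sqrt((1 + a)^2 - a^2 * rho2)
}

#' Convenience geometry and ring pair for tracking simulations
#'
#' A square detector sized so the Au(111) ring sits at `au_radius_px`; the
#' ZnO(100) ring then falls at about 83% of that radius, keeping the two
#' probe rings well separated. 12.5 ms frames match the tracking protocol.
#'
#' @param n_px Detector edge, pixels.
#' @param au_radius_px Au(111) ring radius, pixels.
#' @param energy_keV Beam energy, keV.
#' @param frame_interval_s Seconds per frame.
#' @return A [detector_geometry()].
#' @export
dxt_sim_geometry <- function(n_px = 160, au_radius_px = 60, energy_keV = 17.7,
                             frame_interval_s = 0.0125) {
  pitch <- 0.172
  d111 <- d_spacing(phase_au(), c(1, 1, 1))
  lambda <- wavelength_from_energy(energy_keV)
  dist <- au_radius_px * pitch / tan(2 * asin(lambda / (2 * d111)))
  ctr <- (n_px - 1) / 2
  detector_geometry(n_px, n_px, pitch, c(ctr, ctr), dist, frame_interval_s)
}

#' @rdname dxt_sim_geometry
#' @param geom The geometry from `dxt_sim_geometry()`.
#' @param half_width_px Annulus half-width for the ROIs.
#' @return For `dxt_sim_rings()`: list of the Au(111) and ZnO(100) ring ROIs.
#' @export
dxt_sim_rings <- function(geom, energy_keV = 17.7, half_width_px = 2) {
  beam <- beam_spec(energy_keV)
  list(build_ring_roi(phase_au(), c(1, 1, 1), beam, geom, half_width_px),
       build_ring_roi(phase_zno(), c(1, 0, 0), beam, geom, half_width_px))
}

#' Simulate Laue-spot trajectories on two rings
#'
#' Spots are born uniformly over the movie, live a geometric number of frames
#' with the configured mean (truncated at the movie end), and perform
#' independent twisting/bending angular walks mapped to detector coordinates
#' on their assigned ring. Ground-truth identities and angular walks are
#' retained for oracle comparison.
#'
#' @param cfg A [sim_config()] (12.5 ms frames and 5000 frames emulate the
#'   tracking protocol; `n_crystals` is the number of trajectories per ring).
#' @param rings List of two [build_ring_roi()] objects (the Au-like and
#'   ZnO-like rings).
#' @param geom A [detector_geometry()].
#' @param spread_azimuth Logical; when `TRUE` (default) initial azimuths are
#'   evenly spread with random offsets (keeps simultaneously alive spots
#'   separated — the non-crossing regime).
#' @return An object of class `laue_sim`: list with `spots` (tibble
#'   `trajectory_id`, `ring_label`, `frame`, `row_px`, `col_px`, `intensity`),
#'   `truth` (tibble `trajectory_id`, `ring_label`, `frame`, `time_s`,
#'   `chi_deg`, `theta_deg` — cumulative ground-truth angular walks), `cfg`.
#' @export
simulate_laue_trajectories <- function(cfg, rings, geom,
                                       spread_azimuth = TRUE) {
  stopifnot(length(rings) == 2L, inherits(cfg, "sim_config"))
  if (abs(rings[[1]]$radius_px - rings[[2]]$radius_px) < 1e-9) {
    stop("the two rings must be distinct", call. = FALSE)
  }
  rad2deg <- 180 / pi
  dt <- cfg$frame_interval_s
  with_local_seed(cfg$seed, {
    all_spots <- list(); all_truth <- list()
    id <- 0L
    for (ring in rings) {
      two_theta0 <- atan(ring$radius_px * geom$pixel_pitch_mm / geom$distance_mm)
      for (i in seq_len(cfg$n_crystals)) {
        id <- id + 1L
        # births staggered evenly by index: together with the golden-angle
        # azimuth stride this keeps simultaneously alive spots far apart
        birth <- if (is.finite(cfg$lifetime_mean_frames)) {
          as.integer(floor((i - 1L) / cfg$n_crystals * cfg$n_frames))
        } else 0L
        life <- if (is.finite(cfg$lifetime_mean_frames)) {
          1L + stats::rgeom(1L, 1 / cfg$lifetime_mean_frames)
        } else cfg$n_frames
        life <- min(life, cfg$n_frames - birth)
        frames <- birth + 0:(life - 1L)
        chi <- walk_axis(life, dt, cfg$d_rot, cfg$relax_s,
                         cfg$drift_deg_s / rad2deg) * rad2deg
        th <- walk_axis(life, dt, cfg$d_rot, cfg$relax_s,
                        cfg$drift_deg_s / rad2deg) * rad2deg
        az0 <- if (spread_azimuth) {
          # golden-angle stride: consecutively born spots land far apart
          (i - 1) * 137.50776 %% 360 + stats::runif(1, 0, 5)
        } else stats::runif(1, 0, 360)
        az <- az0 + chi
        two_theta <- two_theta0 + 2 * th / rad2deg
        r_px <- geom$distance_mm * tan(two_theta) / geom$pixel_pitch_mm
        all_spots[[id]] <- tibble::tibble(
          trajectory_id = id, ring_label = ring$label, frame = frames,
          row_px = geom$beam_center_px[1] + r_px * sin(az / rad2deg),
          col_px = geom$beam_center_px[2] + r_px * cos(az / rad2deg),
          intensity = cfg$mean_photons)
        all_truth[[id]] <- tibble::tibble(
          trajectory_id = id, ring_label = ring$label, frame = frames,
          time_s = (frames - frames[1]) * dt, chi_deg = chi, theta_deg = th)
      }
    }
    structure(list(spots = dplyr::bind_rows(all_spots),
                   truth = dplyr::bind_rows(all_truth), cfg = cfg),
              class = "laue_sim")
  })
}

#' Render a tracking movie from simulated Laue spots
#'
#' Stamps each spot as an integrated-intensity Gaussian point-spread function
#' (sd `psf_sigma_px`) at its sub-pixel position and Poisson-samples the
#' counts. Background is a flat Poisson term over the stamped region plus the
#' whole frame when `cfg$background_photons > 0`.
#'
#' @param sim A [simulate_laue_trajectories()] result.
#' @param geom A [detector_geometry()].
#' @param psf_sigma_px Gaussian PSF sd, pixels.
#' @return Integer array rows x cols x frames.
#' @export
render_dxt_movie <- function(sim, geom, psf_sigma_px = 1.2) {
  stopifnot(inherits(sim, "laue_sim"))
  cfg <- sim$cfg
  n_frames <- cfg$n_frames
  with_local_seed(cfg$seed + 2L, {
    stack <- array(0L, dim = c(geom$n_rows, geom$n_cols, n_frames))
    half <- max(3L, ceiling(3 * psf_sigma_px))
    sp <- sim$spots
    if (cfg$background_photons > 0) {
      stack[] <- stats::rpois(length(stack), cfg$background_photons)
    }
    for (k in seq_len(nrow(sp))) {
      r0 <- sp$row_px[k]; c0 <- sp$col_px[k]
      rows <- max(0L, floor(r0) - half):min(geom$n_rows - 1L, floor(r0) + half)
      cols <- max(0L, floor(c0) - half):min(geom$n_cols - 1L, floor(c0) + half)
      if (length(rows) == 0L || length(cols) == 0L) next
      gr <- exp(-(rows - r0)^2 / (2 * psf_sigma_px^2))
      gc <- exp(-(cols - c0)^2 / (2 * psf_sigma_px^2))
      lam <- sp$intensity[k] * outer(gr, gc) / (2 * pi * psf_sigma_px^2)
      f <- sp$frame[k] + 1L
      stack[rows + 1L, cols + 1L, f] <- stack[rows + 1L, cols + 1L, f] +
        matrix(stats::rpois(length(lam), lam), nrow = length(rows))
    }
    stack
  })
}

#' Draw decay constants from a truncated two-Gaussian mixture
#'
#' Direct fixture for mobility-decomposition tests: i.i.d. draws from
#' `w1 * N(mu1, sd1^2) + w2 * N(mu2, sd2^2)`, truncated at 0 by resampling.
#'
#' @param mu,sd,w Length-2 numeric vectors of component means, sds and
#'   weights (`sum(w) == 1`).
#' @param n Number of draws.
#' @param seed RNG seed.
#' @return Tibble with columns `value` (1/s) and `component` (1 or 2).
#' @export
generate_decay_samples <- function(mu, sd, w, n, seed = 1L) {
  stopifnot(length(mu) == 2L, length(sd) == 2L, length(w) == 2L,
            abs(sum(w) - 1) < 1e-9, all(sd > 0), n >= 1)
  with_local_seed(seed, {
    comp <- sample.int(2L, n, replace = TRUE, prob = w)
    x <- stats::rnorm(n, mu[comp], sd[comp])
    bad <- which(x <= 0)
    while (length(bad) > 0L) {
      x[bad] <- stats::rnorm(length(bad), mu[comp[bad]], sd[comp[bad]])
      bad <- bad[x[bad] <= 0]
    }
    tibble::tibble(value = x, component = comp)
  })
}
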