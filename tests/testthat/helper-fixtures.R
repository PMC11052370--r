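# Shared fixtures and independent brute-force oracles.

# small blinking-geometry fixture: Au(111) ring on a compact detector
small_dxb_setup <- function(n_px = 48, radius_px = 14, half_width_px = 0.7) {
  geom <- dxb_sim_geometry(n_px, radius_px)
  roi <- build_ring_roi(phase_au(), c(1, 1, 1), beam_spec(17.7), geom,
                        half_width_px = half_width_px)
  list(geom = geom, roi = roi)
}

# standard blinking study configuration (100 ms x 2000 frames protocol)
dxb_study_config <- function(seed, d_rot, n_crystals, n_frames = 2000L,
                             mixture = NULL) {
  sim_config(seed = seed, n_frames = n_frames, frame_interval_s = 0.1,
             d_rot = d_rot, rocking_width_deg = 30, mean_photons = 50,
             background_photons = 0.5, n_crystals = n_crystals,
             relax_s = "auto", mixture = mixture)
}

# independent closed form for the stationary blinking ACF (OU tilt with
# stationary spread equal to the rocking width, i.e. a = 1)
blinking_acf_closed_form <- function(tau_s, d_rot, rocking_width_deg = 30) {
  sw <- rocking_width_deg * pi / 180
  relax <- sw^2 / d_rot
  sqrt(3) / sqrt(4 - exp(-2 * tau_s / relax))
}

# decay constant of the analytic blinking ACF by an independent nls fit
blinking_truth_T <- function(d_rot, max_lag_frames, frame_interval_s = 0.1,
                             rocking_width_deg = 30) {
  tau <- seq_len(max_lag_frames) * frame_interval_s
  m <- blinking_acf_closed_form(tau, d_rot, rocking_width_deg)
  sw <- rocking_width_deg * pi / 180
  fit <- stats::nls(m ~ k + A * exp(-T * tau),
                    start = list(k = min(m), A = m[1] - min(m),
                                 T = 2 * d_rot / sw^2))
  stats::coef(fit)[["T"]]
}

# brute-force ACF by explicit double loop (oracle for compute_acf)
brute_acf <- function(x, max_lag) {
  n <- length(x)
  denom <- sum(x^2) / n
  vapply(0:max_lag, function(m) {
    s <- 0
    for (t in seq_len(n - m)) s <- s + x[t] * x[t + m]
    (s / (n - m)) / denom
  }, numeric(1))
}

# brute-force temporal MSD by explicit double loop (oracle for compute_msd)
brute_msd <- function(x, max_lag) {
  n <- length(x)
  vapply(seq_len(max_lag), function(m) {
    s <- 0
    for (t in seq_len(n - m)) s <- s + (x[t + m] - x[t])^2
    s / (n - m)
  }, numeric(1))
}

# brute-force annulus membership by scanning every pixel (oracle for
# build_ring_roi)
brute_annulus <- function(geom, radius, half_width) {
  hits <- list()
  for (r in 0:(geom$n_rows - 1L)) for (c in 0:(geom$n_cols - 1L)) {
    rr <- sqrt((r - geom$beam_center_px[1])^2 + (c - geom$beam_center_px[2])^2)
    if (abs(rr - radius) <= half_width) {
      masked <- FALSE
      for (m in geom$mask_rects) {
        if (r >= m$row0 && r <= m$row1 && c >= m$col0 && c <= m$col1) {
          masked <- TRUE
        }
      }
      if (!masked) hits[[length(hits) + 1L]] <- c(r, c)
    }
  }
  do.call(rbind, hits)
}

# exhaustive two-sided rank-sum p by enumerating every group assignment
# (oracle for compare_distributions in the exact regime)
enumerate_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  rk <- rank(pooled)
  n_a <- length(a)
  w_obs <- sum(rk[seq_along(a)])
  e_w <- n_a * mean(rk)
  sets <- utils::combn(length(pooled), n_a)
  ws <- apply(sets, 2, function(ii) sum(rk[ii]))
  mean(abs(ws - e_w) >= abs(w_obs - e_w) - 1e-9)
}

# Poisson traces whose rate follows a stationary AR(1), giving an exactly
# exponential intensity ACF at positive lags with decay constant T_true
ar1_blinking_trace <- function(n, T_true, dt, mu = 20, contrast = 0.6) {
  phi <- exp(-T_true * dt)
  g <- numeric(n)
  g[1] <- stats::rnorm(1)
  for (i in 2:n) g[i] <- phi * g[i - 1] + stats::rnorm(1, 0, sqrt(1 - phi^2))
  lam <- pmax(mu * (1 + contrast * g), 0)
  stats::rpois(n, lam)
}

# synthetic angular trajectories (no detector): Brownian chi/theta walks
make_angular_walks <- function(n_traj, n_frames, dt, step_sd_deg, seed,
                               id_offset = 0L) {
  set.seed(seed)
  out <- lapply(seq_len(n_traj), function(i) {
    tibble::tibble(
      trajectory_id = i + id_offset,
      frame = 0:(n_frames - 1L),
      time_s = (0:(n_frames - 1L)) * dt,
      chi_deg = c(0, cumsum(stats::rnorm(n_frames - 1L, 0, step_sd_deg))),
      theta_deg = c(0, cumsum(stats::rnorm(n_frames - 1L, 0, step_sd_deg))))
  })
  dplyr::bind_rows(out)
}
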