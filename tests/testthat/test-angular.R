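# Twisting/bending decomposition, lifetime filter, MSD and its
# anomalous-diffusion fit.

test_that("angular decomposition follows the stated conventions", {
  geom <- detector_geometry(200, 200, 0.172, c(100, 100), 50, 0.0125)
  # fixed spot: both angles stay at zero
  fixed <- tibble::tibble(frame = 0:9, row_px = 100, col_px = 150)
  a0 <- to_angular(fixed, geom)
  expect_true(all(a0$chi_deg == 0) && all(a0$theta_deg == 0))
  expect_equal(a0$time_s, (0:9) * 0.0125)
  # pure azimuthal rotation of +1 degree per frame about the beam center
  az <- (0:9) * 1 * pi / 180
  rot <- tibble::tibble(frame = 0:9, row_px = 100 + 50 * sin(az),
                        col_px = 100 + 50 * cos(az))
  a1 <- to_angular(rot, geom)
  expect_equal(diff(a1$chi_deg), rep(1, 9), tolerance = 1e-9)
  expect_equal(a1$theta_deg, rep(0, 10), tolerance = 1e-9)
  # radial step with d(2theta) = 0.2 degrees gives d(theta) = 0.1 degrees
  tth0 <- atan(50 * 0.172 / 50)
  r1 <- 50 / 0.172 * tan(tth0 + 0.2 * pi / 180)
  rad <- tibble::tibble(frame = 0:1, row_px = 100,
                        col_px = 100 + c(50, r1))
  a2 <- to_angular(rad, geom)
  expect_equal(a2$theta_deg[2], 0.1, tolerance = 1e-9)
  expect_equal(a2$chi_deg[2], 0, tolerance = 1e-9)
  # azimuth wrap across the +/-180 degree seam is continuous
  az3 <- seq(178, 184, by = 1) * pi / 180
  wrapped <- tibble::tibble(frame = 0:6, row_px = 100 + 50 * sin(az3),
                            col_px = 100 + 50 * cos(az3))
  a3 <- to_angular(wrapped, geom)
  expect_equal(diff(a3$chi_deg), rep(1, 6), tolerance = 1e-9)
  # zero radius is undefined
  expect_error(to_angular(tibble::tibble(frame = 0:1, row_px = 100,
                                         col_px = c(100, 120)), geom),
               "zero radius")
})

test_that("angular decomposition inverts the Laue simulation exactly", {
  geom <- dxt_sim_geometry(96, 30)
  rings <- dxt_sim_rings(geom)
  cfg <- sim_config(seed = 14, n_frames = 300, frame_interval_s = 0.0125,
                    d_rot = 1e-6, n_crystals = 10)
  sim <- simulate_laue_trajectories(cfg, rings, geom)
  ang <- to_angular(sim$spots, geom)
  expect_equal(ang$chi_deg, sim$truth$chi_deg, tolerance = 1e-8)
  expect_equal(ang$theta_deg, sim$truth$theta_deg, tolerance = 1e-8)
})

test_that("lifetime filtering keeps the stated range and partitions", {
  traj <- dplyr::bind_rows(
    tibble::tibble(trajectory_id = 1, frame = 0:2),
    tibble::tibble(trajectory_id = 2, frame = 0:9),
    tibble::tibble(trajectory_id = 3, frame = 10:59))
  f <- filter_by_lifetime(traj, 5, Inf)
  expect_setequal(unique(f$trajectory_id), c(2, 3))
  expect_equal(attr(f, "lifetime_counts")[["kept"]], 2L)
  expect_identical(nrow(filter_by_lifetime(traj, 0, Inf)), nrow(traj))
  short <- filter_by_lifetime(traj, 0, 9)
  long <- filter_by_lifetime(traj, 10, Inf)
  expect_equal(attr(short, "lifetime_counts")[["kept"]] +
               attr(long, "lifetime_counts")[["kept"]], 3L)
  expect_error(filter_by_lifetime(traj, 10, 5), "min_frames")
})

test_that("temporal MSD matches closed forms and the brute-force loop", {
  dt <- 0.0125
  # linear drift: delta^2(t) = v^2 t^2 exactly
  v <- 3
  drift <- tibble::tibble(frame = 0:99, time_s = (0:99) * dt,
                          chi_deg = v * (0:99) * dt, theta_deg = 0)
  cv <- compute_msd(drift, "chi")
  expect_equal(cv$msd, v^2 * cv$lag_s^2, tolerance = 1e-12)
  # stationary trajectory: identically zero, classified as such
  still <- tibble::tibble(frame = 0:49, time_s = (0:49) * dt,
                          chi_deg = 0, theta_deg = 0)
  cv0 <- compute_msd(still, "chi")
  expect_true(all(cv0$msd == 0))
  expect_identical(fit_msd(cv0)$regime, "stationary")
  # brute-force double-loop equality on random walks up to length 200
  set.seed(5)
  for (n in c(20, 99, 200)) {
    x <- cumsum(rnorm(n))
    a <- tibble::tibble(frame = 0:(n - 1), time_s = (0:(n - 1)) * dt,
                        chi_deg = x, theta_deg = -x)
    got <- compute_msd(a, "chi")
    expect_equal(got$msd, brute_msd(x, n %/% 4), tolerance = 1e-12)
    both <- compute_msd(a, "both")
    expect_equal(both$msd, 2 * got$msd, tolerance = 1e-12)
  }
  expect_error(compute_msd(still[1:2, ], "chi"), "too short")
})

test_that("anomalous-diffusion fit recovers noiseless parameters and
           classifies regimes", {
  tt <- seq(0.0125, 2, by = 0.0125)
  mk <- function(D, a, b) {
    structure(tibble::tibble(lag_s = tt, msd = D * tt^a + 2 * b^2,
                             n_pairs = rev(seq_along(tt))),
              class = c("msd_curve", "tbl_df", "tbl", "data.frame"))
  }
  f1 <- fit_msd(mk(2, 1, 0))
  expect_equal(f1$D_alpha, 2, tolerance = 1e-4)
  expect_equal(f1$alpha, 1, tolerance = 1e-4)
  expect_identical(f1$regime, "normal")
  expect_identical(fit_msd(mk(0.5, 0.5, 0.1))$regime, "subdiffusion")
  expect_identical(fit_msd(mk(0.5, 1.8, 0))$regime, "superdiffusion")
  expect_equal(fit_msd(mk(1.5, 0.7, 0.2))$beta, 0.2, tolerance = 1e-3)
  expect_error(fit_msd(mk(1, 1, 0)[1:3, ]), "at least 4")
  td <- tidy(f1)
  expect_identical(td$term, c("D_alpha", "alpha", "beta"))
  expect_identical(glance(f1)$regime, "normal")
})

test_that("Brownian walks recover the diffusive slope within 15%", {
  dt <- 0.0125
  D <- 0.4                               # deg^2/s; true MSD slope = 2 D
  ang <- make_angular_walks(10, 5000, dt, sqrt(2 * D * dt), seed = 61)
  fits <- fit_msd_trajectories(ang, "chi", max_lag_frames = 250)
  expect_true(all(fits$converged))
  expect_lt(abs(median(fits$alpha) - 1), 0.1)
  ens <- fit_msd(ensemble_msd(ang, "chi", 250))
  expect_lt(abs(ens$D_alpha / (2 * D) - 1), 0.15)
  expect_lt(abs(ens$alpha - 1), 0.1)
})
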