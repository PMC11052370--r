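# Generator contracts: determinism, increment statistics, lifetime law,
# blinking-decorrelation ordering.

test_that("generators are bit-reproducible given a seed and leave the
           global RNG untouched", {
  cfg <- sim_config(seed = 12, n_frames = 50, n_crystals = 5)
  w1 <- simulate_orientation_walks(cfg)
  set.seed(999)                          # must not influence the generator
  w2 <- simulate_orientation_walks(cfg)
  expect_identical(w1, w2)
  expect_false(identical(
    w1, simulate_orientation_walks(sim_config(seed = 13, n_frames = 50,
                                              n_crystals = 5))))
  s1 <- generate_decay_samples(c(0.05, 0.12), c(0.01, 0.02), c(0.5, 0.5),
                               100, seed = 4)
  s2 <- generate_decay_samples(c(0.05, 0.12), c(0.01, 0.02), c(0.5, 0.5),
                               100, seed = 4)
  expect_identical(s1, s2)
  # the helper restores any pre-existing RNG state
  set.seed(101); before <- runif(1)
  set.seed(101); invisible(simulate_orientation_walks(cfg))
  expect_identical(runif(1), before)
})

test_that("orientation increments have the diffusive variance 2 D dt", {
  cfg <- sim_config(seed = 6, n_frames = 25000, n_crystals = 4, d_rot = 0.05,
                    frame_interval_s = 0.2)
  w <- simulate_orientation_walks(cfg)
  incr <- unlist(lapply(split(w$tilt_deg * pi / 180, w$crystal), diff))
  v <- var(incr)
  target <- 2 * 0.05 * 0.2
  se <- target * sqrt(2 / length(incr))
  expect_lt(abs(v - target), 3 * se)
  # zero diffusion freezes every orientation
  w0 <- simulate_orientation_walks(sim_config(seed = 2, n_frames = 100,
                                              n_crystals = 3, d_rot = 0))
  expect_true(all(w0$tilt_deg == 0) && all(w0$azimuth_deg == 0))
})

test_that("mixture spec validation and population split", {
  expect_error(sim_config(mixture = list(d_rot = c(1, 2), w = c(0.6, 0.6))),
               "sum to 1")
  cfg <- sim_config(seed = 1, n_frames = 10, n_crystals = 100,
                    mixture = list(d_rot = c(0.01, 0.1), w = c(0.68, 0.32)))
  w <- simulate_orientation_walks(cfg)
  tab <- table(dplyr::distinct(w[, c("crystal", "d_rot")])$d_rot)
  expect_equal(as.integer(tab), c(68L, 32L))
})

test_that("decay-sample moments match the mixture law", {
  mu <- c(0.05, 0.12); sd <- c(0.01, 0.02); w <- c(0.68, 0.32)
  s <- generate_decay_samples(mu, sd, w, 1e5, seed = 9)
  m_true <- sum(w * mu)
  v_true <- sum(w * (sd^2 + mu^2)) - m_true^2
  expect_lt(abs(mean(s$value) - m_true), 3 * sqrt(v_true / 1e5))
  expect_true(all(s$value > 0))
  # single-component degenerate case
  s1 <- generate_decay_samples(mu, sd, c(1, 0), 5000, seed = 2)
  expect_true(all(s1$component == 1))
})

test_that("noiseless blinking decorrelates faster as d_rot grows", {
  s <- small_dxb_setup()
  acf1 <- function(drot) {
    cfg <- dxb_study_config(seed = 40, d_rot = drot, n_crystals = 40,
                            n_frames = 1500L)
    mv <- simulate_dxb_movie(cfg, s$roi, s$geom, pixel_map = "one_per_pixel")
    lam <- mv$noiseless
    n <- nrow(lam)
    # mean normalized ACF at a 1 s lag over crystals
    mean(apply(lam, 2, function(x) {
      mean(x[1:(n - 10)] * x[11:n]) / mean(x^2)
    }))
  }
  vals <- vapply(c(0.01, 0.1, 1), acf1, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("Laue trajectory lifetimes follow the geometric law", {
  geom <- dxt_sim_geometry(96, 30)
  rings <- dxt_sim_rings(geom)
  cfg <- sim_config(seed = 3, n_frames = 20000, frame_interval_s = 0.0125,
                    d_rot = 1e-7, n_crystals = 400, mean_photons = 100,
                    lifetime_mean_frames = 20)
  sim <- simulate_laue_trajectories(cfg, rings, geom)
  lt <- trajectory_lifetimes(sim$spots)
  # drop the censored tail (spots born near the movie end)
  births <- sim$spots |>
    dplyr::group_by(trajectory_id) |>
    dplyr::summarise(birth = min(frame))
  keep <- births$trajectory_id[births$birth < 20000 - 400]
  x <- lt$lifetime[lt$trajectory_id %in% keep]
  # chi-square GOF against geometric(1/20) on binned lifetimes
  brk <- c(0, 5, 10, 20, 40, 80, Inf)
  obs <- table(cut(x, brk))
  # lifetime L = 1 + geometric(1/20), so P(L <= k) = pgeom(k - 1, 1/20)
  p_bin <- diff(pgeom(brk - 1, prob = 1 / 20))
  expect_gt(stats::chisq.test(obs, p = p_bin / sum(p_bin))$p.value, 0.01)
  # infinite lifetime: one full-length trajectory per ring
  cfg1 <- sim_config(seed = 4, n_frames = 500, n_crystals = 1,
                     lifetime_mean_frames = Inf, d_rot = 1e-7)
  s1 <- simulate_laue_trajectories(cfg1, rings, geom)
  expect_equal(length(unique(s1$spots$trajectory_id)), 2L)   # one per ring
  expect_true(all(table(s1$spots$trajectory_id) == 500L))
})

test_that("simulated spots on the two rings are never cross-assigned", {
  geom <- dxt_sim_geometry()
  rings <- dxt_sim_rings(geom)
  cfg <- sim_config(seed = 8, n_frames = 800, frame_interval_s = 0.0125,
                    d_rot = 1e-6, n_crystals = 40, lifetime_mean_frames = 80)
  sim <- simulate_laue_trajectories(cfg, rings, geom)
  routed <- sim$spots |>
    dplyr::group_by(trajectory_id, ring_label) |>
    dplyr::summarise(r = mean(sqrt((row_px - geom$beam_center_px[1])^2 +
                                   (col_px - geom$beam_center_px[2])^2)),
                     .groups = "drop") |>
    dplyr::mutate(assigned = vapply(r, function(x) {
      assign_ring(x, rings, 2)
    }, character(1)))
  expect_identical(routed$assigned, routed$ring_label)
})
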