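# Theta-chi motion maps: histogram algebra, projections, peaks/FWHM,
# subtraction and hotspot superposition.

two_pop_stats <- function(n, shift_chi = 0, shift_theta = 0, seed = 1) {
  set.seed(seed)
  tibble::tibble(trajectory_id = seq_len(n),
                 s_chi = rnorm(n, -3 + shift_chi, 0.3),
                 s_theta = rnorm(n, -3 + shift_theta, 0.3))
}

test_that("motion histograms are unit-normalized with consistent
           projections", {
  st <- two_pop_stats(500)
  h <- build_motion_hist(st, bins = 40)
  expect_equal(sum(h$density), 1, tolerance = 1e-12)
  expect_equal(sum(h$counts), h$n_points)
  expect_equal(h$chi_proj$density, rowSums(h$density), tolerance = 1e-15)
  expect_equal(sum(h$theta_proj$density), 1, tolerance = 1e-12)
  # identical trajectories collapse to one occupied bin and point-mass
  # marginals
  one <- tibble::tibble(trajectory_id = 1:20, s_chi = -2.5, s_theta = -2.5)
  h1 <- build_motion_hist(one, bins = 10)
  expect_equal(sum(h1$counts > 0), 1L)
  expect_equal(max(h1$chi_proj$density), 1)
  expect_equal(max(h1$theta_proj$density), 1)
  expect_error(build_motion_hist(one[0, ]), "no trajectories")
})

test_that("per-trajectory statistics feed the map and separate populations
           by mobility", {
  dt <- 0.0125
  slow <- make_angular_walks(120, 400, dt, 0.02, seed = 7)
  fast <- make_angular_walks(120, 400, dt, 0.02 * sqrt(10), seed = 8,
                             id_offset = 200L)
  st_all <- motion_statistics(dplyr::bind_rows(slow, fast), lag_frames = 1L)
  expect_identical(attr(st_all, "axis_statistic"), "log10_msd")
  # a x10 MSD ratio is a unit shift in log10 units on both axes
  ms <- st_all |>
    dplyr::mutate(pop = ifelse(trajectory_id <= 200, "slow", "fast")) |>
    dplyr::group_by(pop) |>
    dplyr::summarise(chi = mean(s_chi), theta = mean(s_theta))
  expect_equal(diff(range(ms$chi)), 1, tolerance = 0.1)
  expect_equal(diff(range(ms$theta)), 1, tolerance = 0.1)
  # bimodal chi marginal with peak separation ~1 in log10 units
  h <- build_motion_hist(st_all, bins = 60)
  proj <- h$chi_proj
  lo <- proj[proj$center < mean(ms$chi), ]
  hi <- proj[proj$center >= mean(ms$chi), ]
  sep <- hi$center[which.max(hi$density)] - lo$center[which.max(lo$density)]
  expect_equal(sep, 1, tolerance = 0.25)
})

test_that("peak and FWHM come from parabolic and half-maximum
           interpolation", {
  set.seed(12)
  x <- rnorm(1e5, 0, 0.5)
  brk <- seq(-3, 3, length.out = 81)
  h <- hist(x, breaks = brk, plot = FALSE)
  hist_1d <- tibble::tibble(center = h$mids, count = h$counts)
  pf <- peak_and_fwhm(hist_1d)
  expect_lt(abs(pf$peak), 0.05)
  expect_equal(pf$fwhm, 2 * sqrt(2 * log(2)) * 0.5, tolerance = 0.05)
  # symmetric triangular histogram peaks at the center of symmetry
  tri <- tibble::tibble(center = 1:9, count = c(1, 2, 3, 4, 5, 4, 3, 2, 1))
  expect_equal(peak_and_fwhm(tri)$peak, 5)
  # single occupied bin reports one bin width
  single <- tibble::tibble(center = 1:5, count = c(0, 0, 3, 0, 0))
  expect_equal(peak_and_fwhm(single)$fwhm, 1)
  # plateau maximum resolves to the leftmost maximal bin with a warning
  plat <- tibble::tibble(center = 1:6, count = c(1, 4, 4, 4, 1, 0))
  expect_warning(pfp <- peak_and_fwhm(plat), "plateau")
  expect_equal(pfp$peak, 2)
})

test_that("subtraction maps are exact algebra on shared edges", {
  stA <- two_pop_stats(2000, seed = 3)
  stB <- two_pop_stats(2000, shift_chi = -0.6, shift_theta = -0.6, seed = 4)
  edges <- motion_hist_edges(list(stA, stB), bins = 40)
  hA <- build_motion_hist(stA, edges = edges)
  hB <- build_motion_hist(stB, edges = edges)
  self_diff <- subtract_hists(hA, hA)
  expect_true(all(self_diff$diff == 0))
  d <- subtract_hists(hB, hA)              # B shifted toward lower values
  expect_equal(sum(d$diff), 0, tolerance = 1e-12)
  # positive mass sits lower-left of the depleted (negative) mass
  centers <- function(e) (e[-1] + e[-length(e)]) / 2
  cc <- centers(d$chi_edges); tc <- centers(d$theta_edges)
  pos <- pmax(d$diff, 0); neg <- pmax(-d$diff, 0)
  com <- function(w) c(sum(rowSums(w) * cc), sum(colSums(w) * tc)) / sum(w)
  expect_true(all(com(pos) < com(neg) - 0.3))
  # mismatched edges are refused
  hC <- build_motion_hist(stB, bins = 40)
  expect_error(subtract_hists(hA, hC), "edges differ")
})

test_that("hotspot superposition reports centroid displacements", {
  stA <- two_pop_stats(800, seed = 5)
  stB <- two_pop_stats(800, shift_chi = 0.5, seed = 6)
  edges <- motion_hist_edges(list(stA, stB), bins = 50)
  hA <- build_motion_hist(stA, edges = edges)
  hB <- build_motion_hist(stB, edges = edges)
  rep0 <- superpose_hotspots(list(a = hA, b = hA))
  expect_equal(rep0$displacements$d_chi, 0)
  expect_equal(rep0$displacements$d_theta, 0)
  rep1 <- superpose_hotspots(list(a = hA, b = hB), quantile = 0.9)
  expect_equal(rep1$displacements$d_chi, 0.5, tolerance = 0.12)
  expect_equal(rep1$displacements$d_theta, 0, tolerance = 0.12)
  # quantile 0 selects every occupied bin
  rep_all <- superpose_hotspots(list(a = hA), quantile = 0)
  expect_equal(nrow(rep_all$hotspots), sum(hA$density > 0))
  expect_error(superpose_hotspots(list(hA, build_motion_hist(stB, bins = 50))),
               "edges differ")
})

test_that("result plots build without error", {
  st <- two_pop_stats(300, seed = 9)
  h <- build_motion_hist(st, bins = 30)
  expect_s3_class(autoplot(h), "ggplot")
  expect_s3_class(autoplot(subtract_hists(h, h)), "ggplot")
  s <- generate_decay_samples(c(0.05, 0.12), c(0.01, 0.02), c(0.5, 0.5),
                              2000, seed = 2)
  expect_s3_class(autoplot(fit_two_gaussians(s$value)), "ggplot")
  samples <- tibble::tibble(value = s$value, condition = "ligand-free")
  expect_s3_class(plot_decay_box(samples), "ggplot")
})
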