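# Ring prediction, ROI construction and dual-probe ring assignment.

dxt_geom <- detector_geometry(195, 487, 0.172, c(97, 243), 95, 0.0125)
pink <- beam_spec(17.7, 0.1, "pink")
mono177 <- beam_spec(17.7)

test_that("energy-to-wavelength conversion matches the defining constant", {
  expect_equal(wavelength_from_energy(12.3984), 1.0)
  expect_equal(wavelength_from_energy(17.7), 12.3984 / 17.7, tolerance = 1e-12)
  expect_equal(wavelength_from_energy(17.7), 0.70047, tolerance = 1e-4)
  expect_error(wavelength_from_energy(0), "positive")
  expect_error(wavelength_from_energy(-3), "positive")
})

test_that("d-spacings match hand-computed closed forms", {
  au <- phase_au(); zno <- phase_zno()
  expect_equal(d_spacing(au, c(2, 0, 0)), 2.04)                 # a/2
  expect_equal(d_spacing(zno, c(0, 0, 2)), 2.6, tolerance = 1e-12) # c/2
  # independent evaluations of the cubic/hexagonal formulas
  expect_equal(d_spacing(au, c(1, 1, 1)), 4.08 / sqrt(3), tolerance = 1e-12)
  expect_equal(d_spacing(zno, c(1, 0, 0)),
               1 / sqrt((4 / 3) / 3.25^2), tolerance = 1e-12)
  expect_equal(d_spacing(zno, c(1, 0, 1)),
               1 / sqrt((4 / 3) / 3.25^2 + 1 / 5.2^2), tolerance = 1e-12)
  expect_equal(d_spacing(zno, c(1, 0, 2)),
               1 / sqrt((4 / 3) / 3.25^2 + 4 / 5.2^2), tolerance = 1e-12)
  # frozen hand-calculator values
  expect_equal(d_spacing(au, c(1, 1, 1)), 2.355589, tolerance = 1e-6)
  expect_equal(d_spacing(zno, c(1, 0, 0)), 2.814583, tolerance = 1e-6)
  expect_equal(d_spacing(zno, c(1, 0, 1)), 2.475255, tolerance = 1e-6)
  expect_equal(d_spacing(zno, c(1, 0, 2)), 1.909838, tolerance = 1e-6)
  expect_error(d_spacing(au, c(0, 0, 0)), "0,0,0|no d-spacing")
  expect_error(crystal_phase("X", "hexagonal", a = 3), "c")
  expect_error(crystal_phase("Y", "cubic", a = 4, c = 5), "must not carry")
})

test_that("ring radius follows Bragg law with flat-detector projection", {
  # d chosen so 2 theta = 45 degrees: radius = distance * tan(45) / pitch
  lam <- 1
  d45 <- lam / (2 * sin(pi / 8))
  g <- detector_geometry(256, 256, 1, c(128, 128), 100, 0.1)
  expect_equal(ring_radius(d45, beam_spec(12.3984), g), 100, tolerance = 1e-9)
  # full chain at the tracking geometry
  r <- ring_radius(d_spacing(phase_au(), c(1, 1, 1)), pink, dxt_geom)
  expect_equal(r, 169.93, tolerance = 1e-4)
  expect_error(ring_radius(0.3, pink, dxt_geom), "no reflection")
})

test_that("ring radius is strictly decreasing in d-spacing", {
  ds <- seq(1.2, 4, length.out = 25)
  rr <- vapply(ds, ring_radius, numeric(1), beam = mono177, geom = dxt_geom)
  expect_true(all(diff(rr) < 0))
})

test_that("pink-beam radius band brackets the central radius", {
  d <- d_spacing(phase_au(), c(1, 1, 1))
  band <- ring_radius_band(d, pink, dxt_geom)
  r0 <- ring_radius(d, mono177, dxt_geom)
  expect_lt(band[1], r0)
  expect_gt(band[2], r0)
  expect_equal(ring_radius_band(d, mono177, dxt_geom), c(r0, r0))
})

test_that("ring ROI pixels equal brute-force annulus enumeration", {
  g <- detector_geometry(64, 64, 1, c(31.5, 31.5), 100, 0.1,
                         mask_rects = list(list(row0 = 0, row1 = 10,
                                                col0 = 20, col1 = 40)))
  lam <- 1
  # choose d to place the ring at radius 10 px
  target_2theta <- atan(10 * 1 / 100)
  d <- lam / (2 * sin(target_2theta / 2))
  ph <- crystal_phase("Au", "cubic", a = d)  # (100) of this lattice has d = a
  roi <- build_ring_roi(ph, c(1, 0, 0), beam_spec(12.3984), g, 1)
  expect_equal(roi$radius_px, 10, tolerance = 1e-9)
  brute <- brute_annulus(g, roi$radius_px, 1)
  got <- as.matrix(roi$pixels[, c("row", "col")])
  dimnames(got) <- NULL
  expect_equal(got[order(got[, 1], got[, 2]), ],
               brute[order(brute[, 1], brute[, 2]), ])
  # masking can only shrink the pixel set
  g0 <- detector_geometry(64, 64, 1, c(31.5, 31.5), 100, 0.1)
  roi0 <- build_ring_roi(ph, c(1, 0, 0), beam_spec(12.3984), g0, 1)
  expect_gte(nrow(roi0$pixels), nrow(roi$pixels))
  # annulus membership invariant
  expect_true(all(abs(roi$pixels$radius_px - roi$radius_px) <= 1))
  # fully masked ring errors
  gm <- detector_geometry(64, 64, 1, c(31.5, 31.5), 100, 0.1,
                          mask_rects = list(list(row0 = 0, row1 = 63,
                                                 col0 = 0, col1 = 63)))
  expect_error(build_ring_roi(ph, c(1, 0, 0), beam_spec(12.3984), gm, 1),
               "empty ROI")
})

test_that("the six dual-probe rings are uniquely assignable at 2 px", {
  rois <- standard_ring_set(mono177, dxt_geom)
  radii <- vapply(rois, `[[`, numeric(1), "radius_px")
  expect_length(radii, 6L)
  expect_true(all(abs(diff(sort(radii))) > 2 * 2))  # pairwise > 2 px at tol 2
  for (lab in names(rois)) {
    expect_identical(assign_ring(radii[[lab]], rois, 2), lab)
  }
  # unassigned and ambiguous cases
  expect_true(is.na(assign_ring(5, rois, 2)))
  mid <- mean(sort(radii)[1:2])
  expect_error(assign_ring(mid, rois, tolerance_px = 10), "ambiguous")
  expect_error(assign_ring(100, list(), 2), "no candidate")
})

test_that("roi JSON export round-trips the audit fields", {
  s <- small_dxb_setup()
  path <- withr::local_tempfile(fileext = ".json")
  write_roi_json(s$roi, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(back$label, "Au(111)")
  expect_equal(back$radius_px, s$roi$radius_px)
  expect_equal(nrow(back$pixels), nrow(s$roi$pixels))
})
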