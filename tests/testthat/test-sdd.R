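test_that("moment ellipse recovers disks and rotated ellipses within a pixel", {
  disk <- rasterize_disk_mask(50)
  e <- ellipse_from_moments(disk)
  expect_equal(e$major_axis, 100, tolerance = 0.01)
  expect_equal(e$minor_axis, 100, tolerance = 0.01)
  ell <- rasterize_ellipse_mask(60, 30)
  e0 <- ellipse_from_moments(ell)
  expect_lt(abs(e0$major_axis - 120), 1)
  expect_lt(abs(e0$minor_axis - 60), 1)
  # invariant to rotation by 30 degrees
  e30 <- ellipse_from_moments(rasterize_ellipse_mask(60, 30, pi / 6))
  expect_lt(abs(e30$major_axis - e0$major_axis), 1)
  expect_lt(abs(e30$minor_axis - e0$minor_axis), 1)
  # pixel size scales the axes
  es <- ellipse_from_moments(disk, pixel_size = 2e-6)
  expect_equal(es$major_axis, e$major_axis * 2e-6, tolerance = 1e-12)
  expect_error(ellipse_from_moments(matrix(FALSE, 5, 5)), "empty")
  # two components: the largest wins, with a warning
  two <- matrix(FALSE, 80, 160)
  two[20:60, 20:60] <- TRUE
  two[30:40, 120:130] <- TRUE
  expect_warning(e2 <- ellipse_from_moments(two), "largest")
  expect_lt(abs(e2$centroid[["x"]] - 40), 1)
})

test_that("spheroid geometry reduces to the sphere and matches quadrature", {
  sph <- spheroid_surface_volume(2e-3, 2e-3)
  expect_equal(sph$volume, 4 / 3 * pi * (1e-3)^3, tolerance = 1e-12)
  expect_equal(sph$area, 4 * pi * (1e-3)^2, tolerance = 1e-12)
  ob <- spheroid_surface_volume(4, 2)
  expect_equal(ob$volume, pi / 6 * 32, tolerance = 1e-12)
  expect_equal(ob$area, spheroid_area_quadrature(2, 1), tolerance = 1e-6)
  # continuity of the series branch near a = b
  near <- spheroid_surface_volume(2, 2 * (1 - 1e-7))
  expect_equal(near$area, 4 * pi, tolerance = 1e-6)
  expect_error(spheroid_surface_volume(2, -1), "positive")
  expect_error(spheroid_surface_volume(2, 3), ">= minor")
})

test_that("evaporation rate is recovered exactly on a noiseless d2-law series", {
  s <- gen_droplet_series(d0 = 2e-3, kappa = 4.5e-9, lock_time = 400,
                          aspect_ratio = 1.3, noise_sigma = 0)
  curve <- drying_curve(s)
  expect_equal(curve$normalized_d2[1], 1, tolerance = 1e-12)
  fit <- suppressWarnings(fit_evaporation_rate(curve, fit_window = c(0, 300)))
  expect_equal(fit$kappa, 4.5e-9, tolerance = 1e-12)
})

test_that("evaporation rate under 1% axis noise stays within 3 standard errors", {
  s <- gen_droplet_series(d0 = 2e-3, kappa = 4.5e-9, lock_time = 120,
                          aspect_ratio = 1.2, noise_sigma = 0.01,
                          sampling_rate = 1, duration = 99, seed = 8)
  fit <- fit_evaporation_rate(drying_curve(s), fit_window = c(0, 99))
  expect_equal(fit$n, 100)
  expect_lt(abs(fit$kappa - 4.5e-9), 3 * fit$se)
})

test_that("a growing droplet is rejected by the rate fit", {
  grow <- droplet_series(0:19, (1 + 0:19 / 100) * 1e-3,
                         (1 + 0:19 / 100) * 1e-3, 30)
  expect_error(fit_evaporation_rate(drying_curve(grow), c(0, 19)),
               "not evaporating")
})

test_that("lock point detection lands within one sample of the plateau", {
  s <- gen_droplet_series(d0 = 2e-3, kappa = 4.5e-9, lock_time = 40,
                          aspect_ratio = 1, noise_sigma = 0,
                          sampling_rate = 1, duration = 80)
  curve <- drying_curve(s)
  lp <- detect_lock_point(curve, kappa = 4.5e-9)
  expect_true(lp$found)
  expect_lte(abs(lp$time - 40), 1)
  expect_equal(lp$mean_concentration,
               attr(curve, "solute_mass") / lp$volume_at_lock,
               tolerance = 1e-12)
  # monotone shrinkage to the end: no lock point
  s2 <- gen_droplet_series(d0 = 2e-3, kappa = 4.5e-9, lock_time = 500,
                           noise_sigma = 0, duration = 300)
  expect_false(detect_lock_point(drying_curve(s2), 4.5e-9)$found)
  # plateau from the start locks at the first qualifying sample
  flat <- droplet_series(0:19, rep(1e-3, 20), rep(1e-3, 20), 30)
  lp0 <- detect_lock_point(drying_curve(flat), 4.5e-9)
  expect_true(lp0$found)
  expect_equal(lp0$time, 0)
})

test_that("Peclet number and enrichment follow their defining relations", {
  expect_equal(peclet_number(8 * 1e-10, 1e-10), 1, tolerance = 1e-15)
  # back-computed from a published-scale pair: kappa = 4.53e-9, Ds = 0.93e-10
  expect_equal(peclet_number(4.53e-9, 0.93e-10), 6.09, tolerance = 1e-3)
  expect_lt(peclet_number(1e-9, 1), 1e-8)
  expect_error(peclet_number(-1, 1), "positive")
  expect_identical(surface_enrichment(0), 1)
  expect_equal(suppressWarnings(surface_enrichment(20)), 11, tolerance = 1e-12)
  expect_equal(surface_enrichment(5), 2.28125, tolerance = 1e-12)
  pe <- seq(0, 19, by = 0.5)
  expect_true(all(diff(surface_enrichment(pe)) > 0))
  expect_error(surface_enrichment(-0.1), "non-negative")
  expect_warning(surface_enrichment(25), "validity")
})

test_that("enrichment inversion is an exact round trip", {
  expect_identical(invert_enrichment(1), 0)
  expect_equal(invert_enrichment(11), 20, tolerance = 1e-7)
  for (pe in c(0.5, 6.09, 19.17))
    expect_equal(invert_enrichment(suppressWarnings(surface_enrichment(pe))),
                 pe, tolerance = 1e-8)
  expect_error(invert_enrichment(0.9), ">= 1")
})

test_that("diffusivity estimation round-trips a simulated droplet", {
  kappa <- 4.5e-9
  ds_true <- 0.93e-10
  s <- gen_droplet_series(d0 = 2e-3, kappa = kappa, lock_time = 400,
                          aspect_ratio = 1.2, noise_sigma = 0)
  curve <- drying_curve(s)
  lp <- detect_lock_point(curve, kappa)
  pe_true <- peclet_number(kappa, ds_true)
  cs <- surface_enrichment(pe_true) * lp$mean_concentration
  est <- estimate_diffusivity(kappa, lp, cs)
  expect_equal(est$diffusivity, ds_true, tolerance = 1e-6)
  # internal consistency: Pe = kappa / (8 Ds) and E = E(Pe)
  expect_equal(est$peclet, est$kappa / (8 * est$diffusivity),
               tolerance = 1e-12)
  expect_equal(est$enrichment, surface_enrichment(est$peclet),
               tolerance = 1e-8)
  # delta-method uncertainty: a finite-difference check of the chain
  cs_se <- 0.02 * cs
  est_u <- estimate_diffusivity(kappa, lp, cs, kappa_se = 0.01 * kappa,
                                cs_se = cs_se)
  pe_hi <- invert_enrichment((cs + cs_se) / lp$mean_concentration)
  expect_equal(est_u$peclet_se, pe_hi - est_u$peclet, tolerance = 0.05)
  expect_gt(est_u$diffusivity_se, 0)
  # degenerate flat profile and non-physical enrichment
  flat <- estimate_diffusivity(kappa, lp, lp$mean_concentration)
  expect_true(flat$flat_profile)
  expect_identical(flat$diffusivity, Inf)
  expect_error(estimate_diffusivity(kappa, lp, 0.5 * lp$mean_concentration),
               "non-physical")
})
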