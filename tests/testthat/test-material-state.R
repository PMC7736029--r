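test_that("Gordon-Taylor endpoints are exact and interior values match hand substitution", {
  gt <- gordon_taylor_params(tg_solid = 389, tg_water = 136,
                             k_constant = 6.04)
  expect_identical(gordon_taylor_tg(0, gt), 389)
  expect_identical(gordon_taylor_tg(1, gt), 136)
  # direct hand substitution at w_w = 0.05:
  # (0.95*389 + 6.04*0.05*136) / (0.95 + 6.04*0.05)
  expect_equal(gordon_taylor_tg(0.05, gt), 327.9728, tolerance = 1e-4)
  expect_error(gordon_taylor_tg(1.2, gt), "\\[0, 1\\]")
})

test_that("Gordon-Taylor is strictly decreasing and bounded for K > 0", {
  for (k in c(0.5, 1, 6.04, 20)) {
    gt <- gordon_taylor_params(k_constant = k)
    tg <- gordon_taylor_tg(seq(0, 1, by = 0.01), gt)
    expect_true(all(diff(tg) < 0))
    expect_true(all(tg >= 136 & tg <= 389))
  }
})

test_that("fitting recovers the Gordon-Taylor constant", {
  gt_true <- gordon_taylor_params(k_constant = 6.04)
  w <- seq(0.02, 0.3, length.out = 10)
  tg <- gordon_taylor_tg(w, gt_true)
  fit <- fit_gordon_taylor(w, tg)
  expect_equal(fit$k_constant, 6.04, tolerance = 1e-6)
  # noisy recovery: estimate within its own standard error band
  set.seed(11)
  fit_n <- fit_gordon_taylor(w, tg + rnorm(10, 0, 2))
  expect_lt(abs(fit_n$k_constant - 6.04), 2 * fit_n$k_se)
  expect_error(fit_gordon_taylor(w[1:2], tg[1:2]), "at least 3")
  expect_error(fit_gordon_taylor(rep(0.1, 5), rep(350, 5)), "degenerate")
})

test_that("noisy Gordon-Taylor fits cover the truth at the stated rate", {
  gt_true <- gordon_taylor_params(k_constant = 6.04)
  w <- seq(0.02, 0.3, length.out = 10)
  tg0 <- gordon_taylor_tg(w, gt_true)
  set.seed(202)
  fits <- lapply(1:200, function(i) fit_gordon_taylor(w, tg0 + rnorm(10, 0, 2)))
  # a +/- 2 SE band at n = 10 has ~92% nominal coverage (t, 9 df); the
  # nominal-level band uses the t quantile. Thresholds allow binomial
  # error at 200 replicates.
  cov2se <- mean(vapply(fits, function(f)
    abs(f$k_constant - 6.04) <= 2 * f$k_se, TRUE))
  cov_t <- mean(vapply(fits, function(f)
    abs(f$k_constant - 6.04) <= stats::qt(0.975, 9) * f$k_se, TRUE))
  expect_gte(cov2se, 0.87)
  expect_gte(cov_t, 0.91)
})

test_that("GAB isotherm is zero at zero activity and strictly increasing", {
  iso <- default_trehalose_isotherm()
  expect_identical(equilibrium_moisture(0, iso), 0)
  aw <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(equilibrium_moisture(aw, iso)) > 0))
  expect_gt(equilibrium_moisture(0.6, iso), equilibrium_moisture(0.3, iso))
  expect_error(equilibrium_moisture(1, iso), "\\[0, 1\\)")
})

test_that("GAB fitting recovers parameters from sorption data", {
  iso <- sorption_isotherm(0.058, 9.5, 0.92)
  clean <- gen_sorption_dataset(iso, n = 15, noise_sigma = 0)
  fit <- fit_isotherm(clean$water_activity, clean$moisture)
  expect_equal(fit$monolayer_capacity, 0.058, tolerance = 1e-6)
  expect_equal(fit$energy_constant_c, 9.5, tolerance = 1e-5)
  expect_equal(fit$correction_constant_k, 0.92, tolerance = 1e-6)
  # 2% relative noise, fixed seed: parameters back within 1%...
  noisy <- gen_sorption_dataset(iso, n = 15, noise_sigma = 0.02, seed = 5)
  fit_n <- fit_isotherm(noisy$water_activity, noisy$moisture)
  expect_equal(fit_n$monolayer_capacity, 0.058, tolerance = 0.01)
  expect_equal(fit_n$correction_constant_k, 0.92, tolerance = 0.01)
  # ...and the fitted curve within the 2% noise scale
  aw <- seq(0.1, 0.85, by = 0.05)
  expect_equal(equilibrium_moisture(aw, fit_n), equilibrium_moisture(aw, iso),
               tolerance = 0.02)
  expect_error(fit_isotherm(c(0.1, 0.2, 0.3), c(1, 2, 3)), "at least 4")
  expect_error(fit_isotherm(seq(0.3, 0.5, length.out = 6), rep(0.01, 6)),
               "span")
  expect_error(fit_isotherm(seq(0.1, 0.8, length.out = 6), rep(0, 6)),
               "non-positive")
})

test_that("stickiness curves satisfy their defining equation and ordering", {
  gt <- gordon_taylor_params()
  iso <- default_trehalose_isotherm()
  grid <- seq(300, 370, by = 10)
  c0 <- build_stickiness_curve(gt, iso, offset = 0, temperature_grid = grid)
  c10 <- build_stickiness_curve(gt, iso, offset = 10, temperature_grid = grid)
  # each point re-evaluates its defining equation to < 1e-6 K
  for (cc in list(c0, c10)) {
    off <- attr(cc, "offset")
    for (i in seq_len(nrow(cc))) {
      tg_i <- gordon_taylor_tg(
        wet_basis_fraction(equilibrium_moisture(cc$relative_humidity[i], iso)),
        gt)
      expect_lt(abs(tg_i + off - cc$dry_bulb_temperature[i]), 1e-6)
    }
    expect_true(all(diff(cc$relative_humidity) < 0))
  }
  # offset curves never cross; 10 K curve lies at higher humidity
  both <- merge(as.data.frame(c0), as.data.frame(c10),
                by = "dry_bulb_temperature")
  expect_true(all(both$specific_humidity.y > both$specific_humidity.x))
})

test_that("stickiness roots agree with a brute-force RH scan", {
  gt <- gordon_taylor_params()
  iso <- default_trehalose_isotherm()
  cc <- build_stickiness_curve(gt, iso, offset = 10,
                               temperature_grid = c(310, 330, 350))
  rh_grid <- seq(1e-4, 0.999, by = 1e-4)
  for (i in seq_len(nrow(cc))) {
    resid <- abs(gordon_taylor_tg(
      wet_basis_fraction(equilibrium_moisture(rh_grid, iso)), gt) +
      10 - cc$dry_bulb_temperature[i])
    expect_lt(abs(rh_grid[which.min(resid)] - cc$relative_humidity[i]), 2e-4)
  }
})

test_that("zone classification partitions the chart monotonically", {
  gt <- gordon_taylor_params()
  iso <- default_trehalose_isotherm()
  # bone-dry cold state: far below the dry Tg of 389 K
  expect_equal(as.character(classify_zone(
    moist_air_state(300, relative_humidity = 1e-9), gt, iso)), "safe")
  # construct a state exactly at Tg + offset/2 for its humidity: transition
  x_mid <- equilibrium_moisture(0.5, iso)
  tg_mid <- gordon_taylor_tg(x_mid / (1 + x_mid), gt)
  z <- classify_zone(moist_air_state(tg_mid + 5, relative_humidity = 0.5),
                     gt, iso)
  expect_equal(as.character(z), "transition")
  # hot humid state: hand-chain shows plasticized Tg below T_db - 10
  hot <- moist_air_state(360, relative_humidity = 0.45)
  x_eq <- equilibrium_moisture(0.45, iso)
  tg_hand <- gordon_taylor_tg(x_eq / (1 + x_eq), gt)
  expect_gt(360, tg_hand + 10)
  expect_equal(as.character(classify_zone(hot, gt, iso)), "risk")
  # moving T_db up at fixed (moderate) humidity only ever goes
  # safe -> transition -> risk
  y_fix <- specific_humidity_from_rh(320, 0.1)
  zs <- vapply(seq(300, 440, by = 2), function(tdb) {
    rh <- as.numeric(rh_from_specific_humidity(tdb, y_fix))
    as.character(classify_zone(moist_air_state(tdb, relative_humidity = rh),
                               gt, iso))
  }, "")
  ord <- c(safe = 1, transition = 2, risk = 3)
  expect_true(all(diff(ord[zs]) >= 0))
  expect_error(classify_zone(moist_air_state(280, specific_humidity = 0.1),
                             gt, iso), "supersaturated")
})

test_that("dihydrate risk uses a strict threshold", {
  expect_false(dihydrate_risk(moist_air_state(300, relative_humidity = 0.30)))
  expect_true(dihydrate_risk(moist_air_state(300, relative_humidity = 0.52)))
  expect_false(dihydrate_risk(moist_air_state(300, relative_humidity = 0.44)))
})
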