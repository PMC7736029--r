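make_config <- function(...) {
  args <- list(
    dry_gas_mass_flow = 0.0063,
    inlet_set_temperature = 403.15,
    feed_rate = 1.86e-6 / 60,
    heat_loss_p4_p5 = 2, heat_loss_p5_p9 = 1,
    ambient_state = moist_air_state(295.15, relative_humidity = 0.40))
  repl <- list(...)
  args[names(repl)] <- repl
  do.call(dryer_config, args)
}

test_that("zero feed leaves temperature and humidity untouched at P4", {
  cfg <- make_config(feed_rate = 0, heat_loss_p4_p5 = 0, heat_loss_p5_p9 = 0)
  st <- station_states(cfg)
  expect_equal(st$dry_bulb_temperature[st$station_id == "P4"],
               st$dry_bulb_temperature[st$station_id == "P3"])
  expect_true(all(abs(st$specific_humidity - st$specific_humidity[1]) < 1e-15))
})

test_that("water mass is conserved across the stations", {
  cfg <- make_config()
  st <- station_states(cfg)
  y1 <- st$specific_humidity[st$station_id == "P1"]
  y9 <- st$specific_humidity[st$station_id == "P9"]
  sprayed <- cfg$feed_rate * cfg$feed_density * cfg$feed_water_fraction
  expect_equal((y9 - y1) * cfg$dry_gas_mass_flow, sprayed,
               tolerance = 1e-12)
  # humidity never decreases downstream of P3
  down <- st[st$station_id %in% c("P3", "P4", "P5", "P7", "P9"), ]
  expect_true(all(diff(down$specific_humidity) >= 0))
})

test_that("hot and cold configurations land on opposite sides of the design space", {
  gt <- gordon_taylor_params()
  iso <- default_trehalose_isotherm()
  # high feed at low temperature: insufficient drying, risk/condensation
  cold <- station_states(make_config(inlet_set_temperature = 318.15,
                                     feed_rate = 2.5e-6 / 60),
                         gt, iso)
  bad <- cold[cold$station_id %in% c("P5", "P7", "P9"), ]
  expect_true(any(bad$supersaturated | (!is.na(bad$zone) & bad$zone == "risk")))
  # 130 degC inlet analog at moderate feed: product-side stations safe
  hot <- station_states(make_config(), gt, iso)
  expect_equal(hot$zone[hot$station_id == "P5"], "safe")
  expect_false(any(hot$supersaturated))
})

test_that("response surface recovers an exact quadratic and rejects thin designs", {
  set.seed(3)
  fr <- runif(12, 1, 6); tin <- runif(12, 310, 410)
  beta <- c(5, 2, 0.05, -0.1, -2e-4, 4e-3)
  rh <- beta[1] + beta[2] * fr + beta[3] * tin + beta[4] * fr^2 +
    beta[5] * tin^2 + beta[6] * fr * tin
  pts <- data.frame(feed_rate = fr, inlet_temperature = tin, rh = rh,
                    passed = TRUE)
  surf <- suppressWarnings(fit_rh_response_surface(pts))
  expect_equal(unname(surf$coefficients),
               beta[c(1, 2, 3, 4, 5, 6)], tolerance = 1e-8)
  expect_equal(predict(surf, fr[1], tin[1]), rh[1], tolerance = 1e-8)
  # with noise, training predictions stay within 2 sigma
  pts_n <- pts
  pts_n$rh <- rh + rnorm(12, 0, 0.005)
  surf_n <- fit_rh_response_surface(pts_n)
  expect_true(all(abs(predict(surf_n, fr, tin) - pts_n$rh) < 2 * 0.005))
  expect_error(fit_rh_response_surface(pts[1:5, ]), "at least 6")
  collinear <- data.frame(feed_rate = 1:7, inlet_temperature = 2 * (1:7),
                          rh = rnorm(7), passed = TRUE)
  expect_error(fit_rh_response_surface(collinear), "rank deficient")
})

test_that("operation limit band brackets passed and failed runs", {
  pts <- data.frame(rh = c(50, 57.64, 63.72, 70),
                    passed = c(TRUE, TRUE, FALSE, FALSE))
  band <- operation_limit_band(pts)
  expect_equal(unname(band), c(57.64, 63.72))
  expect_equal(unname(operation_limit_band(
    data.frame(rh = c(40, 60), passed = c(TRUE, FALSE)))), c(40, 60))
  expect_warning(operation_limit_band(
    data.frame(rh = c(65, 60), passed = c(TRUE, FALSE))), "overlap")
  expect_error(operation_limit_band(
    data.frame(rh = c(1, 2), passed = c(TRUE, TRUE))), "at least one")
})

test_that("cyclone cut size follows the Barth model and its scaling laws", {
  cfg <- cyclone_config(inlet_width = 0.006, inlet_height = 0.013,
                        body_diameter = 0.044,
                        vortex_finder_diameter = 0.011,
                        vortex_length = 0.07,
                        gas_volumetric_flow = 0.0058)
  # hand evaluation of the same geometry through the model equations
  u_e <- 0.0058 / (0.006 * 0.013)
  r_e <- (0.044 - 0.006) / 2
  r_i <- 0.011 / 2
  u_i <- u_e * r_e / r_i
  v_r <- 0.0058 / (2 * pi * r_i * 0.07)
  d50_hand <- sqrt(18 * 1.85e-5 * v_r * r_i / ((1500 - 1.2) * u_i^2))
  expect_equal(cyclone_cutoff(cfg), d50_hand, tolerance = 1e-9)
  # quadrupling the gas flow halves the cut size
  cfg4 <- cyclone_config(0.006, 0.013, 0.044, 0.011, 0.07, 4 * 0.0058)
  expect_equal(cyclone_cutoff(cfg4), cyclone_cutoff(cfg) / 2,
               tolerance = 1e-12)
  # doubling the density difference divides by sqrt(2)
  cfg_rho <- cyclone_config(0.006, 0.013, 0.044, 0.011, 0.07, 0.0058,
                            particle_density = 2 * (1500 - 1.2) + 1.2)
  expect_equal(cyclone_cutoff(cfg_rho), cyclone_cutoff(cfg) / sqrt(2),
               tolerance = 1e-12)
  expect_error(cyclone_config(0.03, 0.013, 0.044, 0.011, 0.07, 0.0058),
               "body radius")
})

test_that("yield accounting matches direct substitution and flags anomalies", {
  # 500 mg at 4 wt% residual moisture from 30 mg/mL x 20 mL
  expect_equal(process_yield(500e-6, 0.04, 30, 20e-6), 0.80,
               tolerance = 1e-12)
  expect_identical(process_yield(0, 0.04, 30, 20e-6), 0)
  # rm180 = 0 reduces to the plain mass recovery ratio
  expect_equal(process_yield(450e-6, 0, 30, 20e-6), 0.75, tolerance = 1e-12)
  # invariant under unit changes (mg/mL == kg/m^3)
  expect_equal(process_yield(500e-6, 0.04, 30, 20e-6),
               process_yield(500e-6, 0.04, 0.030 * 1000, 20e-6),
               tolerance = 1e-15)
  expect_warning(y <- process_yield(700e-6, 0, 30, 20e-6), "anomaly")
  expect_gt(y, 1)
  expect_error(process_yield(500e-6, 0.04, 0, 20e-6), "zero")
})

test_that("sensor logs parse, segment and summarize", {
  cfg <- make_config()
  log <- gen_process_log(cfg, sensor_noise = list(t = 0, rh = 0, p = 0,
                                                  fr = 0), seed = 2)
  truth <- attr(log, "true_boundaries")
  seg <- segment_phases(log, solution_switch_time = truth[["PrP"]])
  expect_true(all(abs(seg$boundaries[names(truth)[-1]] - truth[-1]) <= 1.5))
  ss <- steady_state_extract(log, "PrP", window = 300, phases = seg)
  expect_true(attr(ss, "stationary"))
  expect_equal(ss$sd[ss$channel == "rh_p9"], 0, tolerance = 1e-10)
  # a ramping window fails the stationarity check
  ramp <- log
  sel <- seg$phase == "PrP"
  ramp$t_p5[sel] <- ramp$t_p5[sel] + seq(0, 60, length.out = sum(sel))
  ss_ramp <- steady_state_extract(ramp, "PrP", window = 300, phases = seg)
  expect_false(attr(ss_ramp, "stationary"))
  # missing channel and non-monotone time are parse errors
  bad <- data.frame(time_s = 1:3, T_P3_R_C = 1:3)
  expect_error(parse_sensor_log(bad), "missing channel")
  full <- data.frame(time_s = c(1, 2, 2), T_P3_R_C = 0, T_P5_R_C = 0,
                     T_P9_R_C = 0, RH_P9_R_pct = 0, p_P9_R_Pa = 1e5,
                     FR_P11_R_mL_min = 0)
  expect_error(parse_sensor_log(full), "strictly increasing")
})

test_that("filter pressure check flags drifts beyond 5%", {
  base <- data.frame(time_s = 0:599, T_P3_R_C = 70, T_P5_R_C = 45,
                     T_P9_R_C = 40, RH_P9_R_pct = 30,
                     p_P9_R_Pa = 101000, FR_P11_R_mL_min = 2)
  expect_equal(filter_pressure_check(parse_sensor_log(base))$max_relative_change,
               0, tolerance = 1e-12)
  drift <- base
  drift$p_P9_R_Pa <- 101000 *
    (1 - 0.03 * pmax(0, drift$time_s - 60) / (599 - 60))
  fp <- filter_pressure_check(parse_sensor_log(drift))
  expect_equal(fp$max_relative_change, 0.03, tolerance = 1e-9)
  expect_true(fp$pass)
  step <- base
  step$p_P9_R_Pa[300:600] <- 101000 * 0.92
  expect_false(filter_pressure_check(parse_sensor_log(step))$pass)
})
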