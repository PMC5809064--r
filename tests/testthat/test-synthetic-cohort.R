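test_that("the noise-free forward model is the closed-form attenuation law", {
  ph <- phantom_map("wedge", shape = c(16, 16), spacing_mm = 2, cax_cm = 15)
  b <- beam_spec("B1", mu = 150)
  cfg <- sim_config(noise_sigma = 0)
  img <- simulate_transit_image(ph, b, config = cfg)
  expect_equal(img$signal, cfg$s0 * 150 * exp(-cfg$mu_eff * ph$thickness),
               tolerance = 1e-12)
})

test_that("output drift multiplies the whole image; noise-free", {
  ph <- phantom_map("anatomy", shape = c(24, 24), spacing_mm = 2)
  b <- beam_spec("B1", mu = 100)
  cfg <- sim_config(noise_sigma = 0)
  base <- simulate_transit_image(ph, b, config = cfg)
  drift <- simulate_transit_image(ph, b,
    perturbation_spec("output_drift", output_scale = 0.03), cfg)
  expect_equal(drift$signal, base$signal * 1.03, tolerance = 1e-12)
})

test_that("a setup shift translates the image (interior pixels)", {
  ph <- phantom_map("step", shape = c(24, 24), spacing_mm = 2, cax_cm = 12,
                    step_cm = 6)
  b <- beam_spec("B1", mu = 100)
  cfg <- sim_config(noise_sigma = 0)
  base <- simulate_transit_image(ph, b, config = cfg)
  # 6 mm = 3 whole pixels along +x: interior columns shift right by 3
  shifted <- simulate_transit_image(ph, b,
    perturbation_spec("setup_shift", shift_mm = c(6, 0)), cfg)
  expect_equal(shifted$signal[, 4:24], base$signal[, 1:21], tolerance = 1e-10)
  # against an independently shifted array at a non-integer shift (5 mm)
  shifted5 <- simulate_transit_image(ph, b,
    perturbation_spec("setup_shift", shift_mm = c(5, 0)), cfg)
  co <- epidivd:::grid_xy(base)
  wimg <- image_grid(ph$thickness, ph$spacing_mm, ph$origin_mm)
  w_expect <- interp_bilinear(wimg, co$x - 5, co$y, clamp = TRUE)
  expect_equal(shifted5$signal, cfg$s0 * 100 * exp(-cfg$mu_eff * w_expect),
               tolerance = 1e-10)
  expect_error(simulate_transit_image(ph, b,
    perturbation_spec("setup_shift", shift_mm = c(500, 0)), cfg), "extent")
})

test_that("noise-free signal strictly decreases with thickness", {
  ph <- phantom_map("wedge", shape = c(8, 16), spacing_mm = 2, cax_cm = 15,
                    slope_cm_per_mm = 0.2)
  img <- simulate_transit_image(ph, beam_spec("B1", mu = 100),
                                config = sim_config(noise_sigma = 0))
  # thickness increases along x, so signal must strictly decrease
  expect_true(all(diff(t(img$signal)) < 0))
})

test_that("partial acquisition blanks the trailing row band", {
  ph <- phantom_map("flat", shape = c(20, 20), spacing_mm = 2)
  img <- simulate_transit_image(ph, beam_spec("B1", mu = 100),
    perturbation_spec("partial_acquisition", blank_fraction = 0.4),
    sim_config(noise_sigma = 0))
  expect_true(all(img$signal[13:20, ] == 0))
  expect_true(all(img$signal[1:12, ] > 0))
  expect_equal(attr(img, "blank_fraction"), 0.4)
})

test_that("simulation is deterministic given the seed", {
  ph <- phantom_map("anatomy", shape = c(24, 24), spacing_mm = 2)
  b <- beam_spec("B1", mu = 100)
  i1 <- simulate_transit_image(ph, b, config = sim_config(rng_seed = 42))
  i2 <- simulate_transit_image(ph, b, config = sim_config(rng_seed = 42))
  expect_identical(i1$signal, i2$signal)

  plans <- list(small_plan("P001"), small_plan("P002", "breast"))
  t1 <- simulate_cohort(plans, config = sim_config(rng_seed = 7))
  t2 <- simulate_cohort(plans, config = sim_config(rng_seed = 7))
  expect_identical(t1, t2)
})

test_that("perturbation kinds carry the documented error class", {
  expect_equal(perturbation_spec("none")$error_class, "none")
  expect_equal(perturbation_spec("setup_shift")$error_class, "1")
  expect_equal(perturbation_spec("attenuator")$error_class, "1")
  expect_equal(perturbation_spec("output_drift")$error_class, "1")
  expect_equal(perturbation_spec("morphologic_change")$error_class, "2")
  expect_equal(perturbation_spec("partial_acquisition")$error_class, "artifact")
})

test_that("an error-free noiseless cohort is entirely clean", {
  plans <- list(small_plan("P001"))
  rates <- c(setup_shift = 0, morphologic_change = 0, attenuator = 0,
             output_drift = 0, partial_acquisition = 0)
  tests <- simulate_cohort(plans, error_rates = rates,
                           config = sim_config(rng_seed = 3, noise_sigma = 0))
  expect_true(all(tests$error_class == "none"))
  # R is exact up to averaging the non-uniform anatomy signal over the ROI
  expect_equal(tests$r_value, rep(1, nrow(tests)), tolerance = 5e-3)
  expect_equal(tests$gamma_percent, rep(100, nrow(tests)))
  expect_false(any(tests$warning))
})

test_that("injected class-1 fraction matches its rate (binomial check)", {
  plans <- lapply(1:24, function(i) small_plan(sprintf("P%03d", i)))
  rates <- c(setup_shift = 0.1, morphologic_change = 0, attenuator = 0,
             output_drift = 0, partial_acquisition = 0)
  tests <- simulate_cohort(plans, error_rates = rates,
                           config = sim_config(rng_seed = 11),
                           correct_after_warning = FALSE)
  # one perturbation draw per fraction; count at fraction level
  frac <- unique(tests[c("patient_id", "fraction", "error_class")])
  phat <- mean(frac$error_class == "1")
  n <- nrow(frac)
  ci <- 0.1 + c(-1, 1) * qnorm(0.995) * sqrt(0.1 * 0.9 / n)
  expect_gt(phat, ci[1])
  expect_lt(phat, ci[2])
})

test_that("arc images integrate sub-beams and keep the CAX round trip exact", {
  ph <- phantom_map("anatomy", shape = c(32, 32), spacing_mm = 2, cax_cm = 18)
  arc <- beam_spec("A01", 0, mu = 240, arc_span_deg = 360)
  cfg <- sim_config(noise_sigma = 0)
  img <- simulate_arc_image(ph, arc, config = cfg)
  expect_error(simulate_arc_image(ph, arc, config = cfg, n_sub = 4), "8")
  # rotation about the CAX preserves the central thickness, so the transit
  # dose chain reconstructs the planned dose exactly
  cal <- calibration()
  m <- measure_transit(img, roi_radius_mm = 2.1)
  R <- compute_R(reconstruct_iso_dose(m, cal),
                 planned_iso_dose(ph$cax_thickness, 240, cal))
  expect_equal(R, 1, tolerance = 1e-3)
})
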