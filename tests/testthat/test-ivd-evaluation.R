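test_that("tolerance comparisons are inclusive and any failure raises the warning", {
  tol <- tolerance_config()
  ok <- evaluate_test(1.00, 100, tol, "pelvis", 0)
  expect_true(ok$pass_r && ok$pass_gamma_percent && ok$pass_gamma_mean)
  expect_false(ok$warning)
  # boundaries are inclusive: 0.95/1.05, 90, 0.4
  for (case in list(list(r = 0.95), list(r = 1.05),
                    list(gp = 90), list(gm = 0.4))) {
    fl <- evaluate_test(case$r %||% 1, case$gp %||% 100, tol, "pelvis",
                        case$gm %||% 0)
    expect_false(fl$warning)
  }
  # one index out of tolerance is enough
  expect_true(evaluate_test(1, 89.9, tol, "pelvis", 0)$warning)
  expect_true(evaluate_test(1.051, 100, tol, "pelvis", 0)$warning)
  expect_true(evaluate_test(1, 100, tol, "pelvis", 0.401)$warning)
  expect_error(evaluate_test(1, 100, tol, "knee", 0), "unknown site")
})

test_that("site-specific gamma criteria follow the clinical action limits", {
  tol <- tolerance_config()
  expect_equal(tol$site_criteria$HN$delta_s_percent, 3)
  expect_equal(tol$site_criteria$HN$delta_d_mm, 3)
  for (site in c("breast", "thorax", "abdomen", "pelvis")) {
    expect_equal(tol$site_criteria[[site]]$delta_s_percent, 5)
    expect_equal(tol$site_criteria[[site]]$delta_d_mm, 5)
  }
  expect_equal(unname(tol$max_shift_mm["HN"]), 3)
  expect_equal(unname(tol$max_shift_mm["pelvis"]), 5)
})

test_that("artifact exclusion applies the blanked-row and integral-signal rules", {
  tests <- data.frame(id = 1:4,
                      blank_fraction = c(0, 0.40, 0.02, 0),
                      integral_ratio = c(1.0, 0.6, 0.98, 0.45))
  sp <- exclude_artifacts(tests)
  expect_equal(sp$retained$id, c(1, 3))
  expect_equal(sp$excluded$id, c(2, 4))
  expect_equal(nrow(sp$retained) + nrow(sp$excluded), nrow(tests))
})

test_that("simulated partial acquisitions are excluded at about their injection rate", {
  plans <- lapply(1:16, function(i) small_plan(sprintf("P%03d", i)))
  rates <- c(setup_shift = 0, morphologic_change = 0, attenuator = 0,
             output_drift = 0, partial_acquisition = 0.15)
  tests <- simulate_cohort(plans, error_rates = rates,
                           config = sim_config(rng_seed = 5))
  sp <- exclude_artifacts(tests)
  expect_equal(nrow(sp$retained) + nrow(sp$excluded), nrow(tests))
  expect_true(all(sp$excluded$error_class == "artifact"))
  frac <- unique(tests[c("patient_id", "fraction", "error_class")])
  phat <- mean(frac$error_class == "artifact")
  n <- nrow(frac)
  ci <- 0.15 + c(-1, 1) * qnorm(0.995) * sqrt(0.15 * 0.85 / n)
  expect_gt(phat, ci[1]); expect_lt(phat, ci[2])
})

test_that("patient summary uses the two-stage unweighted mean", {
  tests <- data.frame(patient_id = "P1", site = "breast", technique = "IMRT",
                      beam_id = c("A", "A", "B", "B"),
                      r_value = c(1.00, 1.06, 0.96, 0.98),
                      gamma_percent = c(95, 91, 99, 97),
                      gamma_mean = c(0.2, 0.3, 0.1, 0.2),
                      stringsAsFactors = FALSE)
  s <- summarize_patient(tests)
  expect_equal(unname(s$r_beam[c("A", "B")]), c(1.03, 0.97))
  # the patient is in tolerance on R despite one off-tolerance test
  expect_equal(s$r_bar, 1.00)
  expect_true(s$pass_r)
  expect_equal(s$gamma_percent_bar, mean(c(93, 98)))
  # a single test is its own summary
  s1 <- summarize_patient(tests[1, ])
  expect_equal(s1$r_bar, 1.00)
  expect_equal(s1$gamma_mean_bar, 0.2)
  # permutation invariance
  s2 <- summarize_patient(tests[c(3, 1, 4, 2), ])
  expect_equal(s2$r_bar, s$r_bar)
  expect_equal(s2$gamma_percent_bar, s$gamma_percent_bar)
  expect_error(summarize_patient(tests[0, ]), "no evaluable tests")
})

test_that("cohort aggregation computes T% and P% per group and index", {
  tests <- data.frame(
    patient_id = rep(c("P1", "P2"), each = 4),
    site = "pelvis", technique = "IMRT",
    beam_id = rep(c("A", "B"), 4),
    r_value = 1, gamma_percent = c(95, 95, 85, 95, rep(95, 4)),
    gamma_mean = 0.2, stringsAsFactors = FALSE)
  tests$pass_r <- TRUE
  tests$pass_gamma_percent <- tests$gamma_percent >= 90
  tests$pass_gamma_mean <- TRUE
  summ <- lapply(split(tests, tests$patient_id), summarize_patient)
  agg <- aggregate_cohort(tests, summ)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$n_tests, 8)
  expect_equal(agg$n_patients, 2)
  expect_equal(agg$t_pct_r, 100)
  # 7 of 8 tests pass gamma%
  expect_equal(agg$t_pct_gamma_percent, 87.5)
  expect_equal(agg$t_pct_gamma_percent_disp, 88)  # half-up display rounding
  expect_equal(agg$p_pct_gamma_percent, 100)      # both patient means pass
})

test_that("display rounding is half-up, truncation differs where expected", {
  expect_equal(epidivd:::round_half_up(74.5), 75)
  expect_equal(epidivd:::round_half_up(75.5), 76)  # R's round() would give 76 too, but 74.5 -> 74
  expect_equal(round(74.5), 74)                    # the convention difference
  expect_equal(epidivd:::round_half_up(-0.5), -1)
})

test_that("classify_error returns ground truth verbatim and rules are advisory", {
  t1 <- data.frame(warning = TRUE, error_class = "1")
  expect_equal(classify_error(t1), "class1")
  t2 <- data.frame(warning = TRUE, error_class = "2")
  expect_equal(classify_error(t2), "class2")
  expect_error(classify_error(data.frame(warning = FALSE, error_class = "1")),
               "passing test")
  # slow monotone drift ending beyond tolerance suggests a morphological change
  drift <- seq(1.00, 1.06, length.out = 10)
  res <- classify_error(data.frame(warning = TRUE, error_class = NA),
                        r_series = drift)
  expect_equal(as.character(res), "class2")
  expect_true(attr(res, "advisory"))
  # an isolated jump suggests a setup/delivery cause
  jump <- c(1.00, 1.01, 0.99, 1.08, 1.00, 1.01)
  expect_equal(as.character(classify_error(
    data.frame(warning = TRUE, error_class = NA), r_series = jump)), "class1")
})

test_that("patient-level pass rates dominate test-level rates under corrections", {
  plans <- lapply(1:12, function(i)
    small_plan(sprintf("P%03d", i), site = c("pelvis", "breast")[1 + i %% 2]))
  tests <- simulate_cohort(plans, config = sim_config(rng_seed = 17),
                           correct_after_warning = TRUE)
  ev <- evaluate_cohort(tests)
  t_all <- with(ev$cohort, sum(t_pct_r * n_tests + t_pct_gamma_percent * n_tests +
                               t_pct_gamma_mean * n_tests) / (3 * sum(n_tests)))
  p_all <- with(ev$cohort, sum(p_pct_r * n_patients + p_pct_gamma_percent * n_patients +
                               p_pct_gamma_mean * n_patients) / (3 * sum(n_patients)))
  expect_gte(p_all, t_all)
})
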