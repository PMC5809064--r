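#' Tolerance configuration
#'
#' The tolerance levels of the IVD procedure: R in [0.95, 1.05] (all bounds
#' inclusive), gamma% >= 90, gamma_mean <= 0.4, together with the per-site
#' gamma criteria (3%/3 mm for head-and-neck, 5%/5 mm elsewhere — the
#' distance criterion matches the maximum setup displacement accepted
#' clinically) and the CBCT action limits.
#'
#' @param r_low,r_high R tolerance band (default 0.95, 1.05).
#' @param gamma_percent_min minimum gamma% (default 90).
#' @param gamma_mean_max maximum gamma_mean (default 0.4).
#' @param site_criteria named list mapping site to a [gamma_criteria].
#' @param max_shift_mm named vector of CBCT action limits (mm).
#' @return An object of class `tolerance_config`.
#' @export
tolerance_config <- function(r_low = 0.95, r_high = 1.05,
                             gamma_percent_min = 90, gamma_mean_max = 0.4,
                             site_criteria = NULL, max_shift_mm = NULL) {
  if (!(r_low < 1 && 1 < r_high)) stop("R band must contain 1")
  if (gamma_percent_min <= 0 || gamma_percent_min > 100)
    stop("gamma_percent_min must be in (0, 100]")
  if (gamma_mean_max <= 0) stop("gamma_mean_max must be positive")
  if (is.null(site_criteria)) {
    site_criteria <- list(
      HN      = gamma_criteria(3, 3),
      breast  = gamma_criteria(5, 5),
      thorax  = gamma_criteria(5, 5),
      abdomen = gamma_criteria(5, 5),
      pelvis  = gamma_criteria(5, 5))
  }
  if (is.null(max_shift_mm))
    max_shift_mm <- c(HN = 3, breast = 5, thorax = 5, abdomen = 5, pelvis = 5)
  structure(list(r_low = r_low, r_high = r_high,
                 gamma_percent_min = gamma_percent_min,
                 gamma_mean_max = gamma_mean_max,
                 site_criteria = site_criteria, max_shift_mm = max_shift_mm),
            class = "tolerance_config")
}

#' Evaluate one IVD test against the tolerance levels
#'
#' One test is the triple (R, gamma%, gamma_mean) for one beam of one
#' fraction. Each index is compared inclusively against its tolerance and a
#' warning is raised when at least one index is out of tolerance.
#'
#' @param r_value isocentre dose ratio R.
#' @param gamma_result a `gamma_result` from [compute_gamma], or a numeric
#'   gamma% (then supply `gamma_mean`).
#' @param tol a [tolerance_config].
#' @param site treatment site (must be a key of `tol$site_criteria`).
#' @param gamma_mean gamma_mean value when `gamma_result` is numeric.
#' @return list with `pass_r`, `pass_gamma_percent`, `pass_gamma_mean`,
#'   `warning`.
#' @export
evaluate_test <- function(r_value, gamma_result, tol = tolerance_config(),
                          site = "pelvis", gamma_mean = NULL) {
  if (!site %in% names(tol$site_criteria)) stop("unknown site: ", site)
  if (inherits(gamma_result, "gamma_result")) {
    gp <- gamma_result$gamma_percent
    gm <- gamma_result$gamma_mean
  } else {
    gp <- gamma_result
    gm <- gamma_mean
  }
  if (!all(is.finite(c(r_value, gp, gm)))) stop("indices must be finite")
  pass_r <- r_value >= tol$r_low & r_value <= tol$r_high
  pass_gp <- gp >= tol$gamma_percent_min
  pass_gm <- gm <= tol$gamma_mean_max
  list(pass_r = pass_r, pass_gamma_percent = pass_gp, pass_gamma_mean = pass_gm,
       warning = !(pass_r && pass_gp && pass_gm))
}

#' Exclude acquisition artifacts from the analysis
#'
#' Tests whose images were corrupted by the acquisition itself (panel
#' mispositioned, acquisition not synchronised with delivery, partially
#' acquired images) show extreme index values and are excluded before any
#' averaging. The rule flags a test when more than 5% of image rows are
#' blanked or the integral signal falls below 50% of the reference image's.
#'
#' @param tests data.frame of IVD tests with columns `blank_fraction` and
#'   `integral_ratio`.
#' @param blank_max maximum tolerated blanked-row fraction (default 0.05).
#' @param integral_min minimum integral-signal ratio vs reference (0.5).
#' @return list with data.frames `retained` and `excluded`.
#' @export
exclude_artifacts <- function(tests, blank_max = 0.05, integral_min = 0.5) {
  stopifnot(is.data.frame(tests),
            all(c("blank_fraction", "integral_ratio") %in% names(tests)))
  bad <- tests$blank_fraction > blank_max | tests$integral_ratio < integral_min
  list(retained = tests[!bad, , drop = FALSE],
       excluded = tests[bad, , drop = FALSE])
}

#' Per-patient summary by two-stage averaging
#'
#' For each beam, R is averaged over the days it was tested (R_beam); the
#' patient mean R-bar is the unweighted average of the R_beam values. The
#' gamma indices are averaged with the same two-stage modality. The patient
#' is in tolerance on an index when its mean satisfies the same inclusive
#' tolerance as a single test.
#'
#' @param tests data.frame of the (artifact-retained) tests of one patient,
#'   with columns `beam_id`, `r_value`, `gamma_percent`, `gamma_mean`.
#' @param tol a [tolerance_config].
#' @return list of class `patient_summary`: `r_beam` (named vector),
#'   `r_bar`, `gamma_percent_bar`, `gamma_mean_bar`, per-index `pass_*`
#'   flags and `in_tolerance`.
#' @export
summarize_patient <- function(tests, tol = tolerance_config()) {
  stopifnot(is.data.frame(tests))
  if (nrow(tests) == 0) stop("no evaluable tests for this patient")
  stage1 <- function(v) c(tapply(v, tests$beam_id, mean))  # plain named vector
  r_beam <- stage1(tests$r_value)
  gp_beam <- stage1(tests$gamma_percent)
  gm_beam <- stage1(tests$gamma_mean)
  r_bar <- mean(r_beam)
  gp_bar <- mean(gp_beam)
  gm_bar <- mean(gm_beam)
  pass_r <- r_bar >= tol$r_low && r_bar <= tol$r_high
  pass_gp <- gp_bar >= tol$gamma_percent_min
  pass_gm <- gm_bar <= tol$gamma_mean_max
  structure(list(
    patient_id = if ("patient_id" %in% names(tests)) tests$patient_id[1] else NA,
    site = if ("site" %in% names(tests)) tests$site[1] else NA,
    technique = if ("technique" %in% names(tests)) tests$technique[1] else NA,
    n_tests = nrow(tests),
    r_beam = r_beam, r_bar = r_bar,
    gamma_percent_bar = gp_bar, gamma_mean_bar = gm_bar,
    pass_r = pass_r, pass_gamma_percent = pass_gp, pass_gamma_mean = pass_gm,
    in_tolerance = pass_r && pass_gp && pass_gm),
    class = "patient_summary")
}

# round half away from zero, the convention used for the displayed integer
# percentages (R's round() is half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Aggregate a cohort into T% and P% tables
#'
#' Per (site, technique) group and per index: T% is the percentage of
#' retained tests with that index in tolerance; P% is the percentage of
#' patients whose two-stage mean index is in tolerance. Unrounded values are
#' kept alongside the half-up-rounded integers used for display.
#'
#' @param tests data.frame of retained tests with pass flags (see
#'   [evaluate_test]) and `site`/`technique` columns.
#' @param summaries list of `patient_summary` objects (or a data.frame with
#'   the same pass columns plus `site`/`technique`).
#' @return data.frame of class `cohort_summary`, one row per group, with
#'   `n_patients`, `n_tests`, `t_pct_*`, `p_pct_*` and their `*_disp`
#'   rounded counterparts.
#' @export
aggregate_cohort <- function(tests, summaries) {
  stopifnot(is.data.frame(tests))
  if (!is.data.frame(summaries)) {
    summaries <- do.call(rbind, lapply(summaries, function(s)
      data.frame(patient_id = s$patient_id, site = s$site,
                 technique = s$technique, pass_r = s$pass_r,
                 pass_gamma_percent = s$pass_gamma_percent,
                 pass_gamma_mean = s$pass_gamma_mean,
                 stringsAsFactors = FALSE)))
  }
  groups <- unique(rbind(tests[c("site", "technique")],
                         summaries[c("site", "technique")]))
  groups <- groups[order(groups$site, groups$technique), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    ti <- tests$site == groups$site[g] & tests$technique == groups$technique[g]
    pi <- summaries$site == groups$site[g] & summaries$technique == groups$technique[g]
    if (!any(ti) && !any(pi)) {
      message("empty group omitted: ", groups$site[g], "/", groups$technique[g])
      return(NULL)
    }
    pct <- function(x) if (length(x)) 100 * mean(x) else NA_real_
    data.frame(
      site = groups$site[g], technique = groups$technique[g],
      n_patients = sum(pi), n_tests = sum(ti),
      t_pct_r = pct(tests$pass_r[ti]),
      t_pct_gamma_percent = pct(tests$pass_gamma_percent[ti]),
      t_pct_gamma_mean = pct(tests$pass_gamma_mean[ti]),
      p_pct_r = pct(summaries$pass_r[pi]),
      p_pct_gamma_percent = pct(summaries$pass_gamma_percent[pi]),
      p_pct_gamma_mean = pct(summaries$pass_gamma_mean[pi]),
      stringsAsFactors = FALSE)
  }))
  for (col in grep("^(t|p)_pct_", names(out), value = TRUE))
    out[[paste0(col, "_disp")]] <- round_half_up(out[[col]])
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Classify the cause of an off-tolerance test
#'
#' With simulator ground truth (an `error_class` field on the test), the
#' injected class is returned verbatim. Without ground truth, a rule-based
#' *advisory* suggestion is produced from the patient's R series for the
#' beam: a slow monotone drift of R across fractions that ends beyond the
#' tolerance band suggests a morphological change (class 2); an isolated
#' jump against an otherwise stable series suggests a setup/delivery cause
#' (class 1); anything else is left unexplained. In clinical use the
#' attribution is adjudicated by a physicist and a radiation oncologist;
#' the rule only ranks hypotheses.
#'
#' @param test a single-row data.frame (or list) for a warned test; must
#'   carry `warning = TRUE`. If it has a non-`"none"` `error_class`, that
#'   ground truth is returned.
#' @param r_series optional numeric vector of R values across fractions for
#'   the same beam, used for the rule-based suggestion.
#' @param tol a [tolerance_config].
#' @return `"class1"`, `"class2"` or `"unexplained"`; rule-based results
#'   carry an attribute `advisory = TRUE`.
#' @export
classify_error <- function(test, r_series = NULL, tol = tolerance_config()) {
  warn <- if (is.data.frame(test)) test$warning[1] else test$warning
  if (is.null(warn) || !isTRUE(warn))
    stop("classify_error called on a passing test")
  ec <- if (is.data.frame(test)) test$error_class[1] else test$error_class
  if (!is.null(ec) && !is.na(ec) && ec %in% c("1", "2"))
    return(paste0("class", ec))
  out <- "unexplained"
  if (!is.null(r_series) && length(r_series) >= 4) {
    d <- diff(r_series)
    ends_out <- r_series[length(r_series)] < tol$r_low ||
                r_series[length(r_series)] > tol$r_high
    monotone <- all(d >= -1e-9) || all(d <= 1e-9)
    slow <- max(abs(d)) <= (tol$r_high - tol$r_low) / 2
    if (monotone && slow && ends_out) {
      out <- "class2"
    } else {
      n_out <- sum(r_series < tol$r_low | r_series > tol$r_high)
      if (n_out >= 1 && n_out <= ceiling(length(r_series) / 3)) out <- "class1"
    }
  }
  attr(out, "advisory") <- TRUE
  out
}
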