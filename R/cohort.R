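#' Build a cohort of treatment plans
#'
#' Generates [plan_spec] objects for a cohort. `n_per_group` gives the number
#' of patients per (site, technique) cell; the default reproduces the study
#' cohort's distribution of 147 patients over 5 sites x 2 techniques. IMRT
#' plans draw 5-9 static beams at spread gantry angles; VMAT plans draw 1-2
#' arcs. Uses the current RNG stream.
#'
#' @param n_per_group named numeric vector `"<site>.<technique>" -> count`,
#'   or `NULL` for the study distribution.
#' @param mu_range range of monitor units per beam.
#' @return list of [plan_spec] objects.
#' @export
make_cohort_plans <- function(n_per_group = NULL, mu_range = c(80, 200)) {
  if (is.null(n_per_group)) n_per_group <- study_patient_counts()
  plans <- list()
  pid <- 0
  for (key in names(n_per_group)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    site <- parts[1]; technique <- parts[2]
    for (i in seq_len(n_per_group[[key]])) {
      pid <- pid + 1
      if (technique == "IMRT") {
        nb <- sample(5:9, 1)
        angles <- sort(stats::runif(nb, 0, 360))
        beams <- lapply(seq_len(nb), function(b)
          beam_spec(sprintf("B%02d", b), angles[b],
                    mu = stats::runif(1, mu_range[1], mu_range[2])))
      } else {
        nb <- sample(1:2, 1)
        beams <- lapply(seq_len(nb), function(b)
          beam_spec(sprintf("A%02d", b), stats::runif(1, 0, 360),
                    mu = stats::runif(1, 2 * mu_range[1], 2 * mu_range[2]),
                    arc_span_deg = 360 / nb))
      }
      plans[[pid]] <- plan_spec(sprintf("P%03d", pid), site, technique, beams,
                                n_fractions = sample(25:33, 1))
    }
  }
  plans
}

# the study cohort: patients per (site, technique), 147 in total
study_patient_counts <- function() {
  c(breast.IMRT = 8,  breast.VMAT = 31,
    thorax.IMRT = 20, thorax.VMAT = 6,
    abdomen.IMRT = 20, abdomen.VMAT = 24,
    pelvis.IMRT = 12, pelvis.VMAT = 8,
    HN.IMRT = 12, HN.VMAT = 6)
}

#' Default per-fraction error rates
#'
#' The per-fraction probabilities with which the cohort simulator injects
#' each perturbation kind. Defaults encode the study conditions: 15% of
#' images carry acquisition artifacts; error-prone sites (breast, thorax)
#' draw dose-affecting errors at a 25% rate versus 10% elsewhere, split 9:1
#' between class-1 causes (setup shift, attenuator, output drift) and
#' class-2 morphological change.
#'
#' @param site treatment site, or `NULL` for the generic 10% level.
#' @return named vector of probabilities (summing to < 1).
#' @export
cohort_error_rates <- function(site = NULL) {
  base <- if (!is.null(site) && site %in% c("breast", "thorax")) 0.25 else 0.10
  c(setup_shift = 0.75 * base,
    attenuator = 0.10 * base,
    output_drift = 0.05 * base,
    morphologic_change = 0.10 * base,
    partial_acquisition = 0.15)
}

# draw one perturbation for a fraction given rates; magnitudes are the
# generator's study conditions (shifts 3-8 mm, 5-15% thickness loss,
# 2 cm attenuator patch, 3-6% output drift, 40% truncation)
draw_perturbation <- function(rates, field_extent_mm) {
  u <- stats::runif(1)
  edges <- cumsum(rates)
  kind <- "none"
  for (k in seq_along(edges)) if (u < edges[k]) { kind <- names(rates)[k]; break }
  switch(kind,
    none = perturbation_spec("none"),
    setup_shift = {
      mag <- stats::runif(1, 3, 8)
      th <- stats::runif(1, 0, 2 * pi)
      perturbation_spec("setup_shift", shift_mm = mag * c(cos(th), sin(th)))
    },
    morphologic_change =
      perturbation_spec("morphologic_change",
                        thickness_scale = -stats::runif(1, 0.05, 0.15)),
    attenuator =
      perturbation_spec("attenuator", patch_cm = 2,
                        patch_centre_mm = stats::runif(2, -0.25, 0.25) * field_extent_mm,
                        patch_size_mm = 30),
    output_drift =
      perturbation_spec("output_drift",
                        output_scale = sample(c(-1, 1), 1) * stats::runif(1, 0.03, 0.06)),
    partial_acquisition = perturbation_spec("partial_acquisition"))
}

#' Forward-simulate an IVD cohort
#'
#' For every plan: a site-typical anatomy phantom is built, reference transit
#' images are acquired at the (clean) reference fraction, and `n_test_fractions`
#' subsequent fractions are tested. One perturbation per fraction is drawn
#' from `error_rates` (a setup error affects every beam of the session) and
#' applied to all of that fraction's beams. Each beam-fraction yields one IVD
#' test record: R from the transit-dose chain, gamma% and gamma_mean from the
#' gamma analysis against the reference image, artifact metadata, tolerance
#' flags, and the injected perturbation kind/class as hidden ground truth.
#'
#' Morphological changes persist across fractions (they model the patient,
#' not the session); with `correct_after_warning = TRUE` a persisting change
#' is cleared after the first fraction that raises a warning, emulating the
#' clinical correction loop that re-aligns the patient mean indices.
#'
#' @param plans list of [plan_spec] objects (non-empty).
#' @param error_rates named vector of per-fraction probabilities (see
#'   [cohort_error_rates]); `NULL` uses the per-site defaults.
#' @param config a [sim_config]; its `rng_seed` drives the whole cohort.
#' @param cal a [calibration] used for dose reconstruction.
#' @param tol a [tolerance_config].
#' @param n_test_fractions tested fractions per patient (>= 5).
#' @param correct_after_warning clear persisting errors after a warned
#'   fraction (default TRUE).
#' @param n_arc_sub sub-beams per simulated arc.
#' @return data.frame with one row per IVD test: identifiers, indices,
#'   artifact metadata, pass flags (NA for artifact rows), `warning`, and the
#'   ground-truth `kind` and `error_class`.
#' @export
simulate_cohort <- function(plans, error_rates = NULL, config = sim_config(),
                            cal = calibration(sid_mm = config$sid_mm,
                                              sdd_mm = config$sdd_mm),
                            tol = tolerance_config(), n_test_fractions = 5,
                            correct_after_warning = TRUE, n_arc_sub = 8) {
  if (length(plans) == 0) stop("empty plan list")
  if (!is.null(error_rates)) {
    if (any(error_rates < 0) || any(error_rates > 1) || sum(error_rates) > 1)
      stop("error_rates must be probabilities summing to <= 1")
  }
  if (n_test_fractions < 5) stop("at least five IVD tests are scheduled per patient")
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  cfg <- config; cfg$rng_seed <- NULL

  shape <- c(64, 64)   # cohort grid; single-image functions default to 128
  spacing <- 2
  rows <- vector("list", 0)
  for (plan in plans) {
    rates <- if (is.null(error_rates)) cohort_error_rates(plan$site) else error_rates
    phantom <- site_phantom(plan$site, shape = shape, spacing_mm = spacing,
                            cax_jitter_cm = stats::rnorm(1, 0, 1))
    w_plan <- phantom$cax_thickness
    crit <- tol$site_criteria[[plan$site]]
    sim_one <- function(beam, pert) {
      if (beam$arc_span_deg > 0)
        simulate_arc_image(phantom, beam, pert, cfg, n_sub = n_arc_sub)
      else
        simulate_transit_image(phantom, beam, pert, cfg)
    }
    refs <- lapply(plan$beams, sim_one, pert = perturbation_spec("none"))
    d_tps <- vapply(plan$beams, function(b)
      planned_iso_dose(w_plan, b$mu, cal), numeric(1))
    persist <- NULL
    for (f in seq_len(n_test_fractions)) {
      pert <- if (!is.null(persist)) persist else
        draw_perturbation(rates, shape[2] * spacing)
      if (is.null(persist) && pert$kind == "morphologic_change") persist <- pert
      frac_warned <- FALSE
      for (b in seq_along(plan$beams)) {
        beam <- plan$beams[[b]]
        img <- sim_one(beam, pert)
        blank <- attr(img, "blank_fraction")
        integral <- sum(img$signal) / sum(refs[[b]]$signal)
        m <- measure_transit(img)
        r_val <- compute_R(reconstruct_iso_dose(m, cal), d_tps[b])
        is_artifact <- blank > 0.05 || integral < 0.5
        # artifact records are excluded from all averages; their (grossly
        # off-tolerance) gamma is computed with a coarse search to avoid
        # paying the full lattice for a dead image region
        gcrit <- if (is_artifact)
          gamma_criteria(crit$delta_s_percent, crit$delta_d_mm,
                         search_radius_mm = crit$delta_d_mm,
                         search_pitch_mm = crit$delta_d_mm / 2)
        else crit
        gr <- compute_gamma(refs[[b]], img, gcrit)
        fl <- evaluate_test(r_val, gr, tol, plan$site)
        warned <- !is_artifact && fl$warning
        frac_warned <- frac_warned || warned
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = plan$patient_id, site = plan$site,
          technique = plan$technique,
          machine_id = "LINAC1",
          reference_plan = paste0(plan$patient_id, "_", plan$technique),
          beam_id = beam$beam_id, fraction = f,
          r_value = r_val, gamma_percent = gr$gamma_percent,
          gamma_mean = gr$gamma_mean,
          blank_fraction = blank, integral_ratio = integral,
          artifact = is_artifact,
          pass_r = if (is_artifact) NA else fl$pass_r,
          pass_gamma_percent = if (is_artifact) NA else fl$pass_gamma_percent,
          pass_gamma_mean = if (is_artifact) NA else fl$pass_gamma_mean,
          warning = if (is_artifact) NA else fl$warning,
          kind = pert$kind, error_class = pert$error_class,
          stringsAsFactors = FALSE)
      }
      if (correct_after_warning && frac_warned) persist <- NULL
    }
  }
  do.call(rbind, rows)
}

#' Evaluate and aggregate a simulated or imported test table
#'
#' Convenience wrapper: artifact exclusion, per-patient two-stage summaries
#' and the cohort T%/P% tables from a test data.frame as produced by
#' [simulate_cohort] (or re-derived from an index table).
#'
#' @param tests data.frame of IVD tests.
#' @param tol a [tolerance_config].
#' @return list: `retained`, `excluded`, `summaries` (list of
#'   `patient_summary`), `cohort` (a `cohort_summary` data.frame).
#' @export
evaluate_cohort <- function(tests, tol = tolerance_config()) {
  split_tests <- exclude_artifacts(tests)
  retained <- split_tests$retained
  summaries <- lapply(split(retained, retained$patient_id),
                      summarize_patient, tol = tol)
  list(retained = retained, excluded = split_tests$excluded,
       summaries = summaries,
       cohort = aggregate_cohort(retained, summaries))
}
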