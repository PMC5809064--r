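#' Simulator configuration
#'
#' Forward-model parameters of the synthetic EPID chain. The noise-free
#' transit signal is \eqn{S(x,y) = s_0 \, MU \, e^{-\mu_{eff} w'(x,y)}},
#' optionally blurred by a Gaussian point-spread function and multiplied by
#' i.i.d. relative Gaussian noise. `s0` is the in-air signal per MU at the
#' detector plane; its default is tied to the default [calibration] so that
#' dose reconstruction is the exact inverse of the forward model.
#'
#' @param rng_seed integer seed; `NULL` uses the current RNG stream (as the
#'   cohort simulator does internally).
#' @param s0 in-air signal per MU at the detector (a.u./MU). Default
#'   `k_s * dose_per_mu * (sid/sdd)^2` of the default calibration.
#' @param mu_eff effective attenuation coefficient (1/cm); 0.05 is typical of
#'   a 6 MV beam in water.
#' @param noise_sigma relative Gaussian noise s.d. (default 0.01).
#' @param psf_sigma_mm Gaussian blur width in mm (0 disables).
#' @param sid_mm,sdd_mm source-isocentre and source-detector distances (mm).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(rng_seed = NULL, s0 = NULL, mu_eff = 0.05,
                       noise_sigma = 0.01, psf_sigma_mm = 0,
                       sid_mm = 1000, sdd_mm = 1600) {
  if (mu_eff <= 0) stop("mu_eff must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (!(sdd_mm > sid_mm && sid_mm > 0)) stop("require sdd_mm > sid_mm > 0")
  if (is.null(s0)) s0 <- (sid_mm / sdd_mm)^2  # k_s = dose_per_mu = 1 defaults
  if (s0 <= 0) stop("s0 must be positive")
  structure(list(rng_seed = rng_seed, s0 = s0, mu_eff = mu_eff,
                 noise_sigma = noise_sigma, psf_sigma_mm = psf_sigma_mm,
                 sid_mm = sid_mm, sdd_mm = sdd_mm),
            class = "sim_config")
}

#' Beam and plan specifications
#'
#' `beam_spec` describes one treatment beam (or arc): monitor units and the
#' planned isocentre dose D_tps. `plan_spec` groups the beams of a patient
#' plan with the treatment site and technique. IMRT plans carry 5-9 static
#' beams; VMAT plans 1-2 arcs; treatment courses exceed 20 fractions.
#'
#' @param beam_id label.
#' @param gantry_deg gantry angle (degrees); for an arc, the arc span is
#'   given by `arc_span_deg`.
#' @param mu monitor units (> 0).
#' @param planned_iso_dose_cgy planned isocentre dose D_tps (cGy, > 0).
#' @param arc_span_deg arc length in degrees (0 for a static beam).
#' @export
beam_spec <- function(beam_id, gantry_deg = 0, mu = 100,
                      planned_iso_dose_cgy = NA_real_, arc_span_deg = 0) {
  if (mu <= 0) stop("mu must be positive")
  if (!is.na(planned_iso_dose_cgy) && planned_iso_dose_cgy <= 0)
    stop("planned_iso_dose_cgy must be positive")
  structure(list(beam_id = as.character(beam_id), gantry_deg = gantry_deg,
                 mu = mu, planned_iso_dose_cgy = planned_iso_dose_cgy,
                 arc_span_deg = arc_span_deg),
            class = "beam_spec")
}

#' @rdname beam_spec
#' @param patient_id patient label.
#' @param site treatment site: `"breast"`, `"thorax"`, `"abdomen"`,
#'   `"pelvis"` or `"HN"`.
#' @param technique `"IMRT"` or `"VMAT"`.
#' @param beams list of [beam_spec] objects.
#' @param n_fractions scheduled fractions (> 20).
#' @export
plan_spec <- function(patient_id, site, technique = c("IMRT", "VMAT"),
                      beams, n_fractions = 28) {
  technique <- match.arg(technique)
  site <- match.arg(site, c("breast", "thorax", "abdomen", "pelvis", "HN"))
  nb <- length(beams)
  if (technique == "IMRT" && (nb < 5 || nb > 9))
    stop("IMRT plans carry 5-9 beams")
  if (technique == "VMAT" && (nb < 1 || nb > 2))
    stop("VMAT plans carry 1-2 arcs")
  if (n_fractions <= 20) stop("treatment courses have more than 20 fractions")
  structure(list(patient_id = as.character(patient_id), site = site,
                 technique = technique, beams = beams,
                 n_fractions = n_fractions),
            class = "plan_spec")
}

#' Perturbation specification
#'
#' Ground-truth error injected into a simulated fraction, together with its
#' error class: class 1 for setup/delivery causes (`setup_shift`,
#' `attenuator`, `output_drift`), class 2 for `morphologic_change`
#' (weight loss, tumour shrinkage), `"artifact"` for `partial_acquisition`
#' (image truncated by an acquisition fault), `"none"` otherwise.
#'
#' @param kind one of `"none"`, `"setup_shift"`, `"morphologic_change"`,
#'   `"attenuator"`, `"output_drift"`, `"partial_acquisition"`.
#' @param shift_mm `(dx, dy)` patient displacement (mm) for `setup_shift`.
#' @param thickness_scale fractional thickness change (e.g. -0.10) for
#'   `morphologic_change`.
#' @param patch_cm,patch_centre_mm,patch_size_mm attenuator patch thickness
#'   (cm water-equivalent), centre and square side (mm).
#' @param output_scale fractional output change (e.g. 0.03) for `output_drift`.
#' @param blank_fraction fraction of trailing rows blanked for
#'   `partial_acquisition` (default 0.4).
#' @export
perturbation_spec <- function(kind = c("none", "setup_shift", "morphologic_change",
                                       "attenuator", "output_drift",
                                       "partial_acquisition"),
                              shift_mm = c(0, 0), thickness_scale = 0,
                              patch_cm = 2, patch_centre_mm = c(0, 0),
                              patch_size_mm = 30, output_scale = 0,
                              blank_fraction = 0.4) {
  kind <- match.arg(kind)
  error_class <- switch(kind,
    none = "none",
    setup_shift = , attenuator = , output_drift = "1",
    morphologic_change = "2",
    partial_acquisition = "artifact")
  structure(list(kind = kind, shift_mm = shift_mm,
                 thickness_scale = thickness_scale, patch_cm = patch_cm,
                 patch_centre_mm = patch_centre_mm, patch_size_mm = patch_size_mm,
                 output_scale = output_scale, blank_fraction = blank_fraction,
                 error_class = error_class),
            class = "perturbation_spec")
}

# apply a perturbation to a thickness map; returns the perturbed phantom
perturb_phantom <- function(phantom, pert) {
  w <- phantom$thickness
  img <- image_grid(w, phantom$spacing_mm, phantom$origin_mm)
  if (pert$kind == "setup_shift") {
    extent <- c(ncol(w), nrow(w)) * phantom$spacing_mm
    if (any(abs(pert$shift_mm) > extent))
      stop("setup shift larger than grid extent")
    co <- grid_xy(img)
    # anatomy moves by +shift: w'(x, y) = w(x - dx, y - dy), edge-clamped
    w <- interp_bilinear(img, co$x - pert$shift_mm[1], co$y - pert$shift_mm[2],
                         clamp = TRUE)
  } else if (pert$kind == "morphologic_change") {
    w <- w * (1 + pert$thickness_scale)
  } else if (pert$kind == "attenuator") {
    co <- grid_xy(img)
    inpatch <- abs(co$x - pert$patch_centre_mm[1]) <= pert$patch_size_mm / 2 &
               abs(co$y - pert$patch_centre_mm[2]) <= pert$patch_size_mm / 2
    w <- w + pert$patch_cm * inpatch
  }
  if (any(w < 0)) stop("perturbation produced negative thickness")
  out <- phantom
  out$thickness <- w
  out$cax_thickness <- phantom_cax_thickness(out)
  out
}

# separable Gaussian blur with edge renormalisation (kernel truncated at 3 sigma)
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  h <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-h:h)^2) / (2 * sigma_px^2))
  conv1 <- function(v) {
    n <- length(v)
    out <- num <- numeric(n)
    for (o in -h:h) {
      w <- k[o + h + 1]
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)  # replicate edges
      out <- out + w * v[idx]
      num <- num + w
    }
    out / num
  }
  m <- apply(m, 2, conv1)
  t(apply(t(m), 2, conv1))
}

#' Simulate a transit portal image
#'
#' Forward model of the EPID transit signal through a (possibly perturbed)
#' phantom: \eqn{S = s_0 MU e^{-\mu_{eff} w'}} per pixel, then optional
#' Gaussian PSF blur and multiplicative Gaussian noise
#' \eqn{S \leftarrow S (1 + \epsilon)}, \eqn{\epsilon \sim N(0, \sigma^2)}.
#' An `output_drift` perturbation scales \eqn{s_0}; `partial_acquisition`
#' zeroes the trailing block of rows after noise. Deterministic given
#' `config$rng_seed`.
#'
#' @param phantom a [phantom_map] on the EPID grid.
#' @param beam a [beam_spec].
#' @param perturbation a [perturbation_spec] (default: none).
#' @param config a [sim_config].
#' @return An [image_grid] with attributes `mu`, `beam_id` and
#'   `blank_fraction`.
#' @export
simulate_transit_image <- function(phantom, beam,
                                   perturbation = perturbation_spec("none"),
                                   config = sim_config()) {
  stopifnot(inherits(phantom, "phantom_map"), inherits(beam, "beam_spec"),
            inherits(perturbation, "perturbation_spec"),
            inherits(config, "sim_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  ph <- perturb_phantom(phantom, perturbation)
  s0 <- config$s0
  if (perturbation$kind == "output_drift") s0 <- s0 * (1 + perturbation$output_scale)
  S <- s0 * beam$mu * exp(-config$mu_eff * ph$thickness)
  if (config$psf_sigma_mm > 0)
    S <- gaussian_blur(S, config$psf_sigma_mm / phantom$spacing_mm[1])
  if (config$noise_sigma > 0)
    S <- S * (1 + stats::rnorm(length(S), 0, config$noise_sigma))
  blank <- 0
  if (perturbation$kind == "partial_acquisition") {
    blank <- perturbation$blank_fraction
    nb <- ceiling(blank * nrow(S))
    if (nb > 0) S[(nrow(S) - nb + 1):nrow(S), ] <- 0
  }
  img <- image_grid(S, phantom$spacing_mm, phantom$origin_mm)
  attr(img, "mu") <- beam$mu
  attr(img, "beam_id") <- beam$beam_id
  attr(img, "blank_fraction") <- blank
  attr(img, "cax_thickness") <- ph$cax_thickness
  img
}

# rotate a thickness map about the grid centre (bilinear, edge-clamped)
rotate_thickness <- function(phantom, angle_deg) {
  img <- image_grid(phantom$thickness, phantom$spacing_mm, phantom$origin_mm)
  co <- grid_xy(img)
  a <- angle_deg * pi / 180
  xq <- cos(a) * co$x + sin(a) * co$y
  yq <- -sin(a) * co$x + cos(a) * co$y
  out <- phantom
  out$thickness <- interp_bilinear(img, xq, yq, clamp = TRUE)
  out$cax_thickness <- phantom_cax_thickness(out)
  out
}

#' Simulate an integrated VMAT arc image
#'
#' The EPID image analysed for an arc is the sum of the signals of the beam
#' entries along the arc. This is emulated by splitting the arc into
#' `n_sub` equally spaced sub-beams, each crossing the phantom rotated to its
#' gantry angle, and summing the sub-images. Rotation about the CAX leaves
#' the central-axis thickness unchanged, so the transit dose chain treats an
#' arc like a static beam.
#'
#' @inheritParams simulate_transit_image
#' @param n_sub number of sub-beams (>= 8).
#' @export
simulate_arc_image <- function(phantom, beam,
                               perturbation = perturbation_spec("none"),
                               config = sim_config(), n_sub = 8) {
  if (n_sub < 8) stop("arc integration uses at least 8 sub-beams")
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  cfg_sub <- config
  cfg_sub$rng_seed <- NULL
  cfg_sub$noise_sigma <- 0   # noise applied once on the integrated image
  span <- if (beam$arc_span_deg > 0) beam$arc_span_deg else 360
  angles <- beam$gantry_deg + span * (seq_len(n_sub) - 0.5) / n_sub
  sub_mu <- beam$mu / n_sub
  acc <- NULL
  pert_geom <- perturbation
  if (pert_geom$kind %in% c("output_drift", "partial_acquisition"))
    pert_geom <- perturbation_spec("none")
  # perturb in the patient frame once, then rotate: rotation about the CAX
  # leaves the central-axis thickness of the perturbed anatomy unchanged
  ph_p <- perturb_phantom(phantom, pert_geom)
  for (a in angles) {
    ph_a <- rotate_thickness(ph_p, a)
    sub_beam <- beam_spec(beam$beam_id, a, sub_mu, beam$planned_iso_dose_cgy)
    si <- simulate_transit_image(ph_a, sub_beam, perturbation_spec("none"), cfg_sub)
    acc <- if (is.null(acc)) si$signal else acc + si$signal
  }
  if (perturbation$kind == "output_drift")
    acc <- acc * (1 + perturbation$output_scale)
  if (config$noise_sigma > 0)
    acc <- acc * (1 + stats::rnorm(length(acc), 0, config$noise_sigma))
  blank <- 0
  if (perturbation$kind == "partial_acquisition") {
    blank <- perturbation$blank_fraction
    nb <- ceiling(blank * nrow(acc))
    if (nb > 0) acc[(nrow(acc) - nb + 1):nrow(acc), ] <- 0
  }
  img <- image_grid(acc, phantom$spacing_mm, phantom$origin_mm)
  attr(img, "mu") <- beam$mu
  attr(img, "beam_id") <- beam$beam_id
  attr(img, "blank_fraction") <- blank
  attr(img, "cax_thickness") <- ph_p$cax_thickness
  img
}
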