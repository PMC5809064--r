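#' EPID dosimetric calibration
#'
#' Commissioning parameters of the transit-dosimetry chain: the EPID
#' calibration factor `k_s` (signal per cGy in air at the detector plane),
#' the absolute dose output under reference conditions (cGy/MU), the beam
#' quality index TPR20/10, the MU linearity correction and the geometry.
#' The effective attenuation coefficient `mu_eff` follows from the beam
#' quality through a small monotone lookup ([mu_eff_from_tpr]) unless
#' overridden.
#'
#' @param k_s EPID calibration factor (a.u. per cGy, > 0).
#' @param dose_per_mu absolute dose under reference conditions (cGy/MU, > 0).
#' @param tpr_20_10 beam quality index, in (0.5, 0.9); default 0.67 (6 MV).
#' @param mu_linearity function of MU returning a positive multiplicative
#'   correction; default identity (perfectly linear response).
#' @param mu_eff effective attenuation coefficient (1/cm); `NULL` derives it
#'   from `tpr_20_10`.
#' @param sid_mm,sdd_mm source-isocentre and source-detector distances (mm).
#' @return An object of class `calibration`.
#' @export
calibration <- function(k_s = 1, dose_per_mu = 1, tpr_20_10 = 0.67,
                        mu_linearity = function(mu) 1,
                        mu_eff = NULL, sid_mm = 1000, sdd_mm = 1600) {
  if (k_s <= 0 || dose_per_mu <= 0) stop("k_s and dose_per_mu must be positive")
  if (tpr_20_10 <= 0.5 || tpr_20_10 >= 0.9)
    stop("tpr_20_10 outside the plausible range (0.5, 0.9)")
  if (!(sdd_mm > sid_mm && sid_mm > 0)) stop("require sdd_mm > sid_mm > 0")
  if (is.null(mu_eff)) mu_eff <- mu_eff_from_tpr(tpr_20_10)
  if (mu_linearity(100) <= 0) stop("mu_linearity must be positive")
  structure(list(k_s = k_s, dose_per_mu = dose_per_mu, tpr_20_10 = tpr_20_10,
                 mu_linearity = mu_linearity, mu_eff = mu_eff,
                 sid_mm = sid_mm, sdd_mm = sdd_mm),
            class = "calibration")
}

#' Effective attenuation coefficient from beam quality
#'
#' Monotone lookup from TPR20/10 to an effective broad-beam attenuation
#' coefficient in water (1/cm), linearly interpolated between tabulated
#' anchor points (higher beam quality penetrates more, so mu decreases).
#' Around TPR20/10 = 0.67 (a 6 MV beam) it returns about 0.05/cm.
#'
#' @param tpr_20_10 beam quality index.
#' @export
mu_eff_from_tpr <- function(tpr_20_10) {
  tab_tpr <- c(0.58, 0.62, 0.67, 0.72, 0.78)
  tab_mu  <- c(0.062, 0.056, 0.050, 0.044, 0.038)
  stats::approx(tab_tpr, tab_mu, xout = tpr_20_10, rule = 2)$y
}

#' Transit measurement at the central axis
#'
#' Extracts the mean transit signal in a circular ROI around the CAX together
#' with the delivered MU and the radiological thickness `w_cax` crossed along
#' the central axis on that day (in clinic, from the registered planning
#' CT/CBCT; in simulations, from the ground-truth phantom). These are the
#' inputs of the mid-plane dose reconstruction.
#'
#' @param image transit [image_grid] (from [simulate_transit_image] or
#'   [read_image]).
#' @param w_cax_cm central-axis radiological thickness (cm, >= 0). Default:
#'   the image's `cax_thickness` attribute when present.
#' @param mu delivered monitor units; default the image's `mu` attribute.
#' @param roi_radius_mm ROI radius (default 5 mm).
#' @return An object of class `transit_measurement` with fields `s_t`,
#'   `w_cax_cm`, `mu`, `roi_radius_mm`.
#' @export
measure_transit <- function(image, w_cax_cm = attr(image, "cax_thickness"),
                            mu = attr(image, "mu"), roi_radius_mm = 5) {
  stopifnot(inherits(image, "image_grid"))
  if (is.null(w_cax_cm) || is.na(w_cax_cm) || w_cax_cm < 0)
    stop("w_cax_cm must be a non-negative radiological thickness")
  if (is.null(mu) || mu <= 0) stop("mu must be positive")
  co <- grid_xy(image)
  roi <- co$x^2 + co$y^2 <= roi_radius_mm^2
  if (!any(roi)) stop("ROI contains no pixels; enlarge roi_radius_mm")
  s_t <- mean(image$signal[roi])
  if (s_t < 0) stop("negative transit signal")
  structure(list(s_t = s_t, w_cax_cm = w_cax_cm, mu = mu,
                 roi_radius_mm = roi_radius_mm),
            class = "transit_measurement")
}

#' Reconstruct the isocentre dose from a transit measurement
#'
#' Mid-plane backprojection: the detector signal is divided by the EPID
#' calibration factor, corrected for MU linearity, backprojected from the
#' exit side to the patient mid-plane through half the radiological path,
#' and rescaled by the inverse-square factor from the detector plane to the
#' isocentre plane:
#' \deqn{D_{iso} = \frac{s_t}{k_s}\, L(MU)\, e^{+\mu_{eff} w_{cax}/2}\,
#'       \left(\frac{sdd}{sid}\right)^2 .}
#' With the day's actual `w_cax` this recovers the dose truly delivered at
#' the mid-plane point, and it is the exact inverse of the simulator's
#' forward model at the CAX when noise and PSF are off. It is a minimal
#' transit model defined by this package, not a re-implementation of any
#' commercial reconstruction.
#'
#' @param m a [measure_transit] result.
#' @param cal a [calibration].
#' @return Reconstructed isocentre dose D_iso (cGy).
#' @export
reconstruct_iso_dose <- function(m, cal) {
  stopifnot(inherits(m, "transit_measurement"), inherits(cal, "calibration"))
  if (m$s_t <= 0) stop("no transit signal")
  # a physical path cannot exceed the source-detector distance
  if (m$w_cax_cm * 10 > cal$sdd_mm) stop("w_cax inconsistent with geometry")
  (m$s_t / cal$k_s) * cal$mu_linearity(m$mu) *
    exp(cal$mu_eff * m$w_cax_cm / 2) * (cal$sdd_mm / cal$sid_mm)^2
}

#' Isocentre dose ratio R
#'
#' The first IVD index: the ratio between the reconstructed and the planned
#' isocentre dose, \eqn{R = D_{iso} / D_{tps}}, in tolerance when
#' \eqn{0.95 \le R \le 1.05}.
#'
#' @param d_iso reconstructed isocentre dose (cGy).
#' @param d_tps planned isocentre dose (cGy, > 0).
#' @export
compute_R <- function(d_iso, d_tps) {
  if (any(d_tps <= 0)) stop("d_tps must be positive")
  d_iso / d_tps
}

#' Planned isocentre dose of the simulator's forward model
#'
#' The planning value D_tps consistent with the synthetic chain: the
#' mid-plane dose behind the planning thickness,
#' \eqn{D_{tps} = (cGy/MU) \cdot MU \cdot e^{-\mu_{eff} w_{plan}/2}}.
#'
#' @param w_plan_cm planning central-axis radiological thickness (cm).
#' @param mu monitor units.
#' @param cal a [calibration].
#' @export
planned_iso_dose <- function(w_plan_cm, mu, cal = calibration()) {
  cal$dose_per_mu * mu * exp(-cal$mu_eff * w_plan_cm / 2)
}
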