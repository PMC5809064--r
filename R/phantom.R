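#' Water-equivalent phantom thickness map
#'
#' The simulator's stand-in for the patient anatomy crossed by a beam: a 2D
#' map of water-equivalent thickness (cm) on the same grid as the EPID image
#' (beam's-eye view). Patterns provide the spatial structure that drives the
#' gamma analysis:
#' \describe{
#'   \item{flat}{uniform thickness `cax_cm`.}
#'   \item{wedge}{linear ramp along x, `slope_cm_per_mm` about the CAX.}
#'   \item{step}{`cax_cm` for x <= 0, `cax_cm + step_cm` for x > 0.}
#'   \item{ridges}{sinusoidal ridges in x and y of amplitude `amplitude_cm`
#'     and period `period_mm` — a high-gradient field.}
#'   \item{anatomy}{elliptical dome of central thickness `cax_cm` with ridges
#'     superimposed; the default cohort anatomy (body contour plus internal
#'     heterogeneity).}
#' }
#'
#' @param pattern one of `"flat"`, `"wedge"`, `"step"`, `"ridges"`, `"anatomy"`.
#' @param shape grid dimensions `(rows, cols)`; default 128 x 128.
#' @param spacing_mm pixel spacing in mm (default 2).
#' @param cax_cm thickness at the central axis (cm).
#' @param amplitude_cm ridge amplitude (cm) for `ridges` / `anatomy`.
#' @param period_mm ridge period (mm).
#' @param slope_cm_per_mm wedge slope.
#' @param step_cm step height.
#' @return An object of class `phantom_map` with fields `thickness` (cm),
#'   `spacing_mm`, `origin_mm` and `cax_thickness` (cm at the CAX).
#' @export
phantom_map <- function(pattern = c("anatomy", "flat", "wedge", "step", "ridges"),
                        shape = c(128, 128), spacing_mm = 2, cax_cm = 20,
                        amplitude_cm = 2, period_mm = 30,
                        slope_cm_per_mm = 0.05, step_cm = 8) {
  pattern <- match.arg(pattern)
  nr <- shape[1]; nc <- shape[2]
  origin <- -c((nc - 1) / 2 * spacing_mm, (nr - 1) / 2 * spacing_mm)
  x <- matrix(origin[1] + (seq_len(nc) - 1) * spacing_mm, nr, nc, byrow = TRUE)
  y <- matrix(origin[2] + (seq_len(nr) - 1) * spacing_mm, nr, nc)
  w <- switch(pattern,
    flat   = matrix(cax_cm, nr, nc),
    wedge  = cax_cm + slope_cm_per_mm * x,
    step   = cax_cm + step_cm * (x > 0),
    ridges = cax_cm + amplitude_cm * (sin(2 * pi * x / period_mm) +
                                      sin(2 * pi * y / period_mm)) / 2,
    anatomy = {
      a <- max(abs(x)) * 0.95; b <- max(abs(y)) * 0.95
      dome <- pmax(0, 1 - (x / a)^2 - (y / b)^2)
      cax_cm * sqrt(dome) +
        amplitude_cm * (sin(2 * pi * x / period_mm) + sin(2 * pi * y / period_mm)) / 2 *
          (dome > 0.05)
    })
  w <- pmax(w, 0)
  pm <- structure(list(thickness = w, spacing_mm = rep_len(spacing_mm, 2),
                       origin_mm = origin, pattern = pattern),
                  class = "phantom_map")
  pm$cax_thickness <- phantom_cax_thickness(pm)
  pm
}

# thickness (cm) interpolated at the CAX (0, 0)
phantom_cax_thickness <- function(phantom) {
  img <- image_grid(phantom$thickness, phantom$spacing_mm, phantom$origin_mm)
  as.numeric(interp_bilinear(img, 0, 0, clamp = TRUE))
}

#' @export
print.phantom_map <- function(x, ...) {
  cat(sprintf("phantom_map (%s): %d x %d @ %g mm, CAX thickness %.2f cm, range [%.2f, %.2f] cm\n",
              x$pattern, nrow(x$thickness), ncol(x$thickness), x$spacing_mm[1],
              x$cax_thickness, min(x$thickness), max(x$thickness)))
  invisible(x)
}

# site-typical anatomy phantoms. Central thicknesses are realistic
# water-equivalent values; breast and thorax get stronger internal gradients
# (tissue/lung interfaces, sloping contours), which is what makes their
# transit images most sensitive to setup errors.
site_phantom_defaults <- function(site) {
  switch(site,
    breast  = list(cax_cm = 12, amplitude_cm = 3.0),
    thorax  = list(cax_cm = 18, amplitude_cm = 3.0),
    abdomen = list(cax_cm = 22, amplitude_cm = 1.5),
    pelvis  = list(cax_cm = 25, amplitude_cm = 1.5),
    HN      = list(cax_cm = 14, amplitude_cm = 2.0),
    stop("unknown site: ", site))
}

#' Site-typical anatomy phantom
#'
#' Convenience wrapper around [phantom_map] choosing central thickness and
#' heterogeneity amplitude typical of each treatment site (breast and thorax
#' carry the strongest gradients).
#'
#' @param site one of `"breast"`, `"thorax"`, `"abdomen"`, `"pelvis"`, `"HN"`.
#' @param shape,spacing_mm grid geometry, as in [phantom_map].
#' @param cax_jitter_cm additive perturbation of the central thickness, used
#'   by the cohort simulator to vary patients.
#' @export
site_phantom <- function(site, shape = c(128, 128), spacing_mm = 2,
                         cax_jitter_cm = 0) {
  d <- site_phantom_defaults(site)
  phantom_map("anatomy", shape = shape, spacing_mm = spacing_mm,
              cax_cm = d$cax_cm + cax_jitter_cm, amplitude_cm = d$amplitude_cm)
}
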