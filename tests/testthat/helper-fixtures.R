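# shared fixture builders; everything is generated in code at test time

`%||%` <- function(a, b) if (is.null(a)) b else a

# smooth random reference/current pair on a 16x16 grid at 2 mm: a band-limited
# field plus a modest translation, output scaling and noise — the regime the
# gamma comparison sees clinically. Both the engine and the exhaustive oracle
# quantise the displacement search, with per-pixel error bounded by
# |grad S| * lattice_pitch / S_tol; the field's gradient is normalised to
# `grad_limit` (a.u./mm) so that this bound stays well below the 0.02
# agreement tolerance for the oracle's delta_d/20 pitch.
make_gamma_pair <- function(shift_max_mm = 2, scale_max = 0.03,
                            noise_sigma = 0.001, grad_limit = 0.12) {
  f <- epidivd:::gaussian_blur(matrix(stats::runif(32 * 32), 32, 32), 4)[9:24, 9:24]
  f <- f - mean(f)
  gmax <- max(abs(diff(f)), abs(t(diff(t(f))))) / 2   # per mm at 2 mm pixels
  m <- 85 + (grad_limit / gmax) * f
  ref <- image_grid(m, 2)
  sh <- stats::runif(2, -shift_max_mm, shift_max_mm)
  sc <- 1 + stats::runif(1, -scale_max, scale_max)
  co <- epidivd:::grid_xy(ref)
  cur <- interp_bilinear(ref, co$x - sh[1], co$y - sh[2], clamp = TRUE) * sc *
    (1 + stats::rnorm(length(m), 0, noise_sigma))
  list(ref = ref, cur = image_grid(matrix(cur, 16, 16), 2))
}

# small uniform phantom + beam for transit-chain tests
flat_setup <- function(cax_cm = 20, mu = 120, noise = 0, shape = c(32, 32)) {
  list(phantom = phantom_map("flat", shape = shape, spacing_mm = 2, cax_cm = cax_cm),
       beam = beam_spec("B1", mu = mu),
       config = sim_config(noise_sigma = noise),
       cal = calibration())
}

# a high-gradient field: steep sinusoidal ridges, the geometry most
# sensitive to setup shifts
ridge_phantom <- function(shape = c(64, 64))
  phantom_map("ridges", shape = shape, spacing_mm = 2, cax_cm = 20,
              amplitude_cm = 4, period_mm = 20)

# minimal valid index-record data.frame
make_records <- function(n = 6, patient = "P001", site = "pelvis") {
  data.frame(patient_id = patient, reference_plan = paste0(patient, "_IMRT"),
             pathology = site, machine_id = "LINAC1",
             beam = rep(sprintf("B%02d", 1:2), length.out = n),
             fraction = rep(seq_len(ceiling(n / 2)), each = 2)[1:n],
             r_value = stats::runif(n, 0.97, 1.03),
             gamma_percent = stats::runif(n, 92, 100),
             gamma_mean = stats::runif(n, 0.1, 0.3),
             stringsAsFactors = FALSE)
}

# tiny IMRT plan (5 beams is the minimum) for fast cohort runs
small_plan <- function(patient_id = "P001", site = "pelvis", technique = "IMRT") {
  if (technique == "IMRT") {
    beams <- lapply(1:5, function(b) beam_spec(sprintf("B%02d", b),
                                               gantry_deg = 72 * b, mu = 100))
  } else {
    beams <- list(beam_spec("A01", 0, mu = 300, arc_span_deg = 360))
  }
  plan_spec(patient_id, site, technique, beams, n_fractions = 28)
}
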