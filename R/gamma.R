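#' Gamma-analysis criteria
#'
#' Parameters of the global 2D gamma comparison between a reference and a
#' current portal image: the signal-to-agreement criterion \eqn{\Delta S\%}
#' (percent of the global normalisation value, the maximum reference signal
#' over the evaluated area) and the distance-to-agreement criterion
#' \eqn{\Delta d} (mm). A pixel passes when \eqn{\gamma < 1} (strict).
#'
#' The evaluated ("irradiated") area is the set of reference pixels at or
#' above `low_signal_cutoff` times the normalisation value. The minimisation
#' searches a circular displacement lattice of radius `search_radius_mm` and
#' pitch `search_pitch_mm`; setting the pitch equal to the pixel spacing and
#' the images on a common grid restricts the search to pixel centres
#' (no interpolation).
#'
#' @param delta_s_percent signal criterion \eqn{\Delta S\%} (> 0), percent of
#'   the global normalisation value. Clinical values here: 3 (H&N) or 5.
#' @param delta_d_mm distance criterion \eqn{\Delta d} in mm (> 0).
#' @param pass_threshold gamma cutoff for a passing pixel (default 1).
#' @param low_signal_cutoff fraction of the normalisation value below which
#'   reference pixels are excluded from the analysis (default 0.10).
#' @param search_radius_mm radius of the displacement search (default
#'   `3 * delta_d_mm`).
#' @param search_pitch_mm pitch of the displacement lattice (default
#'   `delta_d_mm / 10`).
#' @param refine run the local pattern-search refinement of each pixel's
#'   minimum below the lattice pitch (default `TRUE`). Set `FALSE` to
#'   restrict the minimisation to the fixed lattice, e.g. for a
#'   pixel-centre-only search.
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(delta_s_percent, delta_d_mm, pass_threshold = 1,
                           low_signal_cutoff = 0.10,
                           search_radius_mm = 3 * delta_d_mm,
                           search_pitch_mm = delta_d_mm / 10,
                           refine = TRUE) {
  if (delta_s_percent <= 0 || delta_d_mm <= 0) stop("criteria must be positive")
  if (low_signal_cutoff < 0 || low_signal_cutoff >= 1)
    stop("low_signal_cutoff must be in [0, 1)")
  structure(list(delta_s_percent = delta_s_percent, delta_d_mm = delta_d_mm,
                 pass_threshold = pass_threshold,
                 low_signal_cutoff = low_signal_cutoff,
                 search_radius_mm = search_radius_mm,
                 search_pitch_mm = search_pitch_mm, refine = refine),
            class = "gamma_criteria")
}

# circular displacement lattice (mm offsets), as a data.frame ox/oy/r2
gamma_lattice <- function(radius, pitch) {
  k <- floor(radius / pitch + 1e-9)
  off <- expand.grid(ox = (-k:k) * pitch, oy = (-k:k) * pitch)
  r2 <- off$ox^2 + off$oy^2
  keep <- r2 <= radius^2 + 1e-9
  data.frame(ox = off$ox[keep], oy = off$oy[keep], r2 = r2[keep])
}

#' Global 2D gamma analysis of two portal images
#'
#' For each evaluated reference pixel \eqn{r},
#' \deqn{\gamma(r) = \min_{|d| \le R} \sqrt{ (\Delta S(r,d)/S_{tol})^2 + (|d|/\Delta d)^2 }}
#' where \eqn{\Delta S(r,d)} is the difference between the reference signal at
#' \eqn{r} and the current image bilinearly interpolated at \eqn{r + d}, and
#' \eqn{S_{tol} = \Delta S\%/100} of the maximum reference signal over the
#' evaluated area (global normalisation). Summaries are \eqn{\gamma\%}, the
#' percentage of evaluated pixels with \eqn{\gamma <} `pass_threshold`, and
#' \eqn{\gamma_{mean}}, the mean gamma over the evaluated pixels.
#'
#' The current image need not share the reference grid: it is sampled on its
#' own coordinates at the displaced query points, so differing grids are
#' handled as long as they overlap spatially. Displacements that fall outside
#' the current image are skipped. The search visits lattice points in order of
#' increasing \eqn{|d|} and stops once the distance term alone exceeds every
#' pixel's running minimum, which makes near-agreeing images cheap.
#'
#' @param reference,current [image_grid] objects; `reference` defines the
#'   evaluated pixels and the normalisation.
#' @param criteria a [gamma_criteria].
#' @return An object of class `gamma_result`: `gamma_map` (an [image_grid]
#'   with `NA` outside the evaluated area), `gamma_percent`, `gamma_mean`,
#'   `n_evaluated`, plus the normalisation value used.
#' @export
compute_gamma <- function(reference, current, criteria) {
  stopifnot(inherits(reference, "image_grid"), inherits(current, "image_grid"),
            inherits(criteria, "gamma_criteria"))
  R <- reference$signal
  if (!all(is.finite(R)) || !all(is.finite(current$signal)))
    stop("non-finite signal in input image")
  norm0 <- max(R)
  mask <- R >= criteria$low_signal_cutoff * norm0
  if (!any(mask)) stop("empty irradiated area: all pixels below low-signal cutoff")
  norm <- max(R[mask])
  if (norm <= 0) stop("empty irradiated area: non-positive normalisation")
  s_tol <- criteria$delta_s_percent / 100 * norm
  dd2 <- criteria$delta_d_mm^2

  lat <- gamma_lattice(criteria$search_radius_mm, criteria$search_pitch_mm)
  ord <- order(lat$r2)
  ox <- lat$ox[ord]; oy <- lat$oy[ord]; dterms <- lat$r2[ord] / dd2
  co <- grid_xy(reference)
  midx <- which(mask)
  xm <- co$x[midx]; ym <- co$y[midx]; rm <- R[midx]
  g2m <- rep(Inf, length(midx))
  bx <- by <- rep(0, length(midx))   # per-pixel argmin displacement
  for (k in seq_along(dterms)) {
    # lattice points are visited in order of growing |d|; a pixel whose
    # running minimum is already below the bare distance term cannot improve
    act <- which(g2m > dterms[k])
    if (length(act) == 0L) break
    val <- interp_bilinear(current, xm[act] + ox[k], ym[act] + oy[k])
    cand <- ((rm[act] - val) / s_tol)^2 + dterms[k]
    upd <- !is.na(cand) & cand < g2m[act]
    g2m[act[upd]] <- cand[upd]
    bx[act[upd]] <- ox[k]; by[act[upd]] <- oy[k]
  }
  # local pattern-search refinement around each pixel's argmin: the coarse
  # lattice locates the basin, halved steps resolve the minimum within it
  r2max <- criteria$search_radius_mm^2 + 1e-9
  refine_steps <- if (isTRUE(criteria$refine))
    criteria$search_pitch_mm * c(0.5, 0.25, 0.125) else numeric(0)
  for (p in refine_steps) {
    act <- seq_along(g2m)
    for (pass in 1:3) {
      improved <- logical(length(act))
      for (dx in c(-p, 0, p)) for (dy in c(-p, 0, p)) {
        if (dx == 0 && dy == 0) next
        nx <- bx[act] + dx; ny <- by[act] + dy
        inr <- nx^2 + ny^2 <= r2max
        if (!any(inr)) next
        val <- interp_bilinear(current, xm[act] + nx, ym[act] + ny)
        cand <- ((rm[act] - val) / s_tol)^2 + (nx^2 + ny^2) / dd2
        upd <- inr & !is.na(cand) & cand < g2m[act]
        if (any(upd)) {
          g2m[act[upd]] <- cand[upd]
          bx[act[upd]] <- nx[upd]; by[act[upd]] <- ny[upd]
          improved <- improved | upd
        }
      }
      # later passes only revisit pixels whose minimum is still moving
      act <- act[improved]
      if (length(act) == 0L) break
    }
  }
  g2 <- matrix(Inf, nrow(R), ncol(R))
  g2[midx] <- g2m
  evaluated <- mask & is.finite(g2)
  if (!any(evaluated)) stop("no spatial overlap between reference and current image")
  gmap <- sqrt(g2)
  gmap[!evaluated] <- NA_real_
  gvals <- gmap[evaluated]
  structure(list(
    gamma_map = image_grid(gmap, reference$spacing_mm, reference$origin_mm),
    gamma_percent = 100 * mean(gvals < criteria$pass_threshold),
    gamma_mean = mean(gvals),
    n_evaluated = sum(evaluated),
    normalisation = norm,
    criteria = criteria), class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("gamma_result: %.1f%%/%g mm — gamma%% = %.2f, gamma_mean = %.3f (n = %d)\n",
              x$criteria$delta_s_percent, x$criteria$delta_d_mm,
              x$gamma_percent, x$gamma_mean, x$n_evaluated))
  invisible(x)
}

#' Exhaustive-search gamma oracle
#'
#' Independent reference computation of the gamma map by brute force: every
#' point of a dense displacement lattice of pitch `subsample_mm` (within
#' radius `3 * delta_d_mm`) is visited for every evaluated pixel, with its own
#' bilinear sampling of the current image and no search pruning. Intended as a
#' test oracle on small grids; it shares only the gamma definition with
#' [compute_gamma], not its implementation.
#'
#' @param reference,current [image_grid] objects (small; <= 64 x 64 advised).
#' @param criteria a [gamma_criteria].
#' @param subsample_mm lattice pitch; must be `< delta_d_mm`.
#' @return A `gamma_result` (without pruning-dependent fields).
#' @export
brute_force_gamma <- function(reference, current, criteria,
                              subsample_mm = criteria$delta_d_mm / 20) {
  if (subsample_mm >= criteria$delta_d_mm) stop("oracle too coarse: subsample_mm >= delta_d_mm")
  R <- reference$signal
  norm <- max(R)
  mask <- R >= criteria$low_signal_cutoff * norm
  if (!any(mask)) stop("empty irradiated area")
  s_tol <- criteria$delta_s_percent / 100 * max(R[mask])
  dd <- criteria$delta_d_mm
  radius <- criteria$search_radius_mm

  # independent plain bilinear sampler on the current grid
  cs <- current$signal
  cnr <- nrow(cs); cnc <- ncol(cs)
  cx0 <- current$origin_mm[1]; cy0 <- current$origin_mm[2]
  cdx <- current$spacing_mm[1]; cdy <- current$spacing_mm[2]
  sample_current <- function(x, y) {
    u <- (x - cx0) / cdx; v <- (y - cy0) / cdy   # 0-based pixel coords
    out <- rep(NA_real_, length(u))
    ok <- u >= 0 & u <= cnc - 1 & v >= 0 & v <= cnr - 1
    if (!any(ok)) return(out)
    u <- u[ok]; v <- v[ok]
    j <- pmin(floor(u), cnc - 2L); i <- pmin(floor(v), cnr - 2L)
    if (cnc < 2L) j <- rep(0L, length(u))
    if (cnr < 2L) i <- rep(0L, length(v))
    fu <- u - j; fv <- v - i
    a <- cs[cbind(i + 1L, j + 1L)];                 b <- cs[cbind(i + 1L, pmin(j + 2L, cnc))]
    d <- cs[cbind(pmin(i + 2L, cnr), j + 1L)];      e <- cs[cbind(pmin(i + 2L, cnr), pmin(j + 2L, cnc))]
    out[ok] <- (a * (1 - fu) + b * fu) * (1 - fv) + (d * (1 - fu) + e * fu) * fv
    out
  }

  kk <- floor(radius / subsample_mm + 1e-9)
  offs <- expand.grid(ox = (-kk:kk) * subsample_mm, oy = (-kk:kk) * subsample_mm)
  inr <- offs$ox^2 + offs$oy^2 <= radius^2 + 1e-9
  oxv <- offs$ox[inr]; oyv <- offs$oy[inr]
  co <- grid_xy(reference)
  xm <- co$x[mask]; ym <- co$y[mask]; rm <- R[mask]
  best <- rep(Inf, length(rm))
  for (k in seq_along(oxv)) {
    val <- sample_current(xm + oxv[k], ym + oyv[k])
    cand <- ((rm - val) / s_tol)^2 + (oxv[k]^2 + oyv[k]^2) / dd^2
    sel <- !is.na(cand) & cand < best
    best[sel] <- cand[sel]
  }
  g2 <- matrix(NA_real_, nrow(R), ncol(R))
  g2[mask] <- best
  g2[mask & !is.finite(g2)] <- NA_real_
  gmap <- sqrt(g2)
  gvals <- gmap[!is.na(gmap)]
  structure(list(
    gamma_map = image_grid(gmap, reference$spacing_mm, reference$origin_mm),
    gamma_percent = 100 * mean(gvals < criteria$pass_threshold),
    gamma_mean = mean(gvals),
    n_evaluated = length(gvals),
    normalisation = max(R[mask]),
    criteria = criteria), class = "gamma_result")
}

#' Map of gamma failures
#'
#' Binary mask of evaluated pixels with \eqn{\gamma > 1}, the overlay used to
#' localise the cause of an off-tolerance gamma test. Pixels with gamma
#' exactly 1 are not in the mask (they fail the strict pass test `gamma < 1`
#' but do not exceed 1).
#'
#' @param result a `gamma_result` from [compute_gamma].
#' @return logical matrix, `TRUE` where `gamma > 1`; `FALSE` elsewhere
#'   (including outside the evaluated area).
#' @export
gamma_failure_map <- function(result) {
  stopifnot(inherits(result, "gamma_result"))
  g <- result$gamma_map$signal
  m <- !is.na(g) & g > 1
  m
}
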