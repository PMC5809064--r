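test_that("identity comparison gives an all-zero gamma map", {
  set.seed(11)
  img <- make_gamma_pair()$ref
  g <- compute_gamma(img, img, gamma_criteria(5, 5))
  expect_equal(max(g$gamma_map$signal, na.rm = TRUE), 0)
  expect_equal(g$gamma_percent, 100)
  expect_equal(g$gamma_mean, 0)
  expect_true(g$n_evaluated <= prod(dim(img)))
})

test_that("a uniform +3% offset at 5%/5mm yields gamma = 0.6 everywhere", {
  ref <- image_grid(matrix(100, 16, 16), 2)
  cur <- image_grid(matrix(103, 16, 16), 2)
  g <- compute_gamma(ref, cur, gamma_criteria(5, 5))
  vals <- g$gamma_map$signal[!is.na(g$gamma_map$signal)]
  # displacement cannot reduce a spatially uniform difference
  expect_equal(unique(round(vals, 12)), 0.6)
  expect_equal(g$gamma_percent, 100)
  expect_equal(g$gamma_mean, 0.6)
  # and the oracle closed form agrees
  go <- brute_force_gamma(ref, cur, gamma_criteria(5, 5))
  expect_equal(go$gamma_mean, 0.6, tolerance = 1e-12)
})

test_that("a one-pixel step shift under centre-only search hits gamma exactly 1", {
  # step 100|50 at 3 mm pixels; current shifted one pixel; 3%/3 mm
  ref <- image_grid(cbind(matrix(100, 12, 6), matrix(50, 12, 6)), 3)
  cur <- image_grid(cbind(matrix(100, 12, 7), matrix(50, 12, 5)), 3)
  crit <- gamma_criteria(3, 3, search_pitch_mm = 3, refine = FALSE)
  g <- compute_gamma(ref, cur, crit)
  # the pixel just right of the original edge: ref 50, current 100; the
  # nearest matching signal sits one pixel (= delta_d) away
  co <- epidivd:::grid_xy(g$gamma_map)
  edge_val <- g$gamma_map$signal[co$x == 1.5 & co$y == 1.5]
  expect_equal(edge_val, 1)
  # gamma == 1 fails the strict pass test but is not in the failure map
  fm <- gamma_failure_map(g)
  expect_false(fm[co$x == 1.5 & co$y == 1.5])
  expect_lt(g$gamma_percent, 100)
})

test_that("engine matches the exhaustive brute-force oracle on random fields", {
  set.seed(301)
  devs <- replicate(6, {
    p <- make_gamma_pair()
    crit <- gamma_criteria(3, 3)
    ge <- compute_gamma(p$ref, p$cur, crit)
    go <- brute_force_gamma(p$ref, p$cur, crit)
    max(abs(ge$gamma_map$signal - go$gamma_map$signal), na.rm = TRUE)
  })
  expect_lt(max(devs), 0.02)
})

test_that("oracle rejects a lattice coarser than the distance criterion", {
  p <- list(ref = image_grid(matrix(100, 8, 8), 2),
            cur = image_grid(matrix(100, 8, 8), 2))
  expect_error(brute_force_gamma(p$ref, p$cur, gamma_criteria(3, 3),
                                 subsample_mm = 3), "coarse")
})

test_that("enlarging either criterion never worsens any pixel (fixed lattice)", {
  set.seed(77)
  for (i in 1:5) {
    p <- make_gamma_pair(shift_max_mm = 3)
    base <- gamma_criteria(3, 3, search_radius_mm = 9, search_pitch_mm = 0.5,
                           refine = FALSE)
    g0 <- compute_gamma(p$ref, p$cur, base)
    wider_s <- gamma_criteria(5, 3, search_radius_mm = 9, search_pitch_mm = 0.5,
                              refine = FALSE)
    wider_d <- gamma_criteria(3, 5, search_radius_mm = 9, search_pitch_mm = 0.5,
                              refine = FALSE)
    for (g1 in list(compute_gamma(p$ref, p$cur, wider_s),
                    compute_gamma(p$ref, p$cur, wider_d))) {
      expect_true(all(g1$gamma_map$signal <= g0$gamma_map$signal + 1e-9,
                      na.rm = TRUE))
      expect_gte(g1$gamma_percent, g0$gamma_percent)
      expect_lte(g1$gamma_mean, g0$gamma_mean + 1e-9)
    }
  }
})

test_that("global gamma is invariant under a common rescaling of both images", {
  set.seed(99)
  p <- make_gamma_pair()
  crit <- gamma_criteria(5, 5)
  g1 <- compute_gamma(p$ref, p$cur, crit)
  g2 <- compute_gamma(image_grid(p$ref$signal * 7.3, 2),
                      image_grid(p$cur$signal * 7.3, 2), crit)
  expect_equal(g2$gamma_map$signal, g1$gamma_map$signal, tolerance = 1e-10)
  expect_equal(g2$gamma_percent, g1$gamma_percent)
})

test_that("gamma% accounts for every evaluated pixel", {
  set.seed(5)
  p <- make_gamma_pair(shift_max_mm = 4)
  g <- compute_gamma(p$ref, p$cur, gamma_criteria(2, 2))
  vals <- g$gamma_map$signal[!is.na(g$gamma_map$signal)]
  expect_equal(length(vals), g$n_evaluated)
  expect_equal(g$gamma_percent + 100 * mean(vals >= 1), 100)
  expect_true(g$gamma_percent >= 0 && g$gamma_percent <= 100)
})

test_that("a smooth image translated by half the distance criterion passes everywhere", {
  x <- seq(-15, 15, by = 2)
  blob <- outer(x, x, function(y, x) 100 * exp(-(x^2 + y^2) / 200))
  ref <- image_grid(blob, 2)
  co <- epidivd:::grid_xy(ref)
  cur <- image_grid(matrix(interp_bilinear(ref, co$x - 2.5, co$y, clamp = TRUE),
                           nrow(blob)), 2)
  g <- compute_gamma(ref, cur, gamma_criteria(5, 5))
  inner <- g$gamma_map$signal[3:14, 3:14]
  expect_true(all(inner[!is.na(inner)] < 1))
})

test_that("low-signal pixels are excluded and an empty field is an error", {
  sig <- matrix(1, 16, 16); sig[6:10, 6:10] <- 100
  ref <- image_grid(sig, 2)
  g <- compute_gamma(ref, ref, gamma_criteria(5, 5))
  expect_equal(g$n_evaluated, 25)
  expect_error(compute_gamma(image_grid(matrix(0, 8, 8), 2),
                             image_grid(matrix(0, 8, 8), 2),
                             gamma_criteria(5, 5)), "irradiated")
})
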