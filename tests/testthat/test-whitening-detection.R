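make_cube2 <- function(b1, b2, wl = c(950, 1326)) {
  v <- array(c(b1, b2), c(dim(b1), 2))
  hyper_cube(v, wl, meta = list(calibrated = TRUE))
}

test_that("ratio image divides the nearest requested bands per pixel", {
  m <- matrix(0.6, 3, 3)
  cube <- make_cube2(m, m)
  mask <- sample_mask(matrix(TRUE, 3, 3))
  ri <- ratio_image(cube, mask)
  expect_equal(unname(ri[2, 2]), 1)

  cube2 <- make_cube2(matrix(0.6, 3, 3), matrix(0.1, 3, 3))
  ri2 <- ratio_image(cube2, mask)
  expect_equal(unname(ri2[1, 1]), 6)
  expect_equal(attr(ri2, "band_num_nm"), 950)
  expect_equal(attr(ri2, "band_den_nm"), 1326)

  expect_error(ratio_image(cube, mask, detection_config(lambda_num = 800)),
               "outside")
  # background sentinel
  part <- sample_mask(matrix(c(TRUE, rep(FALSE, 8)), 3, 3))
  expect_equal(sum(!is.na(ratio_image(cube2, part))), 1L)
})

test_that("near-zero denominators drop pixels from the ratio foreground", {
  den <- matrix(0.1, 2, 2); den[1, 1] <- 0
  cube <- make_cube2(matrix(0.5, 2, 2), den)
  mask <- sample_mask(matrix(TRUE, 2, 2))
  ri <- ratio_image(cube, mask)
  expect_true(is.na(ri[1, 1]))
  expect_equal(attr(ri, "n_excluded"), 1L)
})

test_that("the ratio is invariant under per-pixel spectrum scaling", {
  ph <- small_abnormal()
  d <- dim(ph$cal$values)
  set.seed(5)
  thick <- matrix(stats::runif(d[1] * d[2], 0.5, 2), d[1], d[2])
  scaled <- ph$cal$values * array(rep(thick, d[3]), d)
  cube2 <- hyper_cube(scaled, ph$cal$wavelengths, ph$cal$meta)
  r1 <- ratio_image(ph$cal, ph$mask)
  r2 <- ratio_image(cube2, ph$mask)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("binarization is inclusive at the threshold and filters speckle", {
  mask <- sample_mask(matrix(TRUE, 6, 6))
  img <- matrix(5, 6, 6)  # all exactly at T
  cfg <- detection_config(threshold = 5, min_region_pixels = 0L)
  expect_true(all(threshold_binary(img, mask, cfg) == 1L))

  expect_true(all(threshold_binary(matrix(4.99, 6, 6), mask, cfg) == 0L))

  # isolated 1-pixel islands die under the 5-pixel speckle filter
  cb <- matrix(0, 6, 6); cb[cbind(c(1, 3, 5), c(1, 3, 5))] <- 9
  cfg5 <- detection_config(threshold = 5, min_region_pixels = 5L)
  expect_true(all(threshold_binary(cb, mask, cfg5) == 0L))
  expect_equal(sum(threshold_binary(cb, mask, cfg) == 1L), 3L)

  expect_error(threshold_binary(matrix(1, 2, 2), mask), "aligned")
})

test_that("percent whitening follows exact integer counting", {
  mask <- sample_mask(matrix(TRUE, 10, 20))
  bin <- matrix(0L, 10, 20); bin[, 1:10] <- 1L
  rep_ <- whitening_percentage(bin, mask)
  expect_equal(rep_$Wp, 100L)
  expect_equal(rep_$Hp, 100L)
  expect_equal(rep_$Pwp, 50)

  expect_equal(whitening_percentage(matrix(1L, 10, 20), mask)$Pwp, 100)

  # 4x4 toy grid: 12-pixel mask, 3 whitened -> 25%
  m4 <- matrix(c(1, 1, 1, 0,
                 1, 1, 1, 0,
                 1, 1, 1, 0,
                 1, 1, 1, 0), 4, 4, byrow = TRUE) == 1
  b4 <- matrix(0L, 4, 4); b4[1, 1] <- b4[2, 2] <- b4[3, 1] <- 1L
  expect_equal(whitening_percentage(b4, sample_mask(m4))$Pwp, 25)

  bad <- matrix(0L, 4, 4); bad[1, 4] <- 1L
  expect_error(whitening_percentage(bad, sample_mask(m4)), "outside")
  expect_error(whitening_percentage(matrix(0L, 2, 2),
                                    sample_mask(matrix(FALSE, 2, 2))),
               "empty")
})

test_that("Tp = Wp + Hp holds and Pwp is monotone in the threshold", {
  ph <- small_abnormal()
  ri <- ratio_image(ph$cal, ph$mask)
  prev <- Inf
  for (T in 1:10) {
    cfg <- detection_config(threshold = T)
    r <- whitening_percentage(threshold_binary(ri, ph$mask, cfg), ph$mask)
    expect_identical(r$Tp, r$Wp + r$Hp)
    expect_gte(r$Pwp, 0); expect_lte(r$Pwp, 100)
    expect_lte(r$Pwp, prev)
    prev <- r$Pwp
  }
})

test_that("planted whitened fractions are recovered across severities", {
  for (f in c(0.10, 0.25, 0.50)) {
    spec <- phantom_spec(spatial_shape = c(80L, 125L),
                         whitening_fraction = f, seed = 900L + round(100 * f))
    sim <- generate_cube(spec)
    cal <- calibrate(sim$raw, sim$refs)
    mask <- segment_background(cal)
    bin <- threshold_binary(ratio_image(cal, mask), mask)
    r <- whitening_percentage(bin, mask)
    expect_lt(abs(r$Pwp - 100 * f), 2)
  }
})

test_that("the 3-sigma screen flags constructed outliers only", {
  expect_equal(sigma3_screen(rep(50, 5)), rep(FALSE, 5))
  # 20 identical values and one displaced by delta: the outlier's
  # deviation is n/sqrt(n+1) = 4.36 sigma of the full set, so exactly it
  # is flagged for any delta > 0
  out <- c(rep(50, 20), 54)
  flags <- sigma3_screen(out)
  expect_equal(sum(flags), 1L)
  expect_true(flags[length(out)])
  expect_error(sigma3_screen(c(1, 2)), "at least 3")
})

test_that("mesh-plot export keeps the full grid with NA background", {
  img <- matrix(c(1, 2, 3, 4), 2, 2)
  grid <- mesh_plot_data(img)
  expect_equal(nrow(grid), 4L)
  expect_equal(grid$intensity[grid$x == 1 & grid$y == 2], 2)

  mask <- sample_mask(matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))
  grid2 <- mesh_plot_data(img, mask)
  expect_true(is.na(grid2$intensity[grid2$x == 1 & grid2$y == 2]))
  expect_equal(sum(is.na(grid2$intensity)), 1L)
})

test_that("whitened pixels form the upper intensity mode, above threshold 5", {
  ph <- small_abnormal()
  ri <- ratio_image(ph$cal, ph$mask)
  grid <- mesh_plot_data(ri, ph$mask)
  dens <- stats::density(grid$intensity[!is.na(grid$intensity)])
  peaks <- which(diff(sign(diff(dens$y))) == -2) + 1L
  modes <- dens$x[peaks]
  expect_gt(max(modes), 5)
  expect_lt(min(modes), 5)  # healthy tissue mode sits below the threshold
})
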