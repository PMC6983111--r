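test_that("unfold stacks foreground spectra in row-major spatial order", {
  v <- array(seq_len(2 * 2 * 3), c(2, 2, 3))
  cube <- hyper_cube(v, c(900, 950, 1000))
  full <- sample_mask(matrix(TRUE, 2, 2))
  unf <- unfold(list(list(cube = cube, mask = full)))
  expect_equal(dim(unf$X), c(4L, 3L))
  expect_equal(unf$X[1, ], v[1, 1, ])           # (1,1) first
  expect_equal(unf$X[2, ], v[1, 2, ])           # then (1,2): row-major
  expect_equal(unf$index$row, c(1L, 1L, 2L, 2L))
  expect_equal(unf$index$col, c(1L, 2L, 1L, 2L))

  part <- sample_mask(matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2))
  expect_equal(nrow(unfold(list(list(cube = cube, mask = part)))$X), 3L)

  other <- hyper_cube(v, c(900, 951, 1000))
  expect_error(unfold(list(list(cube = cube, mask = full),
                           list(cube = other, mask = full, id = "b"))),
               "wavelength axis.*'b'")
})

test_that("refolding scores inverts unfolding on the foreground", {
  ph <- small_abnormal()
  unf <- unfold(list(list(cube = ph$cal, mask = ph$mask, id = "s")))
  pm <- fit_pca(unf, 3)
  imgs <- refold_scores(pm, unf$index, dim(ph$cal$values)[1:2], component = 1)
  img <- imgs$s
  expect_equal(sum(!is.na(img)), ph$mask$n_foreground)
  expect_equal(img[cbind(unf$index$row, unf$index$col)], pm$scores[, 1])
  expect_true(all(is.na(img[!ph$mask$mask])))
  expect_error(refold_scores(pm, unf$index, c(80, 125), samples = "nope"),
               "unknown sample")
  expect_error(refold_scores(pm, unf$index, c(80, 125), component = 9))
})

test_that("PCA matches a dense covariance eigendecomposition", {
  set.seed(314)
  for (i in 1:20) {
    n <- sample(5:50, 1); p <- sample(3:20, 1)
    X <- matrix(stats::rnorm(n * p), n, p) %*%
      diag(stats::runif(p, 0.2, 3))
    k <- min(n - 1, p)
    pm <- fit_pca(X, k)

    ev <- eigen(stats::cov(X), symmetric = TRUE)
    expect_equal(pm$explained_variance_fraction,
                 (ev$values / sum(ev$values))[seq_len(k)], tolerance = 1e-8)
    expect_equal(abs(pm$loadings), abs(ev$vectors[, seq_len(k)]),
                 tolerance = 1e-8, ignore_attr = TRUE)

    # full-rank reconstruction
    pm_full <- fit_pca(X, min(n, p))
    rec <- pm_full$scores %*% t(pm_full$loadings) +
      matrix(pm_full$mean_spectrum, n, p, byrow = TRUE)
    expect_equal(rec, X, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(sum(pm_full$all_variance_fractions), 1, tolerance = 1e-10)
  }
})

test_that("PCA loadings are orthonormal with the sign convention applied", {
  ph <- small_abnormal()
  unf <- unfold(list(list(cube = normalize_cube(ph$cal, ph$mask),
                          mask = ph$mask)))
  pm <- fit_pca(unf, 3)
  expect_equal(crossprod(pm$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pm$explained_variance_fraction) <= 1e-12))
  expect_lte(sum(pm$explained_variance_fraction), 1 + 1e-10)
  for (j in 1:3)
    expect_gt(pm$loadings[which.max(abs(pm$loadings[, j])), j], 0)
})

test_that("rank-1 data concentrates all variance in the first component", {
  set.seed(1)
  X <- outer(stats::rnorm(30), stats::rnorm(6))
  pm <- fit_pca(X, 2)
  expect_equal(pm$explained_variance_fraction[1], 1, tolerance = 1e-10)
  expect_error(fit_pca(X, 7), "n_components")
})

test_that("waveband selection finds loading extrema with stated tie rules", {
  fake <- function(v, wl) {
    m <- structure(list(loadings = matrix(v, ncol = 1), wavelengths = wl),
                   class = "pca_model")
    m$scores <- matrix(0, 1, 1)
    m
  }
  wl <- seq(900, 990, by = 10)
  # single interior peak
  v <- c(0.1, 0.2, 0.3, 0.9, 0.3, 0.2, 0.1, 0.1, 0.1, 0.1)
  expect_equal(select_wavebands(fake(v, wl), 1, 1), 930)
  # monotone vector: only the high endpoint is an extremum
  v <- seq(0.1, 1, length.out = 10)
  expect_warning(got <- select_wavebands(fake(v, wl), 1, 2), "only 1")
  expect_equal(got, 990)
  # plateau counts once, at its first band
  v <- c(0.1, 0.5, 0.5, 0.5, 0.1, 0.1, 0.8, 0.1, 0.1, 0.1)
  expect_equal(select_wavebands(fake(v, wl), 1, 2), c(910, 960))
  # equal-|loading| peaks: tie broken toward the lower wavelength
  v <- c(0.1, 0.7, 0.1, 0.1, 0.7, 0.1, 0.1, 0.4, 0.1, 0.1)
  expect_equal(select_wavebands(fake(v, wl), 1, 1), 910)
  # extrema ranked on |loading|: sign does not matter
  v <- c(0.1, -0.9, 0.1, 0.1, 0.5, 0.1, 0.1, 0.1, 0.1, 0.1)
  expect_equal(select_wavebands(fake(v, wl), 1, 1), 910)
})

test_that("planted 950/1326 nm features are recovered from the phantom ensemble", {
  ens <- pca_ensemble()
  pm <- fit_pca(ens$unfolded, 3)
  rk <- rank_components(pm, ens$unfolded$index, ens$groups)
  best <- rk$component[1]
  got <- select_wavebands(pm, best, 2)
  wl <- ens$wavelengths
  expect_equal(got[1], wl[which.min(abs(wl - 950))])
  expect_equal(got[2], wl[which.min(abs(wl - 1326))])
})

test_that("the discriminating component separates the whitened region", {
  ens <- pca_ensemble()
  pm <- fit_pca(ens$unfolded, 3)
  best <- rank_components(pm, ens$unfolded$index, ens$groups)$component[1]
  expect_gt(rank_components(pm, ens$unfolded$index,
                            ens$groups)$standardized_difference[1], 2)

  # within one abnormal sample, scores inside the planted region differ
  ph <- small_abnormal()
  norm <- normalize_cube(ph$cal, ph$mask)
  unf1 <- unfold(list(list(cube = norm, mask = ph$mask, id = "s")))
  pm1 <- fit_pca(unf1, 3)
  img <- refold_scores(pm1, unf1$index, dim(norm$values)[1:2], 1)$s
  w <- ph$sim$truth$whitening & ph$mask$mask
  h <- ph$mask$mask & !w
  pooled <- sqrt((stats::var(img[w]) + stats::var(img[h])) / 2)
  expect_gt(abs(mean(img[w]) - mean(img[h])) / pooled, 2)
})

test_that("band_anova reproduces hand-computed sums of squares", {
  # {1,2} vs {3,5}: SSB = 6.25 (df 1), SSW = 2.5 (df 2) -> F = 5
  got <- band_anova(c(1, 2), c(3, 5))
  expect_equal(got$F, 5)
  expect_equal(got$p, stats::pf(5, 1, 2, lower.tail = FALSE))

  expect_equal(band_anova(c(1, 2, 3), c(1, 2, 3))$F, 0)
  degen <- band_anova(c(0, 0), c(1, 1))
  expect_equal(degen$F, Inf)
  expect_equal(degen$p, 0)
  const <- band_anova(c(2, 2), c(2, 2))
  expect_equal(const$F, 0)
  expect_equal(const$p, 1)
  expect_error(band_anova(1, c(1, 2)), "at least 2")
})

test_that("band_anova agrees with aov and with the F = t^2 identity", {
  set.seed(9)
  for (i in 1:10) {
    a <- stats::rnorm(sample(3:8, 1)); b <- stats::rnorm(sample(3:8, 1), 0.5)
    got <- band_anova(a, b)
    df <- data.frame(y = c(a, b),
                     g = rep(c("a", "b"), c(length(a), length(b))))
    ref <- summary(stats::aov(y ~ g, df))[[1]]
    expect_equal(got$F, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(got$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(got$F, unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("per-band ranking flags the characteristic bands as significant", {
  ens <- pca_ensemble()
  g <- ens$groups[rownames(ens$mean_spectra)]
  tab <- band_ranking(ens$mean_spectra[g == "abnormal", ],
                      ens$mean_spectra[g == "normal", ],
                      ens$wavelengths)
  expect_true(all(tab$F >= 0))
  expect_true(all(tab$p > 0 & tab$p <= 1))
  b950 <- which.min(abs(ens$wavelengths - 950))
  b1326 <- which.min(abs(ens$wavelengths - 1326))
  expect_lt(tab$p[b950], 0.05)
  expect_lt(tab$p[b1326], 0.05)
})
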