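test_that("spectrum centre holds the image mean; constant images are pure DC", {
  img <- rand_img(12, 10, seed = 21)
  mag <- fft_magnitude(img)
  centre <- c(floor(12 / 2) + 1, floor(10 / 2) + 1)
  expect_equal(mag[centre[1], centre[2]], mean(img$pixels), tolerance = 1e-12)

  cmag <- fft_magnitude(radiograph(matrix(7, 8, 8)))
  expect_equal(cmag[5, 5], 7, tolerance = 1e-12)
  expect_true(all(cmag[-(5 + (5 - 1) * 8)] < 1e-9))
})

test_that("fft_magnitude matches the direct double-sum evaluation", {
  img <- rand_img(8, 8, seed = 22)
  expect_equal(fft_magnitude(img), dft_magnitude_oracle(img$pixels),
               tolerance = 1e-11)
})

test_that("low_freq_curve matches the explicit ring-membership oracle", {
  img <- rand_img(64, 64, seed = 23)
  mag <- fft_magnitude(img)
  sig <- low_freq_curve(mag, fraction = 0.08, n_bins = 64)
  expect_equal(sig$curve, ring_curve_oracle(mag, 0.08, 64), tolerance = 1e-12)
  expect_equal(sig$auc, sum((sig$curve[-1] + sig$curve[-64]) / 2),
               tolerance = 1e-12)
})

test_that("the curve ignores energy outside the low-frequency band", {
  # smooth isotropic blob
  g <- outer(dnorm(seq(-3, 3, length.out = 64)),
             dnorm(seq(-3, 3, length.out = 64)))
  base <- round(g / max(g) * 20000)
  img_lo <- radiograph(base)
  checker <- 500 * outer(rep(c(0, 1), 32), rep(c(0, 1), 32),
                         function(a, b) (a + b) %% 2)
  img_hi <- radiograph(base + checker)
  s_lo <- low_freq_curve(fft_magnitude(img_lo), fraction = 0.05, n_bins = 32)
  s_hi <- low_freq_curve(fft_magnitude(img_hi), fraction = 0.05, n_bins = 32)
  expect_equal(s_lo$curve, s_hi$curve, tolerance = 1e-9)
})

test_that("radial binning is transposition-invariant for isotropic images", {
  g <- outer(dnorm(seq(-3, 3, length.out = 48)),
             dnorm(seq(-3, 3, length.out = 48)))
  img <- radiograph(round(g / max(g) * 30000))
  timg <- radiograph(t(img$pixels))
  a <- low_freq_curve(fft_magnitude(img), fraction = 0.08, n_bins = 32)
  b <- low_freq_curve(fft_magnitude(timg), fraction = 0.08, n_bins = 32)
  expect_equal(a$curve, b$curve, tolerance = 1e-6)
})

test_that("curve amplitudes scale linearly with global intensity gain", {
  img <- rand_img(32, 32, seed = 24, maxval = 20000)
  doubled <- radiograph(img$pixels * 2)
  a <- low_freq_curve(fft_magnitude(img), fraction = 0.08, n_bins = 32)
  b <- low_freq_curve(fft_magnitude(doubled), fraction = 0.08, n_bins = 32)
  expect_equal(b$curve, 2 * a$curve, tolerance = 1e-9)
  expect_true(all(a$curve >= 0))
  expect_gt(a$auc, 0)
})

test_that("over-narrow fractions raise the populated-ring validation error", {
  mag <- fft_magnitude(rand_img(16, 16, seed = 25))
  expect_error(low_freq_curve(mag, fraction = 0.001, n_bins = 16),
               "rings", class = "radiopos_validation_error")
})

test_that("band_spec validates its edges", {
  expect_error(band_spec(0.3, 0.2), class = "radiopos_validation_error")
  expect_error(band_spec(-0.1, 0.2), class = "radiopos_validation_error")
  expect_error(band_spec(0.1, 0.6), class = "radiopos_validation_error")
  expect_s3_class(band_spec(0.02, 0.15), "band_spec")
})

test_that("Butterworth band-pass kills constants and selects gratings", {
  # constant image has only DC energy
  suppressWarnings(
    out <- butterworth_band(radiograph(matrix(1000, 32, 32)),
                            band_spec(0.05, 0.25, 2))
  )
  expect_true(all(out$pixels == 0))

  # vertical grating: in-band frequency passes, out-of-band is suppressed
  grate <- function(freq) {
    radiograph(matrix(round(5000 + 4000 * cos(2 * pi * freq * (0:63))),
                      64, 64, byrow = FALSE))
  }
  band <- band_spec(0.1, 0.3, 2)
  amp <- function(img) diff(range(butterworth_band(img, band)$pixels))
  ratio <- amp(grate(0.2)) / max(amp(grate(0.015)), 1)
  expect_gt(ratio, 10)
})

test_that("library curves are the arithmetic mean of member curves", {
  w <- tiny_world()
  tpl <- w$phantom$template
  cfg <- w$cfg
  groups <- lapply(radiopos_positions(), function(pos)
    lapply(1:2, function(i) make_position_image(tpl, pos, cfg, i)))
  names(groups) <- radiopos_positions()
  lib <- build_library(groups, fraction = w$fraction, n_bins = 64)
  for (pos in c("head", "limbs")) {
    member <- vapply(groups[[pos]], function(im)
      frequency_signature(im, fraction = w$fraction, n_bins = 64)$curve,
      numeric(64))
    expect_equal(lib$entries[[pos]]$curve, rowMeans(member),
                 tolerance = 1e-12)
  }
  one <- groups
  one[["head"]] <- one[["head"]][1]
  lib1 <- build_library(one, fraction = w$fraction, n_bins = 64)
  expect_equal(lib1$entries$head$curve,
               frequency_signature(groups$head[[1]], fraction = w$fraction,
                                   n_bins = 64)$curve)
})

test_that("build_library insists on exactly the six canonical positions", {
  w <- tiny_world()
  img <- make_position_image(w$phantom$template, "head", w$cfg, 1)
  expect_error(build_library(list(head = list(img))), "missing position",
               class = "radiopos_validation_error")
})

test_that("signature library JSON round-trips exactly", {
  w <- tiny_world()
  tpl <- w$phantom$template
  groups <- lapply(radiopos_positions(), function(pos)
    list(make_position_image(tpl, pos, w$cfg, 1)))
  names(groups) <- radiopos_positions()
  lib <- build_library(groups, fraction = w$fraction, n_bins = 32)
  path <- withr::local_tempfile(fileext = ".json")
  write_library(lib, path)
  back <- read_library(path)
  expect_equal(back$norm, lib$norm)
  expect_equal(back$fraction, lib$fraction)
  for (pos in radiopos_positions())
    expect_equal(back$entries[[pos]]$curve, lib$entries[[pos]]$curve)
})
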