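test_that("downscale preserves proportions, constants, and validates", {
  img <- rand_img(100, 40, seed = 41)
  expect_identical(downscale(img, 1), img)
  half <- downscale(img, 0.5)
  expect_identical(dim(half), c(50L, 20L))
  const <- radiograph(matrix(123, 40, 40))
  expect_true(all(downscale(const, 0.5)$pixels == 123))
  expect_error(downscale(img, 0.05), class = "radiopos_validation_error")
  expect_error(downscale(img, 1.5), class = "radiopos_validation_error")
})

test_that("score maps equal the per-offset loop oracle", {
  for (seed in c(51, 52)) {
    tpl <- rand_img(20, 16, seed = seed)
    inp <- rand_img(6, 5, seed = seed + 100)
    sm <- score_maps(inp, tpl, scale = 1)
    oracle <- score_maps_oracle(inp$pixels, tpl$pixels)
    expect_identical(dim(sm$m_map), c(15L, 12L))
    expect_lt(max(abs(sm$m_map - oracle$m_map)), 1e-7)
    expect_lt(max(abs(sm$r_map - oracle$r_map)), 1e-7)
  }
})

test_that("score maps stay in range and flag degenerate inputs", {
  tpl <- rand_img(25, 25, seed = 53)
  inp <- rand_img(8, 8, seed = 54)
  sm <- score_maps(inp, tpl, scale = 1)
  expect_true(all(sm$r_map >= -1 & sm$r_map <= 1))
  expect_true(all(sm$m_map >= 0))
  expect_error(score_maps(rand_img(30, 30, seed = 1), tpl, scale = 1),
               class = "radiopos_validation_error")
  expect_warning(
    score_maps(radiograph(matrix(5, 6, 6)), tpl, scale = 1),
    "constant input")
})

test_that("an exact crop correlates perfectly at its true offset", {
  tpl <- rand_img(40, 30, seed = 55, maxval = 30000)
  r0 <- 12; c0 <- 7
  crop <- radiograph(tpl$pixels[r0:(r0 + 9), c0:(c0 + 7)])
  sm <- score_maps(crop, tpl, scale = 1)
  expect_equal(sm$r_map[r0, c0], 1, tolerance = 1e-9)
  expect_equal(which(sm$r_map == max(sm$r_map)),
               (c0 - 1) * nrow(sm$r_map) + r0)

  # Pearson affine invariance: gain 2, offset 500 (no clipping at 16 bit)
  crop2 <- radiograph(crop$pixels * 2 + 500)
  sm2 <- score_maps(crop2, tpl, scale = 1)
  expect_lt(max(abs(sm2$r_map - sm$r_map)), 1e-9)
})

test_that("locate recovers every exact-crop offset on a synthetic template", {
  # High-contrast binary template: every window has energy far below the
  # aligned self-match, so the product-score argmax provably coincides
  # with the correlation argmax (Cauchy-Schwarz margin ~ sqrt(n(1-p))).
  set.seed(56)
  tpl <- radiograph(matrix(65535 * rbinom(60 * 24, 1, 0.5), 60, 24))
  ir <- 12; ic <- 10
  offsets <- expand.grid(r = seq(1, 60 - ir + 1, by = 6),
                         c = seq(1, 24 - ic + 1, by = 4))
  for (i in seq_len(nrow(offsets))) {
    r0 <- offsets$r[i]; c0 <- offsets$c[i]
    crop <- radiograph(tpl$pixels[r0:(r0 + ir - 1), c0:(c0 + ic - 1)])
    loc <- locate(crop, tpl, scale = 1)
    expect_equal(loc$box, c(r0, c0, ir, ic))
    expect_equal(loc$r_max, 1, tolerance = 1e-9)
  }
})

test_that("uncorrelated noise still yields a valid match region", {
  tpl <- rand_img(40, 30, seed = 57)
  noise <- rand_img(10, 8, seed = 58)
  loc <- locate(noise, tpl, scale = 1)
  expect_length(loc$box, 4)
  expect_true(loc$box[1] >= 1 && loc$box[2] >= 1)
  expect_true(loc$overlap_fraction >= 0 && loc$overlap_fraction <= 1)
  expect_type(loc$fallback_used, "logical")
})

test_that("box_iou is exact rectangle arithmetic", {
  expect_equal(box_iou(c(1, 1, 10, 10), c(1, 1, 10, 10)), 1)
  expect_equal(box_iou(c(1, 1, 10, 10), c(11, 11, 5, 5)), 0)
  expect_equal(box_iou(c(1, 1, 4, 4), c(3, 3, 4, 4)), 4 / 28)
})

test_that("recognize runs the whole pipeline and annotates the right zone", {
  w <- tiny_world()
  tpl <- w$phantom$template
  groups <- lapply(radiopos_positions(), function(pos)
    lapply(1:2, function(i) make_position_image(tpl, pos, w$cfg, i)))
  names(groups) <- radiopos_positions()
  lib <- build_library(groups, fraction = w$fraction)

  img <- make_position_image(tpl, "head", w$cfg, index = 5)
  res <- recognize(img, lib, tpl, scale = 0.25)
  expect_s3_class(res, "match_result")
  expect_equal(res$classification$chosen, "head")
  expect_true("head" %in% res$annotations$region)

  # exact crop of the pelvis zone: pelvis must carry the largest overlap
  zn <- tpl$regions[tpl$regions$name == "pelvis", ]
  crop <- radiograph(tpl$image$pixels[zn$row_min:zn$row_max,
                                      zn$col_min:zn$col_max])
  res2 <- recognize(crop, lib, tpl, scale = 0.25)
  expect_equal(res2$annotations$region[1], "pelvis")
})

test_that("shifted crops of one band localize to distinct boxes in one region", {
  w <- tiny_world()
  tpl <- w$phantom$template
  zn <- tpl$regions[tpl$regions$name == "lumbar", ]
  boxes <- list()
  for (dc in c(-4, 0, 4)) {
    crop <- radiograph(tpl$image$pixels[zn$row_min:zn$row_max,
                                        (zn$col_min + dc):(zn$col_max + dc)])
    loc <- locate(preprocess(crop), tpl, scale = 1)
    boxes[[length(boxes) + 1]] <- loc$box
    ann <- annotate_region(tpl, loc$box)
    expect_true("lumbar" %in% ann$region)
  }
  expect_gt(length(unique(vapply(boxes, paste, collapse = ",",
                                 character(1)))), 1)
})
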