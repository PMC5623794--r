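test_that("synth_config validates its fields", {
  expect_error(synth_config(noise_sigma = -1), class = "radiopos_validation_error")
  expect_error(synth_config(gain_range = c(0, 1)), class = "radiopos_validation_error")
  expect_error(synth_config(gain_range = c(1.2, 0.8)), class = "radiopos_validation_error")
  expect_error(synth_config(impulse_fraction = 0.5), class = "radiopos_validation_error")
  expect_s3_class(synth_config(), "synth_config")
})

test_that("phantom generation is deterministic and within the 16-bit range", {
  cfg <- synth_config(seed = 3, template_shape = c(200, 120))
  a <- make_phantom(cfg)
  b <- make_phantom(cfg)
  expect_identical(a$template$image$pixels, b$template$image$pixels)
  expect_identical(a$config, b$config)
  px <- a$template$image$pixels
  expect_true(all(px >= 0 & px <= 65535))
  expect_error(make_phantom(synth_config(template_shape = c(40, 30))),
               "too small", class = "radiopos_validation_error")
})

test_that("every zone is brighter than the background on average", {
  w <- tiny_world()
  tpl <- w$phantom$template
  px <- tpl$image$pixels
  mask <- matrix(TRUE, nrow(px), ncol(px))
  for (i in seq_len(nrow(tpl$regions))) {
    zn <- tpl$regions[i, ]
    mask[zn$row_min:zn$row_max, zn$col_min:zn$col_max] <- FALSE
  }
  bg_mean <- mean(px[mask])
  for (i in seq_len(nrow(tpl$regions))) {
    zn <- tpl$regions[i, ]
    expect_gt(mean(px[zn$row_min:zn$row_max, zn$col_min:zn$col_max]),
              bg_mean)
  }
})

test_that("position images are reproducible and respect the noiseless identity", {
  w <- tiny_world()
  tpl <- w$phantom$template
  a <- make_position_image(tpl, "joint", w$cfg, index = 4)
  b <- make_position_image(tpl, "joint", w$cfg, index = 4)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$meta$true_box, b$meta$true_box)
  expect_false(identical(a$pixels,
                         make_position_image(tpl, "joint", w$cfg, 5)$pixels))

  clean_cfg <- synth_config(seed = w$cfg$seed, template_shape = dim(tpl$image),
                            noise_sigma = 0, gain_range = c(1, 1),
                            impulse_fraction = 0)
  img <- make_position_image(tpl, "pelvis", clean_cfg, index = 1)
  bx <- img$meta$true_box
  expect_identical(img$pixels,
                   tpl$image$pixels[bx[1]:(bx[1] + bx[3] - 1),
                                    bx[2]:(bx[2] + bx[4] - 1)])
  expect_error(make_position_image(tpl, "torso", w$cfg, 1),
               class = "radiopos_validation_error")
})

test_that("datasets count out, split disjointly, and stay near their zones", {
  w <- tiny_world()
  dat <- make_dataset(w$phantom$template, w$cfg)
  man <- dat$manifest
  expect_equal(nrow(man), 6 * (w$cfg$n_library + w$cfg$n_per_position))
  expect_equal(length(dat$images), nrow(man))
  expect_length(intersect(man$filename[man$split == "library"],
                          man$filename[man$split == "eval"]), 0)
  d <- dim(w$phantom$template$image)
  zones <- w$phantom$template$regions
  for (i in seq_len(nrow(man))) {
    bx <- c(man$row0[i], man$col0[i], man$rows[i], man$cols[i])
    expect_true(bx[1] >= 1 && bx[2] >= 1 &&
                  bx[1] + bx[3] - 1 <= d[1] && bx[2] + bx[4] - 1 <= d[2])
    zn <- zones[zones$name == man$position[i], ]
    zone_box <- c(zn$row_min, zn$col_min, zn$row_max - zn$row_min + 1,
                  zn$col_max - zn$col_min + 1)
    expect_gte(box_iou(bx, zone_box), 0.6)  # <= 10% jitter on each axis
  }
})

test_that("dataset files land on disk with a matching manifest", {
  w <- tiny_world()
  cfg <- synth_config(seed = 5, template_shape = dim(w$phantom$template$image),
                      n_per_position = 1, n_library = 1)
  out <- withr::local_tempdir()
  dat <- make_dataset(w$phantom$template, cfg, out_dir = out)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_true(all(file.exists(file.path(out, dat$manifest$filename))))
  back <- read_radiograph(file.path(out, dat$manifest$filename[1]))
  expect_identical(back$pixels, dat$images[[dat$manifest$filename[1]]]$pixels)
})

test_that("library curves separate positions far beyond within-position spread", {
  # measured under the default generator conditions (500 x 200 canvas,
  # noise sigma 0.05, gain 0.8-1.2), with 4 members per position
  cfg <- synth_config()
  tpl <- make_phantom(cfg)$template
  frac <- fraction_for_scale(cfg$template_shape[1])
  n_member <- 4
  curves <- lapply(radiopos_positions(), function(pos)
    vapply(seq_len(n_member), function(i)
      frequency_signature(make_position_image(tpl, pos, cfg, i),
                          fraction = frac)$curve, numeric(256)))
  names(curves) <- radiopos_positions()
  centres <- lapply(curves, rowMeans)
  norm <- max(unlist(centres))
  within <- mean(vapply(radiopos_positions(), function(pos)
    mean(apply(curves[[pos]], 2, function(cv)
      mean_variance(cv / norm, centres[[pos]] / norm))), numeric(1)))
  pairs <- utils::combn(radiopos_positions(), 2)
  between <- min(apply(pairs, 2, function(pr)
    mean_variance(centres[[pr[1]]] / norm, centres[[pr[2]]] / norm)))
  expect_gt(between, 5 * within)
})
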