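#' Configuration for the synthetic phantom generator
#'
#' The generator emulates the data the pipeline is calibrated on: a
#' stitched whole-body phantom radiograph with six structurally distinct
#' anatomical zones, plus per-position crops degraded by exposure
#' variation (multiplicative gain), Gaussian noise and salt-and-pepper
#' impulses.
#'
#' @param seed Integer master seed; all generation is reproducible from
#'   it.
#' @param template_shape `c(rows, cols)` of the phantom canvas. The
#'   default 500 x 200 is the working scale; the full-size atlas is
#'   2000 x 800.
#' @param noise_sigma Gaussian noise standard deviation as a fraction of
#'   the 16-bit intensity range, default 0.05.
#' @param gain_range Multiplicative exposure variation `c(lo, hi)`,
#'   default `c(0.8, 1.2)`.
#' @param impulse_fraction Fraction of pixels replaced by salt/pepper
#'   impulses, in `[0, 0.1]`, default 0 (calibrated flat-panel detectors
#'   show negligible residual impulse noise; raise it to stress the
#'   median filter).
#' @param n_per_position Evaluation images generated per position,
#'   default 20.
#' @param n_library Library-building images per position, default 10
#'   (the reference protocol averages 10 per position).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, template_shape = c(500L, 200L),
                         noise_sigma = 0.05, gain_range = c(0.8, 1.2),
                         impulse_fraction = 0, n_per_position = 20L,
                         n_library = 10L) {
  if (noise_sigma < 0) rp_stop("noise_sigma must be >= 0")
  if (length(gain_range) != 2L || gain_range[1] <= 0 ||
      gain_range[1] > gain_range[2])
    rp_stop("gain_range must be c(lo, hi) with 0 < lo <= hi")
  if (impulse_fraction < 0 || impulse_fraction > 0.1)
    rp_stop("impulse_fraction must be in [0, 0.1]")
  if (n_per_position < 0 || n_library < 0)
    rp_stop("image counts must be non-negative")
  structure(list(seed = as.integer(seed),
                 template_shape = as.integer(template_shape),
                 noise_sigma = noise_sigma, gain_range = gain_range,
                 impulse_fraction = impulse_fraction,
                 n_per_position = as.integer(n_per_position),
                 n_library = as.integer(n_library)),
            class = "synth_config")
}

# Proportional zone layout: row/column spans as fractions of the canvas,
# head to limbs top to bottom as on a frontal whole-body radiograph.
zone_layout <- function(shape) {
  rows <- shape[1]
  cols <- shape[2]
  fr <- data.frame(
    name = radiopos_positions(),
    r0 = c(0.03, 0.19, 0.37, 0.53, 0.68, 0.83),
    r1 = c(0.16, 0.34, 0.50, 0.65, 0.80, 0.97),
    c0 = c(0.28, 0.12, 0.38, 0.22, 0.30, 0.24),
    c1 = c(0.72, 0.88, 0.62, 0.78, 0.70, 0.76),
    stringsAsFactors = FALSE
  )
  out <- data.frame(
    name = fr$name,
    row_min = pmax(1, round(fr$r0 * rows)),
    row_max = pmin(rows, round(fr$r1 * rows)),
    col_min = pmax(1, round(fr$c0 * cols)),
    col_max = pmin(cols, round(fr$c1 * cols)),
    stringsAsFactors = FALSE
  )
  if (any(out$row_max - out$row_min < 15) || any(out$col_max - out$col_min < 15))
    rp_stop("template_shape ", rows, "x", cols,
            " too small to place the six zones (each needs >= 16 px)")
  out
}

# Squared normalized elliptical distance from the centre of an nr x nc
# block: < 1 inside the ellipse with semi-axes ry (rows), rx (cols).
ellipse_d2 <- function(nr, nc, cy, cx, ry, rx) {
  y <- (seq_len(nr) - cy) / ry
  x <- (seq_len(nc) - cx) / rx
  outer(y^2, rep(1, nc)) + outer(rep(1, nr), x^2)
}

# Band-limited Gaussian texture with a target standard deviation,
# generated by Butterworth-filtering white noise.
band_noise <- function(nr, nc, band, sd_target) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  gain <- ifftshift2(butterworth_gain(nr, nc, band))
  tex <- Re(stats::fft(stats::fft(z) * gain, inverse = TRUE)) / (nr * nc)
  s <- stats::sd(tex)
  if (s == 0) return(matrix(0, nr, nc))
  tex * (sd_target / s)
}

# Per-zone base (soft-tissue) intensity. Also painted as an apron around
# the zone bbox so that jittered crop windows see the zone's own base
# level instead of dark canvas background: without the apron, the strip
# of background dragged in by the jitter adds a large, draw-dependent
# low-frequency component to the signature.
zone_base <- function(name) {
  switch(name, head = 9000, lungs = 36000, lumbar = 16000, pelvis = 15000,
         joint = 12000, limbs = 10000,
         rp_stop("unknown zone name: ", name))
}

# Render one zone's structure into a local matrix. Structures are inset
# by a 12% margin on each side so that the <= 10% sub-window jitter of
# make_position_image translates them instead of truncating them: the
# magnitude spectrum is translation-invariant, so the inset keeps each
# position's signature stable across jittered crops.
render_zone <- function(name, nr, nc) {
  cy <- (nr + 1) / 2
  cx <- (nc + 1) / 2
  ins_r <- round(0.12 * nr)
  z <- switch(
    name,
    head = {  # bright skull ellipse with a smooth interior
      d2 <- ellipse_d2(nr, nc, cy, cx, 0.46 * nr, 0.42 * nc)
      base <- matrix(zone_base("head"), nr, nc)
      inside <- d2 < 1
      base[inside] <- 46000 * (0.8 + 0.2 * (1 - d2[inside]))
      base
    },
    lungs = {  # bright thorax holding two dark, textured lung fields
      base <- matrix(zone_base("lungs"), nr, nc)
      tex <- band_noise(nr, nc, band_spec(0.02, 0.15, 2L), 3500)
      for (fx in c(0.30, 0.70)) {
        d2 <- ellipse_d2(nr, nc, cy, fx * nc, 0.36 * nr, 0.17 * nc)
        inside <- d2 < 1
        base[inside] <- 8000 + tex[inside]
      }
      base
    },
    lumbar = {  # vertically periodic bright vertebral blocks
      base <- matrix(zone_base("lumbar"), nr, nc)
      n_vert <- 6L
      span <- nr - 2L * ins_r
      pitch <- span / n_vert
      h <- max(2L, round(0.55 * pitch))
      ci <- max(1, round(0.30 * nc)):min(nc, round(0.70 * nc))
      for (k in seq_len(n_vert)) {
        r0 <- ins_r + round((k - 1) * pitch) + 1
        base[r0:min(nr, r0 + h - 1), ci] <- 50000
      }
      base
    },
    pelvis = {  # bright elliptical ring
      d2 <- ellipse_d2(nr, nc, cy, cx, 0.44 * nr, 0.45 * nc)
      base <- matrix(zone_base("pelvis"), nr, nc)
      base[d2 < 1] <- 20000
      base[d2 >= 0.45 & d2 < 1] <- 48000
      base
    },
    joint = {  # two bright bones meeting, with fine trabecular texture
      base <- matrix(zone_base("joint"), nr, nc)
      tex <- band_noise(nr, nc, band_spec(0.20, 0.45, 2L), 3500)
      w <- max(2L, round(0.09 * nc))
      upper <- max(1, round(cx - 1.3 * w)):min(nc, round(cx - 1.3 * w) + w)
      lower <- max(1, round(cx + 0.3 * w)):min(nc, round(cx + 0.3 * w) + w)
      ri_u <- (ins_r + 1):round(0.46 * nr)
      ri_l <- round(0.54 * nr):(nr - ins_r)
      base[ri_u, upper] <- 45000 + tex[ri_u, upper]
      base[ri_l, lower] <- 45000 + tex[ri_l, lower]
      gap <- round(0.46 * nr):round(0.54 * nr)
      ci <- max(1, round(0.25 * nc)):min(nc, round(0.75 * nc))
      base[gap, ci] <- 52000
      base
    },
    limbs = {  # long thin rods: the least projected mass of the six
      base <- matrix(zone_base("limbs"), nr, nc)
      w <- max(2L, round(0.035 * nc))
      ri <- (ins_r + 1):(nr - ins_r)
      for (fx in c(0.30, 0.70)) {
        c0 <- round(fx * nc)
        base[ri, max(1, c0 - w %/% 2):min(nc, c0 + w %/% 2)] <- 38000
      }
      base
    },
    rp_stop("unknown zone name: ", name)
  )
  clip(z, 0, 65535)
}

#' Generate the synthetic whole-body phantom template
#'
#' Renders a body-shaped intensity canvas with six structurally distinct
#' zones in fixed proportional locations (skull ellipse, textured lung
#' fields, periodic lumbar spine, pelvic ring, knee joint with fine
#' trabecular texture, long thin limb rods) over a smoothly varying
#' background, and returns it together with a matching anatomical
#' regions config. Deterministic for a fixed seed.
#'
#' @param cfg A [synth_config()].
#' @return A list with `template` (a [phantom_template()]) and `config`
#'   (the regions config as a list, ready for [yaml::write_yaml()]).
#' @export
make_phantom <- function(cfg) {
  shape <- cfg$template_shape
  zones <- zone_layout(shape)
  canvas <- with_seed(cfg$seed, {
    # smooth background: bilinear upsampling of a coarse random grid
    coarse <- matrix(stats::runif(8 * 4, 3000, 6000), 8, 4)
    bg <- t(EBImage::imageData(EBImage::resize(EBImage::Image(t(coarse)),
                                               w = shape[2], h = shape[1])))
    d <- dim(bg)
    for (i in seq_len(nrow(zones))) {
      # apron: zone base intensity extends 12% beyond the bbox, so the
      # jittered crop window never drags in dark canvas background
      zn <- zones[i, ]
      nr <- zn$row_max - zn$row_min + 1L
      nc <- zn$col_max - zn$col_min + 1L
      mr <- round(0.12 * nr)
      mc <- round(0.12 * nc)
      bg[max(1, zn$row_min - mr):min(d[1], zn$row_max + mr),
         max(1, zn$col_min - mc):min(d[2], zn$col_max + mc)] <-
        zone_base(zn$name)
    }
    for (i in seq_len(nrow(zones))) {
      zn <- zones[i, ]
      nr <- zn$row_max - zn$row_min + 1L
      nc <- zn$col_max - zn$col_min + 1L
      bg[zn$row_min:zn$row_max, zn$col_min:zn$col_max] <-
        render_zone(zn$name, nr, nc)
    }
    clip(round_half_up(bg), 0, 65535)
  })
  img <- radiograph(canvas, bit_depth = 16L)
  template <- phantom_template(img, zones)
  config <- list(
    template = list(rows = shape[1], cols = shape[2], body_height_cm = 165),
    regions = lapply(seq_len(nrow(zones)), function(i) {
      zn <- zones[i, ]
      list(name = zn$name,
           corner1 = c(zn$col_min, zn$row_min),
           corner2 = c(zn$col_max, zn$row_max))
    })
  )
  list(template = template, config = config)
}

# Deterministic per-image seed below 2^31.
image_seed <- function(master, pos_idx, index) {
  as.integer((as.numeric(master) * 1000003 + pos_idx * 10007 + index * 101) %%
               2147483629)
}

#' Generate one noisy position image from the phantom
#'
#' Crops the position's zone with a random sub-window jitter (up to 10%
#' of the zone size on each axis), applies a random exposure gain drawn
#' from `gain_range`, adds Gaussian noise and salt-and-pepper impulses,
#' and clips to the 16-bit range. Deterministic for fixed
#' `(seed, position, index)`.
#'
#' @param template A [phantom_template()] from [make_phantom()].
#' @param position One of the six canonical position names.
#' @param cfg A [synth_config()].
#' @param index Image index (part of the per-image seed).
#' @return A [radiograph()] labelled with the true position; `$meta`
#'   carries `true_box` (`c(row0, col0, rows, cols)` in template
#'   pixels), `gain` and the derived `seed`.
#' @export
make_position_image <- function(template, position, cfg, index = 1L) {
  pos_idx <- match(position, radiopos_positions())
  if (is.na(pos_idx)) rp_stop("unknown position: ", position)
  zones <- template$regions
  zn <- zones[zones$name == position, ]
  if (nrow(zn) != 1L) rp_stop("template has no zone for '", position, "'")
  d <- dim(template$image)
  nr <- zn$row_max - zn$row_min + 1L
  nc <- zn$col_max - zn$col_min + 1L
  seed <- image_seed(cfg$seed, pos_idx, index)
  with_seed(seed, {
    dr <- round(stats::runif(1, -0.1, 0.1) * nr)
    dc <- round(stats::runif(1, -0.1, 0.1) * nc)
    r0 <- clip(zn$row_min + dr, 1, d[1] - nr + 1)
    c0 <- clip(zn$col_min + dc, 1, d[2] - nc + 1)
    px <- template$image$pixels[r0:(r0 + nr - 1), c0:(c0 + nc - 1)]
    gain <- stats::runif(1, cfg$gain_range[1], cfg$gain_range[2])
    px <- px * gain
    if (cfg$noise_sigma > 0)
      px <- px + matrix(stats::rnorm(nr * nc, 0, cfg$noise_sigma * 65535),
                        nr, nc)
    k <- round(cfg$impulse_fraction * nr * nc)
    if (k > 0) {
      at <- sample.int(nr * nc, k)
      px[at] <- ifelse(stats::runif(k) < 0.5, 0, 65535)
    }
    radiograph(clip(round_half_up(px), 0, 65535), bit_depth = 16L,
               label = position,
               meta = list(true_box = c(r0, c0, nr, nc), gain = gain,
                           seed = seed, index = index))
  })
}

#' Generate a labelled synthetic dataset with a manifest
#'
#' Produces `n_library + n_per_position` images per position and a
#' manifest recording, for each image: filename, position, split
#' (`"library"` for the first `n_library` indices, `"eval"` for the
#' rest), true crop box, gain and per-image seed. The two splits are
#' disjoint by construction. If `out_dir` is given, images are written
#' as 16-bit TIFF alongside `manifest.csv`.
#'
#' @param template A [phantom_template()].
#' @param cfg A [synth_config()].
#' @param out_dir Optional output directory.
#' @return A list with `images` (named list of [radiograph()], keyed by
#'   filename) and `manifest` (data frame).
#' @export
make_dataset <- function(template, cfg, out_dir = NULL) {
  n_total <- cfg$n_library + cfg$n_per_position
  if (n_total < 1L) rp_stop("n_library + n_per_position must be >= 1")
  rows <- list()
  images <- list()
  for (pos in radiopos_positions()) {
    for (index in seq_len(n_total)) {
      img <- make_position_image(template, pos, cfg, index)
      fn <- sprintf("%s_%03d.tif", pos, index)
      bx <- img$meta$true_box
      rows[[length(rows) + 1L]] <- data.frame(
        filename = fn, position = pos,
        split = if (index <= cfg$n_library) "library" else "eval",
        index = index, row0 = bx[1], col0 = bx[2], rows = bx[3],
        cols = bx[4], gain = img$meta$gain, seed = img$meta$seed,
        stringsAsFactors = FALSE
      )
      images[[fn]] <- img
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (fn in names(images))
      write_radiograph(images[[fn]], file.path(out_dir, fn))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(images = images, manifest = manifest)
}
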