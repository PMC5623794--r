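#' Normalized, centred 2D Fourier magnitude
#'
#' Computes `|F(u,v)|` of the image with the `1/(MN)` normalization, so
#' the zero-frequency (centre) magnitude equals the image mean. The grid
#' is returned with the zero frequency at row `floor(M/2)+1`, column
#' `floor(N/2)+1`.
#'
#' @param img A [radiograph()].
#' @return A numeric matrix of non-negative magnitudes, same shape as the
#'   image.
#' @export
fft_magnitude <- function(img) {
  if (!is_radiograph(img)) rp_stop("img must be a radiograph")
  px <- img$pixels
  fftshift2(Mod(stats::fft(px)) / length(px))
}

# Centred radial-frequency grid: r(u, v) = sqrt((u/M)^2 + (v/N)^2) with
# u, v the signed frequency indices. Along an axis r reaches ~0.5; at the
# grid corner ~sqrt(0.5).
radial_freq_grid <- function(m, n) {
  u <- freq_index(m) / m
  v <- freq_index(n) / n
  sqrt(outer(u^2, rep(1, n)) + outer(rep(1, m), v^2))
}

#' Butterworth band specification
#'
#' Cut-off radii are normalized radial frequencies (cycles per pixel in
#' the radial metric of [fft_magnitude()]'s grid), with
#' `0 <= low_cut < high_cut <= 0.5`.
#'
#' @param low_cut,high_cut Band edges.
#' @param order Butterworth order (positive integer), default 2.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(low_cut, high_cut, order = 2L) {
  if (!(low_cut >= 0 && low_cut < 0.5)) rp_stop("low_cut must be in [0, 0.5)")
  if (!(high_cut > low_cut && high_cut <= 0.5))
    rp_stop("high_cut must be in (low_cut, 0.5]")
  if (order < 1 || order != floor(order)) rp_stop("order must be a positive integer")
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 order = as.integer(order)), class = "band_spec")
}

#' Frequency signature: low-frequency radial amplitude curve
#'
#' Reduces a centred 2D magnitude grid to a fixed-length 1D curve over
#' the lowest `fraction` of the radial frequency range: cells with radial
#' frequency `r <= fraction * r_max` (the DC cell excluded) are binned
#' into `n_bins` equal-width radial rings, and each curve entry is the
#' mean magnitude of its ring. Rings containing no grid cell are filled
#' by linear interpolation from their nearest populated neighbours
#' (replicated at the ends), so curves from images of different sizes are
#' comparable. The area under the curve (trapezoidal, unit bin spacing)
#' is kept as an auxiliary scalar feature.
#'
#' @param mag Magnitude grid from [fft_magnitude()].
#' @param fraction Low-frequency fraction of the radial range, default
#'   0.02 (the band where anatomical contours concentrate).
#' @param n_bins Curve length, default 256.
#' @param label Optional position label carried on the signature.
#' @return An object of class `freq_signature` with fields `curve`,
#'   `n_bins`, `fraction`, `auc`, `label`.
#' @export
low_freq_curve <- function(mag, fraction = 0.02, n_bins = 256L, label = NULL) {
  if (!is.matrix(mag) || !is.numeric(mag)) rp_stop("mag must be a numeric matrix")
  if (!(fraction > 0 && fraction <= 0.5))
    rp_stop("fraction must be in (0, 0.5]")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) rp_stop("n_bins must be at least 2")
  r <- radial_freq_grid(nrow(mag), ncol(mag))
  thr <- fraction * max(r)
  sel <- r > 0 & r <= thr
  vals <- mag[sel]
  bins <- pmin(n_bins, as.integer(ceiling(r[sel] / (thr / n_bins))))
  pop <- sort(unique(bins))
  if (length(vals) == 0L || length(pop) < 2L)
    rp_stop("fewer than 2 radial rings populated at fraction=", fraction,
            " for a ", nrow(mag), "x", ncol(mag),
            " image; increase fraction or decrease n_bins")
  means <- vapply(pop, function(b) mean(vals[bins == b]), numeric(1))
  curve <- stats::approx(pop, means, xout = seq_len(n_bins), rule = 2)$y
  structure(list(curve = curve, n_bins = n_bins, fraction = fraction,
                 auc = auc_trapz(curve), label = label),
            class = "freq_signature")
}

#' @export
print.freq_signature <- function(x, ...) {
  cat(sprintf("<freq_signature> %d bins, fraction %.3g, AUC %.4g%s\n",
              x$n_bins, x$fraction, x$auc,
              if (is.null(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

#' Compute the frequency signature of a radiograph
#'
#' Convenience wrapper: [preprocess()] (histogram stretch + median
#' filter, optional CLAHE), then [fft_magnitude()] and
#' [low_freq_curve()].
#'
#' @inheritParams low_freq_curve
#' @param img A [radiograph()].
#' @param apply_clahe Passed to [preprocess()].
#' @param preprocessed Set `TRUE` if `img` is already preprocessed.
#' @return A `freq_signature`.
#' @export
frequency_signature <- function(img, fraction = 0.02, n_bins = 256L,
                                apply_clahe = FALSE, preprocessed = FALSE) {
  if (!preprocessed) img <- preprocess(img, apply_clahe = apply_clahe)
  low_freq_curve(fft_magnitude(img), fraction = fraction, n_bins = n_bins,
                 label = img$label)
}

# Centred radial band-pass Butterworth gain grid. The DC cell always has
# gain 0: a band-pass never passes the exposure offset.
butterworth_gain <- function(m, n, band) {
  r <- radial_freq_grid(m, n)
  k2 <- 2L * band$order
  h_high <- 1 / (1 + (r / band$high_cut)^k2)
  if (band$low_cut > 0) {
    h_low <- 1 / (1 + (band$low_cut / r)^k2)
  } else {
    h_low <- matrix(1, m, n)
  }
  h <- h_low * h_high
  h[r == 0] <- 0
  h
}

#' Butterworth band-pass texture extraction
#'
#' Multiplies the image spectrum by a radial band-pass Butterworth gain
#' `H(r) = [1 / (1 + (low/r)^(2k))] * [1 / (1 + (r/high)^(2k))]`,
#' inverse-transforms, clips to the image's intensity range and rounds.
#' The DC component is always removed (the band never passes r = 0), so
#' texture is extracted free of the exposure offset.
#'
#' @param img A [radiograph()].
#' @param band A [band_spec()].
#' @return A [radiograph()] holding the band-limited texture.
#' @export
butterworth_band <- function(img, band) {
  if (!inherits(band, "band_spec")) rp_stop("band must be a band_spec")
  px <- img$pixels
  m <- nrow(px)
  n <- ncol(px)
  gain <- ifftshift2(butterworth_gain(m, n, band))
  out <- Re(stats::fft(stats::fft(px) * gain, inverse = TRUE)) / (m * n)
  maxval <- 2^img$bit_depth - 1
  radiograph(clip(round_half_up(out), 0, maxval), bit_depth = img$bit_depth,
             label = img$label, source = img$source)
}

#' Build the six-position signature library
#'
#' For each of the six canonical positions, preprocesses the member
#' images, computes their frequency signatures and averages the curves
#' into the position's reference curve `F(w)`. The library also stores a
#' shared normalization constant (the maximum amplitude over all six
#' reference curves) that the classifier divides by before computing
#' mean-variance scores, so the decision threshold lives on a fixed
#' scale.
#'
#' @param images Named list mapping each position name to a list of
#'   [radiograph()] objects (at least one per position; the reference
#'   protocol averages 10).
#' @inheritParams frequency_signature
#' @return An object of class `signature_library` with fields `entries`
#'   (named list of `freq_signature`), `fraction`, `n_bins`, `norm`.
#' @export
build_library <- function(images, fraction = 0.02, n_bins = 256L,
                          apply_clahe = FALSE) {
  want <- radiopos_positions()
  missing <- setdiff(want, names(images))
  if (length(missing) > 0L)
    rp_stop("missing position(s) in library input: ",
            paste(missing, collapse = ", "))
  extra <- setdiff(names(images), want)
  if (length(extra) > 0L)
    rp_stop("unknown position(s): ", paste(extra, collapse = ", "))
  entries <- lapply(want, function(pos) {
    grp <- images[[pos]]
    if (length(grp) == 0L) rp_stop("no images for position '", pos, "'")
    curves <- vapply(grp, function(im) {
      frequency_signature(im, fraction = fraction, n_bins = n_bins,
                          apply_clahe = apply_clahe)$curve
    }, numeric(n_bins))
    curve <- rowMeans(matrix(curves, nrow = n_bins))
    structure(list(curve = curve, n_bins = as.integer(n_bins),
                   fraction = fraction, auc = auc_trapz(curve), label = pos),
              class = "freq_signature")
  })
  names(entries) <- want
  norm <- max(vapply(entries, function(e) max(e$curve), numeric(1)))
  structure(list(entries = entries, fraction = fraction,
                 n_bins = as.integer(n_bins), norm = norm),
            class = "signature_library")
}

#' @export
print.signature_library <- function(x, ...) {
  cat(sprintf("<signature_library> %d bins, fraction %.3g, norm %.4g\n",
              x$n_bins, x$fraction, x$norm))
  for (pos in names(x$entries))
    cat(sprintf("  %-7s AUC %.4g\n", pos, x$entries[[pos]]$auc))
  invisible(x)
}

#' Read/write a signature library as JSON
#'
#' The JSON document stores `fraction`, `n_bins`, `norm` and one
#' `{curve, auc}` entry per position; writing then reading restores the
#' library exactly.
#'
#' @param lib A `signature_library`.
#' @param path File path.
#' @return `write_library` returns `path` invisibly; `read_library`
#'   returns the `signature_library`.
#' @export
write_library <- function(lib, path) {
  doc <- list(
    fraction = lib$fraction,
    n_bins = lib$n_bins,
    norm = lib$norm,
    positions = lapply(lib$entries, function(e)
      list(curve = e$curve, auc = e$auc))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  n_bins <- as.integer(doc$n_bins)
  entries <- lapply(radiopos_positions(), function(pos) {
    e <- doc$positions[[pos]]
    if (is.null(e)) rp_stop("library file lacks position '", pos, "'")
    structure(list(curve = as.numeric(e$curve), n_bins = n_bins,
                   fraction = doc$fraction, auc = e$auc, label = pos),
              class = "freq_signature")
  })
  names(entries) <- radiopos_positions()
  structure(list(entries = entries, fraction = doc$fraction,
                 n_bins = n_bins, norm = doc$norm),
            class = "signature_library")
}

#' Export a signature curve as CSV
#'
#' Writes `(bin_index, amplitude)` rows for external plotting.
#'
#' @param sig A `freq_signature`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signature_csv <- function(sig, path) {
  utils::write.csv(
    data.frame(bin_index = seq_len(sig$n_bins), amplitude = sig$curve),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Resolution-matched low-frequency fraction
#'
#' The low-frequency band that carries anatomical contours is physical:
#' a band in cycles per body length. Its extent as a fraction of the
#' digital frequency range therefore scales inversely with the linear
#' pixel resolution. The reference setting is a fraction of 0.02 on the
#' full-size 2000-row template; a template downscaled to `rows` rows
#' needs `base_fraction * reference_rows / rows` to cover the same
#' physical band.
#'
#' @param rows Row count of the template the data comes from.
#' @param base_fraction Fraction at the reference resolution, default
#'   0.02.
#' @param reference_rows Reference template row count, default 2000.
#' @return The resolution-matched fraction (capped at 0.5).
#' @export
fraction_for_scale <- function(rows, base_fraction = 0.02,
                               reference_rows = 2000) {
  min(0.5, base_fraction * reference_rows / rows)
}
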