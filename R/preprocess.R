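#' Linear histogram stretching
#'
#' Maps the image's intensity range linearly onto the full 16-bit range:
#' `out = round(65535 * (f - A) / (B - A))` with `A = min(f)`, `B = max(f)`.
#' The output is always 16-bit, whatever the input depth. A constant image
#' (A == B) cannot be stretched; it maps to all zeros with a warning.
#'
#' @param img A [radiograph()].
#' @return A 16-bit [radiograph()] whose minimum is 0 and maximum 65535
#'   (for non-constant input).
#' @export
stretch_histogram <- function(img) {
  if (!is_radiograph(img)) rp_stop("img must be a radiograph")
  px <- img$pixels
  a <- min(px)
  b <- max(px)
  if (a == b) {
    rp_warn("constant image: histogram stretch is degenerate, returning zeros")
    out <- matrix(0, nrow(px), ncol(px))
  } else {
    out <- round_half_up(65535 * (px - a) / (b - a))
  }
  radiograph(out, bit_depth = 16L, label = img$label, source = img$source,
             meta = img$meta)
}

#' Median filter with edge replication
#'
#' Each output pixel is the median of its `w` x `w` neighbourhood; borders
#' are handled by replicating the nearest edge pixel, which preserves
#' constant images exactly.
#'
#' @param img A [radiograph()].
#' @param w Odd window side, default 5; must not exceed either image
#'   dimension.
#' @return A [radiograph()] of the same size and bit depth.
#' @export
median_filter <- function(img, w = 5L) {
  if (!is_radiograph(img)) rp_stop("img must be a radiograph")
  w <- as.integer(w)
  if (w < 1L || w %% 2L == 0L) rp_stop("window side w must be odd, got ", w)
  px <- img$pixels
  m <- nrow(px)
  n <- ncol(px)
  if (w > min(m, n)) rp_stop("window w=", w, " exceeds image extent ",
                             m, "x", n)
  r <- (w - 1L) %/% 2L
  pad <- px[c(rep(1L, r), seq_len(m), rep(m, r)),
            c(rep(1L, r), seq_len(n), rep(n, r)), drop = FALSE]
  # stack the w^2 shifted views as columns, take the middle order statistic
  k <- (w * w + 1L) %/% 2L
  stack <- matrix(0, m * n, w * w)
  col <- 1L
  for (dc in 0:(w - 1L)) {
    for (dr in 0:(w - 1L)) {
      stack[, col] <- pad[(1L + dr):(m + dr), (1L + dc):(n + dc)]
      col <- col + 1L
    }
  }
  med <- apply(stack, 1L, function(v) sort.int(v, partial = k)[k])
  radiograph(matrix(med, m, n), bit_depth = img$bit_depth, label = img$label,
             source = img$source, meta = img$meta)
}

# CLAHE via EBImage. EBImage requires the image extent to be a multiple of
# the tile grid, so the image is padded by edge replication to the next
# multiple and cropped back afterwards. `limit` follows EBImage's
# convention (contrast-slope multiple, default 2).
clahe_equalize <- function(img, nx = 8L, ny = 8L, limit = 2, bins = 256L) {
  px <- img$pixels
  maxval <- 2^img$bit_depth - 1
  if (min(px) == max(px)) return(img)  # constant image: nothing to equalize
  m <- nrow(px)
  n <- ncol(px)
  m2 <- as.integer(ceiling(m / ny) * ny)
  n2 <- as.integer(ceiling(n / nx) * nx)
  pad <- px[c(seq_len(m), rep(m, m2 - m)), c(seq_len(n), rep(n, n2 - n)),
            drop = FALSE]
  # EBImage images are x-major: transpose so nx tiles run across columns
  eq <- EBImage::clahe(EBImage::Image(t(pad) / maxval),
                       nx = nx, ny = ny, bins = bins, limit = limit)
  out <- t(EBImage::imageData(eq))[seq_len(m), seq_len(n), drop = FALSE]
  out <- clip(round_half_up(out * maxval), 0, maxval)
  radiograph(out, bit_depth = img$bit_depth, label = img$label,
             source = img$source, meta = img$meta)
}

#' Standard preprocessing chain
#'
#' Applies, in order: linear histogram stretching onto the 16-bit range,
#' a `w` x `w` median filter, and optionally contrast-limited adaptive
#' histogram equalization (CLAHE) to compensate exposure variation.
#' With CLAHE off the chain is invariant to positive affine intensity
#' transforms of the input (gain and offset cancel in the stretch).
#'
#' @param img A [radiograph()].
#' @param apply_clahe Apply CLAHE after filtering? Default `FALSE`.
#' @param w Median window side (odd), default 5.
#' @param clahe_nx,clahe_ny CLAHE tile grid, default 8 x 8.
#' @param clahe_limit CLAHE contrast limit (EBImage slope convention),
#'   default 2.
#' @return A 16-bit [radiograph()].
#' @export
preprocess <- function(img, apply_clahe = FALSE, w = 5L,
                       clahe_nx = 8L, clahe_ny = 8L, clahe_limit = 2) {
  out <- median_filter(stretch_histogram(img), w = w)
  if (apply_clahe)
    out <- clahe_equalize(out, nx = clahe_nx, ny = clahe_ny, limit = clahe_limit)
  out
}
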