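#' Downscale a radiograph, preserving aspect ratio
#'
#' Bilinear resampling by the same factor on both axes. `factor = 1`
#' returns the input unchanged.
#'
#' @param img A [radiograph()].
#' @param factor Positive factor `<= 1`.
#' @return A [radiograph()].
#' @export
downscale <- function(img, factor) {
  if (!is_radiograph(img)) rp_stop("img must be a radiograph")
  if (!(factor > 0 && factor <= 1)) rp_stop("factor must be in (0, 1]")
  if (factor == 1) return(img)
  nr <- as.integer(round(nrow(img$pixels) * factor))
  nc <- as.integer(round(ncol(img$pixels) * factor))
  if (nr < 8L || nc < 8L)
    rp_stop("downscaled size ", nr, "x", nc, " is below the 8x8 minimum")
  px <- t(EBImage::imageData(EBImage::resize(EBImage::Image(t(img$pixels)),
                                             w = nc, h = nr)))
  maxval <- 2^img$bit_depth - 1
  radiograph(clip(round_half_up(px), 0, maxval), bit_depth = img$bit_depth,
             label = img$label, source = img$source, meta = img$meta)
}

# Sliding-window sums of Tm and Tm^2 over all ir x ic windows, by
# integral images (exact for integer-valued data in double range).
window_sums <- function(Tm, ir, ic) {
  tr <- nrow(Tm)
  tc <- ncol(Tm)
  kr <- tr - ir + 1L
  kc <- tc - ic + 1L
  int_img <- function(x) {
    cs <- matrix(0, tr + 1L, tc + 1L)
    cs[-1L, -1L] <- t(apply(apply(x, 2L, cumsum), 1L, cumsum))
    cs
  }
  win <- function(cs) {
    cs[(1L + ir):(tr + 1L), (1L + ic):(tc + 1L)] -
      cs[1:kr, (1L + ic):(tc + 1L)] -
      cs[(1L + ir):(tr + 1L), 1:kc] +
      cs[1:kr, 1:kc]
  }
  list(s1 = win(int_img(Tm)), s2 = win(int_img(Tm^2)))
}

# Valid-mode cross-correlation sum(input * window) for every offset,
# computed in the frequency domain.
cross_correlate <- function(input, Tm) {
  tr <- nrow(Tm)
  tc <- ncol(Tm)
  ipad <- matrix(0, tr, tc)
  ipad[seq_len(nrow(input)), seq_len(ncol(input))] <- input
  cc <- Re(stats::fft(stats::fft(Tm) * Conj(stats::fft(ipad)),
                      inverse = TRUE)) / (tr * tc)
  cc[1:(tr - nrow(input) + 1L), 1:(tc - ncol(input) + 1L), drop = FALSE]
}

#' Sliding-window matrix-product and correlation score maps
#'
#' Both images are downscaled by `scale`, then for every valid top-left
#' offset of the input on the template:
#' \itemize{
#'   \item the matrix-product score
#'     `M = sum(input * window) / sum(input^2)` (energy-normalized
#'     product; sensitive to the window's absolute intensity), and
#'   \item the Pearson correlation `R` between the input and the window
#'     (invariant to any positive affine intensity transform of either
#'     image; windows with zero variance score 0 by convention)
#' }
#' are evaluated. The two maps have shape
#' `(T_rows - I_rows + 1) x (T_cols - I_cols + 1)`.
#'
#' @param input,template [radiograph()] objects; after scaling the input
#'   must be strictly smaller than the template on both axes.
#' @param scale Downscale factor in `(0, 1]`, default 0.25.
#' @return An object of class `score_maps`: list with `m_map`, `r_map`,
#'   `scale`, `input_shape_scaled`, `input_shape_full`,
#'   `template_shape_scaled`.
#' @export
score_maps <- function(input, template, scale = 0.25) {
  full_dim <- dim(input)
  inp <- downscale(input, scale)
  tpl <- downscale(template, scale)
  im <- inp$pixels
  tm <- tpl$pixels
  if (nrow(im) >= nrow(tm) || ncol(im) >= ncol(tm))
    rp_stop("scaled input (", nrow(im), "x", ncol(im),
            ") must be strictly smaller than scaled template (",
            nrow(tm), "x", ncol(tm), ")")
  n <- length(im)
  sum_i <- sum(im)
  sum_i2 <- sum(im^2)
  if (sum_i2 == 0) rp_stop("input image is identically zero")
  cc <- cross_correlate(im, tm)
  ws <- window_sums(tm, nrow(im), ncol(im))
  m_map <- cc / sum_i2
  var_i <- sum_i2 - sum_i^2 / n
  var_w <- pmax(ws$s2 - ws$s1^2 / n, 0)
  num <- cc - ws$s1 * (sum_i / n)
  if (var_i <= 0) {
    rp_warn("constant input: correlation map undefined, set to 0")
    r_map <- matrix(0, nrow(cc), ncol(cc))
  } else {
    den <- sqrt(var_i * var_w)
    r_map <- matrix(0, nrow(cc), ncol(cc))
    ok <- var_w > 0
    r_map[ok] <- num[ok] / den[ok]
    r_map <- clip(r_map, -1, 1)
  }
  structure(list(m_map = m_map, r_map = r_map, scale = scale,
                 input_shape_scaled = dim(im),
                 input_shape_full = full_dim,
                 template_shape_scaled = dim(tm)),
            class = "score_maps")
}

# First argmax of a matrix in row-major scan order. Returns c(row, col).
argmax_rowmajor <- function(m) {
  tm <- t(m)
  j <- which.max(tm)
  ncols <- ncol(m)
  c(((j - 1L) %/% ncols) + 1L, ((j - 1L) %% ncols) + 1L)
}

# Boxes are c(row0, col0, rows, cols), 1-based top-left plus extent.
box_intersect <- function(b1, b2) {
  r0 <- max(b1[1], b2[1])
  c0 <- max(b1[2], b2[2])
  r1 <- min(b1[1] + b1[3], b2[1] + b2[3])
  c1 <- min(b1[2] + b1[4], b2[2] + b2[4])
  if (r1 <= r0 || c1 <= c0) return(NULL)
  c(r0, c0, r1 - r0, c1 - c0)
}

box_area <- function(b) b[3] * b[4]

#' Intersection-over-union of two boxes
#'
#' Boxes are `c(row0, col0, rows, cols)` (1-based top-left plus extent).
#'
#' @param b1,b2 Length-4 numeric boxes.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(b1, b2) {
  inter <- box_intersect(b1, b2)
  ia <- if (is.null(inter)) 0 else box_area(inter)
  ia / (box_area(b1) + box_area(b2) - ia)
}

# Map a scaled-coordinate offset back to full resolution.
unscale_box <- function(row0, col0, full_rows, full_cols, scale,
                        bound_rows, bound_cols) {
  r0 <- round((row0 - 1) / scale) + 1
  c0 <- round((col0 - 1) / scale) + 1
  r0 <- clip(r0, 1, max(1, bound_rows - full_rows + 1))
  c0 <- clip(c0, 1, max(1, bound_cols - full_cols + 1))
  c(r0, c0, min(full_rows, bound_rows), min(full_cols, bound_cols))
}

#' Localize an input radiograph on the phantom template
#'
#' Computes the [score_maps()], takes the input-sized rectangle at the
#' argmax of each map (first occurrence in row-major order on exact
#' ties), maps both rectangles back to full-resolution template pixels,
#' and returns their intersection as the recognized region. If the two
#' rectangles do not intersect, the correlation rectangle is used alone
#' (the correlation score is exposure-invariant, the product score is
#' not) and the fallback is recorded.
#'
#' @param input A [radiograph()] (preprocessed).
#' @param template A [phantom_template()] or a plain [radiograph()].
#' @param scale Downscale factor, default 0.25.
#' @return An object of class `match_region`: list with `box`, `m_box`,
#'   `r_box` (all `c(row0, col0, rows, cols)`, full-resolution),
#'   `overlap_fraction` (`|box| / |union of m_box, r_box|`),
#'   `fallback_used`, `m_max`, `r_max`, `scale`.
#' @export
locate <- function(input, template, scale = 0.25) {
  tpl_img <- if (inherits(template, "phantom_template")) template$image
             else template
  sm <- score_maps(input, tpl_img, scale = scale)
  m_at <- argmax_rowmajor(sm$m_map)
  r_at <- argmax_rowmajor(sm$r_map)
  d <- dim(tpl_img)
  fr <- sm$input_shape_full[1]
  fc <- sm$input_shape_full[2]
  m_box <- unscale_box(m_at[1], m_at[2], fr, fc, scale, d[1], d[2])
  r_box <- unscale_box(r_at[1], r_at[2], fr, fc, scale, d[1], d[2])
  inter <- box_intersect(m_box, r_box)
  fallback <- is.null(inter)
  box <- if (fallback) r_box else inter
  union_area <- box_area(m_box) + box_area(r_box) -
    (if (is.null(inter)) 0 else box_area(inter))
  structure(list(box = box, m_box = m_box, r_box = r_box,
                 overlap_fraction = box_area(box) / union_area,
                 fallback_used = fallback,
                 m_max = sm$m_map[m_at[1], m_at[2]],
                 r_max = sm$r_map[r_at[1], r_at[2]],
                 scale = scale),
            class = "match_region")
}

#' @export
print.match_region <- function(x, ...) {
  cat(sprintf(
    "<match_region> box [%d,%d %dx%d] R=%.4f M=%.4g%s\n",
    x$box[1], x$box[2], x$box[3], x$box[4], x$r_max, x$m_max,
    if (x$fallback_used) " (fallback to R box)" else ""))
  invisible(x)
}

#' Full recognition workflow for one radiograph
#'
#' Runs the complete pipeline: preprocessing, frequency-signature
#' extraction, position classification against the library, localization
#' on the phantom template, and anatomical annotation of the matched
#' box. Any stage failure is re-raised with the stage name.
#'
#' @param img A raw [radiograph()].
#' @param lib A `signature_library`.
#' @param template A [phantom_template()].
#' @param threshold Classifier decision threshold, default 0.02.
#' @param scale Matching downscale factor, default 0.25.
#' @param apply_clahe Apply CLAHE during preprocessing, default `FALSE`.
#' @param tiebreak Classifier tie-break mode, see [classify()].
#' @return An object of class `match_result`: list with
#'   `classification` ([classify()] output), `region` ([locate()]
#'   output), `annotations` ([annotate_region()] output) and `source`.
#' @export
recognize <- function(img, lib, template, threshold = 0.02, scale = 0.25,
                      apply_clahe = FALSE,
                      tiebreak = c("both_below", "gap_below")) {
  tiebreak <- match.arg(tiebreak)
  pp <- with_stage("preprocess", preprocess(img, apply_clahe = apply_clahe))
  sig <- with_stage("signature",
                    frequency_signature(pp, fraction = lib$fraction,
                                        n_bins = lib$n_bins,
                                        preprocessed = TRUE))
  cls <- with_stage("classify",
                    classify(sig, lib, threshold = threshold,
                             tiebreak = tiebreak))
  loc <- with_stage("locate", locate(pp, template, scale = scale))
  ann <- with_stage("annotate", annotate_region(template, loc$box))
  structure(list(classification = cls, region = loc, annotations = ann,
                 source = img$source),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> position=%s (by %s), box [%d,%d %dx%d]\n",
              x$classification$chosen, x$classification$decided_by,
              x$region$box[1], x$region$box[2], x$region$box[3],
              x$region$box[4]))
  if (nrow(x$annotations) > 0) {
    for (i in seq_len(nrow(x$annotations)))
      cat(sprintf("  region %-7s overlap %.2f\n",
                  x$annotations$region[i], x$annotations$overlap[i]))
  } else cat("  no annotated region overlaps the box\n")
  invisible(x)
}

#' Serialize a match result to JSON
#'
#' Boxes are emitted 0-based (`[row0, col0, rows, cols]`) for
#' interoperability; all six mean-variance and cosine scores are
#' included so every decision can be audited.
#'
#' @param result A `match_result`.
#' @param path Optional output path; if `NULL`, the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
match_result_json <- function(result, path = NULL) {
  cls <- result$classification
  reg <- result$region
  doc <- list(
    position = cls$chosen,
    decided_by = cls$decided_by,
    threshold = cls$threshold,
    mean_variances = as.list(cls$mean_variances),
    cosines = as.list(cls$cosines),
    box = as.integer(c(reg$box[1] - 1, reg$box[2] - 1, reg$box[3], reg$box[4])),
    m_box = as.integer(c(reg$m_box[1] - 1, reg$m_box[2] - 1, reg$m_box[3],
                         reg$m_box[4])),
    r_box = as.integer(c(reg$r_box[1] - 1, reg$r_box[2] - 1, reg$r_box[3],
                         reg$r_box[4])),
    overlap_fraction = reg$overlap_fraction,
    fallback_used = reg$fallback_used,
    m_max = reg$m_max,
    r_max = reg$r_max,
    regions = if (nrow(result$annotations) > 0) {
      lapply(seq_len(nrow(result$annotations)), function(i)
        list(name = result$annotations$region[i],
             overlap = result$annotations$overlap[i]))
    } else list()
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
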