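#' Anatomical region definitions
#'
#' A region is a named axis-aligned bounding box on the phantom template.
#' Corner pairs follow the atlas-config convention: `[column, row]`,
#' 1-based, inclusive at both ends (the convention in which the reference
#' head box runs from `[260, 1]` to `[540, 285]` on a 2000 x 800 template).
#' Internally boxes are stored as 1-based inclusive row/column ranges.
#'
#' @param name Region name (e.g. `"head"`).
#' @param corner1,corner2 Numeric length-2 vectors `c(column, row)`.
#' @return A one-row data frame with columns `name`, `row_min`, `row_max`,
#'   `col_min`, `col_max`.
#' @export
anatomical_region <- function(name, corner1, corner2) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    rp_stop("region name must be a non-empty string")
  if (length(corner1) != 2L || length(corner2) != 2L)
    rp_stop("region '", name, "': corners must be [column, row] pairs")
  cr <- c(corner1[1], corner2[1])
  rr <- c(corner1[2], corner2[2])
  if (any(cr < 1) || any(rr < 1) || any(cr != floor(cr)) || any(rr != floor(rr)))
    rp_stop("region '", name, "': corner coordinates must be positive integers")
  data.frame(name = name,
             row_min = min(rr), row_max = max(rr),
             col_min = min(cr), col_max = max(cr),
             stringsAsFactors = FALSE)
}

#' Whole-body phantom template
#'
#' Bundles the stitched whole-body phantom radiograph with its named
#' anatomical regions and the canonical position list. The reference
#' template is 2000 rows x 800 columns and corresponds to a 165 cm body.
#'
#' @param image A [radiograph()] (the template).
#' @param regions Data frame of regions as produced by
#'   [anatomical_region()] (row-bound), or `NULL`/empty for an
#'   unannotated template.
#' @param body_height_cm Height of the body the template depicts.
#' @param position_names The six classifier positions; must equal
#'   [radiopos_positions()] as a set.
#' @return An object of class `phantom_template`.
#' @export
phantom_template <- function(image, regions = NULL, body_height_cm = 165,
                             position_names = radiopos_positions()) {
  if (!is_radiograph(image)) rp_stop("image must be a radiograph")
  if (length(position_names) != 6L ||
      !setequal(position_names, radiopos_positions()))
    rp_stop("position_names must be the six canonical positions: ",
            paste(radiopos_positions(), collapse = ", "))
  if (is.null(regions) || nrow(regions) == 0L) {
    rp_warn("template has no anatomical regions: annotation is disabled")
    regions <- data.frame(name = character(), row_min = numeric(),
                          row_max = numeric(), col_min = numeric(),
                          col_max = numeric(), stringsAsFactors = FALSE)
  } else {
    if (anyDuplicated(regions$name))
      rp_stop("duplicate region name: ",
              regions$name[duplicated(regions$name)][1])
    d <- dim(image)
    for (i in seq_len(nrow(regions))) {
      rg <- regions[i, ]
      if (rg$row_max > d[1] || rg$col_max > d[2])
        rp_stop("region '", rg$name, "' exceeds template extent ",
                d[1], "x", d[2])
    }
  }
  structure(list(image = image, regions = regions,
                 body_height_cm = body_height_cm,
                 position_names = radiopos_positions()),
            class = "phantom_template")
}

#' @export
print.phantom_template <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<phantom_template> %dx%d, body %g cm, %d regions\n",
              d[1], d[2], x$body_height_cm, nrow(x$regions)))
  invisible(x)
}

regions_from_config <- function(cfg) {
  regs <- lapply(cfg$regions, function(r) {
    if (is.null(r$name) || is.null(r$corner1) || is.null(r$corner2))
      rp_stop("each region needs name, corner1 and corner2")
    anatomical_region(r$name, unlist(r$corner1), unlist(r$corner2))
  })
  if (length(regs) == 0L) NULL else do.call(rbind, regs)
}

#' Load a phantom template from an image plus a regions config
#'
#' The config (YAML or JSON) holds `template: {rows, cols, body_height_cm}`
#' and `regions: [{name, corner1: [col, row], corner2: [col, row]}]` with
#' 1-based inclusive corners. The image must match the configured shape.
#'
#' @param image_path Path to the template image (PNG/TIFF).
#' @param regions_config Path to the YAML/JSON config.
#' @return A [phantom_template()].
#' @export
load_template <- function(image_path, regions_config) {
  cfg <- if (tolower(tools::file_ext(regions_config)) == "json") {
    jsonlite::read_json(regions_config)
  } else {
    yaml::read_yaml(regions_config)
  }
  if (is.null(cfg$template)) rp_stop("config lacks a 'template' block")
  img <- read_radiograph(image_path)
  d <- dim(img)
  rows <- cfg$template$rows
  cols <- cfg$template$cols
  if (!is.null(rows) && (d[1] != rows || d[2] != cols))
    rp_stop("template image is ", d[1], "x", d[2],
            " but config declares ", rows, "x", cols)
  height <- cfg$template$body_height_cm
  if (is.null(height)) height <- 165
  phantom_template(img, regions_from_config(cfg), body_height_cm = height)
}

#' Save a phantom template (image + regions config)
#'
#' Inverse of [load_template()]: the pair round-trips bit-exactly.
#'
#' @param template A [phantom_template()].
#' @param image_path Output image path (`.tif` recommended for 16-bit).
#' @param config_path Output YAML path.
#' @return `config_path`, invisibly.
#' @export
save_template <- function(template, image_path, config_path) {
  write_radiograph(template$image, image_path)
  d <- dim(template$image)
  regions <- lapply(seq_len(nrow(template$regions)), function(i) {
    rg <- template$regions[i, ]
    list(name = rg$name,
         corner1 = c(rg$col_min, rg$row_min),
         corner2 = c(rg$col_max, rg$row_max))
  })
  yaml::write_yaml(
    list(template = list(rows = d[1], cols = d[2],
                         body_height_cm = template$body_height_cm),
         regions = regions),
    config_path
  )
  invisible(config_path)
}

#' Stitch part images into a whole-body canvas
#'
#' Each part is histogram-stretched, rescaled (bilinear) by its scale
#' factor and pasted at its offset. Where parts overlap, the canvas takes
#' the per-pixel mean of all contributors; untouched canvas stays 0.
#'
#' @param parts List of parts, each a list with `image` (a
#'   [radiograph()]), `row_offset`, `col_offset` (1-based top-left
#'   position on the canvas) and `scale` (positive rescale factor,
#'   default 1).
#' @param canvas_shape `c(rows, cols)` of the output canvas.
#' @return A 16-bit [radiograph()].
#' @export
stitch_parts <- function(parts, canvas_shape) {
  rows <- canvas_shape[1]
  cols <- canvas_shape[2]
  acc <- matrix(0, rows, cols)
  cnt <- matrix(0, rows, cols)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    sc <- if (is.null(p$scale)) 1 else p$scale
    if (sc <= 0) rp_stop("part ", i, ": scale must be positive")
    img <- suppressWarnings(stretch_histogram(p$image))
    px <- img$pixels
    if (sc != 1) {
      nr <- max(1L, as.integer(round(nrow(px) * sc)))
      nc <- max(1L, as.integer(round(ncol(px) * sc)))
      px <- t(EBImage::imageData(EBImage::resize(EBImage::Image(t(px)),
                                                 w = nc, h = nr)))
      px <- clip(round_half_up(px), 0, 65535)
    }
    r0 <- p$row_offset
    c0 <- p$col_offset
    if (r0 < 1 || c0 < 1 || r0 + nrow(px) - 1 > rows || c0 + ncol(px) - 1 > cols)
      rp_stop("part ", i, " does not fit the canvas at offset (",
              r0, ", ", c0, ") with size ", nrow(px), "x", ncol(px))
    ri <- r0:(r0 + nrow(px) - 1)
    ci <- c0:(c0 + ncol(px) - 1)
    acc[ri, ci] <- acc[ri, ci] + px
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  out <- acc
  hit <- cnt > 0
  out[hit] <- round_half_up(acc[hit] / cnt[hit])
  radiograph(out, bit_depth = 16L)
}

#' Annotate a matched box with overlapping anatomical regions
#'
#' Intersects the box with every region of the template and reports, for
#' each region hit, the fraction of the box covered by that region
#' (exact integer rectangle arithmetic), sorted by decreasing overlap.
#'
#' @param template A [phantom_template()].
#' @param box Length-4 vector `c(row0, col0, rows, cols)`: 1-based
#'   top-left corner plus extent, in template pixels.
#' @return Data frame with columns `region` and `overlap`; zero rows if
#'   the box touches no region.
#' @export
annotate_region <- function(template, box) {
  if (length(box) != 4L) rp_stop("box must be c(row0, col0, rows, cols)")
  r0 <- box[1]; c0 <- box[2]; nr <- box[3]; nc <- box[4]
  if (nr <= 0 || nc <= 0) rp_stop("degenerate box: zero area")
  d <- dim(template$image)
  if (r0 < 1 || c0 < 1 || r0 + nr - 1 > d[1] || c0 + nc - 1 > d[2])
    rp_stop("box outside template bounds")
  regs <- template$regions
  if (nrow(regs) == 0L)
    return(data.frame(region = character(), overlap = numeric(),
                      stringsAsFactors = FALSE))
  r1 <- r0 + nr - 1
  c1 <- c0 + nc - 1
  ir <- pmax(0, pmin(regs$row_max, r1) - pmax(regs$row_min, r0) + 1)
  ic <- pmax(0, pmin(regs$col_max, c1) - pmax(regs$col_min, c0) + 1)
  frac <- (ir * ic) / (nr * nc)
  keep <- frac > 0
  out <- data.frame(region = regs$name[keep], overlap = frac[keep],
                    stringsAsFactors = FALSE)
  out[order(-out$overlap, out$region), , drop = FALSE]
}
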