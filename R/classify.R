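#' Mean-variance similarity between two amplitude curves
#'
#' The root-mean-square difference `sqrt(sum((f - F)^2) / n)`. Smaller
#' values mean more similar curves; 0 means identical.
#'
#' @param f,F_ref Numeric vectors of equal length.
#' @return A non-negative scalar.
#' @export
mean_variance <- function(f, F_ref) {
  if (length(f) != length(F_ref))
    rp_stop("curve length mismatch: ", length(f), " vs ", length(F_ref))
  if (length(f) < 1L) rp_stop("curves must be non-empty")
  sqrt(sum((f - F_ref)^2) / length(f))
}

#' Cosine similarity between two amplitude curves
#'
#' `cos(theta) = (f . F) / (|f| |F|)`, in `[-1, 1]`; 1 means the curves
#' are collinear (zero angle). Undefined for a zero vector.
#'
#' @inheritParams mean_variance
#' @return A scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(f, F_ref) {
  if (length(f) != length(F_ref))
    rp_stop("curve length mismatch: ", length(f), " vs ", length(F_ref))
  nf <- sqrt(sum(f^2))
  nF <- sqrt(sum(F_ref^2))
  if (nf == 0 || nF == 0)
    rp_stop("cosine similarity undefined for a zero curve")
  clip(sum(f * F_ref) / (nf * nF), -1, 1)
}

# Normalize a curve by the library's shared scale so the decision
# threshold is meaningful.
normalized_curve <- function(curve, lib) {
  if (lib$norm > 0) curve / lib$norm else curve
}

#' Rank the six positions by mean-variance similarity
#'
#' Scores the input signature against each of the six library curves
#' (both divided by the library's shared normalization constant) and
#' sorts ascending: most similar first. Exact ties keep the canonical
#' position order.
#'
#' @param sig A `freq_signature` (see [frequency_signature()]).
#' @param lib A `signature_library` (see [build_library()]).
#' @return Data frame with columns `position` and `a`, sorted by
#'   increasing `a`.
#' @export
rank_positions <- function(sig, lib) {
  if (sig$n_bins != lib$n_bins)
    rp_stop("signature has ", sig$n_bins, " bins but library has ",
            lib$n_bins)
  f <- normalized_curve(sig$curve, lib)
  a <- vapply(lib$entries, function(e)
    mean_variance(f, normalized_curve(e$curve, lib)), numeric(1))
  out <- data.frame(position = names(a), a = unname(a),
                    stringsAsFactors = FALSE)
  out[order(out$a), , drop = FALSE]  # stable sort: ties keep canonical order
}

#' Classify a radiographic position from its frequency signature
#'
#' Ranks the six positions by normalized mean-variance. If the two
#' smallest scores both fall below `threshold` (the curves are nearly
#' indistinguishable on the mean-variance scale), the decision falls to
#' the cosine similarity between the input curve and the two candidate
#' reference curves, and the larger cosine wins; otherwise the
#' smallest-score position wins outright. With
#' `tiebreak = "gap_below"`, the cosine branch triggers when the *gap*
#' between the two smallest scores is below `threshold` instead.
#'
#' @inheritParams rank_positions
#' @param threshold Decision threshold on the normalized mean-variance
#'   scale, default 0.02.
#' @param tiebreak `"both_below"` (default) or `"gap_below"`.
#' @return An object of class `rp_classification`: list with `chosen`,
#'   `decided_by` (`"mean_variance"` or `"cosine_tiebreak"`),
#'   `mean_variances`, `cosines` (named, canonical order), `ranking`,
#'   `threshold`.
#' @export
classify <- function(sig, lib, threshold = 0.02,
                     tiebreak = c("both_below", "gap_below")) {
  tiebreak <- match.arg(tiebreak)
  ranking <- rank_positions(sig, lib)
  cosines <- vapply(lib$entries, function(e)
    cosine_similarity(sig$curve, e$curve), numeric(1))
  a_sorted <- ranking$a
  use_cosine <- if (tiebreak == "both_below") {
    a_sorted[1] < threshold && a_sorted[2] < threshold
  } else {
    (a_sorted[2] - a_sorted[1]) < threshold
  }
  if (use_cosine) {
    top2 <- ranking$position[1:2]
    chosen <- top2[which.max(cosines[top2])]
    decided_by <- "cosine_tiebreak"
  } else {
    chosen <- ranking$position[1]
    decided_by <- "mean_variance"
  }
  a_named <- stats::setNames(ranking$a, ranking$position)[radiopos_positions()]
  structure(list(chosen = chosen, decided_by = decided_by,
                 mean_variances = a_named,
                 cosines = cosines[radiopos_positions()],
                 ranking = ranking, threshold = threshold),
            class = "rp_classification")
}

#' @export
print.rp_classification <- function(x, ...) {
  cat(sprintf("<classification> %s (by %s)\n", x$chosen, x$decided_by))
  r <- x$ranking
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-7s a=%.5f cos=%.5f\n", r$position[i], r$a[i],
                x$cosines[[r$position[i]]]))
  invisible(x)
}
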