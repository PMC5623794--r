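# Independent brute-force oracles and fixture builders. These never call
# the code paths they check.

# Deterministic random integer image.
rand_img <- function(m, n, seed, maxval = 65535) {
  set.seed(seed)
  radiograph(matrix(sample.int(maxval + 1, m * n, replace = TRUE) - 1, m, n))
}

# Median filter oracle: per-pixel exhaustive neighbourhood sort with
# edge replication implemented as index clamping.
median_oracle <- function(px, w) {
  m <- nrow(px)
  n <- ncol(px)
  r <- (w - 1) / 2
  out <- matrix(0, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      ri <- pmin(pmax((i - r):(i + r), 1), m)
      ci <- pmin(pmax((j - r):(j + r), 1), n)
      out[i, j] <- sort(as.vector(px[ri, ci]))[(w * w + 1) / 2]
    }
  }
  out
}

# Direct evaluation of the normalized 2D DFT magnitude, zero frequency
# centred, via the explicit double sum.
dft_magnitude_oracle <- function(px) {
  m <- nrow(px)
  n <- ncol(px)
  us <- seq_len(m) - 1 - floor(m / 2)
  vs <- seq_len(n) - 1 - floor(n / 2)
  xs <- 0:(m - 1)
  ys <- 0:(n - 1)
  out <- matrix(0, m, n)
  for (a in seq_len(m)) {
    for (b in seq_len(n)) {
      ph <- outer(us[a] * xs / m, vs[b] * ys / n, "+")
      out[a, b] <- Mod(sum(px * exp(-2i * pi * ph))) / (m * n)
    }
  }
  out
}

# Per-offset sliding-window oracle for the matrix-product and Pearson
# correlation scores; Pearson comes from stats::cor (independent route).
score_maps_oracle <- function(ipx, tpx) {
  ir <- nrow(ipx); ic <- ncol(ipx)
  kr <- nrow(tpx) - ir + 1
  kc <- ncol(tpx) - ic + 1
  m_map <- matrix(0, kr, kc)
  r_map <- matrix(0, kr, kc)
  iv <- as.vector(ipx)
  for (k in seq_len(kr)) {
    for (l in seq_len(kc)) {
      win <- tpx[k:(k + ir - 1), l:(l + ic - 1)]
      m_map[k, l] <- sum(ipx * win) / sum(ipx^2)
      wv <- as.vector(win)
      r_map[k, l] <- if (stats::sd(wv) == 0 || stats::sd(iv) == 0) 0
                     else stats::cor(iv, wv)
    }
  }
  list(m_map = m_map, r_map = r_map)
}

# Radial-ring curve oracle: explicit cell enumeration, no vectorized
# binning shared with the implementation.
ring_curve_oracle <- function(mag, fraction, n_bins) {
  m <- nrow(mag); n <- ncol(mag)
  us <- (seq_len(m) - 1 - floor(m / 2)) / m
  vs <- (seq_len(n) - 1 - floor(n / 2)) / n
  r_max <- sqrt(max(abs(us))^2 + max(abs(vs))^2)
  thr <- fraction * r_max
  width <- thr / n_bins
  sums <- numeric(n_bins)
  counts <- numeric(n_bins)
  for (a in seq_len(m)) {
    for (b in seq_len(n)) {
      r <- sqrt(us[a]^2 + vs[b]^2)
      if (r > 0 && r <= thr) {
        bin <- min(n_bins, ceiling(r / width))
        sums[bin] <- sums[bin] + mag[a, b]
        counts[bin] <- counts[bin] + 1
      }
    }
  }
  pop <- which(counts > 0)
  vals <- sums[pop] / counts[pop]
  stats::approx(pop, vals, xout = seq_len(n_bins), rule = 2)$y
}

# Assemble a signature library directly from raw curves (bypassing image
# processing) for classifier tests.
lib_from_curves <- function(curves, fraction = 0.02) {
  n_bins <- length(curves[[1]])
  entries <- lapply(names(curves), function(pos) {
    structure(list(curve = curves[[pos]], n_bins = n_bins,
                   fraction = fraction, auc = sum(curves[[pos]]),
                   label = pos),
              class = "freq_signature")
  })
  names(entries) <- names(curves)
  structure(list(entries = entries, fraction = fraction,
                 n_bins = as.integer(n_bins),
                 norm = max(vapply(entries, function(e) max(e$curve),
                                   numeric(1)))),
            class = "signature_library")
}

sig_from_curve <- function(curve, fraction = 0.02, label = NULL) {
  structure(list(curve = curve, n_bins = length(curve), fraction = fraction,
                 auc = sum(curve), label = label),
            class = "freq_signature")
}

# Small phantom + dataset shared by several test files (lazy, cached).
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(seed = 7, template_shape = c(250, 100),
                          n_per_position = 2, n_library = 2)
      ph <- make_phantom(cfg)
      cache <<- list(cfg = cfg, phantom = ph,
                     fraction = fraction_for_scale(250))
    }
    cache
  }
})
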