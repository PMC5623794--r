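#' @keywords internal
"_PACKAGE"

# Canonical radiographic position names, in the fixed order used for
# tie-breaking throughout the package.
#' The six canonical radiographic positions
#'
#' Returns the fixed, ordered vector of position names the classifier and
#' the phantom atlas use. The order is also the deterministic tie-break
#' order wherever two positions score identically.
#'
#' @return Character vector of length six.
#' @export
radiopos_positions <- function() {
  c("head", "lungs", "lumbar", "pelvis", "joint", "limbs")
}

# Classed validation error so callers/tests can distinguish bad input from
# genuine failures.
rp_stop <- function(..., class = "radiopos_validation_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

rp_warn <- function(...) warning(paste0(...), call. = FALSE)

# Round half away from zero (inputs here are always >= 0, so this is
# round-half-up). base::round() rounds half to even, which would make
# intensity mapping depend on parity.
round_half_up <- function(x) floor(x + 0.5)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Centred signed frequency indices for an axis of length n, in the order
# produced by fftshift: -floor(n/2) .. ceiling(n/2) - 1.
freq_index <- function(n) seq_len(n) - 1L - floor(n / 2)

# Move the zero-frequency bin of a 2D DFT grid to the centre
# (row floor(M/2)+1, column floor(N/2)+1).
fftshift2 <- function(m) {
  d <- dim(m)
  i <- ((seq_len(d[1]) - 1 - floor(d[1] / 2)) %% d[1]) + 1
  j <- ((seq_len(d[2]) - 1 - floor(d[2] / 2)) %% d[2]) + 1
  m[i, j, drop = FALSE]
}

# Inverse of fftshift2.
ifftshift2 <- function(m) {
  d <- dim(m)
  i <- ((seq_len(d[1]) - 1 + floor(d[1] / 2)) %% d[1]) + 1
  j <- ((seq_len(d[2]) - 1 + floor(d[2] / 2)) %% d[2]) + 1
  m[i, j, drop = FALSE]
}

# Trapezoidal area under a curve sampled at unit spacing.
auc_trapz <- function(y) {
  n <- length(y)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2)
}

# Run expr, rewriting any error so the failing pipeline stage is named.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rp_stop("[", stage, "] ", conditionMessage(e),
            class = "radiopos_stage_error")
  })
}

# Evaluate expr with a locally-seeded RNG, restoring global RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
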