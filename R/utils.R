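# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, msg, class = "comigratr_error") {
  if (isTRUE(cond)) rlang::abort(msg, class = class)
  invisible(NULL)
}

#' @keywords internal
geom_mean <- function(x) {
  x <- x[is.finite(x) & x > 0]
  abort_if(length(x) == 0, "geometric mean of an empty or non-positive set")
  exp(mean(log(x)))
}

# z-score a numeric vector; a constant vector maps to all zeros so that
# shape-based clustering does not blow up on flat profiles.
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Gaussian kernel smoothing on a regular 1..n grid. `fwhm` is the kernel full
# width at half maximum in grid units; sigma = fwhm / 2.355. The kernel is
# renormalized at the edges so flat regions stay flat.
gaussian_smooth <- function(x, fwhm) {
  abort_if(fwhm <= 0, "smoothing width must be > 0")
  n <- length(x)
  sigma <- fwhm / 2.355
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- (i - half):(i + half)
    inside <- idx >= 1 & idx <= n
    keep <- inside
    keep[inside] <- !is.na(x[idx[inside]])
    w <- k[keep]
    out[i] <- sum(w * x[idx[keep]]) / sum(w)
  }
  out
}

# Deterministic child seed derived from a user seed and a stage label, kept
# below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
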