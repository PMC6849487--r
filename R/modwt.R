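#' Wavelet filter coefficients for the MODWT
#'
#' Returns the rescaled (MODWT) scaling and wavelet filters for the supported
#' Daubechies families.  MODWT filters are the usual orthonormal DWT filters
#' divided by sqrt(2) so that the transform is energy-preserving across
#' scales without decimation.
#'
#' @param family One of `"d4"` (Daubechies extremal-phase, 4 taps, the
#'   de-facto standard in wavelet functional-connectivity work) or `"haar"`.
#' @return A list with elements `scaling`, `wavelet` (numeric filters),
#'   `length` and `family`.
#' @examples
#' f <- wavelet_filters("d4")
#' sum(f$scaling^2) + sum(f$wavelet^2)  # = 1 for MODWT filters
#' @export
wavelet_filters <- function(family = c("d4", "haar")) {
  family <- match.arg(family)
  g <- switch(family,
    haar = c(1, 1) / sqrt(2),
    d4   = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
  )
  L <- length(g)
  # quadrature mirror: h_l = (-1)^l g_{L-1-l}
  h <- rev(g) * (-1)^(seq_len(L) - 1)
  list(scaling = g / sqrt(2), wavelet = h / sqrt(2), length = L, family = family)
}

# one circular MODWT filtering step with filter upsampled by `step`
.modwt_filter <- function(v, filt, step) {
  n <- length(v)
  out <- numeric(n)
  idx0 <- seq_len(n) - 1L
  for (l in seq_along(filt)) {
    shift <- (l - 1L) * step
    out <- out + filt[l] * v[((idx0 - shift) %% n) + 1L]
  }
  out
}

#' Maximal overlap discrete wavelet transform of a single series
#'
#' Pyramid-algorithm MODWT.  Non-decimated: every level returns a coefficient
#' series of the same length as the input.
#'
#' @param x Numeric vector.
#' @param levels Decomposition depth J.
#' @param family Wavelet family, see [wavelet_filters()].
#' @param boundary `"periodic"` (circular extension) or `"reflection"`
#'   (series reflected to length 2T, transformed circularly, first T
#'   coefficients kept).
#' @return List with `W` (list of detail coefficient vectors, levels 1..J),
#'   `V` (level-J smooth), `levels`, `family`, `boundary`.
#' @export
modwt <- function(x, levels = 2L, family = "d4", boundary = c("periodic", "reflection")) {
  boundary <- match.arg(boundary)
  stopifnot(is.numeric(x), levels >= 1L)
  if (anyNA(x)) stop("modwt: input contains missing values")
  f <- wavelet_filters(family)
  n_min <- max(16L, (2L^levels - 1L) * (f$length - 1L) + 1L)
  if (length(x) < n_min) {
    stop(sprintf(
      "modwt: series length %d too short for a level-%d '%s' decomposition (minimum %d)",
      length(x), levels, f$family, n_min
    ))
  }
  n_keep <- length(x)
  if (boundary == "reflection") x <- c(x, rev(x))
  v <- x
  W <- vector("list", levels)
  for (j in seq_len(levels)) {
    step <- 2L^(j - 1L)
    W[[j]] <- .modwt_filter(v, f$wavelet, step)
    v <- .modwt_filter(v, f$scaling, step)
  }
  if (boundary == "reflection") {
    W <- lapply(W, function(w) w[seq_len(n_keep)])
    v <- v[seq_len(n_keep)]
  }
  list(W = W, V = v, levels = levels, family = f$family, boundary = boundary)
}

#' Scale-2 MODWT detail coefficients for every node of a time-series matrix
#'
#' The scale-2 detail band of a series sampled every `Delta` seconds covers
#' nominally `[fs/8, fs/4]` Hz with `fs = 1/Delta`; the band actually used is
#' reported in the `"band_hz"` attribute of the result.
#'
#' @param ts A [roi_timeseries()] object (or plain T x N matrix).
#' @param wavelet_family,boundary Passed to [modwt()].
#' @return T x N matrix of scale-2 detail coefficients, one column per node,
#'   with attributes `band_hz` (length-2 numeric) and `subject_id`.
#' @export
modwt_scale2 <- function(ts, wavelet_family = "d4", boundary = "periodic") {
  if (inherits(ts, "roi_timeseries")) {
    x <- ts$data
    delta <- ts$sampling_interval
    sid <- ts$subject_id
  } else {
    x <- as.matrix(ts)
    delta <- NA_real_
    sid <- NA_character_
  }
  out <- apply(x, 2L, function(col) {
    modwt(col, levels = 2L, family = wavelet_family, boundary = boundary)$W[[2L]]
  })
  dimnames(out) <- dimnames(x)
  if (!is.na(delta)) {
    fs <- 1 / delta
    attr(out, "band_hz") <- c(fs / 8, fs / 4)
  }
  attr(out, "subject_id") <- sid
  out
}
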