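#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass filter forward and backward (zero phase),
#' so the effective magnitude response is the squared Butterworth response
#' and no phase lag is introduced. Edge transients are suppressed by odd
#' (point-reflected) extension of the signal at both ends plus steady-state
#' initialization of the filter state, as is conventional for two-pass
#' filtering of short gait records.
#'
#' @param series Numeric vector, or T x d matrix filtered column-wise.
#' @param fs Sampling rate in Hz. Must exceed twice the cutoff.
#' @param cutoff Low-pass cutoff frequency in Hz (default 10).
#' @param order Filter order (default 4); the two-pass application doubles
#'   the effective roll-off.
#' @param pad_len Odd-extension length at each end (default `3 * order`).
#' @return Filtered series with the same dimensions as the input.
#' @export
lowpass_zero_phase <- function(series, fs, cutoff = 10, order = 4,
                               pad_len = 3L * order) {
  if (is.matrix(series)) {
    return(apply(series, 2L, lowpass_zero_phase, fs = fs, cutoff = cutoff,
                 order = order, pad_len = pad_len))
  }
  x <- as.numeric(series)
  n <- length(x)
  if (!all(is.finite(x))) stop("non-finite values in series", call. = FALSE)
  if (fs <= 2 * cutoff) {
    stop("sampling rate must exceed twice the cutoff frequency", call. = FALSE)
  }
  if (n <= 3L * order) {
    stop("signal too short for order-", order, " zero-phase filtering (length ",
         n, ")", call. = FALSE)
  }
  pad_len <- min(pad_len, n - 1L)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  b <- bf$b / bf$a[1L]
  a <- bf$a / bf$a[1L]
  zi <- lfilter_zi(b, a)

  # odd extension: point reflection about the first/last sample
  pre <- 2 * x[1L] - x[(pad_len + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad_len)]
  xe <- c(pre, x, post)

  y <- .iir_filter(b, a, xe, zi * xe[1L])
  y <- rev(.iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(pad_len + 1L):(pad_len + n)]
}

# Steady-state initial filter state (direct-form II transposed) for a unit
# step input, so filtering a constant returns that constant from sample one.
lfilter_zi <- function(b, a) {
  nord <- max(length(a), length(b)) - 1L
  bb <- c(b, rep(0, nord + 1L - length(b)))
  aa <- c(a, rep(0, nord + 1L - length(a)))
  # companion matrix of the denominator polynomial (transposed form)
  A <- rbind(-aa[-1L], cbind(diag(1, nord - 1L), 0))
  B <- bb[-1L] - aa[-1L] * bb[1L]
  as.numeric(solve(diag(nord) - t(A), B))
}

#' Euclidean magnitude of a 3D trajectory
#'
#' Collapses a per-axis position series into the scalar distance from the
#' origin, `m(t) = sqrt(x^2 + y^2 + z^2)`, removing orientation effects.
#'
#' @param series T x 3 numeric matrix of positions (m).
#' @return Numeric vector of length T, nonnegative.
#' @export
magnitude <- function(series) {
  series <- as.matrix(series)
  if (!all(is.finite(series))) stop("non-finite values in series", call. = FALSE)
  sqrt(rowSums(series^2))
}

#' Speed of a 3D trajectory
#'
#' Differentiates each axis (central differences at interior samples,
#' one-sided differences at the ends) and takes the Euclidean magnitude of
#' the velocity vector, yielding speed in m/s. Differentiating per axis
#' before taking the magnitude makes the result invariant to rigid rotations
#' of the coordinate frame and to constant positional offsets.
#'
#' @param series T x 3 numeric matrix of (filtered) positions (m).
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of length T (m/s).
#' @export
speed <- function(series, fs) {
  series <- as.matrix(series)
  n <- nrow(series)
  if (n < 3L) stop("need at least 3 samples to differentiate", call. = FALSE)
  d <- apply(series, 2L, function(x) {
    c(x[2L] - x[1L],
      (x[3L:n] - x[1L:(n - 2L)]) / 2,
      x[n] - x[n - 1L]) * fs
  })
  sqrt(rowSums(d^2))
}

#' Interquartile range
#'
#' Dispersion descriptor `IQR = Q3 - Q1`, with quartiles computed by the
#' linear-interpolation convention between order statistics
#' (`stats::quantile` type 7). Robust to outliers outside the central half
#' of the distribution.
#'
#' @param samples Numeric vector with at least 4 finite values.
#' @return Nonnegative scalar.
#' @export
signal_iqr <- function(samples) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 4L) stop("need at least 4 samples for IQR", call. = FALSE)
  q <- quantile(samples, c(0.25, 0.75), type = 7, names = FALSE)
  q[2L] - q[1L]
}

#' Per-segment kinematic features of one recording
#'
#' Runs the preprocessing chain filter -> magnitude -> (position IQR, speed
#' IQR) for every segment of a recording. Mean and SD descriptors of the
#' magnitude and speed signals are computed alongside for the univariate
#' statistics stage; only the IQRs enter the machine-learning feature table
#' by default.
#'
#' @param rec A `SegmentRecording` (see [read_cohort()] / [generate_cohort()]).
#' @param cutoff,order Low-pass filter settings passed to
#'   [lowpass_zero_phase()].
#' @param speed_of_magnitude If `TRUE`, differentiate the magnitude signal
#'   instead of computing the per-axis speed (non-default variant).
#' @return A list with `magnitudes` (per-segment list of `m(t)`), `speeds`,
#'   `fs`, and `features`: a data.frame with one row per segment and columns
#'   `pos_iqr`, `vel_iqr`, `pos_mean`, `pos_sd`, `vel_mean`, `vel_sd`.
#' @export
kinematic_features <- function(rec, cutoff = 10, order = 4,
                               speed_of_magnitude = FALSE) {
  segs <- names(rec$series)
  mags <- vector("list", length(segs))
  spds <- vector("list", length(segs))
  names(mags) <- names(spds) <- segs
  for (s in segs) {
    filt <- lowpass_zero_phase(rec$series[[s]], fs = rec$fs, cutoff = cutoff,
                               order = order)
    m <- magnitude(filt)
    v <- if (speed_of_magnitude) {
      abs(speed(cbind(m, 0, 0), rec$fs))
    } else {
      speed(filt, rec$fs)
    }
    mags[[s]] <- m
    spds[[s]] <- v
  }
  feat <- data.frame(
    segment = segs,
    pos_iqr = vapply(mags, signal_iqr, 0),
    vel_iqr = vapply(spds, signal_iqr, 0),
    pos_mean = vapply(mags, mean, 0),
    pos_sd = vapply(mags, sd, 0),
    vel_mean = vapply(spds, mean, 0),
    vel_sd = vapply(spds, sd, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(magnitudes = mags, speeds = spds, fs = rec$fs, features = feat)
}
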