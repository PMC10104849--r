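#' Canonical frequency-band scheme
#'
#' Construct an ordered set of named frequency bands. The default follows the
#' canonical resting-state definitions used throughout the package:
#' delta 2-4 Hz, theta 5-7 Hz, alpha 8-12 Hz, beta 15-29 Hz. A variant with
#' theta starting at 4 Hz is in circulation in the literature; pass
#' `theta_lo = 4` to use it.
#'
#' @param names character vector of unique band names, ordered by lower edge.
#' @param f_lo,f_hi numeric vectors of band edges in Hz, `f_lo < f_hi`.
#' @return An object of class `band_scheme`: a data.frame with columns
#'   `name`, `f_lo`, `f_hi`.
#' @examples
#' canonical_bands()
#' canonical_bands(theta_lo = 4)
#' @export
band_scheme <- function(names, f_lo, f_hi) {
  stopifnot(length(names) == length(f_lo), length(f_lo) == length(f_hi))
  if (anyDuplicated(names)) stop("band names must be unique")
  if (any(!(f_lo < f_hi))) stop("each band needs f_lo < f_hi")
  if (is.unsorted(f_lo)) stop("bands must be ordered by f_lo")
  structure(
    data.frame(name = as.character(names), f_lo = as.numeric(f_lo),
               f_hi = as.numeric(f_hi), stringsAsFactors = FALSE),
    class = c("band_scheme", "data.frame")
  )
}

#' @rdname band_scheme
#' @param theta_lo lower edge of the theta band (5 Hz default; 4 Hz variant).
#' @export
canonical_bands <- function(theta_lo = 5) {
  band_scheme(c("delta", "theta", "alpha", "beta"),
              c(2, theta_lo, 8, 15),
              c(4, 7, 12, 29))
}

#' Epoched multi-orientation source time series
#'
#' Container for source-localised signal epochs. `data` is a 4-D array with
#' dimensions vertex x orientation x time x epoch; single-orientation data may
#' be supplied as vertex x time x epoch and is promoted.
#'
#' @param data numeric array, vertex x orientation x time x epoch (or
#'   vertex x time x epoch for one orientation).
#' @param fs sampling rate in Hz.
#' @return An `epoched_series` object (list with `data`, `fs`, `epoch_len`).
#' @export
epoched_series <- function(data, fs) {
  if (length(dim(data)) == 3L) {
    d <- dim(data)
    dim(data) <- c(d[1], 1L, d[2], d[3])
  }
  if (length(dim(data)) != 4L) stop("data must be a 3-D or 4-D array")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  if (dim(data)[4] < 1L) stop("at least one epoch required")
  if (!all(is.finite(data))) stop("non-finite values in series data")
  structure(list(data = data, fs = fs, epoch_len = dim(data)[3] / fs),
            class = "epoched_series")
}

#' Dense power spectrum on a shared frequency grid
#'
#' @param freqs strictly ascending frequency grid (Hz).
#' @param power vertex x frequency matrix of non-negative power.
#' @return A `dense_spectrum` object.
#' @export
dense_spectrum <- function(freqs, power) {
  power <- as.matrix(power)
  if (is.unsorted(freqs, strictly = TRUE)) stop("freqs must be strictly ascending")
  if (ncol(power) != length(freqs)) stop("power must have one column per frequency")
  if (any(power < 0)) stop("power must be non-negative")
  structure(list(freqs = as.numeric(freqs), power = power),
            class = "dense_spectrum")
}

#' Band-averaged spectral map for one subject
#'
#' @param subject_id subject identifier.
#' @param power vertex x band matrix of non-negative power.
#' @param scheme the `band_scheme` the columns correspond to.
#' @return A `band_spectral_map` object.
#' @export
band_spectral_map <- function(subject_id, power, scheme) {
  power <- as.matrix(power)
  if (ncol(power) != nrow(scheme)) stop("band count must match scheme length")
  if (any(!is.finite(power)) || any(power < 0)) stop("power must be finite and non-negative")
  colnames(power) <- scheme$name
  structure(list(subject_id = subject_id, power = power, band_scheme = scheme),
            class = "band_spectral_map")
}

# Hann taper of length n (periodic form, standard for Welch averaging)
.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)

# One-sided Welch PSD of a single time series, density scaling.
.welch_1d <- function(x, fs, nper, nover) {
  w <- .hann(nper)
  step <- nper - nover
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  scale <- fs * sum(w^2)
  nfreq <- floor(nper / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)] * w
    sp <- abs(fft(seg))[seq_len(nfreq)]^2 / scale
    # one-sided: double everything except DC (and Nyquist when nper is even)
    sp[-1L] <- sp[-1L] * 2
    if (nper %% 2L == 0L) sp[nfreq] <- sp[nfreq] / 2
    acc <- acc + sp
  }
  acc / length(starts)
}

#' Welch power spectral density of epoched series
#'
#' Averages modified periodograms (Hann taper, one-sided density scaling)
#' across overlapping windows within each epoch and across epochs. The
#' frequency resolution is `1/window_len` Hz: 3-s windows give a 1/3-Hz grid.
#'
#' @param series an [epoched_series()].
#' @param window_len window length in seconds; must not exceed the epoch
#'   length.
#' @param overlap_frac fractional overlap between successive windows, in
#'   `[0, 1)`. Default 0.5.
#' @return A list of [dense_spectrum()] objects, one per orientation, each
#'   with a vertex x frequency power matrix.
#' @examples
#' x <- array(rnorm(1 * 1 * 1200 * 4), c(1, 1, 1200, 4))
#' ser <- epoched_series(x, fs = 200)
#' sp <- welch_psd(ser, window_len = 3)
#' diff(sp[[1]]$freqs)[1]  # 1/3 Hz
#' @export
welch_psd <- function(series, window_len, overlap_frac = 0.5) {
  stopifnot(inherits(series, "epoched_series"))
  if (overlap_frac < 0 || overlap_frac >= 1) stop("overlap_frac must be in [0, 1)")
  if (window_len > series$epoch_len + 1e-12)
    stop("window_len exceeds epoch length")
  d <- dim(series$data)
  if (d[4] < 1L) stop("no epochs")
  nper <- round(window_len * series$fs)
  if (nper < 2L) stop("window too short for sampling rate")
  nover <- floor(overlap_frac * nper)
  nfreq <- floor(nper / 2) + 1L
  freqs <- (seq_len(nfreq) - 1L) / window_len
  out <- vector("list", d[2])
  for (o in seq_len(d[2])) {
    pw <- matrix(0, d[1], nfreq)
    for (v in seq_len(d[1])) {
      acc <- numeric(nfreq)
      for (e in seq_len(d[4]))
        acc <- acc + .welch_1d(series$data[v, o, , e], series$fs, nper, nover)
      pw[v, ] <- acc / d[4]
    }
    out[[o]] <- dense_spectrum(freqs, pw)
  }
  out
}

#' Collapse per-orientation power by the RMS norm
#'
#' Reduces a vertex x orientation x frequency power array to a
#' vertex x frequency map by the root-mean-square across orientations:
#' `sqrt(mean(power^2))` at each vertex/frequency.
#'
#' @param power_per_orientation numeric array, vertex x orientation x
#'   frequency (a list of `dense_spectrum` from [welch_psd()] is also
#'   accepted).
#' @return vertex x frequency matrix (or a `dense_spectrum` when the input
#'   was a spectrum list).
#' @export
orientation_rms <- function(power_per_orientation) {
  if (is.list(power_per_orientation) &&
      all(vapply(power_per_orientation, inherits, TRUE, "dense_spectrum"))) {
    sp <- power_per_orientation
    arr <- array(0, c(nrow(sp[[1]]$power), length(sp), length(sp[[1]]$freqs)))
    for (o in seq_along(sp)) arr[, o, ] <- sp[[o]]$power
    return(dense_spectrum(sp[[1]]$freqs, orientation_rms(arr)))
  }
  p <- power_per_orientation
  if (length(dim(p)) != 3L) stop("expect a vertex x orientation x frequency array")
  if (dim(p)[2] < 1L) stop("at least one orientation required")
  if (any(p < 0)) stop("power must be non-negative")
  sqrt(apply(p^2, c(1, 3), mean))
}

#' Average a dense spectrum over frequency bands
#'
#' Per band, the arithmetic mean of power over frequency bins with
#' `f_lo <= f <= f_hi` (both edges inclusive).
#'
#' @param spec a [dense_spectrum()].
#' @param scheme a [band_scheme()]; every band must contain at least one bin.
#' @param subject_id identifier stored in the result.
#' @return A [band_spectral_map()].
#' @export
band_average <- function(spec, scheme, subject_id = NA_character_) {
  stopifnot(inherits(spec, "dense_spectrum"), inherits(scheme, "band_scheme"))
  out <- matrix(NA_real_, nrow(spec$power), nrow(scheme))
  for (b in seq_len(nrow(scheme))) {
    sel <- spec$freqs >= scheme$f_lo[b] & spec$freqs <= scheme$f_hi[b]
    if (!any(sel)) stop("band '", scheme$name[b], "' contains no frequency bins")
    out[, b] <- rowMeans(spec$power[, sel, drop = FALSE])
  }
  band_spectral_map(subject_id, out, scheme)
}
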