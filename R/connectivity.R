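#' Band-pass filter specification
#'
#' @param name band name.
#' @param f_lo,f_hi pass-band edges in Hz, `0 < f_lo < f_hi`.
#' @param transition width of the raised-cosine transition on each side of
#'   the pass band (Hz).
#' @return A `band_filter_spec` object.
#' @export
band_filter_spec <- function(name, f_lo, f_hi, transition = 0.5) {
  if (!(0 < f_lo && f_lo < f_hi)) stop("need 0 < f_lo < f_hi")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi,
                 transition = transition),
            class = "band_filter_spec")
}

# Zero-phase band-pass of one epoch via the frequency domain: unit gain in
# [f_lo, f_hi], raised-cosine roll-off over `transition` Hz on each side.
# Zero phase by construction (real gain applied symmetrically).
.fft_bandpass <- function(x, fs, f_lo, f_hi, transition) {
  n <- length(x)
  f <- abs((seq_len(n) - 1L)) / n * fs
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  g <- numeric(n)
  g[f >= f_lo & f <= f_hi] <- 1
  lo <- f >= f_lo - transition & f < f_lo
  g[lo] <- 0.5 * (1 + cos(pi * (f_lo - f[lo]) / transition))
  hi <- f > f_hi & f <= f_hi + transition
  g[hi] <- 0.5 * (1 + cos(pi * (f[hi] - f_hi) / transition))
  Re(fft(fft(x) * g, inverse = TRUE)) / n
}

#' Zero-phase band-pass filtering of epoched series
#'
#' Filters every vertex/orientation/epoch independently with a zero-phase
#' frequency-domain band-pass (unit pass-band gain, raised-cosine
#' transitions). Length is preserved; edge transients should be discarded by
#' downstream envelope analyses.
#'
#' @param series an [epoched_series()].
#' @param spec a [band_filter_spec()]; the band must lie below Nyquist.
#' @return A filtered [epoched_series()].
#' @export
band_filter <- function(series, spec) {
  stopifnot(inherits(series, "epoched_series"),
            inherits(spec, "band_filter_spec"))
  if (spec$f_hi >= series$fs / 2) stop("band reaches or exceeds Nyquist")
  d <- dim(series$data)
  out <- series$data
  for (v in seq_len(d[1])) for (o in seq_len(d[2])) for (e in seq_len(d[4]))
    out[v, o, , e] <- .fft_bandpass(series$data[v, o, , e], series$fs,
                                    spec$f_lo, spec$f_hi, spec$transition)
  epoched_series(out, series$fs)
}

# Analytic-signal magnitude of one real epoch.
.hilbert_env <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}

#' Amplitude envelope via the Hilbert transform
#'
#' Magnitude of the analytic signal, computed per epoch. Input should be
#' band-limited (see [band_filter()]).
#'
#' @param band_series an [epoched_series()] of band-limited signals.
#' @return An [epoched_series()] of non-negative envelopes.
#' @export
hilbert_envelope <- function(band_series) {
  stopifnot(inherits(band_series, "epoched_series"))
  d <- dim(band_series$data)
  out <- band_series$data
  for (v in seq_len(d[1])) for (o in seq_len(d[2])) for (e in seq_len(d[4]))
    out[v, o, , e] <- .hilbert_env(band_series$data[v, o, , e])
  epoched_series(out, band_series$fs)
}

# Orthogonalized envelope correlation for one direction within one epoch:
# regress `y` out of nothing -- remove the least-squares projection of `y`
# onto `x` from `y`, then correlate envelopes of x and the residual.
.aec_dir <- function(x, y, keep) {
  beta <- sum(x * y) / sum(x * x)
  resid <- y - beta * x
  if (sd(resid[keep]) == 0) return(NA_real_)
  ex <- .hilbert_env(x)[keep]
  er <- .hilbert_env(resid)[keep]
  if (sd(ex) == 0 || sd(er) == 0) return(NA_real_)
  cor(ex, er)
}

#' Orthogonalized amplitude-envelope correlation between two signals
#'
#' Per epoch both signals are band-pass filtered, each is orthogonalized with
#' respect to the other by least-squares removal of the band-limited partner
#' signal (both directions), Hilbert envelopes of the remaining signal pairs
#' are Pearson-correlated, the two directions are averaged, and the result is
#' averaged across epochs. Orthogonalization removes zero-lag linear leakage,
#' so identical signals yield 0 by construction.
#'
#' @param seed_ts,target_ts [epoched_series()] with one vertex and one
#'   orientation each (or plain time x epoch matrices) sharing fs and epoch
#'   structure.
#' @param spec a [band_filter_spec()].
#' @param fs sampling rate, required when matrices are supplied.
#' @param edge_trim seconds discarded at each epoch edge before the envelope
#'   correlation (filter and Hilbert transients). Default 0.25 s.
#' @param log_envelope correlate log envelopes instead of raw envelopes.
#' @return list with `aec` (mean across directions and epochs; 0 with
#'   `degenerate = TRUE` when orthogonalization leaves no variance) and
#'   `n_epochs`.
#' @export
aec_orthogonalized <- function(seed_ts, target_ts, spec, fs = NULL,
                               edge_trim = 0.25, log_envelope = FALSE) {
  as_mat <- function(z) {
    if (inherits(z, "epoched_series")) {
      d <- dim(z$data)
      if (d[1] != 1L || d[2] != 1L)
        stop("supply a single vertex/orientation series")
      matrix(z$data[1, 1, , ], d[3], d[4])
    } else as.matrix(z)
  }
  if (is.null(fs)) {
    if (!inherits(seed_ts, "epoched_series")) stop("fs required for matrix input")
    fs <- seed_ts$fs
  }
  X <- as_mat(seed_ts); Y <- as_mat(target_ts)
  if (!all(dim(X) == dim(Y))) stop("epoch structure differs between signals")
  ntrim <- round(edge_trim * fs)
  keep <- seq_len(nrow(X))
  if (2L * ntrim >= nrow(X) - 4L) stop("edge_trim leaves too few samples")
  if (ntrim > 0L) keep <- keep[(ntrim + 1L):(length(keep) - ntrim)]
  vals <- numeric(0)
  degenerate <- FALSE
  for (e in seq_len(ncol(X))) {
    xb <- .fft_bandpass(X[, e], fs, spec$f_lo, spec$f_hi, spec$transition)
    yb <- .fft_bandpass(Y[, e], fs, spec$f_lo, spec$f_hi, spec$transition)
    if (log_envelope) {
      dirfun <- function(a, b) {
        beta <- sum(a * b) / sum(a * a)
        r <- b - beta * a
        if (sd(r[keep]) == 0) return(NA_real_)
        ea <- log(.hilbert_env(a)[keep] + .Machine$double.eps)
        er <- log(.hilbert_env(r)[keep] + .Machine$double.eps)
        if (sd(ea) == 0 || sd(er) == 0) return(NA_real_) else cor(ea, er)
      }
      d1 <- dirfun(xb, yb); d2 <- dirfun(yb, xb)
    } else {
      d1 <- .aec_dir(xb, yb, keep); d2 <- .aec_dir(yb, xb, keep)
    }
    if (is.na(d1) || is.na(d2)) { degenerate <- TRUE; next }
    vals <- c(vals, (d1 + d2) / 2)
  }
  if (length(vals) == 0L)
    return(list(aec = 0, n_epochs = 0L, degenerate = TRUE))
  list(aec = mean(vals), n_epochs = length(vals), degenerate = degenerate)
}

#' Seeded whole-map amplitude-envelope connectivity
#'
#' Computes [aec_orthogonalized()] between a seed vertex and every other
#' vertex, for each band of a scheme, yielding one connectivity map per band.
#' The value at the seed itself is defined as 0 (self-orthogonalization is
#' degenerate).
#'
#' @param series an [epoched_series()] with one orientation (extract the
#'   first principal component across orientations upstream).
#' @param seed 1-based seed vertex index.
#' @param scheme a [band_scheme()].
#' @param edge_trim,log_envelope passed to [aec_orthogonalized()].
#' @return list of `seed_connectivity_map` objects (fields `seed`, `band`,
#'   `aec` vertex vector, `n_epochs`), one per band.
#' @export
seed_connectivity_map <- function(series, seed, scheme, edge_trim = 0.25,
                                  log_envelope = FALSE) {
  stopifnot(inherits(series, "epoched_series"))
  d <- dim(series$data)
  if (d[2] != 1L) stop("collapse orientations before connectivity analysis")
  if (seed < 1L || seed > d[1]) stop("seed vertex out of range")
  seed_m <- matrix(series$data[seed, 1, , ], d[3], d[4])
  lapply(seq_len(nrow(scheme)), function(b) {
    spec <- band_filter_spec(scheme$name[b], scheme$f_lo[b], scheme$f_hi[b])
    aec <- numeric(d[1])
    nep <- 0L
    for (v in seq_len(d[1])) {
      if (v == seed) next
      res <- aec_orthogonalized(seed_m,
                                matrix(series$data[v, 1, , ], d[3], d[4]),
                                spec, fs = series$fs, edge_trim = edge_trim,
                                log_envelope = log_envelope)
      aec[v] <- res$aec
      nep <- max(nep, res$n_epochs)
    }
    structure(list(seed = seed, band = scheme$name[b], aec = aec,
                   n_epochs = nep),
              class = "seed_connectivity_map")
  })
}
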