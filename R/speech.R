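#' Glottal pulse table
#'
#' Per voiced glottal cycle: period and peak amplitude, grouped into voiced
#' segments. Difference-based features (jitter, shimmer) are computed within
#' segments only, never across segment boundaries.
#'
#' @param period cycle periods in seconds (> 0).
#' @param amplitude peak amplitudes (>= 0, arbitrary units).
#' @param segment voiced-segment id per cycle (default: one segment).
#' @return A `pulse_table` data.frame.
#' @export
pulse_table <- function(period, amplitude, segment = 1L) {
  if (any(period <= 0)) stop("periods must be > 0")
  if (any(amplitude < 0)) stop("amplitudes must be >= 0")
  structure(data.frame(period = period, amplitude = amplitude,
                       segment = rep_len(segment, length(period))),
            class = c("pulse_table", "data.frame"))
}

.local_fluctuation <- function(values, segment) {
  if (length(values) < 2L) stop("need at least 2 cycles")
  diffs <- unlist(lapply(split(values, segment), function(v)
    if (length(v) >= 2L) abs(diff(v)) else numeric(0)), use.names = FALSE)
  if (length(diffs) == 0L) stop("no segment has 2 consecutive cycles")
  mean(diffs) / mean(values)
}

#' Local jitter
#'
#' Mean absolute difference between consecutive glottal periods within
#' voiced segments, divided by the mean period. Scale-invariant; elevated in
#' dysarthric voice.
#'
#' @param pulses a [pulse_table()].
#' @return jitter as a fraction.
#' @examples
#' jitter_local(pulse_table(rep(c(0.009, 0.011), 10), rep(1, 20)))  # 0.20
#' @export
jitter_local <- function(pulses) .local_fluctuation(pulses$period, pulses$segment)

#' Local shimmer
#'
#' As [jitter_local()], on cycle peak amplitudes.
#'
#' @param pulses a [pulse_table()].
#' @return shimmer as a fraction.
#' @export
shimmer_local <- function(pulses) .local_fluctuation(pulses$amplitude, pulses$segment)

#' Harmonics-to-noise ratio from autocorrelation peaks
#'
#' `10 log10(r / (1 - r))` for each voiced frame's normalised
#' autocorrelation peak `r` (the fraction of frame energy that is periodic),
#' averaged over frames. `r = 0.5` (equal harmonic and noise energy) gives
#' 0 dB.
#'
#' @param r_max autocorrelation peak(s) in (0, 1).
#' @return mean HNR in dB.
#' @export
hnr_db <- function(r_max) {
  if (any(r_max <= 0 | r_max >= 1)) stop("r_max must lie strictly in (0, 1)")
  mean(10 * log10(r_max / (1 - r_max)))
}

#' Standard deviation of pitch over voiced cycles
#'
#' Sample SD of the instantaneous fundamental frequency `1/period` across
#' all voiced cycles.
#'
#' @param pulses a [pulse_table()].
#' @return SD in Hz.
#' @export
f0_std <- function(pulses) {
  if (nrow(pulses) < 2L) stop("need at least 2 cycles")
  sd(1 / pulses$period)
}

#' Vowel-space area proxy from formant dispersion
#'
#' Product of the inter-quartile ranges of F1 and F2 over voiced frames
#' (linear-interpolation quantiles), a simplified proxy for the acoustic
#' vowel space.
#'
#' @param f1,f2 formant tracks in Hz over voiced frames (`0 < F1 < F2`).
#' @return area in Hz^2.
#' @export
vowel_area <- function(f1, f2) {
  if (length(f1) < 4L || length(f2) < 4L) stop("need at least 4 voiced frames")
  if (any(f1 <= 0) || any(f2 <= f1)) stop("need 0 < F1 < F2 per frame")
  iqr <- function(x) diff(quantile(x, c(0.25, 0.75), names = FALSE, type = 7))
  iqr(f1) * iqr(f2)
}

#' Voice-quality composite: first principal component of HNR/jitter/shimmer
#'
#' Standardises the three features (correlation-matrix PCA, since units are
#' incommensurate) and returns the first principal-component score per
#' recording, with the sign oriented so that jitter loads positively —
#' higher scores mean worse voice quality.
#'
#' @param features data.frame/matrix with columns `hnr`, `jitter`,
#'   `shimmer`, one row per recording (>= 3 rows).
#' @return list with `scores`, `loadings`, `var_explained`.
#' @export
voice_quality_pc1 <- function(features) {
  X <- as.matrix(features[, c("hnr", "jitter", "shimmer")])
  if (nrow(X) < 3L) stop("need at least 3 recordings")
  if (any(apply(X, 2, sd) == 0)) stop("zero-variance feature")
  Z <- scale(X)
  eg <- eigen(cor(X), symmetric = TRUE)
  w <- eg$vectors[, 1]
  if (w[2] < 0) w <- -w       # jitter loads positively
  list(scores = as.numeric(Z %*% w),
       loadings = setNames(w, c("hnr", "jitter", "shimmer")),
       var_explained = eg$values[1] / sum(eg$values))
}

#' Aggregate multi-rater speech-impairment ratings
#'
#' Two-stage aggregation of a patient x sentence x rater x feature rating
#' table: ratings are first averaged across sentences for each
#' feature/rater/patient, then across raters. The intermediate
#' patient x rater matrix per feature is returned for reliability analysis
#' with [icc_ck()].
#'
#' @param ratings long data.frame with columns `patient`, `sentence`,
#'   `rater`, `feature`, `score`. Every rater must rate every sentence of
#'   every patient for every feature.
#' @return list with `scores` (patient x feature data.frame of rater means)
#'   and `rater_matrices` (named list of patient x rater matrices, one per
#'   feature).
#' @export
aggregate_ratings <- function(ratings) {
  need <- c("patient", "sentence", "rater", "feature", "score")
  if (!all(need %in% names(ratings)))
    stop("ratings must have columns ", paste(need, collapse = ", "))
  counts <- table(ratings$patient, ratings$rater, ratings$feature)
  n_sent <- length(unique(ratings$sentence))
  if (any(counts != n_sent)) {
    gaps <- which(counts != n_sent, arr.ind = TRUE)
    stop("incomplete sentence sets, e.g. patient ",
         dimnames(counts)[[1]][gaps[1, 1]], " / rater ",
         dimnames(counts)[[2]][gaps[1, 2]], " / ",
         dimnames(counts)[[3]][gaps[1, 3]])
  }
  feats <- sort(unique(ratings$feature))
  pats <- sort(unique(ratings$patient))
  raters <- sort(unique(ratings$rater))
  rater_matrices <- lapply(feats, function(f) {
    sub <- ratings[ratings$feature == f, ]
    m <- tapply(sub$score, list(factor(sub$patient, pats),
                                factor(sub$rater, raters)), mean)
    matrix(m, length(pats), length(raters),
           dimnames = list(pats, raters))
  })
  names(rater_matrices) <- feats
  scores <- data.frame(patient = pats, stringsAsFactors = FALSE)
  for (f in feats) scores[[f]] <- rowMeans(rater_matrices[[f]])
  list(scores = scores, rater_matrices = rater_matrices)
}
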