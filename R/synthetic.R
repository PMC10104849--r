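#' Specification of a synthetic patient/control cohort
#'
#' Describes the generative model used by [gen_cohort()]: control spectra are
#' aperiodic 1/f^chi backgrounds plus Gaussian band peaks with between-subject
#' amplitude jitter and multiplicative vertex-level measurement noise;
#' patients are identical except within a target vertex set, where each
#' band's power is scaled by `1 + severity * effect_b`. The default effect
#' pattern expresses a "spectral acceleration": power shifts out of the
#' slower bands (negative delta/theta effects) into the faster ones
#' (positive alpha/beta effects), all driven by one severity scalar per
#' patient. A synthetic impairment rating is generated as
#' `slope * severity + age_slope * age + noise`.
#'
#' Default cohort sizes (60/60) echo a realistic clinical MEG study scale;
#' smaller cohorts remain valid for fast tests.
#'
#' @param n_controls,n_patients cohort sizes.
#' @param n_vertices vertices in the (pre-aligned) map space.
#' @param scheme a [band_scheme()].
#' @param grid `"banded"` (band-averaged maps) or `"dense"` (full spectra on
#'   `dense_freqs`).
#' @param dense_freqs dense frequency grid (Hz); default 2-30 Hz at 1/3 Hz.
#' @param chi_range range of the subject-mean aperiodic exponent.
#' @param chi_spatial_sd SD of the vertex-level fluctuation of the aperiodic
#'   exponent around the subject mean (cortical 1/f slope varies regionally;
#'   without this, subject-level spectral shape would be a single global
#'   factor shared by every vertex).
#' @param peak_amp named per-band peak amplitudes.
#' @param subj_sd log-normal SD of between-subject peak-amplitude jitter.
#' @param vertex_sd log-normal SD of per-vertex, per-band measurement noise.
#' @param target_vertices vertex indices carrying the patient deviation.
#' @param effects named per-band multiplicative effects per unit severity.
#' @param severity_mean,severity_sd patient severity distribution (normal,
#'   truncated to `[0, severity_max]`).
#' @param severity_max upper truncation of severity, keeping
#'   `1 + severity * effect_b` positive for the default effects.
#' @param outcome_slope,age_slope,outcome_noise_sd outcome model parameters.
#' @param seed RNG seed (mandatory).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_controls = 60, n_patients = 60, n_vertices = 500,
                        scheme = canonical_bands(), grid = c("banded", "dense"),
                        dense_freqs = seq(2, 30, by = 1 / 3),
                        chi_range = c(1.08, 1.22), chi_spatial_sd = 0.05,
                        peak_amp = c(delta = 0.4, theta = 0.5, alpha = 1.2,
                                     beta = 0.6),
                        subj_sd = 0.08, vertex_sd = 0.05,
                        target_vertices = seq_len(min(50, n_vertices)),
                        effects = c(delta = -0.45, theta = -0.2,
                                    alpha = 0.2, beta = 0.9),
                        severity_mean = 1, severity_sd = 0.5,
                        severity_max = 1.8,
                        outcome_slope = 1, age_slope = 0.02,
                        outcome_noise_sd = 0.3, seed) {
  if (missing(seed)) stop("seed is required")
  grid <- match.arg(grid)
  if (any(target_vertices < 1 | target_vertices > n_vertices))
    stop("target vertices outside the vertex set")
  if (!all(is.finite(effects))) stop("effects must be finite")
  if (length(peak_amp) != nrow(scheme) || length(effects) != nrow(scheme))
    stop("peak_amp and effects must have one entry per band")
  structure(as.list(environment()), class = "cohort_spec")
}

# Band membership of each dense frequency bin; out-of-band bins attach to
# the nearest band so vertex noise and deviations act band-coherently.
.band_of <- function(freqs, scheme) {
  centers <- (scheme$f_lo + scheme$f_hi) / 2
  b <- integer(length(freqs))
  for (i in seq_along(freqs)) {
    inside <- which(freqs[i] >= scheme$f_lo & freqs[i] <= scheme$f_hi)
    b[i] <- if (length(inside)) inside[1] else which.min(abs(freqs[i] - centers))
  }
  b
}

#' Generate a synthetic patient/control cohort with ground truth
#'
#' See [cohort_spec()] for the generative model. A fixed seed yields
#' bit-identical output.
#'
#' @param spec a [cohort_spec()].
#' @return list with `patients` and `controls` ([cohort_spectra()]),
#'   `outcome` (data.frame: `subject`, `age`, `severity`, `rating`), and
#'   `ground_truth` (severities, target set, effects, outcome parameters).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  sch <- spec$scheme
  nb <- nrow(sch)
  centers <- (sch$f_lo + sch$f_hi) / 2
  widths <- (sch$f_hi - sch$f_lo) / 4
  ntot <- spec$n_controls + spec$n_patients
  nv <- spec$n_vertices
  severity <- pmin(spec$severity_max,
                   pmax(0, rnorm(spec$n_patients, spec$severity_mean,
                                 spec$severity_sd)))
  scale_pb <- 1 + outer(severity, spec$effects)   # patient x band
  if (any(scale_pb <= 0))
    stop("deviation effects produce non-positive power; reduce |effects| or severity")

  chi <- runif(ntot, spec$chi_range[1], spec$chi_range[2])
  amp <- matrix(spec$peak_amp, ntot, nb, byrow = TRUE) *
    exp(matrix(rnorm(ntot * nb, 0, spec$subj_sd), ntot, nb))

  if (spec$grid == "banded") {
    feat_f <- centers
    feat_band <- seq_len(nb)
    peak_gain <- diag(nb)                 # band peak contributes to its band
  } else {
    feat_f <- spec$dense_freqs
    feat_band <- .band_of(feat_f, sch)
    peak_gain <- vapply(seq_len(nb), function(b)
      exp(-(feat_f - centers[b])^2 / (2 * widths[b]^2)), numeric(length(feat_f)))
    peak_gain <- t(peak_gain)             # band x feature
  }
  nf <- length(feat_f)

  make_map <- function(s, is_patient, pat_idx) {
    chi_v <- chi[s] + rnorm(nv, 0, spec$chi_spatial_sd)  # regional 1/f slope
    base <- exp(outer(-chi_v, log(feat_f)))              # vertex x feature
    peaks <- outer(rep(1, nv), as.numeric(amp[s, ] %*% peak_gain))
    noise <- exp(matrix(rnorm(nv * nb, 0, spec$vertex_sd), nv, nb))
    pw <- (base + peaks) * noise[, feat_band, drop = FALSE]
    if (is_patient) {
      sc <- scale_pb[pat_idx, feat_band]
      pw[spec$target_vertices, ] <- pw[spec$target_vertices, , drop = FALSE] *
        matrix(sc, length(spec$target_vertices), nf, byrow = TRUE)
    }
    if (spec$grid == "banded")
      band_spectral_map(paste0(if (is_patient) "pat" else "ctl",
                               if (is_patient) pat_idx else s), pw, sch)
    else dense_spectrum(feat_f, pw)
  }

  ctl_maps <- lapply(seq_len(spec$n_controls), function(s)
    make_map(s, FALSE, NA))
  pat_maps <- lapply(seq_len(spec$n_patients), function(p)
    make_map(spec$n_controls + p, TRUE, p))

  age <- rnorm(spec$n_patients, 66, 8)
  rating <- spec$outcome_slope * severity + spec$age_slope * age +
    rnorm(spec$n_patients, 0, spec$outcome_noise_sd)
  outcome <- data.frame(subject = paste0("pat", seq_len(spec$n_patients)),
                        age = age, severity = severity, rating = rating,
                        stringsAsFactors = FALSE)
  list(patients = cohort_spectra(pat_maps, "patient",
                                 subject_ids = outcome$subject),
       controls = cohort_spectra(ctl_maps, "control"),
       outcome = outcome,
       ground_truth = list(severity = severity,
                           target_vertices = spec$target_vertices,
                           effects = spec$effects,
                           outcome_slope = spec$outcome_slope,
                           age_slope = spec$age_slope))
}

# Smooth positive envelope modulator: low-passed Gaussian noise, unit SD.
.slow_modulator <- function(n, fs, f_cut = 0.6) {
  m <- .fft_bandpass(rnorm(n), fs, f_lo = 1e-6, f_hi = f_cut,
                     transition = f_cut / 2)
  m / max(sd(m), .Machine$double.eps)
}

#' Generate band-limited series with envelope-coupled vertex pairs
#'
#' Every vertex carries an independent band-limited noise carrier whose
#' amplitude is modulated as `exp(coupling * m(t))` by a slow (< ~0.6 Hz)
#' Gaussian modulator; vertices listed in `coupled_pairs` share their
#' modulator, all others have independent ones. Coupling 0 gives fully
#' independent signals.
#'
#' @param n_vertices number of vertices.
#' @param coupled_pairs two-column matrix of 1-based vertex pairs sharing a
#'   modulator (may be NULL).
#' @param band numeric `c(f_lo, f_hi)` of the carrier band (below Nyquist).
#' @param coupling modulation strength (>= 0).
#' @param n_epochs,fs,epoch_len epoch structure.
#' @param seed RNG seed (mandatory).
#' @return list with `series` ([epoched_series()], one orientation) and
#'   `ground_truth` (pairs, band, coupling).
#' @export
gen_coupled_series <- function(n_vertices, coupled_pairs = NULL,
                               band = c(15, 29), coupling = 0.5,
                               n_epochs = 40, fs = 200, epoch_len = 6,
                               seed) {
  if (missing(seed)) stop("seed is required")
  if (band[2] >= fs / 2 || band[1] <= 0 || band[1] >= band[2])
    stop("invalid band for the sampling rate")
  if (coupling < 0) stop("coupling must be >= 0")
  set.seed(seed)
  nt <- round(epoch_len * fs)
  # modulator group per vertex: coupled pairs share one
  group <- seq_len(n_vertices)
  if (!is.null(coupled_pairs)) {
    coupled_pairs <- matrix(as.integer(coupled_pairs), ncol = 2)
    for (i in seq_len(nrow(coupled_pairs)))
      group[coupled_pairs[i, 2]] <- group[coupled_pairs[i, 1]]
  }
  data <- array(0, c(n_vertices, 1, nt, n_epochs))
  for (e in seq_len(n_epochs)) {
    mods <- list()
    for (v in seq_len(n_vertices)) {
      g <- group[v]
      if (is.null(mods[[as.character(g)]]))
        mods[[as.character(g)]] <- .slow_modulator(nt, fs)
      carrier <- .fft_bandpass(rnorm(nt), fs, band[1], band[2],
                               transition = 0.5)
      data[v, 1, , e] <- exp(coupling * mods[[as.character(g)]]) * carrier
    }
  }
  list(series = epoched_series(data, fs),
       ground_truth = list(coupled_pairs = coupled_pairs, band = band,
                           coupling = coupling))
}

#' Generate a linear mediation triplet
#'
#' `x ~ N(0, 1)`, `m = a x + e_m`, `y = c' x + b m + e_y`, with independent
#' Gaussian noise. The implied total effect of `x` on `y` is `a b + c'`.
#'
#' @param n sample size (>= 10).
#' @param a,b,c_prime path coefficients.
#' @param sd_m,sd_y noise SDs.
#' @param seed RNG seed (mandatory).
#' @return list with `data` (data.frame `x`, `m`, `y`, `age` distractor
#'   covariate) and `ground_truth` (paths and implied effects).
#' @export
gen_mediation <- function(n, a = 0.5, b = 0.5, c_prime = 0, sd_m = 1,
                          sd_y = 1, seed) {
  if (missing(seed)) stop("seed is required")
  if (n < 10) stop("n must be >= 10")
  set.seed(seed)
  x <- rnorm(n)
  m <- a * x + rnorm(n, 0, sd_m)
  y <- c_prime * x + b * m + rnorm(n, 0, sd_y)
  list(data = data.frame(x = x, m = m, y = y, age = rnorm(n, 66, 8)),
       ground_truth = list(a = a, b = b, c_prime = c_prime,
                           acme = a * b, ade = c_prime,
                           total = a * b + c_prime))
}

#' Generate a noisy multi-rater rating table
#'
#' `rating = true score + rater bias + noise`; constant rater biases do not
#' reduce consistency-type reliability, noise does.
#'
#' @param n_items,n_raters table dimensions (>= 2 each).
#' @param true_scores optional per-item true scores (default `N(0, 1)`).
#' @param bias_sd SD of per-rater constant offsets.
#' @param noise_sd SD of cellwise noise.
#' @param seed RNG seed (mandatory).
#' @return list with `ratings` (items x raters matrix) and `ground_truth`.
#' @export
gen_ratings <- function(n_items, n_raters, true_scores = NULL, bias_sd = 0.5,
                        noise_sd = 0.3, seed) {
  if (missing(seed)) stop("seed is required")
  if (n_items < 2 || n_raters < 2) stop("need >= 2 items and raters")
  set.seed(seed)
  if (is.null(true_scores)) true_scores <- rnorm(n_items)
  bias <- rnorm(n_raters, 0, bias_sd)
  ratings <- outer(true_scores, bias, `+`) +
    matrix(rnorm(n_items * n_raters, 0, noise_sd), n_items, n_raters)
  list(ratings = ratings,
       ground_truth = list(true_scores = true_scores, bias = bias,
                           noise_sd = noise_sd))
}
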