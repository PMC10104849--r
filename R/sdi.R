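#' Cohort of spectral maps on a shared vertex space
#'
#' Bundles per-subject spectral maps (band-averaged [band_spectral_map()]s or
#' [dense_spectrum()]s) with their role in the normative comparison.
#'
#' @param maps list of `band_spectral_map` or `dense_spectrum`, one per
#'   subject, all on the same vertex space and frequency grid.
#' @param role `"control"` or `"patient"`.
#' @param subject_ids optional identifiers; defaults to those stored in
#'   band maps, else `S1`, `S2`, ...
#' @return A `cohort_spectra` object.
#' @export
cohort_spectra <- function(maps, role = c("control", "patient"),
                           subject_ids = NULL) {
  role <- match.arg(role)
  if (length(maps) < 1L) stop("at least one subject required")
  getp <- function(m) if (inherits(m, "band_spectral_map")) m$power else m$power
  nv <- nrow(getp(maps[[1]]))
  nf <- ncol(getp(maps[[1]]))
  for (m in maps) {
    p <- getp(m)
    if (nrow(p) != nv || ncol(p) != nf)
      stop("all maps must share vertex count and band/frequency grid")
  }
  if (nf < 2L) stop("need at least 2 bands or bins for correlation")
  if (is.null(subject_ids)) {
    subject_ids <- vapply(seq_along(maps), function(i) {
      id <- if (inherits(maps[[i]], "band_spectral_map")) maps[[i]]$subject_id else NA
      if (is.na(id)) paste0("S", i) else as.character(id)
    }, character(1))
  }
  structure(list(subject_ids = subject_ids, maps = maps, role = role),
            class = "cohort_spectra")
}

# Stack a cohort into a vertex x feature x subject array.
.cohort_array <- function(cohort) {
  getp <- function(m) if (inherits(m, "band_spectral_map")) m$power else m$power
  p1 <- getp(cohort$maps[[1]])
  arr <- array(NA_real_, c(nrow(p1), ncol(p1), length(cohort$maps)))
  for (s in seq_along(cohort$maps)) arr[, , s] <- getp(cohort$maps[[s]])
  arr
}

.R_CLAMP <- 1 - 1e-6

#' Spectral Deviation Index at a single vertex
#'
#' Correlates a patient's cross-frequency power profile with each control's
#' (Pearson), takes the median correlation across controls (midpoint rule for
#' even counts), Fisher-transforms it (`atanh`), and subtracts from 1:
#' `SDI = 1 - atanh(median r)`. Higher values indicate greater deviation from
#' the normative cohort; a median r of 0 gives SDI = 1 exactly, and values go
#' negative once the median r exceeds `tanh(1)`. Correlations are clamped to
#' +/-(1 - 1e-6) before the transform so the index stays finite.
#'
#' Controls whose profile has zero variance are excluded from the median (an
#' undefined correlation is not evidence of similarity); a zero-variance
#' patient profile yields a missing SDI rather than an error.
#'
#' @param patient_profile numeric vector of per-band (or per-bin) power.
#' @param control_profiles list of numeric vectors of the same length.
#' @param log_power correlate log10 power instead of raw power.
#' @return list with `sdi`, `median_r`, `n_controls` used, `clamped` count.
#' @examples
#' sdi_vertex(c(1, 2, 3, 4),
#'            list(c(2, 4, 6, 9), c(4, 3, 2, 1), c(1, 1, 4, 4)))
#' @export
sdi_vertex <- function(patient_profile, control_profiles, log_power = FALSE) {
  if (length(control_profiles) < 1L) stop("at least one control required")
  k <- length(patient_profile)
  if (k < 2L) stop("profiles need length >= 2")
  if (any(lengths(control_profiles) != k)) stop("profile lengths differ")
  if (log_power) {
    patient_profile <- log10(patient_profile)
    control_profiles <- lapply(control_profiles, log10)
  }
  if (sd(patient_profile) == 0 || !all(is.finite(patient_profile)))
    return(list(sdi = NA_real_, median_r = NA_real_, n_controls = 0L,
                clamped = 0L))
  ok <- vapply(control_profiles, function(x) sd(x) > 0, logical(1))
  if (!any(ok))
    return(list(sdi = NA_real_, median_r = NA_real_, n_controls = 0L,
                clamped = 0L))
  r <- vapply(control_profiles[ok], function(x) cor(patient_profile, x),
              numeric(1))
  clamped <- sum(abs(r) > .R_CLAMP)
  r <- pmin(pmax(r, -.R_CLAMP), .R_CLAMP)
  m <- median(r)
  list(sdi = 1 - atanh(m), median_r = m, n_controls = sum(ok),
       clamped = clamped)
}

# Core vectorised SDI over an entire vertex space.
# pat, ctl: vertex x feature x subject arrays. Returns list of per-patient
# results: sdi matrix (vertex x patient), n_controls, clamp counts.
.sdi_core <- function(pat, ctl, log_power = FALSE) {
  if (log_power) { pat <- log10(pat); ctl <- log10(ctl) }
  nv <- dim(pat)[1]; np <- dim(pat)[3]; nc <- dim(ctl)[3]
  sdi <- matrix(NA_real_, nv, np)
  nctl <- matrix(0L, nv, np)
  clamps <- matrix(0L, nv, np)
  nf <- dim(pat)[2]
  for (v in seq_len(nv)) {
    P <- matrix(pat[v, , ], nf, np)          # features x patients
    C <- matrix(ctl[v, , ], nf, nc)          # features x controls
    P0 <- P - rep(colMeans(P), each = nf)
    C0 <- C - rep(colMeans(C), each = nf)
    nP <- sqrt(colSums(P0^2)); nC <- sqrt(colSums(C0^2))
    okP <- nP > 0 & is.finite(nP)
    okC <- nC > 0 & is.finite(nC)
    if (!any(okC)) next
    R <- crossprod(P0, C0[, okC, drop = FALSE]) /
      outer(nP, nC[okC])                     # patients x usable controls
    cl <- abs(R) > .R_CLAMP
    R <- pmin(pmax(R, -.R_CLAMP), .R_CLAMP)
    med <- apply(R, 1, median)
    sdi[v, okP] <- 1 - atanh(med[okP])
    nctl[v, okP] <- sum(okC)
    clamps[v, okP] <- rowSums(cl)[okP]
  }
  list(sdi = sdi, n_controls = nctl, clamped = clamps)
}

.sdi_result <- function(core, patients) {
  lapply(seq_along(patients$maps), function(i) {
    structure(list(subject_id = patients$subject_ids[i],
                   sdi = core$sdi[, i],
                   n_controls = core$n_controls[, i],
                   clamp_count = sum(core$clamped[, i])),
              class = "sdi_map")
  })
}

#' Spectral Deviation Index maps for a patient cohort
#'
#' Applies [sdi_vertex()] independently at every vertex for every patient,
#' against the full control cohort. Vertex order is preserved.
#'
#' @param patients,controls [cohort_spectra()] objects on the same vertex
#'   space (band-averaged maps).
#' @param log_power correlate log10 power instead of raw power.
#' @return list of `sdi_map` objects (fields `subject_id`, `sdi`,
#'   `n_controls`, `clamp_count`), one per patient.
#' @export
sdi_map <- function(patients, controls, log_power = FALSE) {
  pat <- .cohort_array(patients); ctl <- .cohort_array(controls)
  if (dim(pat)[1] != dim(ctl)[1]) stop("vertex counts differ between cohorts")
  if (dim(pat)[2] != dim(ctl)[2]) stop("band/frequency grids differ between cohorts")
  .sdi_result(.sdi_core(pat, ctl, log_power), patients)
}

#' Dense-spectrum variant of the SDI
#'
#' Same recipe as [sdi_map()] but correlating over every frequency bin in
#' `[f_lo, f_hi]` of the dense grid instead of band averages. With a 2-30 Hz
#' range at 1/3-Hz resolution, 85 bins enter each correlation.
#'
#' @param patients,controls [cohort_spectra()] of [dense_spectrum()] objects
#'   on identical grids.
#' @param f_lo,f_hi frequency range (Hz, inclusive).
#' @param log_power correlate log10 power instead of raw power.
#' @return list of `sdi_map` objects.
#' @export
dense_sdi_map <- function(patients, controls, f_lo = 2, f_hi = 30,
                          log_power = FALSE) {
  freqs <- patients$maps[[1]]$freqs
  if (!identical(freqs, controls$maps[[1]]$freqs))
    stop("dense grids differ between cohorts")
  sel <- which(freqs >= f_lo & freqs <= f_hi)
  if (length(sel) < 2L) stop("frequency range [", f_lo, ", ", f_hi,
                             "] contains fewer than 2 bins")
  pat <- .cohort_array(patients)[, sel, , drop = FALSE]
  ctl <- .cohort_array(controls)[, sel, , drop = FALSE]
  if (dim(pat)[1] != dim(ctl)[1]) stop("vertex counts differ between cohorts")
  .sdi_result(.sdi_core(pat, ctl, log_power), patients)
}

#' Mean and standard deviation of SDI maps across patients
#'
#' @param sdi_maps list of `sdi_map` objects from [sdi_map()].
#' @return list with vertex vectors `mean` and `sd` (`sd` is the sample SD;
#'   missing when only one map is supplied). Missing vertices are excluded
#'   pairwise.
#' @export
cohort_summary <- function(sdi_maps) {
  M <- vapply(sdi_maps, function(m) m$sdi, numeric(length(sdi_maps[[1]]$sdi)))
  M <- matrix(M, ncol = length(sdi_maps))
  list(mean = rowMeans(M, na.rm = TRUE),
       sd = if (ncol(M) >= 2L) apply(M, 1, sd, na.rm = TRUE)
            else rep(NA_real_, nrow(M)))
}
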