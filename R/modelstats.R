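#' Ordinary least-squares fit with an explicit AIC convention
#'
#' Wraps [stats::lm()] with pairwise complete-case handling and records the
#' Gaussian AIC, `n log(2 pi RSS / n) + n + 2 (k + 1)` (the residual variance
#' counted as a parameter), so that AIC differences between models on the
#' same cases are convention-independent. A perfect fit (RSS below
#' `n * 1e-12`) is floored and flagged rather than reported as -Inf.
#'
#' @param outcome name of the outcome column.
#' @param predictors character vector of predictor column names.
#' @param data data.frame containing them.
#' @return A `linear_model_fit`: `outcome`, `predictors`, `coefficients`,
#'   `rss`, `n`, `k`, `aic`, `rows` (complete-case row indices),
#'   `degenerate` flag, and the underlying `lm` as `fit`.
#' @export
fit_lm <- function(outcome, predictors, data) {
  cols <- c(outcome, predictors)
  if (!all(cols %in% names(data))) stop("missing columns: ",
    paste(setdiff(cols, names(data)), collapse = ", "))
  rows <- which(complete.cases(data[, cols, drop = FALSE]))
  d <- data[rows, cols, drop = FALSE]
  k <- length(predictors) + 1L
  n <- nrow(d)
  if (n <= k) stop("too few complete cases (n = ", n, ", k = ", k, ")")
  form <- as.formula(paste(outcome, "~",
                           if (length(predictors)) paste(predictors, collapse = " + ")
                           else "1"))
  fit <- lm(form, data = d)
  if (fit$rank < k) stop("rank-deficient design")
  rss <- sum(resid(fit)^2)
  degenerate <- rss < n * 1e-12
  rss_eff <- max(rss, n * 1e-12)
  aic <- n * log(2 * pi * rss_eff / n) + n + 2 * (k + 1)
  structure(list(outcome = outcome, predictors = predictors,
                 coefficients = coef(fit), rss = rss, n = n, k = k,
                 aic = aic, rows = rows, degenerate = degenerate, fit = fit),
            class = "linear_model_fit")
}

#' AIC difference between two fitted models
#'
#' `delta = AIC(a) - AIC(b)`, with `|delta| > 2` flagged as meaningful
#' evidence. Both fits must model the same outcome on the same complete-case
#' subject set, otherwise their AICs are not comparable.
#'
#' @param model_a,model_b `linear_model_fit` objects from [fit_lm()].
#' @return list with `delta_aic`, `meaningful`, `favours` (`"a"`, `"b"` or
#'   `"neither"`).
#' @export
delta_aic <- function(model_a, model_b) {
  if (!identical(model_a$outcome, model_b$outcome))
    stop("models have different outcomes")
  if (!identical(model_a$rows, model_b$rows))
    stop("models were fitted on different subject sets")
  d <- model_a$aic - model_b$aic
  list(delta_aic = d, meaningful = abs(d) > 2,
       favours = if (abs(d) <= 2) "neither" else if (d < 0) "a" else "b")
}

# Patient/control band-power profiles at one vertex:
# subjects x bands matrices.
.profiles_at_vertex <- function(cohort, vertex) {
  t(vapply(cohort$maps, function(m) m$power[vertex, ],
           numeric(ncol(cohort$maps[[1]]$power))))
}

.sdi_from_profiles <- function(pat_prof, ctl_prof, log_power = FALSE) {
  apply(pat_prof, 1, function(p)
    sdi_vertex(p, split(t(ctl_prof), col(t(ctl_prof))),
               log_power = log_power)$sdi)
}

#' Leave-one-band-out contribution to an SDI-outcome relationship
#'
#' Recomputes the SDI at a chosen vertex once per band, each time excluding
#' that band from both patient and control profiles, refits
#' `outcome ~ SDI + age`, and reports
#' `delta AIC = AIC(leave-one-out model) - AIC(full model)`. More positive
#' values indicate a stronger contribution of the excluded band to the
#' relationship; `|delta AIC| > 2` is flagged as meaningful. The sign of the
#' zero-order (age-adjusted) slope of each band's power against the outcome
#' is reported alongside, to convey the direction of the underlying effect.
#'
#' @param patients,controls [cohort_spectra()] of band-averaged maps with at
#'   least 4 bands (3 must remain after exclusion).
#' @param vertex 1-based vertex index (typically a peak vertex).
#' @param outcome_table data.frame with the outcome and age, rows aligned
#'   with the patient cohort.
#' @param outcome,age column names in `outcome_table`.
#' @param log_power correlate log10 band power in the SDI recomputations
#'   (see [sdi_vertex()]).
#' @return data.frame with columns `band`, `delta_aic`, `meaningful`,
#'   `slope_sign`.
#' @export
loo_band_contribution <- function(patients, controls, vertex, outcome_table,
                                  outcome = "rating", age = "age",
                                  log_power = FALSE) {
  scheme <- patients$maps[[1]]$band_scheme
  nb <- nrow(scheme)
  if (nb < 4L) stop("need at least 4 bands for leave-one-out analysis")
  pat <- .profiles_at_vertex(patients, vertex)
  ctl <- .profiles_at_vertex(controls, vertex)
  if (nrow(pat) != nrow(outcome_table))
    stop("outcome table misaligned with patient cohort")
  d <- outcome_table
  d$.sdi_full <- .sdi_from_profiles(pat, ctl, log_power)
  full <- fit_lm(outcome, c(".sdi_full", age), d)
  out <- data.frame(band = scheme$name, delta_aic = NA_real_,
                    meaningful = NA, slope_sign = NA_integer_,
                    stringsAsFactors = FALSE)
  for (b in seq_len(nb)) {
    d$.sdi_loo <- .sdi_from_profiles(pat[, -b, drop = FALSE],
                                     ctl[, -b, drop = FALSE], log_power)
    loo <- fit_lm(outcome, c(".sdi_loo", age), d)
    out$delta_aic[b] <- loo$aic - full$aic
    d$.band <- pat[, b]
    zf <- fit_lm(outcome, c(".band", age), d)
    out$slope_sign[b] <- sign(zf$coefficients[".band"])
  }
  out$meaningful <- abs(out$delta_aic) > 2
  out
}

#' Compare SDI against band-limited models parcel by parcel
#'
#' For every parcel, fits `score ~ SDI + age` and
#' `score ~ delta + theta + alpha + beta + age` (one column per band of the
#' supplied band-power array) on the same subjects, and reports
#' `delta AIC = AIC(SDI model) - AIC(band model)`. Lower values indicate
#' stronger evidence for the SDI model; `|delta AIC| > 2` is flagged.
#'
#' @param parcel_sdi subjects x parcels matrix of SDI values.
#' @param parcel_band_power subjects x parcels x bands array of band power.
#' @param scores per-subject clinical score vector.
#' @param age per-subject age vector.
#' @param band_names names of the third array dimension.
#' @return data.frame with columns `parcel`, `delta_aic`, `meaningful`.
#' @export
compare_sdi_vs_bandlimited <- function(parcel_sdi, parcel_band_power, scores,
                                       age,
                                       band_names = c("delta", "theta",
                                                      "alpha", "beta")) {
  parcel_sdi <- as.matrix(parcel_sdi)
  np <- ncol(parcel_sdi)
  if (dim(parcel_band_power)[1] != nrow(parcel_sdi) ||
      dim(parcel_band_power)[2] != np)
    stop("band-power array misaligned with SDI table")
  if (dim(parcel_band_power)[3] != length(band_names))
    stop("missing parcel band columns")
  out <- data.frame(parcel = if (!is.null(colnames(parcel_sdi)))
                      colnames(parcel_sdi) else paste0("P", seq_len(np)),
                    delta_aic = NA_real_, stringsAsFactors = FALSE)
  for (p in seq_len(np)) {
    d <- data.frame(score = scores, age = age, sdi = parcel_sdi[, p])
    for (b in seq_along(band_names)) d[[band_names[b]]] <- parcel_band_power[, p, b]
    m_sdi <- fit_lm("score", c("sdi", "age"), d)
    m_band <- fit_lm("score", c(band_names, "age"), d)
    out$delta_aic[p] <- m_sdi$aic - m_band$aic
  }
  out$meaningful <- abs(out$delta_aic) > 2
  out
}

.ols_coef <- function(y, X) qr.coef(qr(X), y)

#' Bootstrap causal mediation analysis
#'
#' Decomposes the effect of `x` on `y` into a direct path and an indirect
#' path through mediator `m`, using linear models with optional covariates:
#' the a-path (`m ~ x + cov`), the b-path and direct effect
#' (`y ~ x + m + cov`), and the total effect (`y ~ x + cov`). The average
#' causal mediation effect is `ACME = a * b`, the average direct effect is
#' the `x` coefficient of the full outcome model, and for these linear
#' models `total = ADE + ACME` holds exactly. Uncertainty comes from a
#' non-parametric case-resampling bootstrap: percentile confidence
#' intervals and two-sided p-values
#' `p = 2 min(P(boot <= 0), P(boot >= 0))`.
#'
#' @param x,m,y numeric vectors (exposure, mediator, outcome).
#' @param covariates optional data.frame/matrix of nuisance covariates
#'   (e.g., age).
#' @param n_boot bootstrap draws (>= 100).
#' @param seed RNG seed (mandatory).
#' @param conf confidence level (default 0.95).
#' @return A `mediation_result`: `total`, `ade`, `acme`, `prop_mediated`,
#'   `ci` (matrix), `p` (named vector), `n_boot`, `seed`, `n`.
#' @export
mediate <- function(x, m, y, covariates = NULL, n_boot = 1000, seed,
                    conf = 0.95) {
  if (missing(seed)) stop("seed is required")
  if (n_boot < 100) stop("n_boot must be >= 100")
  cov <- if (is.null(covariates)) NULL else as.matrix(covariates)
  d <- cbind(x = x, m = m, y = y, cov)
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (var(d[, "x"]) == 0 || var(d[, "m"]) == 0 || var(d[, "y"]) == 0)
    stop("zero variance in x, m or y")
  Zc <- if (is.null(cov)) NULL else d[, -(1:3), drop = FALSE]
  paths <- function(dd, Zc) {
    Xa <- cbind(1, dd[, "x"], Zc)
    a <- .ols_coef(dd[, "m"], Xa)[2]
    Xb <- cbind(1, dd[, "x"], dd[, "m"], Zc)
    cb <- .ols_coef(dd[, "y"], Xb)
    tot <- .ols_coef(dd[, "y"], Xa)[2]
    c(acme = a * cb[3], ade = cb[2], total = tot)
  }
  est <- paths(d, Zc)
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, 3,
                 dimnames = list(NULL, c("acme", "ade", "total")))
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    boot[i, ] <- paths(d[idx, , drop = FALSE],
                       if (is.null(Zc)) NULL else Zc[idx, , drop = FALSE])
  }
  al <- (1 - conf) / 2
  ci <- t(apply(boot, 2, quantile, probs = c(al, 1 - al), names = FALSE))
  colnames(ci) <- c("lower", "upper")
  pv <- apply(boot, 2, function(b) min(1, 2 * min(mean(b <= 0), mean(b >= 0))))
  structure(list(total = unname(est["total"]), ade = unname(est["ade"]),
                 acme = unname(est["acme"]),
                 prop_mediated = unname(est["acme"] / est["total"]),
                 ci = ci, p = pv, n_boot = n_boot, seed = seed, n = n,
                 conf = conf),
            class = "mediation_result")
}

#' Intraclass correlation, consistency of k raters (ICC type C,k)
#'
#' Two-way random-effects, consistency form: reliability of the mean of `k`
#' raters, insensitive to constant rater offsets. From the two-way ANOVA
#' decomposition (items and raters as factors),
#' `ICC(C,k) = (MS_items - MS_error) / MS_items`, with a 95% confidence
#' interval from F-distribution bounds on `MS_items / MS_error`
#' (Shrout-Fleiss convention).
#'
#' @param ratings items x raters numeric matrix with no missing cells
#'   (average repeated measurements, e.g. sentences, upstream).
#' @param conf confidence level (default 0.95).
#' @return An `icc_result`: `icc`, `ci`, `ms_rows`, `ms_error`, `k`, `n`.
#' @export
icc_ck <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need >= 2 items and >= 2 raters")
  if (anyNA(ratings)) stop("missing cells not allowed; aggregate upstream")
  long <- data.frame(score = as.vector(ratings),
                     item = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(aov(score ~ item + rater, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; mse <- ms[3]
  icc <- (msr - mse) / msr
  f <- msr / mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  al <- (1 - conf) / 2
  fl <- f / qf(1 - al, df1, df2)
  fu <- f * qf(1 - al, df2, df1)
  structure(list(icc = icc, ci = c(lower = 1 - 1 / fl, upper = 1 - 1 / fu),
                 ms_rows = msr, ms_error = mse, k = k, n = n),
            class = "icc_result")
}
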