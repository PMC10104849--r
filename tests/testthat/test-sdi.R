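test_that("sdi_vertex reproduces hand-computed anchors", {
  # median r = 0 gives SDI = 1 exactly
  exact <- sdi_vertex(c(0, 1, 0, -1), list(c(1, 0, -1, 0)))
  expect_equal(exact$median_r, 0)
  expect_equal(exact$sdi, 1)

  # worked example: r = {0.9944, -1, 0.8944}, median 0.8944
  res <- sdi_vertex(c(1, 2, 3, 4),
                    list(c(2, 4, 6, 9), c(4, 3, 2, 1), c(1, 1, 4, 4)))
  expect_equal(res$median_r, cor(1:4, c(1, 1, 4, 4)), tolerance = 1e-12)
  expect_equal(res$sdi, 1 - atanh(2 / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$clamped, 1L)  # the r = -1 control hits the clamp

  # all controls identical to the patient: clamped, large negative, finite
  res <- sdi_vertex(c(1, 2, 3, 4), list(c(1, 2, 3, 4), c(2, 4, 6, 8)))
  expect_equal(res$sdi, 1 - atanh(1 - 1e-6))
  expect_true(is.finite(res$sdi))
  expect_equal(res$clamped, 2L)

  # degenerate profiles: missing, not an error
  expect_true(is.na(sdi_vertex(c(2, 2, 2, 2), list(c(1, 2, 3, 4)))$sdi))
  expect_true(is.na(sdi_vertex(c(1, 2, 3, 4), list(c(5, 5, 5, 5)))$sdi))
})

test_that("sdi_map matches the nested-loop oracle and preserves structure", {
  pats <- random_band_cohort(3, 10, seed = 11, role = "patient")
  ctls <- random_band_cohort(5, 10, seed = 12)
  maps <- sdi_map(pats, ctls)
  expect_length(maps, 3L)
  expect_equal(sapply(maps, `[[`, "sdi"), sdi_oracle(pats, ctls),
               tolerance = 1e-12)
  expect_true(all(maps[[1]]$n_controls == 5L))

  # single patient, single vertex reduces to sdi_vertex
  p1 <- cohort_spectra(list(band_spectral_map("p", matrix(c(1, 2, 3, 4), 1),
                                              canonical_bands())), "patient")
  c1 <- cohort_spectra(list(band_spectral_map("c", matrix(c(2, 4, 6, 9), 1),
                                              canonical_bands())), "control")
  expect_equal(sdi_map(p1, c1)[[1]]$sdi,
               sdi_vertex(c(1, 2, 3, 4), list(c(2, 4, 6, 9)))$sdi)

  # duplicated profile across vertices gives a constant map
  sch <- canonical_bands()
  pd <- cohort_spectra(list(band_spectral_map("p",
    matrix(c(1, 2, 3, 4), 6, 4, byrow = TRUE), sch)), "patient")
  cd <- cohort_spectra(list(band_spectral_map("c",
    matrix(c(2, 1, 4, 3), 6, 4, byrow = TRUE), sch)), "control")
  expect_equal(length(unique(sdi_map(pd, cd)[[1]]$sdi)), 1L)

  bad <- random_band_cohort(2, 7, seed = 13)
  expect_error(sdi_map(pats, bad), "vertex counts")
})

test_that("SDI is invariant to positive affine rescaling and monotone in median r", {
  pats <- random_band_cohort(2, 5, seed = 21, role = "patient")
  ctls <- random_band_cohort(4, 5, seed = 22)
  base <- sdi_map(pats, ctls)
  resc <- pats
  resc$maps[[1]] <- band_spectral_map("p1", 3.7 * pats$maps[[1]]$power + 1.2,
                                      canonical_bands())
  expect_equal(sdi_map(resc, ctls)[[1]]$sdi, base[[1]]$sdi, tolerance = 1e-10)

  # permuting control order never changes the output
  perm <- ctls
  perm$maps <- ctls$maps[c(3, 1, 4, 2)]
  expect_equal(sdi_map(pats, perm)[[1]]$sdi, base[[1]]$sdi)

  # strictly decreasing in the median correlation
  r <- seq(-0.9, 0.9, by = 0.2)
  sdis <- 1 - atanh(r)
  expect_true(all(diff(sdis) < 0))
})

test_that("dense SDI equals band SDI when bins repeat band values equally", {
  sch <- canonical_bands()
  # 3 bins inside each band, constant within band
  freqs <- c(2, 3, 4, 5, 6, 7, 8, 10, 12, 15, 22, 29)
  set.seed(31)
  mkpair <- function(vals) {
    dense <- dense_spectrum(freqs, matrix(rep(vals, each = 1)[rep(1:4, each = 3)], 1))
    banded <- band_spectral_map("s", matrix(vals, 1), sch)
    list(dense = dense, banded = banded)
  }
  pv <- runif(4, 0.5, 2); cv1 <- runif(4, 0.5, 2); cv2 <- runif(4, 0.5, 2)
  pp <- mkpair(pv); cc1 <- mkpair(cv1); cc2 <- mkpair(cv2)
  dres <- dense_sdi_map(cohort_spectra(list(pp$dense), "patient"),
                        cohort_spectra(list(cc1$dense, cc2$dense), "control"),
                        f_lo = 2, f_hi = 30)
  bres <- sdi_map(cohort_spectra(list(pp$banded), "patient"),
                  cohort_spectra(list(cc1$banded, cc2$banded), "control"))
  expect_equal(dres[[1]]$sdi, bres[[1]]$sdi, tolerance = 1e-12)
})

test_that("dense SDI uses 85 bins over 2-30 Hz at 1/3 Hz resolution", {
  sp <- cohort_spec(n_controls = 3, n_patients = 2, n_vertices = 4,
                    grid = "dense", seed = 41)
  sim <- gen_cohort(sp)
  freqs <- sim$patients$maps[[1]]$freqs
  expect_equal(sum(freqs >= 2 & freqs <= 30), 85L)
  dm <- dense_sdi_map(sim$patients, sim$controls, 2, 30)
  expect_true(all(is.finite(dm[[1]]$sdi)))
  expect_error(dense_sdi_map(sim$patients, sim$controls, 40, 50), "fewer than 2")
})

test_that("cohort_summary computes vertex-wise mean and sample SD", {
  m <- function(v) structure(list(subject_id = "x", sdi = v,
                                  n_controls = rep(1L, length(v)),
                                  clamp_count = 0L), class = "sdi_map")
  two <- cohort_summary(list(m(c(0, 1)), m(c(2, 1))))
  expect_equal(two$mean, c(1, 1))
  expect_equal(two$sd, c(sqrt(2), 0))
  one <- cohort_summary(list(m(c(3, 4))))
  expect_equal(one$mean, c(3, 4))
  expect_true(all(is.na(one$sd)))
  same <- cohort_summary(list(m(c(1, 2)), m(c(1, 2)), m(c(1, 2))))
  expect_true(all(same$sd == 0))
})
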