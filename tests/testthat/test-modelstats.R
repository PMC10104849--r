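test_that("fit_lm matches the stated Gaussian AIC convention and recovers slopes", {
  set.seed(1)
  d <- data.frame(x = rnorm(50), age = rnorm(50, 60, 8))
  d$y <- 2 * d$x + rnorm(50)
  f <- fit_lm("y", c("x", "age"), d)
  ref <- lm(y ~ x + age, data = d)
  expect_equal(f$aic, AIC(ref), tolerance = 1e-10)
  expect_equal(unname(coef(ref)), unname(f$coefficients), tolerance = 1e-12)
  se <- summary(ref)$coefficients["x", "Std. Error"]
  expect_lt(abs(f$coefficients["x"] - 2), 3 * se)

  # predictor order leaves AIC unchanged
  f2 <- fit_lm("y", c("age", "x"), d)
  expect_equal(f2$aic, f$aic)

  # perfect fit floored, flagged
  d$z <- 3 * d$x
  fp <- fit_lm("z", "x", d)
  expect_true(fp$degenerate)
  expect_true(is.finite(fp$aic))

  d$x2 <- d$x
  expect_error(fit_lm("y", c("x", "x2"), d), "rank")
})

test_that("delta_aic is antisymmetric with a |2| meaningfulness threshold", {
  set.seed(2)
  d <- data.frame(x = rnorm(40), w = rnorm(40))
  d$y <- d$x + rnorm(40)
  a <- fit_lm("y", "x", d)
  b <- fit_lm("y", c("x", "w"), d)
  ab <- delta_aic(a, b); ba <- delta_aic(b, a)
  expect_equal(ab$delta_aic, -ba$delta_aic)
  same <- delta_aic(a, a)
  expect_equal(same$delta_aic, 0)
  expect_false(same$meaningful)

  d2 <- d; d2$y[1] <- NA
  c2 <- fit_lm("y", "x", d2)
  expect_error(delta_aic(a, c2), "different subject sets")
})

test_that("a pure-noise predictor costs about one AIC unit on average", {
  set.seed(3)
  deltas <- replicate(200, {
    d <- data.frame(x = rnorm(60))
    d$y <- d$x + rnorm(60)
    d$noise <- rnorm(60)
    delta_aic(fit_lm("y", c("x", "noise"), d), fit_lm("y", "x", d))$delta_aic
  })
  # penalty 2 minus expected fit gain ~ 1
  expect_lt(abs(mean(deltas) - 1), 0.5)
})

test_that("leave-one-band-out analysis ranks driving bands above inert ones", {
  ranks_ok <- sapply(1:8, function(i) {
    sp <- cohort_spec(n_controls = 60, n_patients = 60, n_vertices = 30,
                      target_vertices = 1:10,
                      effects = c(delta = -0.45, theta = 0, alpha = -0.45,
                                  beta = 0),
                      seed = 700 + i)
    sim <- gen_cohort(sp)
    loo <- loo_band_contribution(sim$patients, sim$controls, vertex = 5,
                                 sim$outcome)
    drivers <- loo$delta_aic[loo$band %in% c("delta", "alpha")]
    inert <- loo$delta_aic[loo$band %in% c("theta", "beta")]
    all(drivers > 2) && min(drivers) > max(inert)
  })
  expect_gte(mean(ranks_ok), 0.75)

  sp <- cohort_spec(n_controls = 10, n_patients = 5, n_vertices = 4,
                    scheme = band_scheme(c("a", "b", "c"), c(1, 4, 8),
                                         c(3, 7, 12)),
                    peak_amp = c(1, 1, 1), effects = c(0, 0, 0), seed = 1)
  sim3 <- gen_cohort(sp)
  expect_error(loo_band_contribution(sim3$patients, sim3$controls, 1,
                                     sim3$outcome), "4 bands")
})

test_that("SDI vs band-limited model comparison favours the generating model", {
  set.seed(4)
  n <- 60
  age <- rnorm(n, 66, 8)
  sdi <- matrix(rnorm(n * 3), n, 3)
  bands <- array(rnorm(n * 3 * 4), c(n, 3, 4))

  # scores driven by the parcel's SDI alone
  scores <- 1.5 * sdi[, 2] + 0.02 * age + rnorm(n, 0, 0.4)
  cmp <- compare_sdi_vs_bandlimited(sdi, bands, scores, age)
  expect_lt(cmp$delta_aic[2], -2)

  # scores driven by a single band's power: band model wins despite 3 extra
  # parameters
  scores2 <- 1.5 * bands[, 1, 3] + 0.02 * age + rnorm(n, 0, 0.4)
  cmp2 <- compare_sdi_vs_bandlimited(sdi, bands, scores2, age)
  expect_gt(cmp2$delta_aic[1], 0)

  expect_error(compare_sdi_vs_bandlimited(sdi, bands[, , 1:2], scores, age),
               "band columns")
})

test_that("mediate decomposes exactly, reproduces under a seed, and widens CIs", {
  gm <- gen_mediation(120, a = 0.5, b = 0.4, c_prime = 0.2, seed = 11)
  m1 <- mediate(gm$data$x, gm$data$m, gm$data$y, covariates = gm$data["age"],
                n_boot = 300, seed = 21)
  expect_equal(m1$total, m1$ade + m1$acme, tolerance = 1e-10)
  m2 <- mediate(gm$data$x, gm$data$m, gm$data$y, covariates = gm$data["age"],
                n_boot = 300, seed = 21)
  expect_identical(m1$ci, m2$ci)
  expect_identical(m1$p, m2$p)

  m99 <- mediate(gm$data$x, gm$data$m, gm$data$y, covariates = gm$data["age"],
                 n_boot = 300, seed = 21, conf = 0.99)
  expect_lte(m99$ci["acme", "lower"], m1$ci["acme", "lower"])
  expect_gte(m99$ci["acme", "upper"], m1$ci["acme", "upper"])

  expect_true(m1$ci["acme", "lower"] <= m1$acme &&
              m1$acme <= m1$ci["acme", "upper"])
  expect_error(mediate(rep(1, 20), rnorm(20), rnorm(20), n_boot = 100,
                       seed = 1), "zero variance")
})

test_that("icc_ck matches the ANOVA oracle and the consistency definition", {
  # identical raters
  x <- matrix(rep(rnorm(6), 3), 6, 3)
  expect_equal(icc_ck(x)$icc, 1)
  # constant rater offsets leave consistency ICC at 1
  xo <- x + matrix(rep(c(0, 2, -1), each = 6), 6, 3)
  expect_equal(icc_ck(xo)$icc, 1)

  set.seed(6)
  y <- matrix(rnorm(18), 6, 3)
  res <- icc_ck(y)
  expect_equal(res$icc, icc_oracle(y), tolerance = 1e-10)
  expect_true(res$ci["lower"] <= res$icc && res$icc <= res$ci["upper"])

  # invariant to item order and to shifting one rater
  expect_equal(icc_ck(y[sample(6), ])$icc, res$icc, tolerance = 1e-12)
  y2 <- y; y2[, 2] <- y2[, 2] + 5
  expect_equal(icc_ck(y2)$icc, res$icc, tolerance = 1e-12)

  expect_error(icc_ck(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})
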