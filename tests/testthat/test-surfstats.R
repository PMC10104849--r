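test_that("surface_graph validates and deduplicates edges", {
  g <- surface_graph(4, rbind(c(1, 2), c(2, 1), c(3, 4)))
  expect_equal(nrow(g$edges), 2L)
  expect_error(surface_graph(3, rbind(c(1, 1))), "self-loops")
  expect_error(surface_graph(3, rbind(c(1, 5))), "out of range")
  lat <- lattice_surface_graph(3, 4)
  expect_equal(lat$n_vertices, 12L)
  expect_equal(nrow(lat$edges), 2 * 3 * 4 - 3 - 4)  # grid edge count
})

test_that("vertexwise_glm recovers slopes and handles degenerate fits", {
  set.seed(5)
  n <- 100
  x <- rnorm(n); age <- rnorm(n, 60, 8)
  design <- data.frame(x = x, age = age)

  # null: outcome orthogonal to the contrast
  Y0 <- matrix(rnorm(n * 50), n, 50)
  t0 <- vertexwise_glm(Y0, design, "x")$t
  expect_lt(abs(mean(t0)), 0.5)

  # recovery: beta = 0.5 within 3 SE at nearly every vertex
  B <- 0.5
  Y1 <- outer(x, rep(B, 40)) + matrix(rnorm(n * 40), n, 40)
  st <- vertexwise_glm(Y1, design, "x")
  se <- st$beta / st$t
  expect_gte(mean(abs(st$beta - B) < 3 * se), 0.99)

  # zero-noise degenerate fit is capped and counted
  Yd <- matrix(2 * x, n, 1)
  std <- vertexwise_glm(Yd, data.frame(x = x), "x")
  expect_equal(std$n_capped, 1L)
  expect_equal(abs(std$t[1]), 1e6)

  dup <- data.frame(x = x, x2 = x)
  expect_error(vertexwise_glm(Y0, dup, "x"), "rank deficient")
})

test_that("tfce_enhance matches closed forms in the fine-step limit", {
  # isolated vertex of height h0: integral of h^2 dh = h0^3 / 3
  h0 <- 2.4
  g <- surface_graph(3, rbind(c(2, 3)))
  e <- tfce_enhance(c(h0, 0, 0), g, E = 1, H = 2, dh = h0 / 1000)
  expect_lt(abs(e[1] - h0^3 / 3) / (h0^3 / 3), 0.01)

  # uniform height on a fully connected graph: n * h0^3 / 3 per vertex
  gf <- surface_graph(4, t(combn(4, 2)))
  ef <- tfce_enhance(rep(h0, 4), gf, E = 1, H = 2, dh = h0 / 1000)
  expect_lt(max(abs(ef - 4 * h0^3 / 3)) / (4 * h0^3 / 3), 0.01)

  expect_equal(tfce_enhance(c(0, 0, 0), g), c(0, 0, 0))
  expect_error(tfce_enhance(c(-1, 0, 0), g), "non-negative")
})

test_that("tfce_enhance agrees exactly with the component-search oracle", {
  set.seed(9)
  for (rep in 1:3) {
    nv <- 50
    edges <- cbind(sample(nv, 120, TRUE), sample(nv, 120, TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    g <- surface_graph(nv, edges)
    stat <- runif(nv, 0, 3)
    dh <- max(stat) / 47  # deliberately awkward step
    expect_equal(tfce_enhance(stat, g, E = 1, H = 2, dh = dh),
                 tfce_oracle(stat, g, E = 1, H = 2, dh = dh),
                 tolerance = 1e-12)
    # non-default exponents too
    expect_equal(tfce_enhance(stat, g, E = 0.5, H = 1.5, dh = dh),
                 tfce_oracle(stat, g, E = 0.5, H = 1.5, dh = dh),
                 tolerance = 1e-12)
  }
})

test_that("tfce_enhance is monotone in the input statistic", {
  set.seed(10)
  g <- lattice_surface_graph(5, 5)
  stat <- runif(25, 0, 2)
  base <- tfce_enhance(stat, g, dh = 0.01)
  for (v in c(3, 17)) {
    up <- stat; up[v] <- up[v] + 0.5
    expect_true(all(tfce_enhance(up, g, dh = 0.01) >= base - 1e-12))
  }
})

test_that("permutation_fwe attains the boundary p-value and is seed-reproducible", {
  set.seed(12)
  g <- lattice_surface_graph(5, 8)
  n <- 30
  x <- rnorm(n); age <- rnorm(n)
  design <- data.frame(x = x, age = age)
  # huge injected effect at a patch
  Y <- matrix(rnorm(n * 40, sd = 0.1), n, 40)
  Y[, 1:6] <- Y[, 1:6] + outer(x, rep(3, 6))
  r1 <- permutation_fwe(Y, design, "x", g, n_perm = 99, seed = 42)
  expect_equal(min(r1$p_fwe), 1 / 100)
  expect_true(all(r1$p_fwe > 0 & r1$p_fwe <= 1))
  expect_gte(length(r1$clusters), 1L)
  expect_true(all(1:6 %in% r1$clusters[[1]]))

  r2 <- permutation_fwe(Y, design, "x", g, n_perm = 99, seed = 42)
  expect_identical(r1$p_fwe, r2$p_fwe)
  expect_identical(r1$null_max, r2$null_max)
  expect_error(permutation_fwe(Y, design, "x", g, n_perm = 99), "seed")
})

test_that("bonferroni_secondary multiplies and caps", {
  expect_equal(bonferroni_secondary(0.01, 4), 0.04)
  expect_equal(bonferroni_secondary(0.4, 4), 1)
  expect_equal(bonferroni_secondary(c(0.2, 0.7), 1), c(0.2, 0.7))
  expect_error(bonferroni_secondary(0, 4), "p-values")
})

test_that("peak_vertex takes the largest |statistic| with low-index ties", {
  s <- structure(list(t = c(1, -5, 3)), class = "stat_map")
  expect_equal(peak_vertex(s, 1:3), 2L)
  expect_equal(peak_vertex(s, 3), 3L)
  expect_equal(peak_vertex(c(5, 5), 1:2), 1L)
  expect_error(peak_vertex(s, integer(0)), "empty")
})

test_that("parcel_aggregate means per label and drops unlabelled vertices", {
  expect_equal(parcel_aggregate(c(1, 1, 4), c("a", "a", "b"))$value, c(1, 4))
  expect_equal(parcel_aggregate(rep(2, 5), c(1, 1, 2, 2, 2))$value, c(2, 2))
  one <- parcel_aggregate(c(1, 2, 3), rep("all", 3))
  expect_equal(one$value, 2)
  mixed <- parcel_aggregate(c(1, 2, 9), c("a", "a", NA))
  expect_equal(mixed$value, 1.5)
  expect_error(parcel_aggregate(1:3, c(NA, NA, NA)), "no labelled")
})
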