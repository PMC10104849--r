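# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (nested loops, explicit formulas) and never
# call the code paths they check.

# SDI by explicit per-vertex, per-patient, per-control loops.
sdi_oracle <- function(patients, controls) {
  clamp <- 1 - 1e-6
  nv <- nrow(patients$maps[[1]]$power)
  sapply(seq_along(patients$maps), function(p) {
    sapply(seq_len(nv), function(v) {
      prof <- patients$maps[[p]]$power[v, ]
      rs <- numeric(0)
      for (cmap in controls$maps) {
        cp <- cmap$power[v, ]
        if (sd(cp) > 0) rs <- c(rs, cor(prof, cp))
      }
      if (sd(prof) == 0 || length(rs) == 0) return(NA_real_)
      1 - atanh(median(pmin(pmax(rs, -clamp), clamp)))
    })
  })
}

# TFCE by explicit connected-component search at every threshold level,
# matching the discrete level grid h = dh, 2dh, ..., <= max(stat).
tfce_oracle <- function(stat, graph, E, H, dh) {
  ig <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
  miss <- setdiff(seq_len(graph$n_vertices), unique(as.vector(graph$edges)))
  if (length(miss)) ig <- ig + igraph::vertices(miss)
  out <- numeric(length(stat))
  nlev <- floor(max(stat) / dh + 1e-12)
  for (l in seq_len(nlev)) {
    h <- l * dh
    sup <- which(stat >= h)
    if (length(sup) == 0) break
    comp <- igraph::components(igraph::induced_subgraph(ig, sup))
    out[sup] <- out[sup] + comp$csize[comp$membership]^E * h^H * dh
  }
  out
}

# ICC(C,k) from explicit two-way ANOVA sums of squares.
icc_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  ssr <- k * sum((rowMeans(x) - grand)^2)
  ssc <- n * sum((colMeans(x) - grand)^2)
  sse <- sum((x - grand)^2) - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / msr
}

# Random band-averaged cohorts on a shared vertex space.
random_band_cohort <- function(n, nv, seed, role = "control") {
  set.seed(seed)
  sch <- canonical_bands()
  cohort_spectra(lapply(seq_len(n), function(i)
    band_spectral_map(paste0(role, i),
                      matrix(runif(nv * 4, 0.1, 2), nv, 4), sch)),
    role = role)
}

# Compact rectangular patch of a nr x nc lattice, as vertex indices.
lattice_patch <- function(nr, rows, cols) {
  as.vector(outer(rows, (cols - 1) * nr, `+`))
}
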