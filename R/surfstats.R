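#' Surface adjacency graph
#'
#' Undirected vertex adjacency defining neighbourhoods for cluster support in
#' TFCE. Self-loops are rejected; duplicate and reversed duplicates are
#' collapsed.
#'
#' @param n_vertices number of vertices.
#' @param edges two-column integer matrix of 1-based vertex pairs.
#' @return A `surface_graph` object (fields `n_vertices`, `edges`).
#' @export
surface_graph <- function(n_vertices, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 1L) || any(edges > n_vertices))
      stop("edge vertex index out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops not allowed")
    edges <- t(apply(edges, 1, sort))
    edges <- unique(edges)
  }
  structure(list(n_vertices = as.integer(n_vertices), edges = edges),
            class = "surface_graph")
}

#' Rectangular-lattice surface graph
#'
#' 4-connected lattice mesh, a convenient stand-in for a cortical surface in
#' simulations; vertex `(r, c)` has index `(c - 1) * nr + r`.
#'
#' @param nr,nc lattice dimensions.
#' @return A [surface_graph()].
#' @export
lattice_surface_graph <- function(nr, nc) {
  idx <- function(r, c) (c - 1L) * nr + r
  e <- NULL
  for (c in seq_len(nc)) {
    if (nr > 1)
      e <- rbind(e, cbind(idx(seq_len(nr - 1L), c), idx(seq_len(nr - 1L) + 1L, c)))
    if (c < nc)
      e <- rbind(e, cbind(idx(seq_len(nr), c), idx(seq_len(nr), c + 1L)))
  }
  surface_graph(nr * nc, e)
}

.as_igraph <- function(graph) {
  igraph::graph_from_edgelist(graph$edges, directed = FALSE) +
    igraph::vertices(setdiff(seq_len(graph$n_vertices),
                             unique(as.vector(graph$edges))))
}

# Vectorised OLS t-statistics for one coefficient over many outcome vertices.
# Y: subjects x vertices; X: design with intercept; j: tested column.
# Returns list(t, beta, df, capped).
.glm_tstats <- function(Y, X, j, cap = 1e6) {
  XtXi <- chol2inv(chol(crossprod(X)))
  B <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  s2 <- colSums(res^2) / df
  se <- sqrt(s2 * XtXi[j, j])
  t <- B[j, ] / se
  bad <- !is.finite(t) | abs(t) > cap   # zero residual variance
  if (any(bad)) t[bad] <- sign(B[j, bad]) * cap
  list(t = as.numeric(t), beta = as.numeric(B[j, ]), df = df,
       capped = sum(bad))
}

.build_design <- function(design, contrast, data_names = NULL) {
  if (!is.data.frame(design)) stop("design must be a data.frame")
  if (!contrast %in% names(design)) stop("contrast '", contrast,
                                         "' not a design column")
  X <- cbind(`(Intercept)` = 1, as.matrix(design))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  list(X = X, j = match(contrast, colnames(X)))
}

#' Vertex-wise general linear model
#'
#' Ordinary least squares at every vertex: the outcome map is regressed on
#' all design columns (plus an intercept), and the partial t statistic (and
#' its square, an F with 1 numerator df) is reported for the requested
#' contrast column with all other columns — e.g. age — partialled out.
#' Degenerate fits (zero residual variance) are capped at `1e6` and counted.
#'
#' @param maps subjects x vertices numeric matrix.
#' @param design data.frame of predictors, rows aligned with `maps`.
#' @param contrast name of the design column to test.
#' @return A `stat_map` object: fields `t`, `F`, `beta`, `df`, `contrast`,
#'   `n_capped`.
#' @export
vertexwise_glm <- function(maps, design, contrast) {
  maps <- as.matrix(maps)
  if (nrow(maps) != nrow(design)) stop("subjects misaligned between maps and design")
  d <- .build_design(design, contrast)
  if (nrow(maps) < ncol(d$X) + 1L) stop("too few subjects for the design")
  fit <- .glm_tstats(maps, d$X, d$j)
  structure(list(t = fit$t, F = fit$t^2, beta = fit$beta, df = fit$df,
                 contrast = contrast, n_capped = fit$capped),
            class = "stat_map")
}

#' Threshold-free cluster enhancement
#'
#' Integrates cluster extent and height over all thresholds:
#' `enhanced(v) = sum_h extent(v, h)^E * h^H * dh` over
#' `h = dh, 2 dh, ... <= stat(v)`, where `extent(v, h)` is the size of the
#' connected component containing `v` among supra-threshold vertices. No
#' cluster-forming threshold is required. Negative statistics are not
#' accepted here; two-sided maps are handled by enhancing the positive and
#' negated maps separately (see [permutation_fwe()]).
#'
#' @param stat non-negative vertex statistic vector.
#' @param graph a [surface_graph()] on the same vertices.
#' @param E,H extent and height exponents (defaults 1 and 2).
#' @param dh threshold step; default `max(stat) / 100`.
#' @return numeric vector of enhanced values.
#' @export
tfce_enhance <- function(stat, graph, E = 1, H = 2, dh = NULL) {
  stopifnot(inherits(graph, "surface_graph"))
  if (graph$n_vertices < 1L) stop("empty graph")
  if (length(stat) != graph$n_vertices) stop("stat length must equal n_vertices")
  if (E <= 0 || H <= 0) stop("E and H must be > 0")
  if (any(stat < 0)) stop("stat must be non-negative; enhance sides separately")
  if (all(stat == 0)) return(numeric(length(stat)))
  if (is.null(dh)) dh <- max(stat) / 100
  if (dh <= 0) stop("dh must be > 0")
  .tfce_enhance_cpp(stat, graph$edges[, 1] - 1L, graph$edges[, 2] - 1L,
                    E, H, dh)
}

# Signed two-sided enhancement: positive and negated maps enhanced
# separately on a shared dh, recombined on the support of each sign.
.tfce_two_sided <- function(t, graph, E, H, dh) {
  pos <- pmax(t, 0)
  neg <- pmax(-t, 0)
  enh <- numeric(length(t))
  if (any(pos > 0)) enh[t > 0] <- tfce_enhance(pos, graph, E, H, dh)[t > 0]
  if (any(neg > 0)) enh[t < 0] <- tfce_enhance(neg, graph, E, H, dh)[t < 0]
  enh
}

#' Permutation family-wise error correction with TFCE
#'
#' Vertex-wise GLM followed by TFCE and a max-statistic permutation null.
#' Permutation uses the Freedman-Lane scheme: the reduced model (all design
#' columns except the contrast) is fitted, its residuals are permuted across
#' subjects, re-added to the reduced fit, and the full-model statistic is
#' recomputed; the maximum enhanced statistic over vertices is recorded per
#' permutation. Then
#' `p_FWE(v) = (1 + #(perm max >= enhanced(v))) / (n_perm + 1)`, so the
#' smallest attainable p is `1/(n_perm + 1)`. Clusters are connected
#' components of vertices with `p_FWE < alpha`; each cluster's p is the
#' smallest vertex p inside it and its peak vertex carries the largest |t|.
#'
#' @param maps subjects x vertices matrix.
#' @param design data.frame of predictors (covariates included).
#' @param contrast tested design column.
#' @param graph a [surface_graph()].
#' @param E,H TFCE exponents (defaults 1 and 2).
#' @param dh TFCE step; default `max |t| / 100` of the observed map, reused
#'   for every permutation so enhanced values are comparable.
#' @param n_perm number of permutations.
#' @param seed RNG seed (mandatory: permutations are the inference).
#' @param alpha cluster-defining FWE threshold (default 0.05).
#' @param two_sided enhance both signs of t (default TRUE).
#' @return A `tfce_result`: `stat` (the observed `stat_map`), `enhanced`,
#'   `null_max` (permutation distribution), `p_fwe`, `clusters` (list of
#'   vertex index vectors), `cluster_p`, `peak_vertices`, plus the
#'   parameters used.
#' @export
permutation_fwe <- function(maps, design, contrast, graph, E = 1, H = 2,
                            dh = NULL, n_perm = 1000, seed, alpha = 0.05,
                            two_sided = TRUE) {
  if (missing(seed)) stop("seed is required")
  if (n_perm < 1) stop("n_perm must be >= 1")
  maps <- as.matrix(maps)
  d <- .build_design(design, contrast)
  X <- d$X; j <- d$j
  obs <- vertexwise_glm(maps, design, contrast)
  tobs <- obs$t
  if (is.null(dh)) dh <- max(abs(tobs)) / 100
  if (dh <= 0) dh <- 1e-8
  enh_obs <- if (two_sided) .tfce_two_sided(tobs, graph, E, H, dh)
             else tfce_enhance(pmax(tobs, 0), graph, E, H, dh)

  # Freedman-Lane: permute reduced-model residuals
  Z <- X[, -j, drop = FALSE]
  ZtZi <- chol2inv(chol(crossprod(Z)))
  fitZ <- Z %*% (ZtZi %*% crossprod(Z, maps))
  resZ <- maps - fitZ
  n <- nrow(maps)
  # constants reused across permutations
  XtXi <- chol2inv(chol(crossprod(X)))
  Xpinv <- XtXi %*% t(X)
  df <- n - ncol(X)
  vjj <- XtXi[j, j]
  set.seed(seed)
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    Ystar <- fitZ + resZ[sample.int(n), , drop = FALSE]
    B <- Xpinv %*% Ystar
    s2 <- colSums((Ystar - X %*% B)^2) / df
    tp <- B[j, ] / sqrt(s2 * vjj)
    tp[!is.finite(tp)] <- 0
    ep <- if (two_sided) .tfce_two_sided(tp, graph, E, H, dh)
          else tfce_enhance(pmax(tp, 0), graph, E, H, dh)
    null_max[p] <- max(ep)
  }
  p_fwe <- (1 + vapply(enh_obs, function(e) sum(null_max >= e), numeric(1))) /
    (n_perm + 1)

  sig <- which(p_fwe < alpha)
  clusters <- list(); cluster_p <- numeric(0); peaks <- integer(0)
  if (length(sig) > 0) {
    sub <- igraph::induced_subgraph(.as_igraph(graph), sig)
    comp <- igraph::components(sub)$membership
    for (k in seq_len(max(comp))) {
      cl <- sig[comp == k]
      clusters[[k]] <- cl
      cluster_p[k] <- min(p_fwe[cl])
      peaks[k] <- peak_vertex(obs, cl)
    }
    ord <- order(cluster_p)
    clusters <- clusters[ord]; cluster_p <- cluster_p[ord]; peaks <- peaks[ord]
  }
  structure(list(stat = obs, enhanced = enh_obs, null_max = null_max,
                 p_fwe = p_fwe, clusters = clusters, cluster_p = cluster_p,
                 peak_vertices = peaks, E = E, H = H, dh = dh,
                 n_perm = n_perm, seed = seed, alpha = alpha),
            class = "tfce_result")
}

#' Secondary Bonferroni correction across models
#'
#' Applied across cluster p-values when several models test overlapping
#' hypotheses (e.g., four frequency-defined connectivity models):
#' `p_adj = min(1, p * n_models)`.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param n_models number of models compared.
#' @return adjusted p-values.
#' @export
bonferroni_secondary <- function(p_values, n_models) {
  if (n_models < 1) stop("n_models must be >= 1")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0, 1]")
  pmin(1, p_values * n_models)
}

#' Peak vertex of a cluster
#'
#' The vertex with the largest absolute statistic within a mask; ties are
#' broken toward the lowest index.
#'
#' @param stat a `stat_map` from [vertexwise_glm()] or a numeric vector.
#' @param mask integer vertex indices (non-empty).
#' @return 1-based vertex index.
#' @export
peak_vertex <- function(stat, mask) {
  s <- if (inherits(stat, "stat_map")) stat$t else stat
  if (length(mask) == 0L) stop("empty cluster mask")
  mask[which.max(abs(s[mask]))]
}

#' Aggregate a vertex map into parcels
#'
#' Mean value per labelled parcel (e.g., atlas regions of interest).
#' Vertices with `NA` labels are excluded.
#'
#' @param map numeric vertex vector.
#' @param labels parcel label per vertex (`NA` = unlabelled).
#' @return data.frame with columns `parcel`, `value`.
#' @export
parcel_aggregate <- function(map, labels) {
  if (length(map) != length(labels)) stop("map and labels differ in length")
  keep <- !is.na(labels)
  if (!any(keep)) stop("no labelled vertices")
  agg <- tapply(map[keep], labels[keep], mean)
  data.frame(parcel = names(agg), value = as.numeric(agg),
             stringsAsFactors = FALSE)
}
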