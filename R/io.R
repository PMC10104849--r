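# Lightweight checksum for embedding a config fingerprint in outputs
# (no cryptographic intent).
.config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251)) %%
            .Machine$integer.max)
}

#' Read a subject covariate/outcome table
#'
#' Tab-separated, header row, one row per subject. The identifier column
#' must be unique; lines starting with `#` are ignored.
#'
#' @param path TSV file path.
#' @param id_col identifier column name (default `"subject"`).
#' @return data.frame with typed columns.
#' @export
read_subject_table <- function(path, id_col = "subject") {
  d <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                  stringsAsFactors = FALSE)
  if (!id_col %in% names(d))
    stop("missing id column '", id_col, "' in ", path)
  dup <- d[[id_col]][duplicated(d[[id_col]])]
  if (length(dup))
    stop("duplicate subject id(s): ", paste(unique(dup), collapse = ", "))
  d
}

#' Write a table with an embedded provenance header
#'
#' @param d data.frame.
#' @param path output TSV path.
#' @param seed seed to record in the header comment.
#' @param config object whose fingerprint to record.
#' @export
write_subject_table <- function(d, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# specdev seed=%s config_hash=%s", seed,
                     .config_hash(config)), con)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a surface adjacency from a TSV file
#'
#' Accepts either a two-column edge list or a three-column triangle list
#' (each triangle expanded to its three undirected edges). Vertex indices in
#' the file are 0-based, as is conventional for surface mesh formats, and
#' are converted to R's 1-based indexing on read. Duplicate edges are
#' collapsed.
#'
#' @param path TSV path (no header; `#` comments allowed).
#' @param n_vertices total vertex count; default `max index + 1`.
#' @param index_base index base used in the file (default 0).
#' @return A [surface_graph()].
#' @export
read_surface <- function(path, n_vertices = NULL, index_base = 0) {
  d <- read.delim(path, sep = "\t", header = FALSE, comment.char = "#")
  d <- as.matrix(d)
  if (!ncol(d) %in% c(2L, 3L))
    stop("expect a 2-column edge list or 3-column triangle list")
  idx <- d - index_base + 1L
  if (any(idx < 1L)) stop("vertex index below the declared index base")
  edges <- if (ncol(idx) == 2L) idx
           else rbind(idx[, c(1, 2)], idx[, c(2, 3)], idx[, c(1, 3)])
  if (is.null(n_vertices)) n_vertices <- max(idx)
  if (any(idx > n_vertices)) stop("vertex index out of range")
  surface_graph(n_vertices, edges)
}

#' Write SDI maps as TSV
#'
#' One file per patient would be wasteful; all maps go in one long table:
#' `subject`, `vertex` (1-based), `sdi`, `n_controls`.
#'
#' @param sdi_maps list of `sdi_map` from [sdi_map()].
#' @param path output TSV path.
#' @param seed,config provenance recorded in the header comment.
#' @export
write_sdi_tsv <- function(sdi_maps, path, seed = NA, config = NULL) {
  d <- do.call(rbind, lapply(sdi_maps, function(m)
    data.frame(subject = m$subject_id, vertex = seq_along(m$sdi),
               sdi = m$sdi, n_controls = m$n_controls,
               stringsAsFactors = FALSE)))
  write_subject_table(d, path, seed = seed, config = config)
}

#' Run the full simulated analysis pipeline
#'
#' Orchestrates the stages the package exists for, end to end, on a
#' synthetic cohort: cohort generation, SDI mapping, vertex-wise regression
#' of the SDI maps on the impairment rating (age-adjusted) with TFCE
#' permutation correction, peak-vertex extraction, leave-one-band-out
#' contribution analysis at the peak, and bootstrap mediation
#' (severity -> peak SDI -> rating). When per-subject, per-band seeded
#' connectivity maps are supplied, each band is tested with the same
#' TFCE machinery and the secondary Bonferroni correction is applied across
#' the band models' cluster p-values.
#'
#' Deterministic given the seeds in `config`; stage failures abort with the
#' stage name.
#'
#' @param config list with elements `cohort` (a [cohort_spec()]), `graph`
#'   (a [surface_graph()]), `n_perm`, `seed`, optional `E`, `H`, `alpha`,
#'   `n_boot`, `conn_maps` (named list per band of subjects x vertices
#'   matrices), `out_dir` (when set, TSV artifacts are written there).
#' @return list with `sdi_maps`, `summary`, `tfce`, `peak`, `loo`,
#'   `mediation`, and (when requested) `connectivity`.
#' @export
run_pipeline <- function(config) {
  need <- c("cohort", "graph", "n_perm", "seed")
  if (!all(need %in% names(config)))
    stop("config requires: ", paste(setdiff(need, names(config)), collapse = ", "))
  if (!is.null(config$out_dir) && !dir.exists(config$out_dir))
    stop("pre-flight: output directory does not exist: ", config$out_dir)
  if (config$graph$n_vertices != config$cohort$n_vertices)
    stop("pre-flight: graph and cohort vertex counts differ")
  E <- config$E %||% 1; H <- config$H %||% 2
  alpha <- config$alpha %||% 0.05
  n_boot <- config$n_boot %||% 1000

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sim <- stage("simulate", gen_cohort(config$cohort))
  maps <- stage("sdi", sdi_map(sim$patients, sim$controls))
  smry <- cohort_summary(maps)
  Y <- t(vapply(maps, function(m) m$sdi, numeric(config$graph$n_vertices)))
  design <- sim$outcome[, c("rating", "age")]
  tf <- stage("tfce", permutation_fwe(Y, design, "rating", config$graph,
                                      E = E, H = H, n_perm = config$n_perm,
                                      seed = config$seed, alpha = alpha))
  peak <- if (length(tf$peak_vertices)) tf$peak_vertices[1]
          else peak_vertex(tf$stat, seq_len(config$graph$n_vertices))
  loo <- stage("loo", loo_band_contribution(sim$patients, sim$controls, peak,
                                            sim$outcome))
  med <- stage("mediation", {
    sdi_peak <- vapply(maps, function(m) m$sdi[peak], numeric(1))
    mediate(sim$outcome$severity, sdi_peak, sim$outcome$rating,
            covariates = sim$outcome["age"], n_boot = n_boot,
            seed = config$seed + 1L)
  })
  conn <- NULL
  if (!is.null(config$conn_maps)) {
    conn <- stage("connectivity", {
      res <- lapply(config$conn_maps, function(cm)
        permutation_fwe(cm, design, "rating", config$graph, E = E, H = H,
                        n_perm = config$n_perm, seed = config$seed + 2L,
                        alpha = alpha))
      band_p <- vapply(res, function(r)
        if (length(r$cluster_p)) min(r$cluster_p) else 1, numeric(1))
      list(per_band = res,
           cluster_p = band_p,
           cluster_p_bonferroni = bonferroni_secondary(band_p,
                                                      length(band_p)))
    })
  }
  if (!is.null(config$out_dir)) {
    write_sdi_tsv(maps, file.path(config$out_dir, "sdi_maps.tsv"),
                  seed = config$seed, config = config)
    write_subject_table(sim$outcome,
                        file.path(config$out_dir, "outcome.tsv"),
                        seed = config$seed, config = config)
    write_subject_table(loo, file.path(config$out_dir, "loo_bands.tsv"),
                        seed = config$seed, config = config)
  }
  list(sdi_maps = maps, summary = smry, tfce = tf, peak = peak, loo = loo,
       mediation = med, connectivity = conn,
       config_hash = .config_hash(config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
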