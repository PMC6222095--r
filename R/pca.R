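#' Principal-component clustering of a conformer ensemble
#'
#' Superposes every model onto the first over the topology's reference
#' domains (the structurally central block), assembles the alpha-carbon
#' coordinate matrix, eigendecomposes its covariance, projects onto the
#' first three principal components, and partitions the models into k
#' groups by k-means on those scores (20 restarts under a fixed seed,
#' best inertia kept). Each group's centroid is the member model closest
#' to the group mean in PC space, i.e. the group's representative
#' structure.
#'
#' @param ensemble a `conformer_library` or list of `coord_model`s.
#' @param topology a `chain_topology` providing `reference_domains`.
#' @param k number of groups (default 4).
#' @param n_pc number of components used for clustering (default 3).
#' @param seed k-means RNG seed.
#' @return list of class `pca_report`: `eigenvalues`,
#'   `variance_fractions`, `cumulative_3pc`, `scores` (models x n_pc),
#'   `groups` (integer assignment), `centroid_ids` (model id per group),
#'   `degenerate` (TRUE when the ensemble has ~zero variance).
#' @export
pca_cluster <- function(ensemble, topology, k = 4, n_pc = 3, seed = 1L) {
  models <- if (inherits(ensemble, "conformer_library"))
    lapply(seq_len(length(ensemble)), function(i) library_model(ensemble, i))
  else ensemble
  n <- length(models)
  if (n < k) stop("k exceeds the number of models")
  ref <- models[[1]]
  ca_sel <- function(m) {
    idx <- which(m$atoms$calpha & !m$atoms$glycan)
    idx[order(m$atoms$resno[idx])]
  }
  idx0 <- ca_sel(ref)
  X <- matrix(NA_real_, n, 3 * length(idx0))
  for (i in seq_len(n)) {
    m <- models[[i]]
    sup <- kabsch_superpose(m, ref, topology$reference_domains)
    m <- apply_superposition(m, sup)
    X[i, ] <- as.vector(t(m$xyz[ca_sel(m), , drop = FALSE]))
  }
  total_var <- sum(apply(X, 2, var))
  if (total_var < 1e-8) {
    return(structure(list(
      eigenvalues = rep(0, n_pc), variance_fractions = rep(NA_real_, n_pc),
      cumulative_3pc = NA_real_, scores = matrix(0, n, n_pc),
      groups = rep(1L, n), centroid_ids = c(1L, rep(NA_integer_, k - 1)),
      model_ids = seq_len(n), degenerate = TRUE
    ), class = "pca_report"))
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  vf <- ev / sum(ev)
  scores <- pc$x[, seq_len(min(n_pc, ncol(pc$x))), drop = FALSE]

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  km <- kmeans(scores, centers = k, nstart = 20, iter.max = 100)

  ids <- if (inherits(ensemble, "conformer_library"))
    ensemble$meta$model_id else seq_len(n)
  centroid_ids <- vapply(seq_len(k), function(g) {
    members <- which(km$cluster == g)
    d2 <- rowSums(sweep(scores[members, , drop = FALSE], 2,
                        km$centers[g, ])^2)
    ids[members[which.min(d2)]]
  }, integer(1))
  structure(list(
    eigenvalues = ev,
    variance_fractions = vf,
    cumulative_3pc = sum(vf[seq_len(min(3, length(vf)))]),
    scores = scores,
    groups = km$cluster,
    centroid_ids = centroid_ids,
    model_ids = ids,
    degenerate = FALSE
  ), class = "pca_report")
}

#' @export
print.pca_report <- function(x, ...) {
  if (x$degenerate) {
    cat("pca_report: degenerate ensemble (zero variance)\n")
  } else {
    cat(sprintf(
      "pca_report: %d models, %d groups; first 3 PCs carry %.1f%% variance\n",
      nrow(x$scores), length(x$centroid_ids), 100 * x$cumulative_3pc))
  }
  invisible(x)
}
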