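#' Scaled-down two-conformation recovery experiment
#'
#' Runs the full inference chain at desk scale: builds the synthetic
#' 20-domain chain and its two folded-back archetypes, generates a
#' conformer library by torsion-angle Monte Carlo started from each
#' archetype, synthesizes noisy target curves from the N-terminally
#' extended archetype, the C-terminally extended archetype, and their
#' 50:50 mixture, then for each target applies the dual Rg/R-factor
#' filter and best-100 ranking and classifies the resulting ensemble by
#' its terminal separations. Model curves are computed once on the shared
#' Q grid with the golden-ratio orientational engine and reused across
#' targets.
#'
#' @param n_steps total Monte Carlo steps per archetype (split over the
#'   restarts).
#' @param n_restarts independent restarted runs per archetype, mirroring
#'   the restart protocol used to build real conformer libraries; each
#'   restart begins at the archetype with a fresh seed.
#' @param seed master seed; all randomness derives from it.
#' @param noise relative noise applied to the target curves.
#' @param q_grid Q grid for scoring, 1/nm.
#' @param n_orientations orientations for the scoring engine.
#' @param n_best best-fit ensemble size.
#' @param max_step_deg Monte Carlo step size in degrees.
#' @return list with the library, per-target fit tables, best ensembles,
#'   classification fractions, and the mixture-target PCA split.
#' @export
two_state_benchmark <- function(n_steps = 2500, seed = 1L, noise = 0.02,
                                q_grid = seq(0.02, 1.5, by = 0.03),
                                n_orientations = 150, n_best = 100,
                                max_step_deg = 30, n_restarts = 5) {
  topo <- fh_topology()
  chain <- build_scr_chain(topo, seed = seed)
  arch_nt <- make_archetype(chain, "NT-extended", topo, seed = seed)
  arch_ct <- make_archetype(chain, "CT-extended", topo, seed = seed)

  per_run <- max(1L, as.integer(n_steps / n_restarts))
  runs <- list()
  for (r in seq_len(n_restarts)) {
    runs[[length(runs) + 1]] <- run_tamc(
      tamc_config(arch_nt, topo, n_steps = per_run,
                  max_step_deg = max_step_deg, seed = seed + 100L * r))
    runs[[length(runs) + 1]] <- run_tamc(
      tamc_config(arch_ct, topo, n_steps = per_run,
                  max_step_deg = max_step_deg,
                  seed = seed + 100L * r + 50L))
  }
  lib <- merge_libraries(runs)
  ## odd run ids started from the NT archetype, even ids from the CT one
  lib$meta$start <- ifelse(lib$meta$run %% 2 == 1, "NT", "CT")

  make_target <- function(model, label, sub_seed) {
    base <- debye_curve(model, q_grid)
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(sub_seed)
    sg <- noise * base$intensity
    scattering_curve(q_grid, base$intensity + rnorm(length(q_grid), 0, sg),
                     sigma = sg, label = label)
  }
  t_nt <- make_target(arch_nt, "target NT-extended", seed + 11L)
  t_ct <- make_target(arch_ct, "target CT-extended", seed + 12L)
  base_nt <- debye_curve(arch_nt, q_grid)$intensity
  base_ct <- debye_curve(arch_ct, q_grid)$intensity
  mix <- 0.5 * base_nt + 0.5 * base_ct
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed + 13L)
  sg <- noise * mix
  t_mix <- scattering_curve(q_grid, mix + rnorm(length(q_grid), 0, sg),
                            sigma = sg, label = "target 50:50 mixture")
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  targets <- list(nt = t_nt, ct = t_ct, mix = t_mix)
  exp_rg <- lapply(targets, function(tc) guinier_fit(tc)$rg)

  ## compute model curves once, for every model inside any target's window
  need <- rep(FALSE, length(lib))
  for (rg in exp_rg)
    need <- need | abs(lib$meta$rg_nm - rg) <= 0.05 * rg
  curves <- library_curves(lib, q_grid, subset = which(need),
                           engine = "golden",
                           n_orientations = n_orientations)

  seps <- library_separations(lib)
  out <- list(library = lib, separations = seps, targets = targets,
              experimental_rg = exp_rg)
  for (nm in names(targets)) {
    fits <- fit_library(lib, targets[[nm]], exp_rg[[nm]],
                        model_curves = curves)
    filt <- filter_library(fits, exp_rg[[nm]])
    best <- rank_best(filt, n_best)
    cls <- classify_conformation(seps$nt_com[best$model_id],
                                 seps$ct_com[best$model_id])
    out[[paste0("fits_", nm)]] <- fits
    out[[paste0("best_", nm)]] <- best
    out[[paste0("class_", nm)]] <- cls
    out[[paste0("frac_nt_", nm)]] <- mean(cls == "NT-extended")
    out[[paste0("frac_ct_", nm)]] <- mean(cls == "CT-extended")
  }

  ## mixture target: split the best ensemble into two PCA clusters and
  ## compare their CT-COM separations
  best_mix_lib <- conformer_library(lib$template,
                                    lib$xyz[out$best_mix$model_id])
  pca <- pca_cluster(best_mix_lib, fh_topology(), k = 2, seed = seed)
  ct_by_group <- split(seps$ct_com[out$best_mix$model_id], pca$groups)
  out$mix_pca <- pca
  out$mix_ct_group_means <- vapply(ct_by_group, mean, numeric(1))
  out$mix_group_sizes <- vapply(ct_by_group, length, numeric(1))
  out
}
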