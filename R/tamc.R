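#' Torsion-angle Monte Carlo configuration
#'
#' @param start_model clash-free `coord_model` to start from.
#' @param topology `chain_topology` defining the movable linkers.
#' @param n_steps number of attempted moves.
#' @param max_step_deg maximum torsion perturbation per move, in degrees
#'   (draws are uniform in +-max_step_deg). Typical protocols use 30 for
#'   local searches and 180 for wide ones.
#' @param clash_cutoff steric cutoff in angstroms passed to
#'   [check_clashes()].
#' @param exclude_cys_flanks never rotate the torsions flanking the
#'   conserved cysteines at the linker ends.
#' @param seed integer RNG seed; runs are bit-reproducible given the
#'   config.
#' @return object of class `tamc_config`.
#' @export
tamc_config <- function(start_model, topology = fh_topology(),
                        n_steps = 1000L, max_step_deg = 30,
                        clash_cutoff = 2.2, exclude_cys_flanks = TRUE,
                        seed = 1L) {
  stopifnot(n_steps >= 1, max_step_deg > 0, max_step_deg <= 180)
  structure(list(start_model = start_model, topology = topology,
                 n_steps = as.integer(n_steps), max_step_deg = max_step_deg,
                 clash_cutoff = clash_cutoff,
                 exclude_cys_flanks = exclude_cys_flanks,
                 seed = as.integer(seed)),
            class = "tamc_config")
}

## Rodrigues rotation of points about the line (origin a, unit axis u).
.rotate_about_axis <- function(xyz, a, u, theta) {
  p <- sweep(xyz, 2, a)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  sweep(tcrossprod(p, R), 2, -a)
}

#' Apply a single backbone torsion move
#'
#' Rotates everything C-terminal of the chosen backbone bond rigidly about
#' the bond axis; glycans ride with their attached protein segment. Bond
#' lengths and angles are untouched, so pairwise distances within the
#' static and within the moving segment are preserved exactly.
#'
#' At pseudo-atom (one bead per residue) resolution the phi axis of
#' residue r is the bead(r-1) to bead(r) virtual bond, moving residues r
#' and beyond; the psi axis is bead(r) to bead(r+1), moving residues r+1
#' and beyond.
#'
#' @param model a `coord_model`.
#' @param residue residue number inside a movable linker.
#' @param angle_kind `"phi"` or `"psi"`.
#' @param delta_deg signed rotation in degrees.
#' @param topology `chain_topology` (used to validate the residue).
#' @param exclude_cys_flanks validate against the flank-excluded residue
#'   set.
#' @return the moved `coord_model`.
#' @export
apply_torsion_move <- function(model, residue, angle_kind = c("phi", "psi"),
                               delta_deg, topology = fh_topology(),
                               exclude_cys_flanks = TRUE) {
  angle_kind <- match.arg(angle_kind)
  ok <- movable_residues(topology, exclude_cys_flanks)
  if (!(residue %in% ok))
    stop("residue ", residue, " is not inside a movable linker")
  resno <- model$atoms$resno
  ca <- model$atoms$calpha & !model$atoms$glycan
  bead <- function(r) {
    i <- which(ca & resno == r)
    if (length(i) != 1) stop("no unique alpha-carbon bead for residue ", r)
    model$xyz[i, ]
  }
  if (angle_kind == "phi") {
    a <- bead(residue - 1L); b <- bead(residue)
    moving <- resno >= residue
  } else {
    a <- bead(residue); b <- bead(residue + 1L)
    moving <- resno >= residue + 1L
  }
  u <- b - a
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) stop("degenerate rotation axis at residue ", residue)
  u <- u / nu
  model$xyz[moving, ] <- .rotate_about_axis(
    model$xyz[moving, , drop = FALSE], a, u, delta_deg * pi / 180)
  model
}

#' Run a torsion-angle Monte Carlo simulation
#'
#' Each step picks a uniformly random movable-linker residue and angle
#' kind, draws a perturbation uniform in +-max_step_deg, applies it, and
#' accepts the move if and only if the structure is clash-free; rejected
#' moves are reverted. Acceptance is purely geometric: there is no energy
#' function. Every accepted model is stored with its step index.
#'
#' @param config a `tamc_config`.
#' @return a list of class `tamc_run` with `library` (a
#'   `conformer_library`), `n_attempted`, `n_accepted`, `acceptance_rate`
#'   and `seed`.
#' @export
run_tamc <- function(config) {
  stopifnot(inherits(config, "tamc_config"))
  model <- config$start_model
  if (check_clashes(model, config$clash_cutoff) > 0)
    stop("start model is not clash-free at the configured cutoff")
  res_pool <- movable_residues(config$topology, config$exclude_cys_flanks)
  if (length(res_pool) == 0) stop("no movable residues in topology")

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)

  accepted_xyz <- vector("list", config$n_steps)
  accepted_step <- integer(config$n_steps)
  n_acc <- 0L
  resno <- model$atoms$resno
  for (step in seq_len(config$n_steps)) {
    r <- res_pool[sample.int(length(res_pool), 1)]
    kind <- if (runif(1) < 0.5) "phi" else "psi"
    delta <- runif(1, -config$max_step_deg, config$max_step_deg)
    cand <- apply_torsion_move(model, r, kind, delta, config$topology,
                               config$exclude_cys_flanks)
    if (cpp_clash_count(cand$xyz, resno, config$clash_cutoff, 2L) == 0L) {
      model <- cand
      n_acc <- n_acc + 1L
      accepted_xyz[[n_acc]] <- cand$xyz
      accepted_step[n_acc] <- step
    }
  }
  lib <- conformer_library(
    template = config$start_model,
    xyz_list = accepted_xyz[seq_len(n_acc)],
    meta = data.frame(step = accepted_step[seq_len(n_acc)],
                      run = 1L)
  )
  structure(list(library = lib, n_attempted = config$n_steps,
                 n_accepted = n_acc,
                 acceptance_rate = n_acc / config$n_steps,
                 seed = config$seed),
            class = "tamc_run")
}

#' A library of conformers sharing one topology
#'
#' Stores one template model (atom metadata) plus a coordinate set per
#' conformer and a metadata table (model id, run, step, radius of
#' gyration in nm).
#'
#' @param template a `coord_model` supplying the atom table.
#' @param xyz_list list of n x 3 coordinate matrices (angstrom).
#' @param meta data.frame with one row per conformer.
#' @return object of class `conformer_library`.
#' @export
conformer_library <- function(template, xyz_list, meta = NULL) {
  n <- length(xyz_list)
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(n))
  meta$model_id <- seq_len(n)
  w <- template$atoms$mass
  meta$rg_nm <- vapply(xyz_list, function(x) {
    com <- drop(crossprod(x, w)) / sum(w)
    sqrt(sum(w * rowSums(sweep(x, 2, com)^2)) / sum(w)) / 10
  }, numeric(1))
  structure(list(template = template, xyz = xyz_list, meta = meta),
            class = "conformer_library")
}

#' @export
length.conformer_library <- function(x) length(x$xyz)

#' Extract one conformer as a full coordinate model
#' @param library a `conformer_library`.
#' @param i model index.
#' @return a `coord_model`.
#' @export
library_model <- function(library, i) {
  m <- library$template
  m$xyz <- library$xyz[[i]]
  m$label <- sprintf("model %d", library$meta$model_id[i])
  m$provenance <- list(model_id = library$meta$model_id[i],
                       run = library$meta$run[i])
  m
}

#' @export
print.conformer_library <- function(x, ...) {
  cat(sprintf("conformer_library: %d models, Rg %.2f-%.2f nm\n",
              length(x), min(x$meta$rg_nm), max(x$meta$rg_nm)))
  invisible(x)
}

#' Merge the accepted libraries of several runs
#'
#' Concatenates libraries without deduplication (chained restarts may
#' legitimately revisit conformations); per-run provenance is kept in the
#' `run` column.
#'
#' @param runs list of `tamc_run` or `conformer_library` objects sharing a
#'   topology (same atom count and residue numbering).
#' @return a combined `conformer_library`.
#' @export
merge_libraries <- function(runs) {
  libs <- lapply(runs, function(r) if (inherits(r, "tamc_run")) r$library else r)
  ref <- libs[[1]]$template$atoms$resno
  for (l in libs)
    if (!identical(l$template$atoms$resno, ref) ||
        nrow(l$template$xyz) != nrow(libs[[1]]$template$xyz))
      stop("libraries have mismatched topologies and cannot be merged")
  xyz <- do.call(c, lapply(libs, `[[`, "xyz"))
  run_of <- rep(seq_along(libs), vapply(libs, length, 0L))
  step <- do.call(c, lapply(libs, function(l)
    if ("step" %in% names(l$meta)) l$meta$step else rep(NA_integer_, length(l))))
  conformer_library(libs[[1]]$template, xyz,
                    data.frame(step = step, run = run_of))
}

#' Write a library to a directory of PDB files plus a TSV manifest
#'
#' @param library a `conformer_library`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_library <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(length(library))) {
    write_pdb(library_model(library, i),
              file.path(dir, sprintf("model_%05d.pdb", i)))
  }
  manifest <- file.path(dir, "manifest.tsv")
  write.table(library$meta, manifest, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(manifest)
}
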