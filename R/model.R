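#' Construct a coordinate model
#'
#' A `coord_model` is the unit that is sampled, scored and measured: an
#' ordered set of (pseudo-)atoms with masses, residue numbers, domain
#' assignments and Cartesian coordinates. Internally all coordinates are in
#' angstroms; reported structural parameters (radius of gyration,
#' separations) are in nanometres.
#'
#' @param xyz numeric n x 3 matrix of coordinates in angstroms.
#' @param element character vector of element symbols (used for masses
#'   unless `mass` is supplied).
#' @param resno integer vector of 1-based residue numbers, non-decreasing.
#' @param domain integer vector of domain ids (NA for glycan atoms).
#' @param calpha logical vector flagging the alpha-carbon (or backbone bead)
#'   of each protein residue.
#' @param backbone logical vector flagging backbone atoms.
#' @param glycan logical vector flagging glycan atoms.
#' @param mass optional numeric vector of masses in daltons.
#' @param label free-text model label.
#' @param provenance list recording how the model was generated (seed,
#'   generating move, parent run).
#' @return an object of class `coord_model`.
#' @export
coord_model <- function(xyz, element, resno, domain = NA_integer_,
                        calpha = TRUE, backbone = TRUE, glycan = FALSE,
                        mass = NULL, label = "", provenance = list()) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must have 3 columns")
  n <- nrow(xyz)
  if (n < 1) stop("a model needs at least one atom")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (is.null(mass)) mass <- element_mass(element)
  if (any(mass <= 0)) stop("all masses must be positive")
  atoms <- data.frame(
    element = toupper(trimws(rep_len(element, n))),
    mass = rep_len(mass, n),
    resno = as.integer(rep_len(resno, n)),
    domain = as.integer(rep_len(domain, n)),
    backbone = rep_len(backbone, n),
    calpha = rep_len(calpha, n),
    glycan = rep_len(glycan, n),
    stringsAsFactors = FALSE
  )
  if (is.unsorted(atoms$resno)) stop("residue numbers must be non-decreasing")
  ca_res <- atoms$resno[atoms$calpha & !atoms$glycan]
  if (anyDuplicated(ca_res)) stop("more than one alpha-carbon in a residue")
  structure(
    list(xyz = unname(xyz), atoms = atoms, label = label,
         provenance = provenance),
    class = "coord_model"
  )
}

#' @export
print.coord_model <- function(x, ...) {
  cat(sprintf("coord_model '%s': %d atoms, %d residues, mass %.1f kDa, Rg %.2f nm\n",
              x$label, nrow(x$xyz), length(unique(x$atoms$resno)),
              sum(x$atoms$mass) / 1000, coordinate_rg(x)))
  invisible(x)
}

#' Total molar mass of a model
#' @param model a `coord_model`.
#' @return mass in kilodaltons.
#' @export
model_mass_kda <- function(model) sum(model$atoms$mass) / 1000

.resolve_subset <- function(model, subset) {
  if (is.null(subset)) return(rep(TRUE, nrow(model$xyz)))
  if (is.function(subset)) subset <- subset(model$atoms)
  if (is.numeric(subset)) {
    keep <- rep(FALSE, nrow(model$xyz))
    keep[subset] <- TRUE
    subset <- keep
  }
  if (!any(subset)) stop("subset selects no atoms")
  subset
}

#' Mass-weighted centre of mass
#'
#' @param model a `coord_model`.
#' @param subset optional atom selection: logical vector, integer indices,
#'   or a predicate `function(atoms)` returning a logical vector.
#' @return length-3 numeric vector in angstroms.
#' @export
center_of_mass <- function(model, subset = NULL) {
  keep <- .resolve_subset(model, subset)
  w <- model$atoms$mass[keep]
  drop(crossprod(model$xyz[keep, , drop = FALSE], w)) / sum(w)
}

#' Mass-weighted radius of gyration from coordinates
#'
#' sqrt(sum_i m_i |r_i - COM|^2 / sum_i m_i), reported in nanometres.
#'
#' @inheritParams center_of_mass
#' @return radius of gyration in nm.
#' @export
coordinate_rg <- function(model, subset = NULL) {
  keep <- .resolve_subset(model, subset)
  if (sum(keep) < 2) {
    warning("single-atom model: Rg is 0")
    return(0)
  }
  w <- model$atoms$mass[keep]
  xyz <- model$xyz[keep, , drop = FALSE]
  com <- drop(crossprod(xyz, w)) / sum(w)
  d2 <- rowSums(sweep(xyz, 2, com)^2)
  sqrt(sum(w * d2) / sum(w)) / 10  # angstrom -> nm
}

#' Apply a rigid transform to a model
#'
#' @param model a `coord_model`.
#' @param rotation 3 x 3 rotation matrix (applied on the left).
#' @param translation length-3 vector in angstroms.
#' @return the transformed `coord_model`.
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  model$xyz <- sweep(tcrossprod(model$xyz, rotation), 2, -translation)
  model
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' matched alpha-carbons of two models over a residue-number range.
#' Reflections are excluded by construction.
#'
#' @param mobile,reference `coord_model` objects.
#' @param selection residue-number range `c(first, last)` or NULL for all
#'   shared alpha-carbon residues.
#' @return a list of class `superposition` with elements `rotation` (3 x 3),
#'   `translation` (angstrom 3-vector; the transform is `R x + t`) and
#'   `rmsd` (angstroms over the selection).
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  sel_ca <- function(m) {
    keep <- m$atoms$calpha & !m$atoms$glycan
    if (!is.null(selection))
      keep <- keep & m$atoms$resno >= selection[1] & m$atoms$resno <= selection[2]
    idx <- which(keep)
    idx[order(m$atoms$resno[idx])]
  }
  im <- sel_ca(mobile); ir <- sel_ca(reference)
  common <- intersect(mobile$atoms$resno[im], reference$atoms$resno[ir])
  im <- im[match(common, mobile$atoms$resno[im])]
  ir <- ir[match(common, reference$atoms$resno[ir])]
  if (length(im) < 3 || length(ir) < 3)
    stop(sprintf("superposition needs >=3 matched atoms (got %d and %d)",
                 length(im), length(ir)))
  P <- mobile$xyz[im, , drop = FALSE]
  Q <- reference$xyz[ir, , drop = FALSE]
  pbar <- colMeans(P); qbar <- colMeans(Q)
  H <- crossprod(sweep(P, 2, pbar), sweep(Q, 2, qbar))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- qbar - drop(R %*% pbar)
  moved <- sweep(tcrossprod(P, R), 2, -t)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition result to a model
#' @param model a `coord_model`.
#' @param sup a `superposition` from [kabsch_superpose()].
#' @return the transformed model.
#' @export
apply_superposition <- function(model, sup) {
  transform_model(model, sup$rotation, sup$translation)
}

#' Count steric clashes
#'
#' Number of heavy-atom pairs closer than `cutoff` whose residues are at
#' least `min_resno_sep` apart in sequence (so bonded and adjacent residues
#' never count). Zero clashes means the conformation is accepted as
#' physically realistic.
#'
#' @param model a `coord_model`.
#' @param cutoff contact distance in angstroms (default 2.2, a conservative
#'   hard-sphere heavy-atom contact).
#' @param min_resno_sep minimum residue separation for a pair to count.
#' @return integer clash count.
#' @export
check_clashes <- function(model, cutoff = 2.2, min_resno_sep = 2) {
  if (cutoff <= 0) stop("cutoff must be positive")
  cpp_clash_count(model$xyz, model$atoms$resno, cutoff, min_resno_sep)
}
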