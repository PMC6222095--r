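#' Read a coordinate model from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), assigns masses from the element
#' table, flags alpha-carbons and backbone atoms, and (when a topology is
#' given) labels each residue with its domain. HETATM records are treated
#' as glycan/ligand atoms. Hydrogens are dropped: the package works at
#' heavy-atom resolution.
#'
#' @param path PDB file path.
#' @param topology optional `chain_topology` used to assign domain ids.
#' @return a `coord_model`.
#' @export
read_pdb <- function(path, topology = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  elesy <- at$elesy
  guess <- toupper(substr(trimws(at$elety), 1, 1))
  element <- ifelse(is.na(elesy) | trimws(elesy) == "", guess, trimws(elesy))
  keep <- toupper(element) != "H"
  at <- at[keep, , drop = FALSE]
  element <- element[keep]
  mass <- element_mass(element)  # errors listing any unknown symbol
  resno <- as.integer(at$resno)
  glycan <- at$type == "HETATM"
  domain <- if (!is.null(topology)) domain_of_residue(topology, resno)
            else rep(NA_integer_, length(resno))
  domain[glycan] <- NA_integer_
  coord_model(
    xyz = cbind(at$x, at$y, at$z),
    element = element,
    resno = resno,
    domain = domain,
    calpha = trimws(at$elety) == "CA" & !glycan,
    backbone = trimws(at$elety) %in% c("N", "CA", "C", "O") & !glycan,
    glycan = glycan,
    mass = mass,
    label = basename(path),
    provenance = list(source = path)
  )
}

#' Write a coordinate model to a PDB file
#'
#' Protein atoms are written as ATOM records, glycan atoms as HETATM.
#' Round-tripping through [read_pdb()] preserves coordinates to the PDB
#' format precision of 0.001 angstrom.
#'
#' @param model a `coord_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  n <- nrow(a)
  elety <- ifelse(a$calpha & !a$glycan, "CA", a$element)
  resid <- ifelse(a$glycan, "NAG", "GLY")
  type <- ifelse(a$glycan, "HETATM", "ATOM")
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.vector(t(model$xyz)),
    type = type,
    resno = a$resno, resid = resid,
    eleno = seq_len(n), elety = elety,
    chain = rep("A", n), elesy = a$element,
    end = TRUE
  )
  invisible(path)
}
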