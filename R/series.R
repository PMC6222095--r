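#' Specification of a synthetic SAXS concentration series
#'
#' Defines the ground truth for a simulated dilution series of a
#' self-associating monomer: the monomer model, the monomer-dimer
#' dissociation constant, the concentrations measured, and a synchrotron
#' noise model sigma(I)/I = a + b*Q.
#'
#' @param monomer_model a `coord_model` for the monomer.
#' @param kd_dimer dissociation constant in uM (Inf = no association).
#' @param concentrations mg/ml; the default mirrors a typical 5-point
#'   dilution series between 0.4 and 3.3 mg/ml.
#' @param molar_mass monomer molar mass in kDa (default: from the model).
#' @param q_grid Q values in 1/nm.
#' @param noise_a,noise_b relative-error model coefficients (b in nm).
#' @param seed RNG seed for the noise draws.
#' @return object of class `series_spec`.
#' @export
synthetic_series_spec <- function(monomer_model, kd_dimer = 28,
                                  concentrations = c(0.4, 0.7, 1.1, 2.2, 3.3),
                                  molar_mass = NULL,
                                  q_grid = seq(0.02, 1.5, by = 0.02),
                                  noise_a = 0.01, noise_b = 0.02,
                                  seed = 1L) {
  stopifnot(all(concentrations > 0), kd_dimer > 0, all(diff(q_grid) > 0))
  if (is.null(molar_mass)) molar_mass <- model_mass_kda(monomer_model)
  structure(list(monomer_model = monomer_model, kd_dimer = kd_dimer,
                 concentrations = concentrations, molar_mass = molar_mass,
                 q_grid = q_grid, noise_a = noise_a, noise_b = noise_b,
                 seed = as.integer(seed)),
            class = "series_spec")
}

#' Build a schematic side-by-side dimer of a monomer model
#'
#' Two copies related by a two-fold axis placed just beyond the C-terminal
#' domain, leaving a ~2 nm gap between the two C-terminal domains. The
#' geometry is deliberately schematic: it provides a rigid, plausible
#' dimer scattering curve for testing the concentration-extrapolation
#' machinery, not a structural model of the dimer interface.
#'
#' @param monomer a `coord_model`.
#' @param gap_nm gap between the monomer C-terminal domains.
#' @return a `coord_model` with doubled atoms (second copy's residue
#'   numbers offset by the monomer's residue count).
#' @export
make_dimer <- function(monomer, gap_nm = 2) {
  at <- monomer$atoms
  last_dom <- max(at$domain, na.rm = TRUE)
  ct_idx <- which(at$domain == last_dom)
  ct_com <- center_of_mass(monomer, ct_idx)
  com <- center_of_mass(monomer)
  d <- ct_com - com
  d[3] <- 0                     # keep the C2 axis construction planar
  d <- d / sqrt(sum(d^2))
  pivot <- ct_com + d * (10 * gap_nm / 2 + 10)  # angstrom
  # 180-degree rotation about the z axis through `pivot`
  R <- diag(c(-1, -1, 1))
  copy <- transform_model(monomer, R, pivot - drop(R %*% pivot))
  xyz <- rbind(monomer$xyz, copy$xyz)
  nres <- max(at$resno)
  coord_model(
    xyz = xyz,
    element = c(at$element, at$element),
    resno = c(at$resno, at$resno + nres),
    domain = c(at$domain, at$domain),
    calpha = c(at$calpha, at$calpha),
    backbone = c(at$backbone, at$backbone),
    glycan = c(at$glycan, at$glycan),
    mass = c(at$mass, at$mass),
    label = paste("synthetic dimer of", monomer$label),
    provenance = list(generator = "make_dimer", gap_nm = gap_nm)
  )
}

#' Precompute the monomer and dimer base curves for a series spec
#'
#' @param spec a `series_spec`.
#' @return list with `monomer` and `dimer` scattering curves (exact Debye).
#' @export
series_base_curves <- function(spec) {
  list(monomer = debye_curve(spec$monomer_model, spec$q_grid),
       dimer = debye_curve(make_dimer(spec$monomer_model), spec$q_grid))
}

#' Simulate a noisy SAXS concentration series
#'
#' For each concentration the monomer and dimer curves are mixed according
#' to the monomer-dimer equilibrium at the Kd in `spec` and normalized per
#' unit concentration, so that I(0) is proportional to the weight-average
#' molar mass (exactly, when noise is zero) and increases with
#' concentration whenever Kd is finite. Gaussian noise with
#' sigma(Q) = (a + b*Q) * I(Q) is then added and stored in the curves'
#' sigma column. Bit-reproducible given (spec, seed).
#'
#' @param spec a `series_spec`.
#' @param base optional precomputed [series_base_curves()] result (saves
#'   recomputing the Debye sums across many seeds).
#' @return list of `scattering_curve`, one per concentration.
#' @export
simulate_series <- function(spec, base = NULL) {
  if (is.null(base)) base <- series_base_curves(spec)
  q <- spec$q_grid
  Im <- base$monomer$intensity
  Id <- base$dimer$intensity
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)
  lapply(seq_along(spec$concentrations), function(i) {
    conc <- spec$concentrations[i]
    ct <- conc * 1000 / spec$molar_mass   # uM
    eq <- dimer_fraction(spec$kd_dimer, ct)
    I <- (eq$monomer_conc * Im + eq$dimer_conc * Id) / ct
    sg <- (spec$noise_a + spec$noise_b * q) * I
    In <- I + rnorm(length(q), 0, sg)
    keep <- In > 0
    scattering_curve(q[keep], In[keep],
                     sigma = pmax(sg[keep], 1e-12),
                     concentration = conc,
                     label = sprintf("synthetic %.2g mg/ml", conc))
  })
}
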