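#' R-factor between an experimental and a model curve
#'
#' R = 100 * sum |I_exp - s * I_model| / sum |I_exp|. With
#' `scaling = "fit"` the multiplicative scale s is optimized by
#' golden-section search over a closed interval bracketing the
#' least-squares scale (the L1 objective is convex in s, so the search is
#' exact to tolerance); with `"fixed"` the supplied scale is used as is.
#'
#' @param experimental,model_curve `scattering_curve`s on the same Q grid.
#' @param scaling `"fit"` or `"fixed"`.
#' @param scale fixed scale when `scaling = "fixed"`.
#' @return list with `r_factor` (percent) and `scale`.
#' @export
r_factor <- function(experimental, model_curve, scaling = c("fit", "fixed"),
                     scale = 1) {
  scaling <- match.arg(scaling)
  if (length(experimental$q) != length(model_curve$q) ||
      max(abs(experimental$q - model_curve$q)) > 1e-9)
    stop("curves are on different Q grids; use interpolate_to_grid() first")
  Ie <- experimental$intensity; Im <- model_curve$intensity
  denom <- sum(abs(Ie))
  if (denom == 0) stop("experimental curve is identically zero")
  rf <- function(s) 100 * sum(abs(Ie - s * Im)) / denom
  if (scaling == "fixed") return(list(r_factor = rf(scale), scale = scale))
  s_ls <- sum(Ie * Im) / sum(Im^2)
  lo <- s_ls / 3; hi <- s_ls * 3
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- rf(c1); f2 <- rf(c2)
  while (abs(b - a) > 1e-12 * (abs(a) + abs(b))) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- rf(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- rf(c2)
    }
  }
  s_opt <- (a + b) / 2
  list(r_factor = rf(s_opt), scale = s_opt)
}

#' Interpolate a curve onto a target Q grid
#'
#' Linear interpolation on the measured grid; below the first measured
#' point the curve is extended in Guinier form using its own low-Q fit
#' (the standard way of completing an experimental curve to Q = 0 before
#' model comparison). Targets beyond the measured maximum are an error.
#'
#' @param curve a `scattering_curve`.
#' @param target_q target grid, 1/nm.
#' @param guinier optional precomputed [guinier_fit()] for the extension.
#' @return a `scattering_curve` on `target_q`.
#' @export
interpolate_to_grid <- function(curve, target_q, guinier = NULL) {
  if (max(target_q) > max(curve$q) + 1e-9)
    stop("target grid extends beyond the measured Q range")
  below <- target_q < min(curve$q)
  I <- rep(NA_real_, length(target_q))
  if (any(!below))
    I[!below] <- approx(curve$q, curve$intensity, target_q[!below],
                        rule = 1)$y
  if (any(below)) {
    if (is.null(guinier)) guinier <- guinier_fit(curve)
    I[below] <- guinier$i0 * exp(-(target_q[below] * guinier$rg)^2 / 3)
  }
  sg <- NULL
  if (!is.null(curve$sigma)) {
    sg <- rep(NA_real_, length(target_q))
    if (any(!below))
      sg[!below] <- approx(curve$q, curve$sigma, target_q[!below], rule = 1)$y
    sg[below] <- curve$sigma[1]
  }
  scattering_curve(target_q, I, sigma = sg,
                   concentration = curve$concentration,
                   label = curve$label)
}

#' Score a conformer library against an experimental curve
#'
#' Computes each model's coordinate radius of gyration and, for models
#' inside the Rg prefilter window (or all models when
#' `rg_prefilter = FALSE`), its theoretical curve and best-scale R-factor
#' against the experimental curve. Curves already computed may be passed
#' in to score several targets against one library cheaply.
#'
#' @param library a `conformer_library`.
#' @param experimental a `scattering_curve` defining the Q grid.
#' @param experimental_rg experimental radius of gyration (nm) used by the
#'   filters.
#' @param rg_tol Rg window half-width as a fraction (default 0.05).
#' @param rfac_max R-factor bound in percent (default 5).
#' @param engine `"debye"` (exact) or `"golden"` (orientational grid).
#' @param n_orientations orientations for the golden engine.
#' @param rg_prefilter only compute curves for models passing the Rg
#'   window (the R-factor filter is conjunctive, so skipped models cannot
#'   enter the filtered set).
#' @param model_curves optional precomputed intensity matrix
#'   (models x Q) from [library_curves()].
#' @return data.frame of fit records: `model_id`, `model_rg`, `r_factor`,
#'   `scale`, `passes_rg_filter`, `passes_rfactor_filter`.
#' @export
fit_library <- function(library, experimental, experimental_rg,
                        rg_tol = 0.05, rfac_max = 5,
                        engine = c("debye", "golden"),
                        n_orientations = 300, rg_prefilter = TRUE,
                        model_curves = NULL) {
  engine <- match.arg(engine)
  n <- length(library)
  rg <- library$meta$rg_nm
  pass_rg <- abs(rg - experimental_rg) <=
    rg_tol * experimental_rg + 1e-9  # inclusive at the boundary
  todo <- if (rg_prefilter) which(pass_rg) else seq_len(n)
  if (!is.null(model_curves))
    todo <- todo[!is.na(model_curves[todo, 1])]
  rfac <- rep(NA_real_, n); scl <- rep(NA_real_, n)
  w <- library$template$atoms$mass
  q <- experimental$q
  for (i in todo) {
    I <- if (!is.null(model_curves)) model_curves[i, ]
         else if (engine == "debye") cpp_debye(library$xyz[[i]] / 10, w, q)
         else cpp_golden_curve(library$xyz[[i]] / 10, w, q,
                               as.integer(n_orientations))
    res <- r_factor(experimental, scattering_curve(q, I))
    rfac[i] <- res$r_factor; scl[i] <- res$scale
  }
  data.frame(
    model_id = library$meta$model_id,
    model_rg = rg,
    r_factor = rfac,
    scale = scl,
    passes_rg_filter = pass_rg,
    passes_rfactor_filter = !is.na(rfac) & rfac <= rfac_max
  )
}

#' Theoretical curves for a set of library models
#'
#' @param library a `conformer_library`.
#' @param q Q grid, 1/nm.
#' @param subset model indices (default all).
#' @param engine,n_orientations as in [fit_library()].
#' @return numeric matrix (length(library) x length(q)); rows not in
#'   `subset` are NA.
#' @export
library_curves <- function(library, q, subset = seq_len(length(library)),
                           engine = c("debye", "golden"),
                           n_orientations = 300) {
  engine <- match.arg(engine)
  w <- library$template$atoms$mass
  out <- matrix(NA_real_, length(library), length(q))
  for (i in subset) {
    out[i, ] <- if (engine == "debye") cpp_debye(library$xyz[[i]] / 10, w, q)
                else cpp_golden_curve(library$xyz[[i]] / 10, w, q,
                                      as.integer(n_orientations))
  }
  out
}

#' Dual Rg / R-factor filter
#'
#' Keeps models whose radius of gyration lies within +-rg_tol of the
#' experimental value AND whose R-factor is at most rfac_max; both bounds
#' are inclusive.
#'
#' @param fits fit-record data.frame from [fit_library()].
#' @param experimental_rg experimental Rg in nm.
#' @param rg_tol fractional window half-width (default 0.05).
#' @param rfac_max percent bound (default 5).
#' @return the filtered subset of `fits` (possibly empty, with a warning).
#' @export
filter_library <- function(fits, experimental_rg, rg_tol = 0.05,
                           rfac_max = 5) {
  if (nrow(fits) == 0) stop("no fit records")
  keep <- abs(fits$model_rg - experimental_rg) <=
    rg_tol * experimental_rg + 1e-9 &
    !is.na(fits$r_factor) & fits$r_factor <= rfac_max + 1e-9
  out <- fits[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no models pass the dual filter")
  out
}

#' Best-fit ensemble by R-factor rank
#'
#' @param filtered filtered fit records.
#' @param n ensemble size (default 100; all records if fewer).
#' @return the `n` lowest-R-factor records, ties broken by model id.
#' @export
rank_best <- function(filtered, n = 100) {
  ord <- order(filtered$r_factor, filtered$model_id)
  filtered[head(ord, n), , drop = FALSE]
}

#' Terminal alpha-carbon to centre-of-mass separations
#'
#' The conformation descriptor of a folded-back multidomain chain: the
#' distances from the whole-model mass centre to the N-terminal and
#' C-terminal alpha-carbons, in nm.
#'
#' @param model a `coord_model`.
#' @return list with `nt_com` and `ct_com` (nm).
#' @export
separations <- function(model) {
  ca <- which(model$atoms$calpha & !model$atoms$glycan)
  if (length(ca) < 2) stop("model has no identifiable terminal alpha-carbons")
  nt <- ca[which.min(model$atoms$resno[ca])]
  ct <- ca[which.max(model$atoms$resno[ca])]
  com <- center_of_mass(model)
  list(nt_com = sqrt(sum((model$xyz[nt, ] - com)^2)) / 10,
       ct_com = sqrt(sum((model$xyz[ct, ] - com)^2)) / 10)
}

#' Separations for every model in a library
#' @param library a `conformer_library`.
#' @return data.frame with `model_id`, `nt_com`, `ct_com` (nm).
#' @export
library_separations <- function(library) {
  w <- library$template$atoms$mass
  ca <- which(library$template$atoms$calpha & !library$template$atoms$glycan)
  nt <- ca[which.min(library$template$atoms$resno[ca])]
  ct <- ca[which.max(library$template$atoms$resno[ca])]
  res <- t(vapply(library$xyz, function(x) {
    com <- drop(crossprod(x, w)) / sum(w)
    c(sqrt(sum((x[nt, ] - com)^2)), sqrt(sum((x[ct, ] - com)^2))) / 10
  }, numeric(2)))
  data.frame(model_id = library$meta$model_id,
             nt_com = res[, 1], ct_com = res[, 2])
}

#' Classify a conformation from its terminal separations
#'
#' A terminus is "extended" when its separation from the centre of mass
#' reaches the threshold (default 10 nm) and "bent inwards" otherwise.
#'
#' @param nt_com,ct_com separations in nm (or a list with those fields).
#' @param threshold_nm class boundary.
#' @return one of `"NT-extended"`, `"CT-extended"`, `"compact"`,
#'   `"doubly-extended"`.
#' @export
classify_conformation <- function(nt_com, ct_com = NULL, threshold_nm = 10) {
  if (is.list(nt_com)) { ct_com <- nt_com$ct_com; nt_com <- nt_com$nt_com }
  nt_ext <- nt_com >= threshold_nm
  ct_ext <- ct_com >= threshold_nm
  ifelse(nt_ext & !ct_ext, "NT-extended",
         ifelse(ct_ext & !nt_ext, "CT-extended",
                ifelse(nt_ext & ct_ext, "doubly-extended", "compact")))
}

#' Moment skewness coefficient g1
#'
#' g1 = m3 / m2^(3/2) with central moments m_k = mean((x - mean)^k): the
#' biased moment estimator (no small-sample correction), the form
#' conventionally reported for conformer separation distributions.
#'
#' @param sample numeric vector, n >= 3, nonzero variance.
#' @return skewness coefficient.
#' @export
skewness <- function(sample) {
  if (length(sample) < 3) stop("need at least 3 values")
  m <- mean(sample)
  m2 <- mean((sample - m)^2)
  if (m2 == 0) stop("zero variance")
  mean((sample - m)^3) / m2^1.5
}
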