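.wls_lnI <- function(q, I, sigma) {
  ## weighted least squares of y vs q^2; weights from propagated ln-errors
  x <- q^2
  y <- log(I)
  w <- if (is.null(sigma)) rep(1, length(q)) else (I / sigma)^2
  fit <- lm(y ~ x, weights = w)
  s <- suppressWarnings(summary(fit))  # noise-free input is a perfect fit
  list(slope = coef(fit)[[2]], intercept = coef(fit)[[1]],
       slope_se = s$coefficients[2, 2], r_squared = s$r.squared)
}

#' Guinier fit: radius of gyration and forward scattering
#'
#' Weighted linear fit of ln I(Q) vs Q^2 at low Q, giving
#' Rg = sqrt(-3 * slope) and I(0) = exp(intercept). The approximation
#' holds for Q*Rg up to ~1.5; a conservative working bound of Q*Rg <= 1.1
#' is the default. In `"auto"` mode the widest low-Q window satisfying the
#' bound is found by iterating the fit to self-consistency from an initial
#' minimal window; a fixed `c(qmin, qmax)` window may be given instead.
#'
#' @param curve a `scattering_curve`.
#' @param q_range `"auto"` or a numeric `c(qmin, qmax)` in 1/nm.
#' @param qrg_max Q*Rg bound used in auto mode (default 1.1; up to 1.5 is
#'   defensible for globular shapes).
#' @return list of class `guinier_fit`: `rg` (nm), `i0`, `stderr_rg`,
#'   `q_range`, `q_rg_range`, `n_points`, `r_squared`.
#' @export
guinier_fit <- function(curve, q_range = "auto", qrg_max = 1.1) {
  q <- curve$q; I <- curve$intensity; sg <- curve$sigma
  usable <- I > 0 & q > 0
  pick <- function(lo, hi) which(usable & q >= lo & q <= hi)
  if (is.numeric(q_range)) {
    idx <- pick(q_range[1], q_range[2])
    if (length(idx) < 3) stop("fewer than 3 usable points in the fit range")
  } else {
    first <- which(usable)
    if (length(first) < 3) stop("fewer than 3 usable points")
    ## start from a small low-Q window; under noise a tiny window can
    ## show a spurious positive slope, so widen until it decreases
    k0 <- min(max(5, 3), length(first))
    idx <- first[seq_len(k0)]
    repeat {
      f <- .wls_lnI(q[idx], I[idx], sg[idx])
      if (f$slope < 0) break
      if (length(idx) >= length(first))
        stop("non-Guinier region: ln I does not decrease with Q^2")
      idx <- first[seq_len(min(length(first), 2 * length(idx)))]
    }
    for (it in 1:30) {
      f <- .wls_lnI(q[idx], I[idx], sg[idx])
      if (f$slope >= 0) break  # keep the last decreasing window
      rg <- sqrt(-3 * f$slope)
      new_idx <- pick(0, qrg_max / rg)
      if (length(new_idx) < 3) new_idx <- first[1:3]
      if (identical(new_idx, idx)) break
      idx <- new_idx
    }
    f <- .wls_lnI(q[idx], I[idx], sg[idx])
    if (f$slope >= 0) {
      ## fall back to widening from the low-Q end once more
      idx <- first[seq_len(min(length(first), 3 * k0))]
    }
  }
  f <- .wls_lnI(q[idx], I[idx], sg[idx])
  if (f$slope >= 0) stop("non-Guinier region: ln I does not decrease with Q^2")
  rg <- sqrt(-3 * f$slope)
  structure(list(
    rg = rg,
    i0 = exp(f$intercept),
    stderr_rg = 3 * f$slope_se / (2 * rg),
    q_range = range(q[idx]),
    q_rg_range = range(q[idx]) * rg,
    n_points = length(idx),
    r_squared = f$r_squared
  ), class = "guinier_fit")
}

#' Cross-sectional Guinier fit for elongated particles
#'
#' Weighted linear fit of ln(I(Q) * Q) vs Q^2 over an intermediate-Q
#' window, giving the cross-sectional radius of gyration
#' Rxs = sqrt(-2 * slope). Two windows are conventionally used: a lower
#' one (Rxs-1) sensing the proximity of non-neighbouring domains and a
#' higher one (Rxs-2) sensing neighbouring domains; for an infinite
#' uniform cylinder of radius a, Rxs = a/sqrt(2).
#'
#' @param curve a `scattering_curve`.
#' @param q_range numeric `c(qmin, qmax)` in 1/nm (e.g. c(0.16, 0.26) for
#'   Rxs-1, c(0.4, 0.8) for Rxs-2).
#' @param kind `"RXS-1"` or `"RXS-2"`, a label only.
#' @return list of class `cross_section_fit` with `rxs` (nm),
#'   `intercept`, `q_range`, `kind`, `stderr_rxs`, `r_squared`.
#' @export
cross_section_fit <- function(curve, q_range, kind = c("RXS-1", "RXS-2")) {
  kind <- match.arg(kind)
  q <- curve$q; I <- curve$intensity
  usable <- I > 0 & q > 0 & q >= q_range[1] & q <= q_range[2]
  if (sum(usable) < 3) stop("fewer than 3 usable points in the fit range")
  qq <- q[usable]; iq <- I[usable] * qq
  sg <- if (is.null(curve$sigma)) NULL else curve$sigma[usable] * qq
  f <- .wls_lnI(qq, iq, sg)
  if (f$slope >= 0) stop("ln(I*Q) does not decrease with Q^2 in this window")
  rxs <- sqrt(-2 * f$slope)
  structure(list(rxs = rxs, intercept = f$intercept,
                 q_range = q_range, kind = kind,
                 stderr_rxs = f$slope_se / rxs, r_squared = f$r_squared),
            class = "cross_section_fit")
}

#' Extrapolate a concentration series to zero concentration
#'
#' Weighted linear regression of a scalar parameter (Rg, Rxs, I(0)/c, ...)
#' against concentration; the intercept estimates the monomer value free
#' of self-association, with its standard error from the regression
#' covariance.
#'
#' @param series data.frame with columns `concentration` (mg/ml), `value`
#'   and optionally `stderr`.
#' @return list of class `zero_conc_extrapolation`: `intercept`, `slope`,
#'   `stderr_intercept`, `stderr_slope`, `values_by_conc`.
#' @export
extrapolate_zero <- function(series) {
  series <- as.data.frame(series)
  if (length(unique(series$concentration)) < 3)
    stop("need at least 3 distinct concentrations")
  w <- if ("stderr" %in% names(series) && all(series$stderr > 0))
    1 / series$stderr^2 else rep(1, nrow(series))
  fit <- lm(value ~ concentration, data = series, weights = w)
  s <- suppressWarnings(summary(fit))$coefficients
  structure(list(intercept = s[1, 1], slope = s[2, 1],
                 stderr_intercept = s[1, 2], stderr_slope = s[2, 2],
                 values_by_conc = series),
            class = "zero_conc_extrapolation")
}

#' Dissociation constant from the concentration dependence of I(0)/c
#'
#' I(0)/c is proportional to the weight-average molar mass. Assuming a
#' monomer-dimer equilibrium 2M <-> D with dissociation constant Kd, the
#' weight-average mass is M1 * (1 + dimer mass fraction), so
#' I(0)/c = scale * (1 + f_dimer(c; Kd)) is fitted by least squares with
#' both the scale and Kd free (the scale is profiled analytically).
#'
#' @param series data.frame with columns `concentration` (mg/ml) and
#'   `i0_over_c`.
#' @param molar_mass monomer molar mass in kDa (converts mg/ml to uM).
#' @return list with `kd` (uM; `Inf` when the series does not increase
#'   with concentration), `scale`, `residual` (RSS).
#' @export
kd_from_i0c <- function(series, molar_mass) {
  series <- as.data.frame(series)
  if (length(unique(series$concentration)) < 3)
    stop("need at least 3 distinct concentrations")
  if (any(series$i0_over_c <= 0)) stop("i0_over_c must be positive")
  ct_um <- series$concentration * 1000 / molar_mass
  y <- series$i0_over_c
  slope <- coef(lm(y ~ ct_um))[[2]]
  if (slope <= 1e-10 * mean(y) / mean(ct_um)) {
    return(list(kd = Inf, scale = mean(y), residual = sum((y - mean(y))^2)))
  }
  rss <- function(log_kd) {
    m <- 1 + vapply(ct_um, function(ct)
      dimer_fraction(exp(log_kd), ct)$mass_fraction_dimer, numeric(1))
    s <- sum(y * m) / sum(m^2)
    sum((y - s * m)^2)
  }
  opt <- optimize(rss, c(log(1e-4), log(1e7)), tol = 1e-10)
  kd <- exp(opt$minimum)
  if (kd > 1e6) {  # at the search boundary: no detectable association
    return(list(kd = Inf, scale = mean(y), residual = sum((y - mean(y))^2)))
  }
  m <- 1 + vapply(ct_um, function(ct)
    dimer_fraction(kd, ct)$mass_fraction_dimer, numeric(1))
  list(kd = kd, scale = sum(y * m) / sum(m^2), residual = opt$objective)
}
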