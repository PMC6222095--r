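test_that("Guinier fit inverts an exact Guinier-form curve", {
  rg <- 7.4; i0 <- 250
  q <- seq(0.01, 0.3, by = 0.005)
  cv <- scattering_curve(q, i0 * exp(-(q * rg)^2 / 3))
  gf <- guinier_fit(cv)
  expect_equal(gf$rg, rg, tolerance = 1e-6)
  expect_equal(gf$i0, i0, tolerance = 1e-6)
  expect_lte(gf$q_rg_range[2], 1.1 + 1e-6)
})

test_that("Guinier fit recovers the sphere radius of gyration", {
  R <- 5
  sph <- sphere_cloud(radius_nm = R)
  cv <- debye_curve(sph, seq(0.01, 1, by = 0.01))
  ## noise-free oracle curves are fitted in a conservative window where
  ## the Guinier truncation bias is below the 1% level
  gf <- guinier_fit(cv, qrg_max = 0.8)
  expect_equal(gf$rg, R * sqrt(3 / 5), tolerance = 0.01)
})

test_that("Guinier fit errors are informative", {
  q <- seq(0.01, 0.3, by = 0.01)
  rising <- scattering_curve(q, exp(+q^2 * 3))
  expect_error(guinier_fit(rising), "non-Guinier")
  short <- scattering_curve(c(0.01, 0.02, 0.3), c(1, 1, 1))
  expect_error(guinier_fit(short, q_range = c(0.1, 0.2)), "3 usable")
})

test_that("cross-section fit inverts the exact exponential form", {
  rxs <- 2.2
  q <- seq(0.1, 0.9, by = 0.01)
  cv <- scattering_curve(q, exp(-q^2 * rxs^2 / 2) / q)
  cf <- cross_section_fit(cv, c(0.15, 0.6), "RXS-1")
  expect_equal(cf$rxs, 2.2, tolerance = 1e-6)
})

test_that("cross-section fit recovers a long cylinder's a/sqrt(2)", {
  a <- 2
  cyl <- cylinder_cloud(radius_nm = a, length_nm = 120)
  cv <- debye_curve(cyl, seq(0.02, 1, by = 0.02),
                    weights = rep(1, nrow(cyl$xyz)))
  cf <- cross_section_fit(cv, c(0.3, 0.6), "RXS-2")
  expect_equal(cf$rxs, a / sqrt(2), tolerance = 0.03)
})

test_that("P(r) of a two-point scatterer peaks at the separation", {
  d <- 5
  m <- coord_model(rbind(c(0, 0, 0), c(d * 10, 0, 0)), "X", resno = c(1, 3),
                   calpha = TRUE, mass = c(1, 1))
  cv <- debye_curve(m, seq(0.02, 3, by = 0.02), weights = c(1, 1))
  pr <- pr_transform(cv, dmax = 8, n_bins = 64)
  expect_equal(pr$m1_peak, d, tolerance = 0.3)
})

test_that("P(r) of a sphere recovers dmax ~ 2R and consistent moments", {
  R <- 5
  sph <- sphere_cloud(radius_nm = R)
  cv <- debye_curve(sph, seq(0.01, 1.5, by = 0.01),
                    weights = rep(1, nrow(sph$xyz)))
  pr <- pr_transform(cv, dmax = "auto", n_bins = 64)
  expect_equal(pr$dmax, 2 * R, tolerance = 0.15)
  gf <- guinier_fit(cv, qrg_max = 0.8)
  expect_equal(pr$rg_pr, gf$rg, tolerance = 0.02)
  expect_equal(pr$i0_pr, cv$intensity[1], tolerance = 0.02 * cv$intensity[1])
  ## non-negativity and boundary conditions
  expect_true(all(pr$p >= 0))
  ## forward kernel reproduces the input curve
  expect_lt(sqrt(pr$chi2), 3)
})

test_that("zero-concentration extrapolation behaves like a regression", {
  flat <- data.frame(concentration = c(0.4, 1.1, 2.2), value = c(5, 5, 5))
  ez <- extrapolate_zero(flat)
  expect_equal(ez$intercept, 5)
  expect_equal(ez$slope, 0, tolerance = 1e-12)
  sloped <- data.frame(concentration = c(0.4, 0.7, 1.1, 2.2, 3.3),
                       value = 7.4 + 0.3 * c(0.4, 0.7, 1.1, 2.2, 3.3),
                       stderr = rep(0.05, 5))
  ez2 <- extrapolate_zero(sloped)
  expect_equal(ez2$intercept, 7.4, tolerance = 1e-9)
  ## order invariance
  ez3 <- extrapolate_zero(sloped[c(4, 1, 5, 2, 3), ])
  expect_equal(ez3$intercept, ez2$intercept)
  expect_error(extrapolate_zero(flat[1:2, ]), "3 distinct")
})

test_that("Kd is recovered exactly from a noise-free I(0)/c series", {
  kd <- 28; mm <- 154
  conc <- c(0.4, 0.7, 1.1, 2.2, 3.3)
  i0c <- vapply(conc, function(cc) {
    2.5 * (1 + dimer_fraction(kd, cc * 1000 / mm)$mass_fraction_dimer)
  }, numeric(1))
  fit <- kd_from_i0c(data.frame(concentration = conc, i0_over_c = i0c), mm)
  expect_equal(fit$kd, kd, tolerance = 0.01)
  expect_equal(fit$scale, 2.5, tolerance = 1e-3)
  ## constant series: no detectable association
  fit2 <- kd_from_i0c(data.frame(concentration = conc,
                                 i0_over_c = rep(3, 5)), mm)
  expect_equal(fit2$kd, Inf)
})

test_that("Guinier Rg of model curves tracks the coordinate Rg", {
  for (m in list(fix_arch_nt(), fix_arch_ct())) {
    cv <- debye_curve(m, seq(0.01, 0.5, by = 0.005))
    gf <- guinier_fit(cv, qrg_max = 0.8)
    expect_equal(gf$rg, coordinate_rg(m), tolerance = 0.02)
  }
})
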