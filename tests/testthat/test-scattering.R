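test_that("Debye sum reproduces the two-scatterer closed form", {
  d <- 3  # nm
  m <- coord_model(rbind(c(0, 0, 0), c(d * 10, 0, 0)), "X", resno = c(1, 3),
                   calpha = TRUE, mass = c(1, 1))
  q <- c(0, 0.5, 1, pi / d, 2)
  cv <- debye_curve(m, q, weights = c(1, 1))
  closed <- (1 + ifelse(q == 0, 1, sin(q * d) / (q * d))) / 2
  expect_equal(cv$intensity / cv$intensity[1], closed, tolerance = 1e-12)
  ## at Q*d = pi the normalized intensity is exactly 1/2
  expect_equal(cv$intensity[4] / cv$intensity[1], 0.5, tolerance = 1e-12)
})

test_that("I(0) equals the squared total weight", {
  m <- fix_arch_nt()
  cv <- debye_curve(m, c(0, 0.1))
  expect_equal(cv$intensity[1], sum(m$atoms$mass)^2, tolerance = 1e-10)
})

test_that("Debye curve of a sphere cloud matches the analytic form factor", {
  sph <- sphere_cloud(radius_nm = 5, spacing = 4)
  ## compare at the cloud's own effective radius: near the form-factor
  ## minimum the curve is extremely sensitive to sub-percent radius error
  Reff <- coordinate_rg(sph) * sqrt(5 / 3)
  q <- seq(0.05, 4 / Reff, length.out = 50)
  cv <- debye_curve(sph, q, weights = rep(1, nrow(sph$xyz)))
  x <- q * Reff
  ff <- (3 * (sin(x) - x * cos(x)) / x^3)^2
  rel <- abs(cv$intensity / nrow(sph$xyz)^2 - ff) / ff
  expect_lt(max(rel), 0.01)
})

test_that("Debye curve is invariant under rigid motion", {
  m <- fix_arch_ct()
  q <- seq(0.05, 1.5, by = 0.1)
  c1 <- debye_curve(m, q)
  m2 <- transform_model(m, random_rotation(3), c(100, -50, 30))
  c2 <- debye_curve(m2, q)
  expect_equal(c2$intensity, c1$intensity, tolerance = 1e-9)
})

test_that("golden-grid curve converges to the Debye sum", {
  m <- fix_arch_nt()
  q <- seq(0.02, 1.5, by = 0.03)
  ref <- debye_curve(m, q)
  g300 <- golden_grid_curve(m, q, 300)
  expect_lt(max(abs(g300$intensity - ref$intensity) / ref$intensity), 0.005)
  ## error shrinks (on average) with more orientations
  errs <- vapply(c(40, 120, 360), function(n) {
    g <- golden_grid_curve(m, q, n)
    mean(abs(g$intensity - ref$intensity) / ref$intensity)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  ## single scatterer: flat curve equal to f^2 for any grid
  one <- coord_model(matrix(c(5, 5, 5), 1, 3), "X", resno = 1, mass = 7)
  g1 <- golden_grid_curve(one, q, 17, weights = 7)
  expect_equal(g1$intensity, rep(49, length(q)), tolerance = 1e-12)
  ## translation invariance
  g_shift <- golden_grid_curve(transform_model(m, diag(3), c(30, 10, -5)),
                               q, 100)
  g_base <- golden_grid_curve(m, q, 100)
  expect_equal(g_shift$intensity, g_base$intensity, tolerance = 1e-8)
})

test_that("normalized Kratky of an ideal globule peaks at sqrt(3), 3/e", {
  rg <- 7.4
  q <- seq(0.005, 1, by = 0.005)
  cv <- scattering_curve(q, 100 * exp(-(q * rg)^2 / 3))
  nk <- normalized_kratky(cv, rg, 100)
  expect_true(nk$has_peak)
  expect_equal(nk$peak_x, sqrt(3), tolerance = 1e-3)
  expect_equal(nk$peak_y, 3 / exp(1), tolerance = 1e-3)
})

test_that("Kratky transform flags monotone curves and extended chains", {
  ## monotone increasing transform: no interior peak
  q <- seq(0.01, 0.5, by = 0.01)
  flat <- scattering_curve(q, rep(1, length(q)))
  nk <- normalized_kratky(flat, 5, 1)
  expect_false(nk$has_peak)
  ## the extended synthetic chain is strongly non-globular: peak far
  ## beyond the globular position
  ch <- fix_chain()
  rg <- coordinate_rg(ch)
  cv <- debye_curve(ch, seq(0.02, 3, by = 0.04))
  nk2 <- normalized_kratky(cv, rg, sum(ch$atoms$mass)^2)
  expect_true(nk2$has_peak)
  expect_gt(nk2$peak_x, 3)
})

test_that("curve files round-trip through the 3-column text format", {
  q <- seq(0.02, 1, by = 0.02)
  cv <- scattering_curve(q, exp(-q), sigma = 0.01 * exp(-q),
                         concentration = 1.1, label = "round trip")
  path <- withr::local_tempfile(fileext = ".dat")
  write_dat(cv, path)
  back <- read_dat(path, concentration = 1.1)
  expect_equal(back$q, cv$q, tolerance = 1e-8)
  expect_equal(back$intensity, cv$intensity, tolerance = 1e-8)
  expect_equal(back$sigma, cv$sigma, tolerance = 1e-8)
})

test_that("scattering_curve validates its inputs", {
  expect_error(scattering_curve(c(1, 1), c(1, 2)), "increasing")
  expect_error(scattering_curve(c(-1, 1), c(1, 2)), "non-negative")
  expect_error(scattering_curve(c(0, 1), c(1, NA)), "finite")
  expect_error(scattering_curve(c(0, 1), c(1, 1), sigma = c(1, -1)),
               "positive")
})
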