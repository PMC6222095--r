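test_that("R-factor identity, hand value, and scale optimality", {
  q <- c(0.1, 0.2)
  e <- scattering_curve(q, c(1, 1))
  m_same <- scattering_curve(q, c(1, 1))
  r0 <- r_factor(e, m_same)
  expect_equal(r0$r_factor, 0, tolerance = 1e-9)
  expect_equal(r0$scale, 1, tolerance = 1e-6)
  ## hand evaluation with fixed scale 1
  m2 <- scattering_curve(q, c(1.1, 0.9))
  expect_equal(r_factor(e, m2, scaling = "fixed", scale = 1)$r_factor, 10)
  ## fitted scale can never do worse than a fixed unit scale
  for (seed in 1:5) {
    withr::with_seed(seed, {
      qq <- seq(0.02, 1.5, length.out = 40)
      Ie <- exp(-qq) * runif(1, 0.5, 2) + runif(40, 0, 0.05)
      Im <- exp(-qq) + runif(40, 0, 0.05)
    })
    ec <- scattering_curve(qq, Ie); mc <- scattering_curve(qq, Im)
    expect_lte(r_factor(ec, mc)$r_factor,
               r_factor(ec, mc, "fixed", 1)$r_factor + 1e-9)
  }
  expect_error(r_factor(e, scattering_curve(c(0.1, 0.25), c(1, 1))),
               "interpolate_to_grid")
})

test_that("interpolation is exact on the source grid and for linear data", {
  q <- seq(0.1, 1, by = 0.1)
  cv <- scattering_curve(q, 2 - q)
  same <- interpolate_to_grid(cv, q)
  expect_equal(same$intensity, cv$intensity)
  mid <- interpolate_to_grid(cv, c(0.15, 0.55, 0.95))
  expect_equal(mid$intensity, 2 - c(0.15, 0.55, 0.95), tolerance = 1e-12)
  expect_error(interpolate_to_grid(cv, c(0.5, 1.2)), "beyond")
})

test_that("low-Q completion uses the curve's own Guinier form", {
  rg <- 6; i0 <- 100
  q <- seq(0.05, 0.5, by = 0.005)
  cv <- scattering_curve(q, i0 * exp(-(q * rg)^2 / 3))
  ext <- interpolate_to_grid(cv, c(0, 0.01, 0.1))
  expect_equal(ext$intensity[1], i0, tolerance = 1e-3 * i0)
  expect_equal(ext$intensity[2], i0 * exp(-(0.01 * rg)^2 / 3),
               tolerance = 1e-3 * i0)
})

test_that("the dual filter applies inclusive bounds", {
  fits <- data.frame(model_id = 1:4,
                     model_rg = c(1.05 * 7, 1.051 * 7, 7, 7),
                     r_factor = c(5, 4, 5.0001, 2),
                     scale = 1,
                     passes_rg_filter = NA, passes_rfactor_filter = NA)
  kept <- filter_library(fits, experimental_rg = 7)
  expect_setequal(kept$model_id, c(1, 4))
  empty <- suppressWarnings(filter_library(fits[2, ], 7))
  expect_equal(nrow(empty), 0)
  expect_warning(filter_library(fits[2, ], 7), "no models")
})

test_that("ranking is by R-factor with deterministic tie-breaks", {
  fits <- data.frame(model_id = c(3, 1, 2), model_rg = 7,
                     r_factor = c(2, 2, 1), scale = 1)
  best <- rank_best(fits, 100)
  expect_equal(best$model_id, c(2, 1, 3))
  expect_equal(nrow(rank_best(fits, 2)), 2)
})

test_that("separations of a uniform rod are symmetric", {
  rod <- rod_model(n = 201, length_nm = 20)
  s <- separations(rod)
  expect_equal(s$nt_com, 10, tolerance = 1e-6)
  expect_equal(s$ct_com, 10, tolerance = 1e-6)
})

test_that("conformation classification follows the threshold rule", {
  expect_equal(classify_conformation(14, 5), "NT-extended")
  expect_equal(classify_conformation(5, 14), "CT-extended")
  expect_equal(classify_conformation(5, 5), "compact")
  expect_equal(classify_conformation(12, 12), "doubly-extended")
  ## boundary: threshold itself counts as extended
  expect_equal(classify_conformation(10, 9.999), "NT-extended")
  s <- separations(fix_arch_nt())
  expect_equal(classify_conformation(s), "NT-extended")
})

test_that("skewness matches hand-computed moments", {
  expect_equal(skewness(1:5), 0)
  expect_equal(skewness(c(0, 0, 0, 1)), 1.1547, tolerance = 1e-4)
  withr::with_seed(8, x <- rgamma(500, 2))
  expect_equal(skewness(-x), -skewness(x))
  expect_error(skewness(c(2, 2, 2)), "variance")
  ## agreement with the e1071 moment-form estimator
  expect_equal(skewness(x), e1071::skewness(x, type = 1), tolerance = 1e-12)
})

test_that("library separations agree with the per-model computation", {
  topo <- fix_topology()
  r <- run_tamc(tamc_config(fix_arch_nt(), topo, n_steps = 20, seed = 9))
  tab <- library_separations(r$library)
  i <- length(r$library)
  s <- separations(library_model(r$library, i))
  expect_equal(tab$nt_com[i], s$nt_com, tolerance = 1e-9)
  expect_equal(tab$ct_com[i], s$ct_com, tolerance = 1e-9)
})
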