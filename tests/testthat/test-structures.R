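test_that("element masses resolve and unknown symbols are reported", {
  expect_equal(element_mass(c("C", "N", "O")), c(12.011, 14.007, 15.999))
  expect_error(element_mass("Qq"), "QQ")
})

test_that("coord_model enforces its invariants", {
  xyz <- matrix(0, 2, 3)
  expect_error(coord_model(xyz, "C", resno = c(2, 1)), "non-decreasing")
  expect_error(coord_model(xyz, "C", resno = c(1, 1), calpha = TRUE),
               "alpha-carbon")
  expect_error(coord_model(matrix(c(0, 0, Inf, 0, 0, 0), 2, 3), "C",
                           resno = 1:2), "finite")
  expect_error(coord_model(xyz, "C", resno = 1:2, mass = c(1, -1)),
               "positive")
})

test_that("center of mass is the weighted mean and is equivariant", {
  m <- coord_model(rbind(c(0, 0, 0), c(20, 0, 0)), element = "X",
                   resno = 1:2, mass = c(1, 1))
  expect_equal(center_of_mass(m), c(10, 0, 0))
  m2 <- coord_model(rbind(c(0, 0, 0), c(40, 0, 0)), element = "X",
                    resno = 1:2, mass = c(1, 3))
  expect_equal(center_of_mass(m2), c(30, 0, 0))
  v <- c(3.2, -1.1, 7.7)
  shifted <- transform_model(m2, translation = v)
  expect_equal(center_of_mass(shifted), center_of_mass(m2) + v)
  expect_error(center_of_mass(m, rep(FALSE, 2)), "no atoms")
})

test_that("coordinate Rg matches analytic bodies", {
  ## two equal masses 2 nm apart -> 1 nm
  pair <- coord_model(rbind(c(0, 0, 0), c(20, 0, 0)), element = "X",
                      resno = 1:2, mass = c(1, 1))
  expect_equal(coordinate_rg(pair), 1.0)
  ## uniform solid sphere radius 5 nm -> 5*sqrt(3/5)
  expect_equal(coordinate_rg(sphere_cloud()), 5 * sqrt(3 / 5),
               tolerance = 0.01)
  ## thin rod length 24 nm -> 24/sqrt(12)
  expect_equal(coordinate_rg(rod_model()), 24 / sqrt(12), tolerance = 0.01)
  ## single atom: zero with a warning
  single <- coord_model(matrix(1, 1, 3), "X", resno = 1)
  expect_warning(rg1 <- coordinate_rg(single), "single")
  expect_equal(rg1, 0)
})

test_that("Rg and COM are invariant/equivariant under rigid motion", {
  m <- fix_arch_nt()
  R <- random_rotation(4)
  t <- c(12, -8, 3)
  m2 <- transform_model(m, R, t)
  expect_equal(coordinate_rg(m2), coordinate_rg(m), tolerance = 1e-9)
  expect_equal(center_of_mass(m2), drop(R %*% center_of_mass(m)) + t,
               tolerance = 1e-9)
})

test_that("Kabsch superposition recovers exact transforms", {
  m <- fix_arch_nt()
  self <- kabsch_superpose(m, m)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)

  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  rot <- transform_model(m, Rz, c(5, 5, 5))
  sup <- kabsch_superpose(rot, m)
  expect_equal(sup$rmsd, 0, tolerance = 1e-8)
  expect_equal(sup$rotation %*% Rz, diag(3), tolerance = 1e-8)
  expect_equal(apply_superposition(rot, sup)$xyz, m$xyz, tolerance = 1e-7)
})

test_that("single perturbed atom gives the closed-form RMSD", {
  n <- 60
  withr::with_seed(9, xyz <- matrix(rnorm(3 * n, sd = 15), n, 3))
  a <- coord_model(xyz, "X", resno = seq_len(n), calpha = TRUE)
  b <- a
  ## perturb one atom by 1 A in a way that leaves the optimal transform
  ## essentially the identity (perturbation orthogonal to the lever arm
  ## effects is not exact, so allow a small tolerance)
  b$xyz[1, 1] <- b$xyz[1, 1] + 1
  sup <- kabsch_superpose(b, a)
  expect_equal(sup$rmsd, 1 / sqrt(n), tolerance = 0.02)
})

test_that("superposition agrees with the bio3d reference", {
  m <- fix_arch_nt()
  R <- random_rotation(7)
  moved <- transform_model(m, R, c(4, -2, 9))
  ## add coordinate noise so the fit is non-trivial
  withr::with_seed(11, moved$xyz <- moved$xyz + rnorm(length(moved$xyz),
                                                      sd = 0.3))
  sup <- kabsch_superpose(moved, m, fix_topology()$reference_domains)
  sel <- which(m$atoms$calpha & !m$atoms$glycan &
                 m$atoms$resno >= fix_topology()$reference_domains[1] &
                 m$atoms$resno <= fix_topology()$reference_domains[2])
  ref_fit <- bio3d::fit.xyz(
    fixed = as.vector(t(m$xyz)), mobile = as.vector(t(moved$xyz)),
    fixed.inds = bio3d::atom2xyz(sel), mobile.inds = bio3d::atom2xyz(sel))
  moved_ours <- apply_superposition(moved, sup)
  rmsd_ref <- sqrt(mean((matrix(ref_fit, ncol = 3, byrow = TRUE)[sel, ] -
                           m$xyz[sel, ])^2) * 3)
  expect_equal(sup$rmsd, rmsd_ref, tolerance = 1e-6)
})

test_that("clash counting matches the all-pairs oracle", {
  two <- coord_model(rbind(c(0, 0, 0), c(5, 0, 0)), "X", resno = c(1, 5),
                     calpha = TRUE)
  expect_equal(check_clashes(two, cutoff = 2.2), 0)
  close2 <- coord_model(rbind(c(0, 0, 0), c(1, 0, 0)), "X", resno = c(1, 50),
                        calpha = TRUE)
  expect_equal(check_clashes(close2, cutoff = 2.2), 1)
  expect_error(check_clashes(two, cutoff = -1), "positive")

  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 500
      xyz <- matrix(runif(3 * n, 0, 40), n, 3)
      resno <- sort(sample.int(200, n, replace = TRUE))
    })
    m <- coord_model(xyz, "X", resno = resno, calpha = FALSE)
    for (cutoff in c(1.5, 2.2, 4)) {
      expect_equal(check_clashes(m, cutoff),
                   clash_brute(m, cutoff),
                   info = sprintf("seed %d cutoff %.1f", seed, cutoff))
    }
  }
})

test_that("PDB round trip preserves order, elements and coordinates", {
  m <- fix_arch_ct()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, path)
  back <- read_pdb(path, fix_topology())
  expect_equal(nrow(back$xyz), nrow(m$xyz))
  expect_equal(back$atoms$element, m$atoms$element)
  expect_equal(back$atoms$resno, m$atoms$resno)
  expect_equal(back$atoms$glycan, m$atoms$glycan)
  expect_lt(max(abs(back$xyz - m$xyz)), 1e-3 + 1e-9)
})

test_that("single-CA PDB file loads as one flagged atom", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), path)
  m <- read_pdb(path)
  expect_equal(nrow(m$xyz), 1)
  expect_equal(unname(m$xyz[1, ]), c(0, 0, 0))
  expect_true(m$atoms$calpha[1])
})

test_that("topology validates and round-trips through YAML", {
  topo <- fix_topology()
  expect_equal(nrow(topo$domain_ranges), 20)
  expect_equal(length(topo$movable_linkers) + length(topo$fixed_linkers), 19)
  expect_error(chain_topology(rbind(c(1, 10), c(5, 20)), list(), list(),
                              integer(0), c(1, 10)), "non-overlapping")
  expect_error(
    chain_topology(rbind(c(1, 10), c(12, 20)), list(c(11, 11)), list(),
                   glycan_sites = 11, reference_domains = c(1, 10)),
    "glycan")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_topology(topo, path)
  back <- read_topology(path)
  expect_equal(back$domain_ranges, topo$domain_ranges)
  expect_equal(back$glycan_sites, topo$glycan_sites)
  expect_setequal(vapply(back$movable_linkers, paste, collapse = "-", ""),
                  vapply(topo$movable_linkers, paste, collapse = "-", ""))
})
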