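test_that("torsion moves are identity at zero and invertible", {
  topo <- fix_topology()
  m <- fix_arch_nt()
  res <- movable_residues(topo)[3]
  m0 <- apply_torsion_move(m, res, "phi", 0, topo)
  expect_equal(m0$xyz, m$xyz, tolerance = 1e-12)
  m1 <- apply_torsion_move(m, res, "psi", 37.5, topo)
  m2 <- apply_torsion_move(m1, res, "psi", -37.5, topo)
  expect_lt(max(abs(m2$xyz - m$xyz)), 1e-6)
  expect_error(apply_torsion_move(m, 1, "phi", 10, topo), "movable")
})

test_that("torsion moves are rigid on both sides of the bond", {
  topo <- fix_topology()
  m <- fix_arch_ct()
  res <- movable_residues(topo)[10]
  m1 <- apply_torsion_move(m, res, "phi", 63, topo)
  moving <- m$atoms$resno >= res
  for (side in list(which(moving), which(!moving))) {
    idx <- side[seq(1, length(side), length.out = min(40, length(side)))]
    d0 <- dist(m$xyz[idx, ])
    d1 <- dist(m1$xyz[idx, ])
    expect_lt(max(abs(d0 - d1)), 1e-6)
  }
  ## the static segment is untouched
  expect_identical(m1$xyz[!moving, ], m$xyz[!moving, ])
})

test_that("run_tamc is reproducible and honours its contract", {
  topo <- fix_topology()
  cfg <- tamc_config(fix_arch_nt(), topo, n_steps = 60, seed = 42)
  r1 <- run_tamc(cfg)
  r2 <- run_tamc(cfg)
  expect_equal(r1$n_accepted, r2$n_accepted)
  if (r1$n_accepted > 0)
    expect_identical(r1$library$xyz[[r1$n_accepted]],
                     r2$library$xyz[[r2$n_accepted]])
  expect_equal(r1$acceptance_rate, r1$n_accepted / r1$n_attempted)
  ## every accepted model re-audits as clash-free
  for (i in seq_len(min(10, length(r1$library))))
    expect_equal(check_clashes(library_model(r1$library, i)), 0)
})

test_that("zero cutoff accepts every move", {
  cfg <- tamc_config(fix_arch_nt(), fix_topology(), n_steps = 25,
                     clash_cutoff = 1e-9, seed = 5)
  r <- run_tamc(cfg)
  expect_equal(r$acceptance_rate, 1.0)
})

test_that("a vanishing step size reproduces the start model", {
  cfg <- tamc_config(fix_arch_nt(), fix_topology(), n_steps = 1,
                     max_step_deg = 1e-9, seed = 3)
  r <- run_tamc(cfg)
  expect_equal(r$n_accepted, 1)
  expect_equal(r$library$xyz[[1]], fix_arch_nt()$xyz, tolerance = 1e-6)
})

test_that("libraries merge additively with run provenance", {
  topo <- fix_topology()
  r1 <- run_tamc(tamc_config(fix_arch_nt(), topo, n_steps = 15, seed = 1))
  r2 <- run_tamc(tamc_config(fix_arch_nt(), topo, n_steps = 20, seed = 2))
  lib <- merge_libraries(list(r1, r2))
  expect_equal(length(lib), r1$n_accepted + r2$n_accepted)
  expect_equal(sort(unique(lib$meta$run)), 1:2)
  ## self-merge doubles (duplicates allowed, as in chained restarts)
  lib2 <- merge_libraries(list(r1$library, r1$library))
  expect_equal(length(lib2), 2 * r1$n_accepted)
  ## mismatched topologies refuse to merge
  small <- conformer_library(rod_model(30), list(rod_model(30)$xyz))
  expect_error(merge_libraries(list(r1$library, small)), "mismatch")
})

test_that("sampled libraries span a broad range of sizes", {
  topo <- fix_topology()
  r <- run_tamc(tamc_config(fix_arch_ct(), topo, n_steps = 250,
                            max_step_deg = 30, seed = 11))
  rg <- r$library$meta$rg_nm
  expect_gt(sd(rg) / mean(rg), 0.02)
  expect_gt(r$acceptance_rate, 0)
  expect_lt(r$acceptance_rate, 1)
})

test_that("library I/O writes a manifest plus one PDB per model", {
  topo <- fix_topology()
  r <- run_tamc(tamc_config(fix_arch_nt(), topo, n_steps = 8, seed = 2))
  dir <- withr::local_tempdir()
  write_library(r$library, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_equal(length(list.files(dir, pattern = "\\.pdb$")),
               length(r$library))
  man <- read.table(file.path(dir, "manifest.tsv"), header = TRUE)
  expect_equal(nrow(man), length(r$library))
  expect_true(all(c("model_id", "rg_nm", "run", "step") %in% names(man)))
})
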