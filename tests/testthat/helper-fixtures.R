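## Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_env)) assign(name, builder(), .fixture_env)
  get(name, .fixture_env)
}

fix_topology <- function() fixture("topology", fh_topology)

fix_chain <- function() fixture("chain", function()
  build_scr_chain(fix_topology(), seed = 1L))

fix_arch_nt <- function() fixture("arch_nt", function()
  make_archetype(fix_chain(), "NT-extended", fix_topology(), seed = 1L))

fix_arch_ct <- function() fixture("arch_ct", function()
  make_archetype(fix_chain(), "CT-extended", fix_topology(), seed = 1L))

## uniform-density solid sphere as a cubic-grid fill (deterministic and
## far more uniform than Monte Carlo sampling, so Debye curves track the
## analytic form factor closely); radius in nm, spacing in angstrom.
## The cloud's effective radius is sqrt(5/3) times its coordinate Rg.
sphere_cloud <- function(radius_nm = 5, spacing = 5) {
  R <- radius_nm * 10
  ax <- seq(-R, R, by = spacing)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  g <- g[rowSums(g^2) <= R^2, , drop = FALSE]
  coord_model(g, element = rep("X", nrow(g)), resno = seq_len(nrow(g)),
              calpha = TRUE, label = "sphere cloud")
}

## uniform solid cylinder along x, length and radius in nm
cylinder_cloud <- function(n = 8000, length_nm = 120, radius_nm = 2,
                           seed = 3) {
  withr::with_seed(seed, {
    r <- sqrt(runif(n)) * radius_nm * 10
    th <- runif(n) * 2 * pi
    coord_model(cbind(runif(n, -length_nm * 5, length_nm * 5),
                      r * cos(th), r * sin(th)),
                element = "X", resno = seq_len(n), calpha = TRUE,
                label = "cylinder cloud")
  })
}

## thin rod of equally spaced beads along x, length in nm
rod_model <- function(n = 200, length_nm = 24) {
  coord_model(cbind(seq(0, length_nm * 10, length.out = n), 0, 0),
              element = "X", resno = seq_len(n), calpha = TRUE,
              label = "rod")
}

random_rotation <- function(seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(9), 3, 3)
    qr_d <- qr(A)
    R <- qr.Q(qr_d)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    R
  })
}

## brute-force all-pairs clash oracle
clash_brute <- function(model, cutoff = 2.2, minsep = 2) {
  d <- as.matrix(dist(model$xyz))
  resno <- model$atoms$resno
  sum(d < cutoff & outer(resno, resno, function(a, b) abs(a - b) >= minsep) &
        upper.tri(d))
}
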