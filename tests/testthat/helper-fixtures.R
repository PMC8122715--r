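# Shared test helpers: random rigid motions and ensembles with exact moments.

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Rescale a draw so the sample mean and sample SD are exactly as requested.
exact_moment_sample <- function(n, mean, sd, seed = 1) {
  z <- withr::with_seed(seed, rnorm(n))
  mean + sd * (z - mean(z)) / stats::sd(z)
}

rvonmises_deg_seeded <- function(n, mu_deg, kappa, seed) {
  withr::with_seed(seed, rvonmises_deg(n, mu_deg, kappa))
}

toy_dimer_pdb <- function(torsions = c(37.2, 178.3), r_sep = 5,
                          orientation = c(0, 0, 0)) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  write_fixture_pdb(build_toy_dimer(r_sep, orientation, 10, torsions), path)
  path
}
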