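test_that("system assembly validates couplings", {
  sys <- exciton_system(c(2.551, 2.427),
                        tibble::tibble(i = 1, j = 2, v_ev = 0.061))
  expect_equal(sys$coupling_ev[1, 2], 0.061)
  expect_equal(sys$coupling_ev, t(sys$coupling_ev))

  single <- exciton_system(2.5)
  expect_equal(diagonalize(single)$energies_ev, 2.5)

  expect_error(exciton_system(c(2.5, 2.4),
                              tibble::tibble(i = 1, j = 1, v_ev = 0.1)),
               class = "carospec_input_error")
  expect_error(exciton_system(c(2.5, 2.4),
                              tibble::tibble(i = c(1, 2), j = c(2, 1),
                                             v_ev = c(0.1, 0.1))),
               class = "carospec_input_error")
  asym <- matrix(c(0, 0.1, 0.2, 0), 2)
  expect_error(exciton_system(c(2.5, 2.4), asym),
               class = "carospec_input_error")
})

test_that("the carotenoid dimer's upper exciton state lands at 481 nm", {
  res <- diagonalize(hcp2_exciton_system())
  expect_equal(round(res$wavelengths_nm[1]), 481)
  expect_equal(res$wavelengths_nm[1], 481.3, tolerance = 0.05 / 481)
  # the lower state computes to ~516 nm from the rounded inputs
  expect_equal(round(res$wavelengths_nm[2]), 516)
  expect_true(all(diff(res$energies_ev) < 0))
})

test_that("diagonalization matches the 2x2 closed form to 1e-12 eV", {
  withr::with_seed(5, {
    for (i in 1:20) {
      e <- runif(2, 2, 3)
      v <- runif(1, -0.2, 0.2)
      res <- diagonalize(exciton_system(
        e, tibble::tibble(i = 1, j = 2, v_ev = v)))
      mid <- mean(e)
      half <- sqrt(((e[1] - e[2]) / 2)^2 + v^2)
      expect_equal(res$energies_ev, c(mid + half, mid - half),
                   tolerance = 1e-12)
    }
  })
  # degenerate sites split symmetrically by the coupling
  res <- diagonalize(exciton_system(c(2.5, 2.5),
                                    tibble::tibble(i = 1, j = 2, v_ev = 0.05)))
  expect_equal(res$energies_ev, c(2.55, 2.45), tolerance = 1e-12)
  # no coupling leaves the site energies untouched
  res0 <- diagonalize(exciton_system(c(2.551, 2.427)))
  expect_equal(res0$energies_ev, c(2.551, 2.427))
})

test_that("trace and orthonormality hold on random systems up to N = 20", {
  withr::with_seed(9, {
    for (i in 1:10) {
      n <- sample(2:20, 1)
      e <- runif(n, 2, 3)
      v <- matrix(rnorm(n^2, sd = 0.05), n)
      v <- (v + t(v)) / 2
      diag(v) <- 0
      res <- diagonalize(exciton_system(e, v))
      expect_equal(sum(res$energies_ev), sum(e), tolerance = 1e-9)
      expect_equal(crossprod(res$vectors), diag(n), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  })
})

test_that("point-dipole coupling matches an SI-constants oracle", {
  # oracle: V = mu^2 / (4 pi eps0 R^3) expressed in cm^-1, from raw constants
  debye <- 3.33564e-30   # C m
  eps0 <- 8.8541878128e-12
  h <- 6.62607015e-34
  c_cm <- 2.99792458e10
  v_joule <- debye^2 / (4 * pi * eps0 * (10e-10)^3)
  v_cm1 <- v_joule / (h * c_cm)

  a <- transition_dipole(c(0, 0, 0), c(1, 0, 0), 1)
  b <- transition_dipole(c(0, 0, 10), c(1, 0, 0), 1)
  got <- point_dipole_coupling(a, b)
  expect_equal(ev_to_wavenumber(as.numeric(got)), v_cm1, tolerance = 1e-3)
  expect_equal(as.numeric(got), 6.24e-4, tolerance = 1e-3)

  # perpendicular geometry kills the coupling
  bp <- transition_dipole(c(0, 0, 10), c(0, 1, 0), 1)
  expect_equal(as.numeric(point_dipole_coupling(a, bp)), 0,
               tolerance = 1e-15)

  # R^-3 scaling and exchange symmetry
  b2 <- transition_dipole(c(0, 0, 20), c(1, 0, 0), 1)
  expect_equal(as.numeric(point_dipole_coupling(a, b2)),
               as.numeric(got) / 8, tolerance = 1e-12)
  expect_equal(as.numeric(point_dipole_coupling(b, a)), as.numeric(got))

  close_b <- transition_dipole(c(0, 0, 0.5), c(1, 0, 0), 1)
  expect_true(attr(point_dipole_coupling(a, close_b), "near_singular"))
  expect_false(attr(got, "near_singular"))
})

test_that("exciton spectra obey the dipole-strength sum rule", {
  dip <- function(z, dir, mu) transition_dipole(c(0, 0, z), dir, mu)
  # H-aggregate limit: degenerate parallel dipoles, positive coupling
  sys <- exciton_system(c(2.5, 2.5),
                        tibble::tibble(i = 1, j = 2, v_ev = 0.05),
                        dipoles = list(dip(0, c(1, 0, 0), 10),
                                       dip(5, c(1, 0, 0), 10)))
  res <- diagonalize(sys)
  expect_equal(res$intensities[1], 200, tolerance = 1e-9) # all in upper state
  expect_equal(res$intensities[2], 0, tolerance = 1e-9)
  sp <- exciton_spectrum(res, fwhm = 20)
  expect_lt(lambda_max(sp), ev_to_nm(2.5)) # blue-shifted absorption

  # zero coupling: two equal sticks at the site wavelengths
  sys0 <- exciton_system(c(2.551, 2.427), NULL,
                         dipoles = list(dip(0, c(1, 0, 0), 10),
                                        dip(5, c(1, 0, 0), 10)))
  res0 <- diagonalize(sys0)
  expect_equal(res0$intensities, c(100, 100), tolerance = 1e-9)

  # sum rule is independent of the coupling strength
  withr::with_seed(13, {
    for (i in 1:8) {
      n <- sample(2:6, 1)
      mus <- runif(n, 5, 15)
      dips <- purrr::map(seq_len(n), function(k) {
        transition_dipole(rnorm(3), rnorm(3), mus[k])
      })
      v <- matrix(rnorm(n^2, sd = 0.08), n)
      v <- (v + t(v)) / 2
      diag(v) <- 0
      res <- diagonalize(exciton_system(runif(n, 2, 3), v, dipoles = dips))
      expect_equal(sum(res$intensities), sum(mus^2), tolerance = 1e-6)
    }
  })
})

test_that("the broadened dimer spectrum peaks at the dominant eigenstate", {
  dips <- list(transition_dipole(c(0, 0, 0), c(1, 0, 0), 13),
               transition_dipole(c(0, 0, 5), c(0.99, 0.14, 0), 13))
  res <- diagonalize(hcp2_exciton_system(dipoles = dips))
  sp <- exciton_spectrum(res, fwhm = 10, grid_step = 0.05)
  dominant <- res$wavelengths_nm[which.max(res$intensities)]
  expect_lt(abs(lambda_max(sp) - dominant), 1)

  bare <- diagonalize(hcp2_exciton_system())
  expect_error(exciton_spectrum(bare, fwhm = 10),
               class = "carospec_config_error")
})

test_that("exciton systems survive the JSON round trip", {
  dips <- list(transition_dipole(c(0, 0, 0), c(1, 0, 0), 13),
               transition_dipole(c(0, 0, 5), c(1, 0, 0), 13))
  sys <- hcp2_exciton_system(dipoles = dips)
  path <- withr::local_tempfile(fileext = ".json")
  write_exciton_json(sys, path)
  back <- read_exciton_json(path)
  expect_equal(back$site_energies_ev, sys$site_energies_ev)
  expect_equal(back$coupling_ev, sys$coupling_ev)
  expect_equal(diagonalize(back)$energies_ev,
               diagonalize(sys)$energies_ev, tolerance = 1e-12)
  expect_equal(back$dipoles[[2]]$center, c(0, 0, 5))
})
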