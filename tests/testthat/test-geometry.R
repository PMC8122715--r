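test_that("torsion angles follow the signed IUPAC convention", {
  expect_equal(compute_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                c(1, 1, 0)), 0)
  expect_equal(compute_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                c(1, -1, 0)), 180)
  expect_equal(compute_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                c(1, 0, 1)), 90)
  # collinear middle bond leaves the torsion undefined
  expect_error(compute_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                c(3, 1, 0)),
               class = "carospec_undefined_torsion")
})

test_that("torsions agree with an independent implementation", {
  withr::with_seed(42, {
    for (i in 1:20) {
      p <- matrix(rnorm(12), 4, 3)
      expect_equal(
        compute_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
        as.numeric(bio3d::torsion.xyz(as.vector(t(p)))),
        tolerance = 1e-8
      )
    }
  })
})

test_that("torsions are rigid-motion invariant, mirror-odd and reversal-even", {
  withr::with_seed(7, {
    for (i in 1:15) {
      p <- matrix(rnorm(12, sd = 2), 4, 3)
      ref <- compute_dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
      rot <- random_rotation()
      shift <- rnorm(3, sd = 10)
      q <- sweep(p %*% t(rot), 2, shift, `+`)
      expect_equal(compute_dihedral(q[1, ], q[2, ], q[3, ], q[4, ]), ref,
                   tolerance = 1e-9)
      m <- p
      m[, 3] <- -m[, 3] # mirror flips chirality, negating the torsion
      expect_equal(compute_dihedral(m[1, ], m[2, ], m[3, ], m[4, ]), -ref,
                   tolerance = 1e-9)
      expect_equal(compute_dihedral(p[4, ], p[3, ], p[2, ], p[1, ]), ref,
                   tolerance = 1e-9)
    }
  })
})

test_that("ring dihedrals recover the torsions a fixture was built with", {
  for (tors in list(c(37.2, 178.3), c(74.0, 179.3), c(-45, 160))) {
    g <- build_toy_chromophore("A", 10, tors)
    d <- ring_dihedrals(g)
    expect_equal(d$phi1_deg, tors[1], tolerance = 0.1)
    expect_equal(d$phi2_deg, tors[2], tolerance = 0.1)
  }
})

test_that("PDB loading resolves ligands per chain and flags defects", {
  path <- toy_dimer_pdb()
  geoms <- read_chromophores(path, "CAN")
  expect_length(geoms, 2)
  expect_setequal(purrr::map_chr(geoms, "chain"), c("A", "B"))

  expect_error(read_chromophores(path, "XYZ"),
               class = "carospec_not_found")

  # drop one ring atom from chain A -> incomplete-ligand error naming it
  lines <- readLines(path)
  broken <- withr::local_tempfile(fileext = ".pdb")
  drop <- which(grepl("^HETATM", lines) &
                  substr(lines, 13, 16) == " C5 " &
                  substr(lines, 22, 22) == "A")[1]
  writeLines(lines[-drop], broken)
  err <- expect_error(read_chromophores(broken, "CAN"),
                      class = "carospec_incomplete_ligand")
  expect_match(conditionMessage(err), "C5")
})

test_that("altloc records resolve to the highest-occupancy atom", {
  path <- toy_dimer_pdb()
  lines <- readLines(path)
  i <- which(grepl("^HETATM", lines) & substr(lines, 13, 16) == " C5 " &
               substr(lines, 22, 22) == "A")[1]
  base <- lines[i]
  ref_x <- as.numeric(substr(base, 31, 38))
  lo <- base
  substr(lo, 17, 17) <- "A"
  substr(lo, 31, 38) <- sprintf("%8.3f", ref_x + 2)
  substr(lo, 55, 60) <- "  0.30"
  hi <- base
  substr(hi, 17, 17) <- "B"
  substr(hi, 55, 60) <- "  0.70"
  alt <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(lines[seq_len(i - 1)], lo, hi, lines[-seq_len(i)]), alt)
  g <- read_chromophores(alt, "CAN")[[1]]
  expect_equal(unname(g$coords["C5", 1]), ref_x, tolerance = 1e-3)
})

test_that("the transition-dipole axis tracks the polyene chain", {
  # perfectly collinear chain along x (tiny y jitter breaks exact degeneracy)
  xyz <- cbind(seq(0, 9), rep(c(0.001, -0.001), 5), 0)
  rownames(xyz) <- paste0("P", 1:10)
  g <- chromophore_geometry("A", "CAN", xyz,
                            quadruples = list(beta1 = paste0("P", 1:4),
                                              beta2 = paste0("P", 7:10)),
                            polyene = paste0("P", 1:10))
  d <- transition_dipole_axis(g, magnitude = 13)
  expect_equal(d$center, colMeans(xyz), tolerance = 1e-9)
  expect_equal(abs(d$direction[1]), 1, tolerance = 1e-4)
  expect_equal(d$magnitude, 13)

  # reversing atom order leaves the sign-normalized direction unchanged
  g_rev <- chromophore_geometry("A", "CAN", xyz[10:1, ],
                                quadruples = list(beta1 = paste0("P", 4:1),
                                                  beta2 = paste0("P", 10:7)),
                                polyene = paste0("P", 10:1))
  expect_equal(transition_dipole_axis(g_rev)$direction, d$direction,
               tolerance = 1e-9)

  # realistic zigzag: principal axis close to the end-to-end vector
  gz <- build_toy_chromophore("A", 12, c(45, 170))
  dz <- transition_dipole_axis(gz)
  ends <- gz$coords[gz$polyene[c(1, length(gz$polyene))], ]
  e2e <- (ends[2, ] - ends[1, ]) / sqrt(sum((ends[2, ] - ends[1, ])^2))
  ang <- acos(min(1, abs(sum(dz$direction * e2e)))) * 180 / pi
  expect_lt(ang, 5)

  # spherically symmetric coordinates have no unique long axis
  sph <- rbind(diag(3), -diag(3)) * 2
  rownames(sph) <- paste0("S", 1:6)
  gs <- chromophore_geometry("A", "CAN", sph,
                             quadruples = list(beta1 = paste0("S", 1:4),
                                               beta2 = paste0("S", 3:6)),
                             polyene = paste0("S", 1:6))
  expect_error(transition_dipole_axis(gs),
               class = "carospec_degenerate_axis")
})

test_that("the orientation factor hits its closed-form values and bounds", {
  dip <- function(center, dir) transition_dipole(center, dir, 1)
  stacked <- pair_geometry(dip(c(0, 0, 0), c(1, 0, 0)),
                           dip(c(0, 0, 5), c(1, 0, 0)))
  expect_equal(stacked$kappa, 1, tolerance = 1e-12)
  expect_equal(stacked$r_angstrom, 5)

  collinear <- pair_geometry(dip(c(0, 0, 0), c(0, 0, 1)),
                             dip(c(0, 0, 5), c(0, 0, 1)))
  expect_equal(collinear$kappa, -2, tolerance = 1e-12)

  perp <- pair_geometry(dip(c(0, 0, 0), c(1, 0, 0)),
                        dip(c(0, 0, 5), c(0, 1, 0)))
  expect_equal(perp$kappa, 0, tolerance = 1e-12)

  expect_error(pair_geometry(dip(c(0, 0, 0), c(1, 0, 0)),
                             dip(c(0, 0, 0), c(0, 1, 0))),
               class = "carospec_singular_geometry")

  withr::with_seed(3, {
    for (i in 1:50) {
      k <- pair_geometry(dip(rnorm(3), rnorm(3)), dip(rnorm(3) + 5, rnorm(3)))$kappa
      expect_gte(k, -2)
      expect_lte(k, 2)
    }
  })
})

test_that("geometric results are invariant under rigid motion of the structure", {
  g <- build_toy_chromophore("A", 10, c(37.2, 178.3))
  ref <- ring_dihedrals(g)
  withr::with_seed(21, {
    for (i in 1:5) {
      rot <- random_rotation()
      shift <- rnorm(3, sd = 20)
      coords <- sweep(g$coords %*% t(rot), 2, shift, `+`)
      rownames(coords) <- rownames(g$coords)
      gr <- chromophore_geometry("A", "CAN", coords, polyene = g$polyene)
      moved <- ring_dihedrals(gr)
      expect_equal(moved$phi1_deg, ref$phi1_deg, tolerance = 1e-6)
      expect_equal(moved$phi2_deg, ref$phi2_deg, tolerance = 1e-6)
    }
  })
})
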