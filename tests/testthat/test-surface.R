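test_that("the four reference anchors calibrate to within 2 nm each", {
  m <- calibrate_surface(hcp2_anchors())
  expect_true(all(abs(m$residuals_nm) <= 2))
  expect_equal(predict_lambda_max(m, 37.2, 178.3, "protein"), 492,
               tolerance = 2 / 492)
  # both condensed-phase environments are red-shifting relative to hexane
  offs <- m$env_offsets_ev
  expect_lt(offs[["protein"]], 0)
  expect_lt(offs[["water"]], 0)
  expect_identical(offs[["hexane"]], 0)
  aug <- augment(m)
  expect_equal(aug$.resid, m$residuals_nm)
})

test_that("calibration recovers known parameters from a synthetic design", {
  truth <- surface_model(1.9, 7.5, 8.2,
                         c(protein = -0.06, water = -0.025))
  design <- tibble::tibble(
    phi1_deg = c(10, 45, 80, 30, 60, 150),
    phi2_deg = c(170, 160, 100, 140, 175, 20),
    environment = c("protein", "protein", "hexane", "water", "water",
                    "hexane")
  )
  design$lambda_max_nm <- predict(truth, design)
  fit <- calibrate_surface(design, fixed = NULL)
  est <- tidy(fit)
  want <- c(einf_ev = 1.9, b_ev = 7.5, n0 = 8.2,
            offset_protein = -0.06, offset_water = -0.025)
  got <- setNames(est$estimate, est$term)[names(want)]
  expect_equal(unname(got), unname(want), tolerance = 0.01)

  # refitting a fitted model to its own predictions is idempotent
  design2 <- design
  design2$lambda_max_nm <- predict(fit, design2)
  refit <- calibrate_surface(design2, fixed = NULL)
  expect_equal(tidy(refit)$estimate, est$estimate, tolerance = 1e-3)
})

test_that("under-determined or ill-labelled calibrations fail fast", {
  two <- hcp2_anchors()[1:2, ]
  expect_error(calibrate_surface(two, fixed = NULL),
               class = "carospec_calibration_error")
  # offsets cannot be identified from a single environment
  one_env <- dplyr::mutate(hcp2_anchors()[1:2, ], environment = "protein")
  expect_error(calibrate_surface(one_env, fixed = c(n0 = 9)),
               class = "carospec_calibration_error")
  m <- calibrate_surface(hcp2_anchors())
  expect_error(predict_lambda_max(m, 40, 160, "membrane"),
               class = "carospec_config_error")
})

test_that("the surface honours cos^2 symmetry and conjugation monotonicity", {
  m <- surface_model(1.3, 14, 9, c(protein = -0.09))
  phis <- seq(5, 175, by = 10)
  expect_equal(predict_lambda_max(m, phis, 120, "protein"),
               predict_lambda_max(m, -phis, -120, "protein"))
  expect_equal(predict_lambda_max(m, phis, 120, "protein"),
               predict_lambda_max(m, 180 - phis, 60, "protein"))
  # lambda_max decreases as phi1 moves from planarity toward 90 degrees
  seq_to_90 <- seq(0, 90, by = 5)
  lams <- predict_lambda_max(m, seq_to_90, 170, "protein")
  expect_true(all(diff(lams) < 0))
  # 90/90 is the global minimum over the torsion grid
  grid <- scan_surface(m, step = 5, environment = "protein")
  at_min <- which.min(grid$lambda_max_nm)
  expect_equal(c(grid$phi1_deg[at_min], grid$phi2_deg[at_min]), c(90, 90))
  # maxima sit at a fully planar corner
  corner <- grid[which.max(grid$lambda_max_nm), ]
  expect_true(corner$phi1_deg %in% c(0, 180) && corner$phi2_deg %in% c(0, 180))
})

test_that("scan grids separate display offsets from analysis values", {
  m <- surface_model(1.3, 14, 9)
  plain <- scan_surface(m, step = 15, environment = "hexane")
  shifted <- scan_surface(m, step = 15, environment = "hexane",
                          display_offset_nm = 25)
  expect_equal(shifted$lambda_display_nm, plain$lambda_max_nm + 25)
  expect_equal(shifted$lambda_max_nm, plain$lambda_max_nm)

  # vanishing conjugation coefficient gives a flat surface
  flat <- scan_surface(surface_model(2.5, 1e-9, 9), step = 30)
  expect_lt(diff(range(flat$lambda_max_nm)), 1e-6)

  expect_error(scan_surface(m, step = 0), class = "carospec_input_error")
  expect_error(scan_surface(m, step = 91), class = "carospec_input_error")
})

test_that("surface models survive the JSON round trip", {
  m <- calibrate_surface(hcp2_anchors())
  path <- withr::local_tempfile(fileext = ".json")
  write_surface_json(m, path)
  back <- read_surface_json(path)
  d <- hcp2_anchors()
  expect_equal(predict(back, d), predict(m, d), tolerance = 1e-12)
})

test_that("anchor tables survive the CSV round trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_anchors_csv(hcp2_anchors(), path)
  back <- read_anchors_csv(path)
  expect_equal(back$lambda_max_nm, hcp2_anchors()$lambda_max_nm)
  m <- calibrate_surface(back)
  expect_true(all(abs(m$residuals_nm) <= 2))
})
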