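#' Construct a conjugation-surface model
#'
#' A surrogate for the torsion-dependent absorption maximum of a carotenoid.
#' The effective conjugation increases as either end-ring approaches
#' planarity (s-cis near 0° or s-trans near 180°), which a free-electron-style
#' energy expression captures:
#' \deqn{E(\phi_1, \phi_2) = E_\infty + \frac{B}{n_0 + \cos^2\phi_1 +
#'   \cos^2\phi_2} + \Delta_{env}, \qquad \lambda_{max} = hc / E.}
#' \eqn{E_\infty} is the infinite-conjugation asymptote, \eqn{B} the
#' conjugation-length coefficient, \eqn{n_0} the effective base conjugation
#' of the polyene chain, and \eqn{\Delta_{env}} an additive environment
#' offset (hexane is the zero reference). The \eqn{\cos^2} dependence makes
#' the surface symmetric under \eqn{\phi \to -\phi} and
#' \eqn{\phi \to 180° - \phi}: s-cis and s-trans planar forms are degenerate
#' in the surrogate, both maximally red-shifted.
#'
#' @param einf_ev Infinite-conjugation energy asymptote (eV).
#' @param b_ev Conjugation-length coefficient (eV), > 0.
#' @param n0 Effective base conjugation count (dimensionless), > 0.
#' @param env_offsets_ev Named numeric vector of environment offsets (eV);
#'   `hexane` is forced to 0. Negative offsets are red shifts.
#' @param display_offset_nm Constant display-only wavelength offset (nm) used
#'   when rendering scan grids; never applied to analysis values.
#' @return A `surface_model` object.
#' @seealso [calibrate_surface()], [predict.surface_model()], [scan_surface()]
#' @export
surface_model <- function(einf_ev, b_ev, n0,
                          env_offsets_ev = c(hexane = 0),
                          display_offset_nm = 0) {
  stopifnot(is.numeric(einf_ev), is.numeric(b_ev), is.numeric(n0))
  if (b_ev <= 0 || n0 <= 0) {
    rlang::abort("`b_ev` and `n0` must be positive.",
                 class = "carospec_input_error")
  }
  env_offsets_ev <- c(hexane = 0, env_offsets_ev[names(env_offsets_ev) != "hexane"])
  m <- structure(
    list(einf_ev = einf_ev, b_ev = b_ev, n0 = n0,
         env_offsets_ev = env_offsets_ev,
         display_offset_nm = display_offset_nm),
    class = "surface_model"
  )
  # the surface must stay positive-energy over the whole torsion range
  worst <- einf_ev + b_ev / (n0 + 2) + min(env_offsets_ev)
  if (!is.finite(worst) || worst <= 0) {
    rlang::abort("model predicts non-positive excitation energies.",
                 class = "carospec_input_error")
  }
  m
}

#' @export
print.surface_model <- function(x, ...) {
  cat("<surface_model>\n")
  cat(sprintf("  E_inf = %.4f eV, B = %.4f eV, n0 = %.4f\n",
              x$einf_ev, x$b_ev, x$n0))
  for (env in names(x$env_offsets_ev)) {
    cat(sprintf("  offset[%s] = %+.4f eV\n", env, x$env_offsets_ev[[env]]))
  }
  if (!is.null(x$residuals_nm)) {
    cat(sprintf("  calibrated on %d anchors, max |resid| = %.3g nm\n",
                length(x$residuals_nm), max(abs(x$residuals_nm))))
  }
  invisible(x)
}

surface_energy_ev <- function(model, phi1_deg, phi2_deg, environment) {
  off <- model$env_offsets_ev[environment]
  if (any(is.na(off))) {
    bad <- unique(environment[!environment %in% names(model$env_offsets_ev)])
    rlang::abort(paste0("unknown environment label(s): ",
                        paste(bad, collapse = ", ")),
                 class = "carospec_config_error")
  }
  c1 <- cos(phi1_deg * pi / 180)^2
  c2 <- cos(phi2_deg * pi / 180)^2
  model$einf_ev + model$b_ev / (model$n0 + c1 + c2) + unname(off)
}

#' Predict the absorption maximum for given torsions and environment
#'
#' @param model A [surface_model()].
#' @param phi1_deg,phi2_deg End-ring torsions (degrees); vectorized.
#' @param environment Environment label(s) present in the model offsets.
#' @return Numeric vector of absorption maxima (nm).
#' @examples
#' m <- surface_model(1.28, 14.2, 9, c(protein = -0.09, water = -0.04))
#' predict_lambda_max(m, 37.2, 178.3, "protein")
#' @export
predict_lambda_max <- function(model, phi1_deg, phi2_deg, environment) {
  stopifnot(inherits(model, "surface_model"))
  ev_to_nm(surface_energy_ev(model, phi1_deg, phi2_deg, environment))
}

#' @describeIn calibrate_surface Predict from a data frame with `phi1_deg`,
#'   `phi2_deg` and `environment` columns; returns a numeric vector (nm).
#' @param object A fitted `surface_model`.
#' @param newdata Data frame of torsions and environments.
#' @export
predict.surface_model <- function(object, newdata, ...) {
  predict_lambda_max(object, newdata$phi1_deg, newdata$phi2_deg,
                     newdata$environment)
}

#' Calibrate the conjugation surface against anchor points
#'
#' Least-squares fit (in energy space) of the surface parameters to anchor
#' observations: torsion pairs with known absorption maxima in known
#' environments. Free parameters are \eqn{E_\infty}, \eqn{B}, \eqn{n_0} and
#' one offset per non-hexane environment present in the anchors; any of them
#' can be pinned through `fixed`. The fit starts from
#' \eqn{E_\infty = 2} eV, \eqn{B = 6} eV, \eqn{n_0 = 9}, offsets 0, and uses
#' bounded Levenberg–Marquardt least squares (1000 iteration cap).
#'
#' With the four crystal-structure anchors of HCP2 (two protein sites, one
#' hexane, one water) the default pin `fixed = c(n0 = 9)` leaves four free
#' parameters for four anchors and the system solves essentially exactly.
#'
#' @param anchors Data frame with columns `phi1_deg`, `phi2_deg`,
#'   `environment`, `lambda_max_nm`; at least as many rows as free
#'   parameters.
#' @param fixed Named numeric vector pinning parameters, e.g.
#'   `c(n0 = 9)` or `c(offset_water = -0.04)`. Offsets are named
#'   `offset_<environment>`.
#' @return A fitted `surface_model` carrying `anchors`, `residuals_nm`
#'   (observed − fitted, nm) and convergence information. [generics::tidy()]
#'   returns the parameter table, [generics::glance()] the fit summary and
#'   [generics::augment()] the anchors with fitted values and residuals.
#' @export
calibrate_surface <- function(anchors, fixed = c(n0 = 9)) {
  if (!is.data.frame(anchors) ||
      !all(c("phi1_deg", "phi2_deg", "environment", "lambda_max_nm") %in%
             names(anchors))) {
    rlang::abort(paste("`anchors` needs phi1_deg, phi2_deg, environment,",
                       "lambda_max_nm columns."),
                 class = "carospec_input_error")
  }
  anchors <- tibble::as_tibble(anchors)
  if (any(anchors$lambda_max_nm <= 300 | anchors$lambda_max_nm >= 700)) {
    rlang::abort("anchor lambda_max values must lie in (300, 700) nm.",
                 class = "carospec_input_error")
  }
  envs <- setdiff(unique(anchors$environment), "hexane")
  par_names <- c("einf_ev", "b_ev", "n0",
                 if (length(envs)) paste0("offset_", envs))
  fixed <- fixed[names(fixed) %in% par_names]
  free <- setdiff(par_names, names(fixed))
  if (length(free) > nrow(anchors)) {
    rlang::abort(sprintf(
      "under-determined calibration: %d free parameters (%s) but only %d anchors.",
      length(free), paste(free, collapse = ", "), nrow(anchors)),
      class = "carospec_calibration_error")
  }
  free_offsets <- grepl("^offset_", free)
  if (any(free_offsets) && length(unique(anchors$environment)) < 2) {
    rlang::abort("anchors must span >= 2 environments to fit environment offsets.",
                 class = "carospec_calibration_error")
  }

  start <- c(einf_ev = 2.0, b_ev = 6.0, n0 = 9.0,
             stats::setNames(rep(0, length(envs)), paste0("offset_", envs)))
  lower <- c(einf_ev = -Inf, b_ev = 1e-6, n0 = 1e-6,
             stats::setNames(rep(-Inf, length(envs)), paste0("offset_", envs)))
  start[names(fixed)] <- fixed

  target_ev <- nm_to_ev(anchors$lambda_max_nm)
  build <- function(theta) {
    p <- start
    p[free] <- theta
    offs <- p[grepl("^offset_", names(p))]
    names(offs) <- sub("^offset_", "", names(offs))
    list(einf_ev = p[["einf_ev"]], b_ev = p[["b_ev"]], n0 = p[["n0"]],
         env_offsets_ev = c(hexane = 0, offs))
  }
  resid_fn <- function(theta) {
    p <- build(theta)
    pred <- p$einf_ev + p$b_ev /
      (p$n0 + cos(anchors$phi1_deg * pi / 180)^2 +
         cos(anchors$phi2_deg * pi / 180)^2) +
      unname(p$env_offsets_ev[anchors$environment])
    pred - target_ev
  }
  opt <- minpack.lm::nls.lm(start[free], lower = lower[free], fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 1000, ftol = 1e-14, ptol = 1e-14))
  p <- build(opt$par)
  rss <- sum(opt$fvec^2)
  if (!opt$info %in% 1:4 && sqrt(rss / nrow(anchors)) > 1e-4) {
    rlang::abort(paste0("calibration did not converge (", opt$message,
                        "); RMS energy residual ",
                        signif(sqrt(rss / nrow(anchors)), 3), " eV."),
                 class = "carospec_convergence_error")
  }
  model <- surface_model(p$einf_ev, p$b_ev, p$n0, p$env_offsets_ev)
  model$anchors <- anchors
  model$fitted_nm <- predict_lambda_max(model, anchors$phi1_deg,
                                        anchors$phi2_deg, anchors$environment)
  model$residuals_nm <- anchors$lambda_max_nm - model$fitted_nm
  model$fixed <- fixed
  model$rss_ev2 <- rss
  model$converged <- opt$info %in% 1:4
  model
}

#' @rdname calibrate_surface
#' @param x A fitted `surface_model`.
#' @param ... Unused.
#' @export
tidy.surface_model <- function(x, ...) {
  est <- c(einf_ev = x$einf_ev, b_ev = x$b_ev, n0 = x$n0)
  offs <- x$env_offsets_ev[names(x$env_offsets_ev) != "hexane"]
  if (length(offs)) {
    est <- c(est, stats::setNames(as.numeric(offs), paste0("offset_", names(offs))))
  }
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    fixed = names(est) %in% names(x$fixed %||% character())
  )
}

#' @rdname calibrate_surface
#' @export
glance.surface_model <- function(x, ...) {
  tibble::tibble(
    n_anchors = if (is.null(x$anchors)) 0L else nrow(x$anchors),
    rss_ev2 = x$rss_ev2 %||% NA_real_,
    max_abs_residual_nm = if (is.null(x$residuals_nm)) NA_real_
                          else max(abs(x$residuals_nm)),
    converged = x$converged %||% NA
  )
}

#' @rdname calibrate_surface
#' @export
augment.surface_model <- function(x, ...) {
  if (is.null(x$anchors)) {
    rlang::abort("model was not calibrated from anchors.",
                 class = "carospec_input_error")
  }
  dplyr::mutate(x$anchors, .fitted = x$fitted_nm, .resid = x$residuals_nm)
}

#' Scan the torsion surface on a regular grid
#'
#' Evaluates the absorption maximum on a \eqn{\phi_1 \times \phi_2} grid over
#' \eqn{[0°, 180°]} for one environment, suitable for contour rendering. An
#' optional constant display offset (nm) can be added for plot alignment —
#' it appears only in the `lambda_display_nm` column; `lambda_max_nm` always
#' holds the analysis value.
#'
#' @param model A [surface_model()].
#' @param step Grid step in degrees, in (0, 90].
#' @param environment Environment label.
#' @param display_offset_nm Display offset (nm); defaults to the model's.
#' @return A `surface_scan` tibble: `phi1_deg`, `phi2_deg`, `lambda_max_nm`,
#'   `lambda_display_nm`.
#' @export
scan_surface <- function(model, step = 5, environment = "hexane",
                         display_offset_nm = NULL) {
  stopifnot(inherits(model, "surface_model"))
  if (step <= 0 || step > 90) {
    rlang::abort("`step` must be in (0, 90] degrees.",
                 class = "carospec_input_error")
  }
  off <- display_offset_nm %||% model$display_offset_nm %||% 0
  grid <- tidyr::expand_grid(
    phi1_deg = seq(0, 180, by = step),
    phi2_deg = seq(0, 180, by = step)
  )
  grid <- dplyr::mutate(
    grid,
    lambda_max_nm = predict_lambda_max(model, .data$phi1_deg, .data$phi2_deg,
                                       environment),
    lambda_display_nm = .data$lambda_max_nm + off
  )
  class(grid) <- c("surface_scan", class(grid))
  attr(grid, "environment") <- environment
  attr(grid, "display_offset_nm") <- off
  grid
}

#' Contour plot of a torsion scan
#'
#' @param object A `surface_scan` from [scan_surface()].
#' @param ... Unused.
#' @return A ggplot (filled contour of the displayed absorption maximum).
#' @export
autoplot.surface_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$phi1_deg, y = .data$phi2_deg,
                                       z = .data$lambda_display_nm)) +
    ggplot2::geom_contour_filled() +
    ggplot2::labs(x = expression(phi[1] ~ "(deg)"),
                  y = expression(phi[2] ~ "(deg)"),
                  fill = expression(lambda[max] ~ "(nm)")) +
    ggplot2::theme_minimal()
}

#' Read and write surface models and anchors
#'
#' Models serialize to JSON (parameters, offsets, display offset); anchors
#' travel as CSV with columns `phi1_deg`, `phi2_deg`, `environment`,
#' `lambda_max_nm`.
#'
#' @param model A `surface_model`.
#' @param path File path.
#' @return Readers return the object; writers return `path` invisibly.
#' @export
write_surface_json <- function(model, path) {
  stopifnot(inherits(model, "surface_model"))
  jsonlite::write_json(
    list(einf_ev = model$einf_ev, b_ev = model$b_ev, n0 = model$n0,
         env_offsets_ev = as.list(model$env_offsets_ev),
         display_offset_nm = model$display_offset_nm),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_surface_json
#' @export
read_surface_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  surface_model(x$einf_ev, x$b_ev, x$n0,
                env_offsets_ev = unlist(x$env_offsets_ev),
                display_offset_nm = x$display_offset_nm %||% 0)
}

#' @rdname write_surface_json
#' @export
read_anchors_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' @rdname write_surface_json
#' @param anchors Anchor data frame.
#' @export
write_anchors_csv <- function(anchors, path) {
  utils::write.csv(as.data.frame(anchors), path, row.names = FALSE)
  invisible(path)
}
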