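#' Summarize a snapshot ensemble of absorption maxima
#'
#' Mean, sample standard deviation (n − 1 denominator) and the two-sided
#' one-sample t confidence interval
#' \eqn{\bar x \pm t_{(1+c)/2,\,n-1}\, s/\sqrt n} for a set of per-snapshot
#' absorption maxima, as used to report snapshot-averaged spectra from
#' molecular-dynamics ensembles.
#'
#' @param x Numeric vector of absorption maxima (nm), or a data frame with a
#'   `lambda_max_nm` column.
#' @param confidence Confidence level in (0, 1); default 0.95.
#' @param ci Compute the confidence interval (requires n >= 2). With
#'   `ci = FALSE` a single observation is summarized without bounds.
#' @return One-row tibble: `n`, `mean_nm`, `sd_nm`, `ci_low_nm`, `ci_high_nm`,
#'   `confidence`.
#' @examples
#' set.seed(1)
#' summarize_ensemble(rnorm(51, mean = 481.9, sd = 12.7))
#' @export
summarize_ensemble <- function(x, confidence = 0.95, ci = TRUE) {
  if (is.data.frame(x)) {
    stopifnot("lambda_max_nm" %in% names(x))
    x <- x$lambda_max_nm
  }
  stopifnot(is.numeric(x), all(is.finite(x)), all(x > 0))
  if (confidence <= 0 || confidence >= 1) {
    rlang::abort("`confidence` must lie strictly between 0 and 1.",
                 class = "carospec_input_error")
  }
  n <- length(x)
  if (ci && n < 2) {
    rlang::abort("confidence interval undefined for n < 2; use `ci = FALSE` for the mean only.",
                 class = "carospec_ci_undefined")
  }
  m <- mean(x)
  s <- if (n >= 2) stats::sd(x) else NA_real_
  half <- if (ci) stats::qt((1 + confidence) / 2, df = n - 1) * s / sqrt(n)
          else NA_real_
  tibble::tibble(
    n = n, mean_nm = m, sd_nm = s,
    ci_low_nm = m - half, ci_high_nm = m + half,
    confidence = confidence
  )
}

#' Circular mean and resultant length of a set of angles
#'
#' Angles live on the circle: torsions of +170° and −170° average to 180°,
#' not 0°. The circular mean is the direction of the mean resultant vector
#' of the unit vectors \eqn{(\cos\theta, \sin\theta)}; its length
#' \eqn{\bar R \in [0, 1]} measures concentration (1 = all angles equal,
#' 0 = no preferred direction, in which case the mean is undefined).
#'
#' @param angles_deg Numeric vector of angles (degrees), any range.
#' @return One-row tibble: `n`, `mean_deg` (in (−180, 180], `NA` when
#'   undefined), `rbar`, `mean_defined`.
#' @export
circular_summary <- function(angles_deg) {
  stopifnot(is.numeric(angles_deg), length(angles_deg) >= 1,
            all(is.finite(angles_deg)))
  rad <- angles_deg * pi / 180
  s <- mean(sin(rad))
  c_ <- mean(cos(rad))
  rbar <- sqrt(s^2 + c_^2)
  defined <- rbar > 1e-12
  mean_deg <- if (defined) {
    ang <- atan2(s, c_) * 180 / pi
    if (ang <= -180) ang + 360 else ang
  } else NA_real_
  tibble::tibble(n = length(angles_deg), mean_deg = mean_deg, rbar = rbar,
                 mean_defined = defined)
}

#' Predict and summarize absorption maxima over a snapshot ensemble
#'
#' Runs the calibrated torsion surface over every snapshot of a dihedral
#' ensemble — the surrogate for per-snapshot excited-state calculations —
#' and summarizes the resulting absorption maxima. If the ensemble already
#' carries a `lambda_max_nm` column it is used as-is and the surface step is
#' skipped.
#'
#' @param ensemble Data frame with `phi1_deg` and `phi2_deg` columns (and
#'   optionally `snapshot` ids and precomputed `lambda_max_nm`).
#' @param model A calibrated [surface_model()]; may be `NULL` when
#'   `lambda_max_nm` is already present.
#' @param environment Environment label for the surface prediction.
#' @param confidence Confidence level for [summarize_ensemble()].
#' @return List with `snapshots` (the ensemble with a `lambda_max_nm`
#'   column) and `summary` (one-row tibble).
#' @export
ensemble_pipeline <- function(ensemble, model = NULL, environment = "protein",
                              confidence = 0.95) {
  stopifnot(is.data.frame(ensemble), nrow(ensemble) >= 1)
  ensemble <- tibble::as_tibble(ensemble)
  if (!"lambda_max_nm" %in% names(ensemble)) {
    if (is.null(model)) {
      rlang::abort("no `lambda_max_nm` column and no surface model supplied.",
                   class = "carospec_config_error")
    }
    stopifnot(all(c("phi1_deg", "phi2_deg") %in% names(ensemble)))
    ensemble <- dplyr::mutate(
      ensemble,
      lambda_max_nm = predict_lambda_max(model, .data$phi1_deg,
                                         .data$phi2_deg, environment)
    )
  }
  list(
    snapshots = ensemble,
    summary = summarize_ensemble(ensemble$lambda_max_nm,
                                 confidence = confidence,
                                 ci = nrow(ensemble) >= 2)
  )
}

#' Read and write snapshot ensembles as CSV
#'
#' Columns: `snapshot`, `phi1_deg`, `phi2_deg` and optionally
#' `lambda_max_nm`.
#'
#' @param ensemble Ensemble data frame.
#' @param path File path.
#' @return Reader returns a tibble; writer returns `path` invisibly.
#' @export
read_ensemble_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' @rdname read_ensemble_csv
#' @export
write_ensemble_csv <- function(ensemble, path) {
  utils::write.csv(as.data.frame(ensemble), path, row.names = FALSE)
  invisible(path)
}

#' Scatter plot of an end-ring dihedral ensemble
#'
#' Torsions are folded to absolute values in [0°, 180°] for display, the
#' conventional rendering of end-ring conformational scatter; analysis
#' functions keep signed angles.
#'
#' @param ensemble Data frame with `phi1_deg`, `phi2_deg`.
#' @param scan Optional `surface_scan` underlay from [scan_surface()].
#' @return A ggplot.
#' @export
plot_dihedral_scatter <- function(ensemble, scan = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(scan)) {
    p <- p + ggplot2::geom_contour_filled(
      data = scan,
      ggplot2::aes(x = .data$phi1_deg, y = .data$phi2_deg,
                   z = .data$lambda_display_nm),
      alpha = 0.7
    )
  }
  p +
    ggplot2::geom_point(
      data = dplyr::mutate(ensemble, phi1_deg = abs(.data$phi1_deg),
                           phi2_deg = abs(.data$phi2_deg)),
      ggplot2::aes(x = .data$phi1_deg, y = .data$phi2_deg)
    ) +
    ggplot2::labs(x = expression(phi[1] ~ "(deg)"),
                  y = expression(phi[2] ~ "(deg)")) +
    ggplot2::theme_minimal()
}
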