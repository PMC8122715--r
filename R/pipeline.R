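# End-to-end runs: crystal-structure analysis (dihedrals -> surface ->
# exciton -> shift decomposition) and snapshot-ensemble analysis. Configs are
# plain lists or YAML files, validated before any computation (fail-fast);
# every run with an output directory writes a manifest (config hash, seed,
# versions) sufficient to reproduce it.

log_line <- function(stage, msg, level = "INFO") {
  message(sprintf("%s | %s | %s | %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), stage, level, msg))
}

as_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    rlang::abort("`config` must be a list or the path to a YAML file.",
                 class = "carospec_config_error")
  }
  config
}

config_md5 <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # the hash identifies the run, not its destination
  config$out_dir <- NULL
  saveRDS(config, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

resolve_surface <- function(config) {
  if (!is.null(config$surface_model)) {
    if (is.character(config$surface_model)) {
      return(read_surface_json(config$surface_model))
    }
    if (inherits(config$surface_model, "surface_model")) {
      return(config$surface_model)
    }
    rlang::abort("`surface_model` must be a surface_model or a JSON path.",
                 class = "carospec_config_error")
  }
  anchors <- config$anchors
  if (is.character(anchors)) anchors <- read_anchors_csv(anchors)
  if (is.null(anchors)) anchors <- hcp2_anchors()
  calibrate_surface(anchors)
}

validate_config <- function(config, required_paths = character()) {
  for (field in required_paths) {
    p <- config[[field]]
    if (is.character(p) && !file.exists(p)) {
      rlang::abort(paste0("config path `", field, "` does not exist: ", p),
                   class = "carospec_config_error")
    }
  }
  conf <- config$confidence %||% 0.95
  if (conf <= 0 || conf >= 1) {
    rlang::abort("`confidence` must lie in (0, 1).",
                 class = "carospec_config_error")
  }
  quad <- config$quadruples %||% default_quadruples()
  if (!is.list(quad) || !all(c("beta1", "beta2") %in% names(quad)) ||
      length(quad$beta1) != 4 || length(quad$beta2) != 4) {
    rlang::abort("`quadruples` must name four atoms for beta1 and beta2.",
                 class = "carospec_config_error")
  }
  invisible(config)
}

write_manifest <- function(config, out_dir, seed = NULL) {
  jsonlite::write_json(
    list(config_md5 = config_md5(config), seed = seed,
         package = "carospec",
         package_version = as.character(utils::packageVersion("carospec")),
         r_version = R.version.string),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, null = "null"
  )
}

#' Crystal-structure analysis run
#'
#' Full analysis of a (real or synthetic) crystal structure holding one or
#' two carotenoid ligands: per-monomer end-ring dihedrals, surrogate
#' absorption maxima, the exciton eigenstates of the dimer, and a staged
#' shift decomposition (solution conformation → protein-distorted
#' conformation → protein environment → excitonic coupling). For a
#' monomer-only structure the exciton and coupling stages are omitted and
#' noted in the report.
#'
#' @param config List or YAML path with fields: `pdb` (path, required);
#'   `residue` (default `"CAN"`); `quadruples` (default
#'   [default_quadruples()]); `environment` (default `"protein"`);
#'   `surface_model` (fitted model or JSON path) or `anchors` (data frame or
#'   CSV path; defaults to [hcp2_anchors()]); `exciton_system` (an
#'   [exciton_system()] or JSON path; when absent a dimer's system is built
#'   from surface site energies and the point-dipole coupling);
#'   `dipole_debye` (default 13); `fwhm` (default 30 nm);
#'   `reference_torsions` / `reference_environment` (solution-state
#'   reference for the decomposition; default the hexane anchor, (40.7°,
#'   143.3°)); `out_dir` (optional: writes `report.json`, `report.md`,
#'   `manifest.json`).
#' @return A `crystal_report` list: `dihedrals`, `monomer_lambda`, `exciton`
#'   (tidy state table or `NULL`), `decomposition`, `notes`.
#' @export
run_crystal_analysis <- function(config) {
  config <- as_run_config(config)
  if (is.null(config$pdb)) {
    rlang::abort("config must name a `pdb` file.",
                 class = "carospec_config_error")
  }
  validate_config(config, required_paths = c("pdb", "surface_model", "anchors",
                                             "exciton_system"))
  residue <- config$residue %||% "CAN"
  env <- config$environment %||% "protein"
  quad <- config$quadruples %||% default_quadruples()
  notes <- character()

  log_line("structure", paste("reading", config$pdb))
  geoms <- read_chromophores(config$pdb, residue, quad,
                             polyene = config$polyene)
  dihedrals <- purrr::list_rbind(purrr::map(geoms, ring_dihedrals))

  log_line("surface", "resolving surface model")
  model <- resolve_surface(config)
  monomer_lambda <- dplyr::mutate(
    dihedrals,
    environment = env,
    lambda_max_nm = predict_lambda_max(model, .data$phi1_deg, .data$phi2_deg,
                                       env)
  )

  exciton_tidy <- NULL
  coupling_ev <- NULL
  if (length(geoms) >= 2) {
    log_line("exciton", "building and diagonalizing the exciton system")
    sys <- config$exciton_system
    if (is.character(sys)) sys <- read_exciton_json(sys)
    if (is.null(sys)) {
      mu <- config$dipole_debye %||% 13
      dips <- purrr::map(geoms, transition_dipole_axis, magnitude = mu)
      v <- as.numeric(point_dipole_coupling(dips[[1]], dips[[2]]))
      coupling_ev <- v
      sys <- exciton_system(
        nm_to_ev(monomer_lambda$lambda_max_nm[1:2]),
        tibble::tibble(i = 1, j = 2, v_ev = v),
        dipoles = dips[1:2]
      )
    }
    res <- diagonalize(sys)
    exciton_tidy <- tidy(res)
    coupling_ev <- coupling_ev %||% sys$coupling_ev[1, 2]
  } else {
    notes <- c(notes, "single chromophore: exciton block omitted")
    log_line("exciton", "single chromophore; skipping", "WARN")
  }

  ref_tor <- config$reference_torsions %||% c(40.7, 143.3)
  ref_env <- config$reference_environment %||% "hexane"
  best <- which.max(monomer_lambda$lambda_max_nm)
  stages <- tibble::tibble(
    label = c("solution conformation",
              "protein-distorted conformation",
              "protein environment"),
    lambda_max_nm = c(
      predict_lambda_max(model, ref_tor[1], ref_tor[2], ref_env),
      predict_lambda_max(model, monomer_lambda$phi1_deg[best],
                         monomer_lambda$phi2_deg[best], ref_env),
      monomer_lambda$lambda_max_nm[best]
    )
  )
  if (!is.null(exciton_tidy)) {
    stages <- dplyr::bind_rows(stages, tibble::tibble(
      label = "excitonic coupling",
      lambda_max_nm = max(exciton_tidy$wavelength_nm)
    ))
  }
  decomposition <- decompose_shift(stages)

  report <- structure(
    list(dihedrals = dihedrals, monomer_lambda = monomer_lambda,
         exciton = exciton_tidy, coupling_ev = coupling_ev,
         decomposition = decomposition, surface = tidy(model),
         notes = notes),
    class = "crystal_report"
  )
  if (!is.null(config$out_dir)) {
    write_crystal_report(report, config)
  }
  report
}

write_crystal_report <- function(report, config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(
      dihedrals = report$dihedrals,
      monomer_lambda = report$monomer_lambda,
      exciton = report$exciton,
      coupling_ev = report$coupling_ev,
      shift_stages = report$decomposition$stages,
      shift_total_nm = report$decomposition$total,
      notes = report$notes
    ),
    file.path(out, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null"
  )
  md <- c(
    "# Crystal-structure analysis",
    "", "## End-ring dihedrals and surrogate absorption maxima", "",
    utils::capture.output(print(as.data.frame(report$monomer_lambda))),
    "", "## Shift decomposition", "",
    utils::capture.output(print(report$decomposition))
  )
  if (!is.null(report$exciton)) {
    md <- c(md, "", "## Exciton states", "",
            utils::capture.output(print(as.data.frame(report$exciton))))
  }
  if (length(report$notes)) md <- c(md, "", paste("Note:", report$notes))
  writeLines(md, file.path(out, "report.md"))
  write_manifest(config, out, seed = config$seed)
  log_line("report", paste("written to", out))
}

#' @export
print.crystal_report <- function(x, ...) {
  cat("<crystal_report>\n\nMonomer absorption maxima:\n")
  print(x$monomer_lambda)
  if (!is.null(x$exciton)) {
    cat("\nExciton states:\n")
    print(x$exciton)
  }
  cat("\n")
  print(x$decomposition)
  for (n in x$notes) cat("Note:", n, "\n")
  invisible(x)
}

#' Snapshot-ensemble analysis run
#'
#' Runs the surrogate surface over a snapshot dihedral ensemble (loaded from
#' CSV, passed as a data frame, or simulated) and reports per-snapshot
#' absorption maxima, the t-based ensemble summary, and circular statistics
#' of both torsions.
#'
#' @param config List or YAML path with fields: `ensemble` (CSV path or data
#'   frame with `phi1_deg`, `phi2_deg` and optionally `lambda_max_nm`), or
#'   `simulate` (list with `n` and `seed`, and either a `mixture` component
#'   table for dihedral sampling or `mean_nm`/`sd_nm` for direct
#'   absorption-maximum draws); `surface_model` / `anchors` as in
#'   [run_crystal_analysis()]; `environment` (default `"protein"`);
#'   `confidence` (default 0.95); `out_dir` (optional).
#' @return An `ensemble_report` list: `snapshots`, `summary`, `circular`.
#' @export
run_ensemble_analysis <- function(config) {
  config <- as_run_config(config)
  validate_config(config, required_paths = c("ensemble", "surface_model",
                                             "anchors"))
  env <- config$environment %||% "protein"
  confidence <- config$confidence %||% 0.95

  ensemble <- config$ensemble
  if (is.character(ensemble)) ensemble <- read_ensemble_csv(ensemble)
  if (is.null(ensemble)) {
    sim <- config$simulate
    if (is.null(sim)) {
      rlang::abort("config needs an `ensemble` or a `simulate` block.",
                   class = "carospec_config_error")
    }
    seed <- sim$seed %||% config$seed %||% 1
    if (!is.null(sim$mean_nm)) {
      log_line("simulate", sprintf("drawing %d snapshot maxima (seed %d)",
                                   sim$n, seed))
      ensemble <- tibble::tibble(
        snapshot = seq_len(sim$n),
        lambda_max_nm = simulate_snapshot_lambdas(sim$mean_nm, sim$sd_nm,
                                                  sim$n, seed)
      )
    } else {
      log_line("simulate", sprintf("sampling %d dihedral snapshots (seed %d)",
                                   sim$n, seed))
      mixture <- sim$mixture %||% default_dihedral_mixture()
      if (is.character(mixture)) mixture <- tibble::as_tibble(utils::read.csv(mixture))
      ensemble <- sample_dihedral_ensemble(mixture, sim$n, seed)
    }
  }

  model <- NULL
  if (!"lambda_max_nm" %in% names(ensemble)) {
    log_line("surface", "resolving surface model")
    model <- resolve_surface(config)
  }
  piped <- ensemble_pipeline(ensemble, model, env, confidence)
  circular <- NULL
  if (all(c("phi1_deg", "phi2_deg") %in% names(piped$snapshots))) {
    circular <- dplyr::bind_rows(
      dplyr::mutate(circular_summary(piped$snapshots$phi1_deg), angle = "phi1"),
      dplyr::mutate(circular_summary(piped$snapshots$phi2_deg), angle = "phi2")
    )
  }

  report <- structure(
    list(snapshots = piped$snapshots, summary = piped$summary,
         circular = circular),
    class = "ensemble_report"
  )
  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_ensemble_csv(report$snapshots, file.path(out, "snapshots.csv"))
    jsonlite::write_json(
      list(summary = report$summary, circular = report$circular),
      file.path(out, "summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null"
    )
    write_manifest(config, out,
                   seed = config$simulate$seed %||% config$seed)
    log_line("report", paste("written to", out))
  }
  report
}

#' @export
print.ensemble_report <- function(x, ...) {
  cat("<ensemble_report>\n\nEnsemble summary:\n")
  print(x$summary)
  if (!is.null(x$circular)) {
    cat("\nCircular dihedral statistics:\n")
    print(x$circular)
  }
  invisible(x)
}
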