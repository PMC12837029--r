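#' Experiment configuration for the end-to-end workflow
#'
#' Bundles every knob of the design -> simulate -> fit -> validate ->
#' select -> compare pipeline. A single master seed deterministically
#' derives all stage seeds (see [derive_seed()]), so the whole experiment
#' is reproducible from one integer.
#'
#' @param bounds named list of `c(lower, upper)` concentration bounds
#'   (default two analytes at 10-30 ug/mL).
#' @param calibration_levels coded factorial levels (default `-2:2`,
#'   giving 25 calibration mixtures for two analytes).
#' @param validation_samplers character subset of `c("mc","lhs","sobol")`.
#' @param n_validation validation mixtures per sampler (default 13).
#' @param grid wavelength grid for simulation (default [default_grid()]).
#' @param trim `c(low, high)` working window in nm (default 200-335).
#' @param noise a [noise_model()]; its seed field is ignored (stage seeds
#'   are derived from `master_seed`).
#' @param models character subset of `c("pls", "ga_pls", "ann")`.
#' @param max_lv latent-variable search bound for PLS (default 5).
#' @param ga a [ga_config()] for the GA-PLS model (seed overridden).
#' @param ann an [ann_config()] (seed overridden).
#' @param bin_step optional coarser step (nm) applied before the GA stage
#'   to bound its cost; `NULL` runs the GA on the full grid.
#' @param grid_cells uniformity-report grid resolution (default 10).
#' @param master_seed integer master seed.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(bounds = list(AZM = c(10, 30), MPM = c(10, 30)),
                              calibration_levels = -2:2,
                              validation_samplers = c("mc", "lhs", "sobol"),
                              n_validation = 13L,
                              grid = default_grid(),
                              trim = c(200, 335),
                              noise = noise_model(),
                              models = c("pls", "ga_pls", "ann"),
                              max_lv = 5L,
                              ga = ga_config(),
                              ann = ann_config(),
                              bin_step = 1,
                              grid_cells = 10L,
                              master_seed = 1L) {
  validation_samplers <- match.arg(validation_samplers,
                                   c("mc", "lhs", "sobol"), several.ok = TRUE)
  models <- match.arg(models, c("pls", "ga_pls", "ann"), several.ok = TRUE)
  structure(list(bounds = bounds, calibration_levels = calibration_levels,
                 validation_samplers = validation_samplers,
                 n_validation = as.integer(n_validation), grid = grid,
                 trim = trim, noise = noise, models = models,
                 max_lv = as.integer(max_lv), ga = ga, ann = ann,
                 bin_step = bin_step, grid_cells = as.integer(grid_cells),
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

stage_noise <- function(noise, seed) {
  noise$seed <- seed
  noise
}

#' Run the full sampling-vs-model comparison experiment
#'
#' Generates the factorial calibration design and one validation design
#' per sampler, simulates all spectra, fits the requested models on the
#' calibration set, validates every model against every sampler's
#' validation set, and summarises: a (sampler x model x analyte)
#' comparison table of RMSEP / R^2 / %RSD, per-sampler uniformity reports,
#' and a Friedman test of the samplers using the per-(model, analyte)
#' RMSEP values as matched blocks.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory: when given, all designs, spectra,
#'   the comparison table and a manifest of md5 hashes are written there.
#' @return list of class `experiment_result` with `designs`, `spectra`,
#'   `models`, `comparison`, `uniformity`, `friedman`, `manifest`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  ms <- config$master_seed
  space <- do.call(design_space, config$bounds)
  library <- default_band_library(space$variables$name)

  prep <- function(design, seed_label) {
    s <- simulate_mixtures(design, library, config$grid,
                           stage_noise(config$noise, derive_seed(ms, seed_label)))
    trim_wavelengths(s, config$trim[1], config$trim[2])
  }

  cal_design <- factorial_calibration_design(space, config$calibration_levels)
  cal <- prep(cal_design, "simulate/calibration")

  designs <- list(calibration = cal_design)
  val_sets <- list()
  for (smp in config$validation_samplers) {
    d <- switch(smp,
      mc = monte_carlo_design(config$n_validation, space,
                              seed = derive_seed(ms, "design/mc")),
      lhs = latin_hypercube_design(config$n_validation, space,
                                   seed = derive_seed(ms, "design/lhs")),
      sobol = sobol_design(config$n_validation, space))
    designs[[smp]] <- d
    val_sets[[smp]] <- prep(d, paste0("simulate/", smp))
  }

  X <- cal$absorbance; Y <- cal$concentrations
  models <- list()
  ga_sel <- NULL
  for (mdl in config$models) {
    if (mdl == "pls") {
      k <- select_lv_loocv(X, Y, min(config$max_lv, nrow(X) - 2L))$n_lv
      models$pls <- fit_pls(X, Y, k)
    } else if (mdl == "ga_pls") {
      ga_cal <- if (!is.null(config$bin_step)) bin_spectra(cal, config$bin_step) else cal
      cfg <- config$ga
      cfg$seed <- derive_seed(ms, "select/ga")
      ga_sel <- ga_select(ga_cal$absorbance, Y, cfg)
      models$ga_pls <- structure(
        list(selection = ga_sel, bin_step = config$bin_step), class = "ga_pls_model")
    } else if (mdl == "ann") {
      cfg <- config$ann
      cfg$seed <- derive_seed(ms, "fit/ann")
      models$ann <- fit_ann(X, Y, cfg)
    }
  }

  predict_model <- function(mdl, val) {
    if (inherits(mdl, "ga_pls_model")) {
      v <- if (!is.null(mdl$bin_step)) bin_spectra(val, mdl$bin_step) else val
      predict(mdl$selection$model,
              v$absorbance[, mdl$selection$selected, drop = FALSE])
    } else predict(mdl, val$absorbance)
  }

  rows <- list()
  for (smp in names(val_sets)) {
    val <- val_sets[[smp]]
    for (mname in names(models)) {
      pred <- predict_model(models[[mname]], val)
      for (j in seq_len(ncol(Y))) {
        met <- error_metrics(val$concentrations[, j], pred[, j])
        rows[[length(rows) + 1L]] <- data.frame(
          sampler = smp, model = mname, analyte = colnames(Y)[j],
          rmsep = met$rmse, r2 = met$r2, mean_recovery = met$mean_recovery,
          rsd_percent = met$rsd_percent)
      }
    }
  }
  comparison <- do.call(rbind, rows)

  uniformity <- lapply(designs[config$validation_samplers],
                       uniformity_report, cells_per_dim = config$grid_cells)

  friedman <- NULL
  if (length(config$validation_samplers) >= 2L && length(models) >= 1L) {
    blocks <- stats::xtabs(rmsep ~ paste(model, analyte) + sampler,
                           data = comparison)
    friedman <- friedman_test(unclass(blocks))
  }

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(designs))
      write_design_csv(designs[[nm]], file.path(out_dir, paste0("design_", nm, ".csv")))
    write_spectra_csv(cal, file.path(out_dir, "spectra_calibration.csv"),
                      file.path(out_dir, "conc_calibration.csv"))
    for (nm in names(val_sets))
      write_spectra_csv(val_sets[[nm]],
                        file.path(out_dir, paste0("spectra_", nm, ".csv")),
                        file.path(out_dir, paste0("conc_", nm, ".csv")))
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(uniformity, file.path(out_dir, "uniformity.json"),
                         digits = NA, auto_unbox = TRUE)
    files <- sort(list.files(out_dir, full.names = TRUE))
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }

  structure(list(config = config, designs = designs, calibration = cal,
                 validation = val_sets, models = models,
                 comparison = comparison, uniformity = uniformity,
                 friedman = friedman, manifest = manifest),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment:", length(x$validation), "sampler(s) x",
      length(x$models), "model(s)\n")
  print(x$comparison, row.names = FALSE)
  if (!is.null(x$friedman))
    cat(sprintf("Friedman across samplers: chisq = %.3f (df %d), p = %.4g\n",
                x$friedman$chisq, x$friedman$df, x$friedman$p_value))
  invisible(x)
}
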