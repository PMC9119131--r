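RUN_CONFIG_KEYS <- c(
  "mode", "input", "output_dir", "p_total", "keq_apo",
  "kd_wt", "kd_slip", "ligand_grid", "temperature_grid",
  "max_temperature", "min_points", "weighted", "delta_g_temperature",
  "delta_h", "delta_s", "plateau_above", "n_peaks_per_conformer",
  "noise_cv", "noise_model", "seed", "plots", "verbose", "what"
)

#' Assemble a run configuration
#'
#' Reads a YAML configuration file (or accepts a named list) and applies
#' overrides, validating the analysis mode and rejecting unknown keys
#' before any computation. Modes: `quantify` (peak volumes to
#' populations), `vanthoff` (temperature series to thermodynamic
#' parameters), `titration` (ligand series to Kd/Bmax), `shift-curve`
#' (forward-model population shift), `simulate` (synthetic data).
#'
#' @param config Path to a YAML file, or a named list.
#' @param ... Individual overrides (e.g. `p_total = 200`) taking
#'   precedence over the file values.
#' @return A validated `run_config` list.
#' @export
run_config <- function(config, ...) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    stop("config must be a YAML file path or a named list", call. = FALSE)
  }
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$mode) ||
      !cfg$mode %in% c("quantify", "vanthoff", "titration", "shift-curve",
                       "simulate")) {
    stop("mode must be one of quantify, vanthoff, titration, shift-curve, ",
         "simulate", call. = FALSE)
  }
  needs_input <- cfg$mode %in% c("quantify", "vanthoff", "titration")
  if (needs_input && is.null(cfg$input)) {
    stop("mode '", cfg$mode, "' requires an input peak-volume table",
         call. = FALSE)
  }
  if (cfg$mode == "titration" && is.null(cfg$p_total)) {
    stop("titration mode requires p_total (µM)", call. = FALSE)
  }
  if (cfg$mode == "shift-curve" &&
      (is.null(cfg$keq_apo) || is.null(cfg$kd_wt) || is.null(cfg$p_total))) {
    stop("shift-curve mode requires keq_apo, kd_wt and p_total",
         call. = FALSE)
  }
  cfg$output_dir <- cfg$output_dir %||% "."
  cfg$verbose <- isTRUE(cfg$verbose)
  cfg$plots <- isTRUE(cfg$plots)
  structure(cfg, class = "run_config")
}

say <- function(cfg, ...) if (isTRUE(cfg$verbose)) message(...)

write_tsv_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  path
}

#' Run an analysis pipeline from a configuration
#'
#' Executes the requested analysis mode and writes its artifacts
#' (delimited tables, a text report, and optionally PDF plots) to the
#' configured output directory. Every defaulted assumption that affects
#' the numbers — the equilibrium-constant direction, the apo equilibrium
#' constant used in the bound-state inversion, clipping of negative
#' bound concentrations — is stated in the report.
#'
#' @param config A [run_config()], YAML path, or named list.
#' @return Invisibly, a named list of the written file paths plus the
#'   main result object.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(cfg$mode,
    "quantify" = pipeline_quantify(cfg),
    "vanthoff" = pipeline_vanthoff(cfg),
    "titration" = pipeline_titration(cfg),
    "shift-curve" = pipeline_shift_curve(cfg),
    "simulate" = pipeline_simulate(cfg)
  )
  invisible(out)
}

pipeline_quantify <- function(cfg) {
  say(cfg, "reading peak table: ", cfg$input)
  tab <- read_peak_table(cfg$input)
  pops <- percent_populations(tab)
  f_tab <- write_tsv_report(pops, file.path(cfg$output_dir,
                                            "populations.tsv"))
  rpt <- c(
    "Conformer population quantification",
    "Keq direction: [WT]/[SLIP] (SLIP -> WT conversion)",
    sprintf("%d condition(s) quantified from %d peaks",
            nrow(pops), nrow(tab)),
    utils::capture.output(print(as.data.frame(pops)))
  )
  f_rpt <- file.path(cfg$output_dir, "quantify_report.txt")
  writeLines(rpt, f_rpt)
  files <- list(populations = f_tab, report = f_rpt)
  if (cfg$plots) {
    f <- file.path(cfg$output_dir, "populations.pdf")
    save_plot(autoplot(pops), f)
    files$plot <- f
  }
  c(files, list(result = pops))
}

pipeline_vanthoff <- function(cfg) {
  tab <- read_peak_table(cfg$input)
  pops <- percent_populations(tab)
  max_t <- cfg$max_temperature %||% 303
  region <- select_linear_region(pops, min_points = cfg$min_points %||% 3L,
                                 max_temperature = max_t)
  excluded <- setdiff(sort(unique(pops$covariate)), region)
  fit <- vant_hoff_fit(pops, region = region,
                       weighted = isTRUE(cfg$weighted))
  t_ref <- cfg$delta_g_temperature %||% 298
  params <- tidy(fit)
  params <- dplyr::bind_rows(params, tibble::tibble(
    term = sprintf("delta_g_%gK", t_ref),
    estimate = delta_g(fit, t_ref), std.error = NA_real_,
    unit = "kcal mol^-1"))
  f_tab <- write_tsv_report(params, file.path(cfg$output_dir,
                                              "vant_hoff_fit.tsv"))
  rpt <- c(
    "Van't Hoff analysis (Keq = [WT]/[SLIP], SLIP -> WT conversion)",
    sprintf("linear region: %s K%s",
            paste(region, collapse = ", "),
            if (length(excluded) > 0L)
              sprintf(" (excluded from fit: %s K)",
                      paste(excluded, collapse = ", "))
            else ""),
    utils::capture.output(print(fit))
  )
  f_rpt <- file.path(cfg$output_dir, "vanthoff_report.txt")
  writeLines(rpt, f_rpt)
  files <- list(fit_table = f_tab, report = f_rpt)
  if (cfg$plots) {
    f <- file.path(cfg$output_dir, "vant_hoff.pdf")
    save_plot(autoplot(fit), f)
    files$plot <- f
  }
  c(files, list(result = fit))
}

pipeline_titration <- function(cfg) {
  tab <- read_peak_table(cfg$input)
  series <- titration_series(tab, p_total = cfg$p_total,
                             keq_apo = cfg$keq_apo)
  say(cfg, sprintf("apo equilibrium constant used in inversion: %g",
                   series$keq_apo))
  fit <- titration_fit(series)
  n_clip <- sum(fit$points$clipped)
  f_pts <- write_tsv_report(fit$points,
                            file.path(cfg$output_dir,
                                      "titration_points.tsv"))
  f_tab <- write_tsv_report(tidy(fit),
                            file.path(cfg$output_dir, "titration_fit.tsv"))
  rpt <- c(
    "Slow-exchange titration analysis (conformational selection)",
    sprintf("Keq_apo used in bound-state inversion: %g", series$keq_apo),
    sprintf("negative bound-WT points clipped to 0: %d", n_clip),
    utils::capture.output(print(fit))
  )
  f_rpt <- file.path(cfg$output_dir, "titration_report.txt")
  writeLines(rpt, f_rpt)
  files <- list(points = f_pts, fit_table = f_tab, report = f_rpt)
  if (cfg$plots) {
    f <- file.path(cfg$output_dir, "isotherm.pdf")
    save_plot(autoplot(fit), f)
    files$plot <- f
  }
  c(files, list(result = fit))
}

pipeline_shift_curve <- function(cfg) {
  model <- four_state_model(cfg$keq_apo, cfg$kd_wt,
                            cfg$kd_slip %||% Inf)
  grid <- cfg$ligand_grid %||% c(0, 25, 50, 100, 200, 500, 1000)
  curve <- predict_shift_curve(model, cfg$p_total, grid)
  f_tab <- write_tsv_report(curve, file.path(cfg$output_dir,
                                             "shift_curve.tsv"))
  files <- list(curve = f_tab)
  if (cfg$plots) {
    f <- file.path(cfg$output_dir, "shift_curve.pdf")
    save_plot(plot_shift_curve(curve), f)
    files$plot <- f
  }
  c(files, list(result = curve))
}

pipeline_simulate <- function(cfg) {
  model <- four_state_model(cfg$keq_apo %||% 1, cfg$kd_wt %||% 684,
                            cfg$kd_slip %||% Inf)
  sc_args <- list(model = model)
  for (k in c("delta_h", "delta_s", "plateau_above", "p_total",
              "temperature_grid", "ligand_grid", "n_peaks_per_conformer",
              "noise_cv", "noise_model", "seed")) {
    if (!is.null(cfg[[k]])) sc_args[[k]] <- cfg[[k]]
  }
  sc <- do.call(synthetic_config, sc_args)
  what <- cfg$what %||% "equilibrium"
  files <- list()
  if (what %in% c("equilibrium", "both")) {
    tab <- generate_equilibrium_series(sc)
    f <- file.path(cfg$output_dir, "synthetic_equilibrium_peaks.csv")
    write_peak_table(tab, f)
    files$equilibrium <- f
  }
  if (what %in% c("titration", "both")) {
    series <- generate_titration(sc)
    f <- file.path(cfg$output_dir, "synthetic_titration_peaks.csv")
    write_peak_table(series$table, f)
    files$titration <- f
  }
  c(files, list(result = sc))
}
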