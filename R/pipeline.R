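#' Default pipeline configuration
#'
#' The study conditions as generated by default: an undifferentiated
#' population of 1,084 cells against 2,920 differentiating cells, 31 FRAP
#' traces per state, 92/75 EB1 cells, 60/70-cell density samples
#' (plus the 107/96-cell iso/hypo-osmotic arms), the 25/50/100-ng blot with
#' 4/2/1-ug lanes, and 500-um^3 cell-volume bins spanning 1,000-3,500 um^3.
#'
#' @param seed master seed; per-stage seeds are derived with [split_seed()].
#' @return a named run-config list.
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = seed,
    bin_edges = seq(1000, 3500, 500),
    reference_state = "ESC",
    states = list(ESC = list(n = 1084), DIF = list(n = 2920)),
    occupancy = list(n = c(ESC = 188, DIF = 182)),
    frap = list(n = 31, noise_sd = 0.02),
    eb1 = list(n_cells = c(ESC = 92, DIF = 75), tracks_per_cell = 60,
               profiles = c(ESC = 158, DIF = 98)),
    density = list(n = c(ESC = 60, DIF = 70, ISO = 107, HYPO = 96),
                   ri_medium = 1.337),
    blot = list(true_percent = 1.5, noise_cv = 0.05),
    model = list(n_per_state = 2000)
  )
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes generate -> scaling -> FRAP -> EB1 -> density/blot -> model in
#' order, under one master seed, and returns a structured report.  Stages
#' whose config section is `NULL` are omitted; the remaining stages are
#' unaffected.  Identical `(config, seed)` give an identical report (up to
#' the provenance timestamp).
#'
#' @param config run-config list (see [default_run_config()] /
#'   [read_run_config()]).
#' @param output_dir optional directory; when given, every stage table is
#'   written as CSV and the report as JSON.
#' @param mparams a [model_params()] object.
#' @return object of class `spindle_report` (a nested list of tibbles plus
#'   `provenance`).
#' @export
run_pipeline <- function(config = default_run_config(), output_dir = NULL,
                         mparams = model_params()) {
  stopifnot(is.list(config), !is.null(config$seed))
  seed <- config$seed
  report <- list()

  # --- synthgen: per-state populations -------------------------------------
  states <- names(config$states)
  cells <- purrr::map_dfr(states, function(st) {
    generate_cell_population(state_params(st), n = config$states[[st]]$n,
                             seed = split_seed(seed, paste0("cells_", st)),
                             mparams = mparams)
  })
  report$cells <- cells

  # --- scaling -------------------------------------------------------------
  if (!is.null(config$bin_edges)) {
    ref <- config$reference_state
    bins <- lapply(setNames(states, states), function(st) {
      summarise_bins(filter(cells, .data$state == st), config$bin_edges)
    })
    per_bin_tests <- NULL
    sub <- NULL
    others <- setdiff(states, ref)
    if (ref %in% states && length(others)) {
      sub <- lapply(setNames(others, others), function(st) {
        subscaling_profile(bins[[ref]], bins[[st]])
      })
      binned <- bin_by_cell_volume(cells, config$bin_edges)
      per_bin_tests <- purrr::map_dfr(others, function(st) {
        purrr::map_dfr(unique(bins[[ref]]$bin), function(b) {
          va <- binned$V_spindle_um3[binned$bin == b & binned$state == ref]
          vb <- binned$V_spindle_um3[binned$bin == b & binned$state == st]
          if (length(va) < 2 || length(vb) < 2) return(NULL)
          mutate(compare_groups(va, vb), bin = b, test_state = st,
                 .before = 1)
        })
      })
    }
    report$scaling <- list(
      bin_summaries = bind_rows(bins, .id = "state"),
      subscaling = sub,
      per_bin_tests = per_bin_tests,
      spearman_pooled = spearman_rho(cells$V_cell_um3, cells$V_spindle_um3),
      volume_comparison = if (length(others) == 1)
        compare_groups(cells$V_cell_um3[cells$state == ref],
                       cells$V_cell_um3[cells$state == others]) else NULL
    )
  }

  # --- centrosome occupancy ------------------------------------------------
  if (!is.null(config$occupancy)) {
    occ_states <- names(config$occupancy$n)
    occ_cells <- purrr::map_dfr(occ_states, function(st) {
      generate_cell_population(state_params(st), n = config$occupancy$n[[st]],
                               seed = split_seed(seed, paste0("occ_", st)),
                               mparams = mparams)
    })
    occ_cells$occupancy_pct <- occupancy(occ_cells$V_centrosome_um3,
                                         occ_cells$V_cell_um3)
    ref <- config$reference_state
    folds <- purrr::map_dfr(setdiff(occ_states, ref), function(st) {
      fc <- fold_change_vs_control(
        occ_cells$occupancy_pct[occ_cells$state == st],
        occ_cells$occupancy_pct[occ_cells$state == ref])
      tibble(state = st, median_fold = fc$median_fold,
             iqr_low = fc$iqr[1], iqr_high = fc$iqr[2])
    })
    report$occupancy <- list(cells = occ_cells, folds = folds)
  }

  # --- FRAP ----------------------------------------------------------------
  if (!is.null(config$frap)) {
    frap_fits <- purrr::map_dfr(states, function(st) {
      tr <- generate_frap_traces(state_params(st), n = config$frap$n,
                                 seed = split_seed(seed, paste0("frap_", st)),
                                 noise_sd = config$frap$noise_sd %||% 0.02)
      mutate(fit_frap_traces(tr), state = st, .before = 1)
    })
    report$frap <- list(
      fits = frap_fits,
      summary = frap_fits %>%
        filter(.data$qc_pass) %>%
        group_by(.data$state) %>%
        summarise(mean_t_half_s = mean(.data$t_half),
                  sd_t_half_s = sd(.data$t_half),
                  n = dplyr::n(), .groups = "drop"))
  }

  # --- EB1 -----------------------------------------------------------------
  if (!is.null(config$eb1)) {
    eb1_cells <- purrr::map_dfr(states, function(st) {
      tr <- generate_comet_tracks(
        state_params(st),
        n_cells = config$eb1$n_cells[[st]],
        tracks_per_cell = config$eb1$tracks_per_cell,
        seed = split_seed(seed, paste0("eb1_", st)))
      kept <- filter_tracks(tr)$kept
      speeds <- mean_growth_speed(kept)
      parts <- kept %>%
        group_by(.data$cell_id) %>%
        dplyr::group_modify(~ comet_partition(.x, .x$V_cell_um3[1])) %>%
        ungroup()
      mutate(left_join(speeds, parts, by = "cell_id"), state = st,
             .before = 1)
    })
    profs <- purrr::map_dfr(states, function(st) {
      pr <- generate_half_spindle_profiles(
        state_params(st), n = config$eb1$profiles[[st]],
        seed = split_seed(seed, paste0("prof_", st)))
      mutate(pole_signal_fractions(pr), state = st, .before = 1)
    })
    report$eb1 <- list(
      per_cell = eb1_cells,
      pole_fractions = profs,
      summary = eb1_cells %>%
        group_by(.data$state) %>%
        summarise(mean_speed_um_per_s = mean(.data$v_p_um_per_s),
                  mean_comets_per_um3 = mean(.data$comets_per_um3),
                  median_astral_bulk_ratio =
                    median(.data$astral_bulk_ratio, na.rm = TRUE),
                  n = dplyr::n(), .groups = "drop"))
  }

  # --- mass density & blot -------------------------------------------------
  if (!is.null(config$density)) {
    dens_states <- names(config$density$n)
    ri_medium <- config$density$ri_medium %||% 1.337
    dens <- purrr::map_dfr(dens_states, function(st) {
      cc <- generate_cell_population(state_params(st),
                                     n = config$density$n[[st]],
                                     seed = split_seed(seed, paste0("dens_", st)),
                                     mparams = mparams)
      ri <- ri_from_mass_density(cc$rho_mg_per_ml, ri_medium)
      tibble(state = st, cell_id = cc$cell_id, ri_raw = ri,
             rho_mg_per_ml = mass_density_from_ri(ri, ri_medium)$rho_mg_per_ml)
    })
    report$density <- list(
      cells = dens,
      summary = dens %>%
        group_by(.data$state) %>%
        summarise(mean_rho = mean(.data$rho_mg_per_ml),
                  sd_rho = sd(.data$rho_mg_per_ml), n = dplyr::n(),
                  .groups = "drop"))
  }
  if (!is.null(config$blot)) {
    blot <- generate_blot_dataset(
      true_tubulin_percent = config$blot$true_percent %||% 1.5,
      noise_cv = config$blot$noise_cv %||% 0.05,
      seed = split_seed(seed, "blot"))
    report$blot <- quantify_tubulin_fraction(blot)
  }

  # --- CPAP-tubulin model --------------------------------------------------
  if (!is.null(config$model)) {
    n_model <- config$model$n_per_state %||% 2000
    model_cells <- purrr::map_dfr(states, function(st) {
      generate_cell_population(state_params(st), n = n_model,
                               seed = split_seed(seed, paste0("model_", st)),
                               mparams = mparams)
    })
    fits <- astral_saturation_analysis(model_cells,
                                       edges = config$bin_edges %||%
                                         seq(1000, 3500, 500))
    est <- estimate_astral_counts(model_cells, mparams)
    report$model <- list(
      fits = fits,
      estimates = est,
      estimator_bias = mean(est$astral_estimate_raw - est$n_astral_true))
  }

  report$provenance <- list(
    config_hash = rlang::hash(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("spindlescale")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  report <- structure(report, class = "spindle_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.spindle_report <- function(x, ...) {
  cat("<spindle_report> stages:",
      paste(setdiff(names(x), "provenance"), collapse = ", "), "\n")
  cat("  seed", x$provenance$seed, "| config", x$provenance$config_hash, "\n")
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Stage tables become CSV files; the report summary (without the large
#' per-cell tables) becomes `report.json`.
#'
#' @param report a `spindle_report`.
#' @param output_dir directory (created if absent).
#' @return `output_dir`, invisibly.
#' @export
write_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$cells)) {
    write_cell_records(report$cells, file.path(output_dir, "cells.csv"))
  }
  if (!is.null(report$frap)) {
    readr::write_csv(report$frap$fits, file.path(output_dir, "frap_fits.csv"))
  }
  if (!is.null(report$eb1)) {
    readr::write_csv(report$eb1$per_cell, file.path(output_dir, "eb1_cells.csv"))
  }
  if (!is.null(report$density)) {
    readr::write_csv(report$density$cells, file.path(output_dir, "density.csv"))
  }
  summary_view <- list(
    scaling = if (!is.null(report$scaling)) list(
      bin_summaries = report$scaling$bin_summaries,
      spearman_pooled = report$scaling$spearman_pooled,
      max_deficit_pct = purrr::map(report$scaling$subscaling,
                                   "max_deficit_pct")),
    occupancy_folds = report$occupancy$folds,
    frap = report$frap$summary,
    eb1 = report$eb1$summary,
    density = report$density$summary,
    blot_percent = report$blot$percent_mean,
    model = if (!is.null(report$model)) list(
      fits = select(report$model$fits, -"fit"),
      estimator_bias = report$model$estimator_bias),
    provenance = report$provenance)
  jsonlite::write_json(summary_view, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(output_dir)
}
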