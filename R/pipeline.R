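#' Pipeline configuration
#'
#' Bundles every tunable the analysis stages consume. The defaults are
#' the package's reference conditions: salinity 35, CO2-system reference
#' temperature 25 degC, total-scale constants with zero pH-scale offset,
#' O2 diffusion coefficient 2.01e-9 m^2 s^-1, 14:10 photoperiod, 100 um
#' linear fit window, Gran window pH 3.0-3.5 and alpha 0.05.
#'
#' @param salinity Practical salinity of the experimental seawater.
#' @param temp_c CO2-system reference temperature, degC.
#' @param ph_scale_offset Additive pH-scale correction (pH units).
#' @param diffusion_coefficient O2 diffusion coefficient, m^2 s^-1.
#' @param h_light,h_dark Photoperiod, h.
#' @param fit_window_um DBL linear-fit window, um.
#' @param gran_ph_window Gran fit pH window.
#' @param alpha Significance level.
#' @param seed Seed echoed into reports.
#' @return A list of class `rl_config`.
#' @export
pipeline_config <- function(salinity = 35, temp_c = 25, ph_scale_offset = 0,
                            diffusion_coefficient = 2.01e-9,
                            h_light = 14, h_dark = 10,
                            fit_window_um = 100,
                            gran_ph_window = c(3.0, 3.5),
                            alpha = 0.05, seed = 1L) {
  structure(list(salinity = salinity, temp_c = temp_c,
                 ph_scale_offset = ph_scale_offset,
                 diffusion_coefficient = diffusion_coefficient,
                 h_light = h_light, h_dark = h_dark,
                 fit_window_um = fit_window_um,
                 gran_ph_window = gran_ph_window,
                 alpha = alpha, seed = seed),
            class = "rl_config")
}

#' Write a simulated study bundle to disk
#'
#' Materialises an [simulate_study()] bundle in the on-disk dialects the
#' pipeline reads: `profiles/*.csv` (paired consecutive traces),
#' `titrations/*.csv`, `incubations.csv`, `volumes/<id>/` TIFF stacks,
#' `species_meta.csv` (protuberance dimensions) and `truth.json`.
#'
#' @param study An `rl_study`.
#' @param dir Target directory (created).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(study, dir) {
  dir.create(file.path(dir, "profiles"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "titrations"), showWarnings = FALSE)
  dir.create(file.path(dir, "volumes"), showWarnings = FALSE)
  for (id in names(study$profiles)) {
    pair <- study$profiles[[id]]
    for (i in seq_along(pair)) {
      write_microprofile(pair[[i]],
                         file.path(dir, "profiles", sprintf("%s_run%d.csv", id, i)))
    }
  }
  for (id in names(study$titrations)) {
    write_titration(study$titrations[[id]],
                    file.path(dir, "titrations", paste0(id, ".csv")))
  }
  readr::write_csv(study$incubations, file.path(dir, "incubations.csv"))
  for (id in names(study$volumes)) {
    write_tiff_stack(study$volumes[[id]], file.path(dir, "volumes", id))
  }
  readr::write_csv(
    study$truth$presets[, c("species", "protuberance_length_mm",
                            "protuberance_diameter_mm")],
    file.path(dir, "species_meta.csv"))
  truth <- study$truth
  truth$presets <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

collect_safely <- function(paths, reader) {
  out <- list()
  failures <- character(0)
  for (p in paths) {
    res <- tryCatch(reader(p), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", basename(p), conditionMessage(res)))
    } else {
      out[[basename(p)]] <- res
    }
  }
  list(values = out, failures = failures)
}

#' Run the full analysis pipeline over an input directory
#'
#' Processes whatever subset of the four input kinds is present:
#' microprofile CSVs (replicate runs per spot are averaged, DBL
#' thickness/flux from oxygen, delta-pH from pH), titration CSVs (Gran
#' alkalinity per tube), `incubations.csv` (replicate rates, species
#' rate table per treatment, OA comparison when two treatments are
#' present), and `volumes/` TIFF stacks (segmentation and
#' morphometrics). When enough stages ran it adds the cross-stage
#' regressions: base DBL thickness against protuberance length (needs
#' `species_meta.csv`) and mean delta-pH against calcification rate.
#' Per-file parse failures are collected, reported and skipped.
#'
#' @param input_dir Directory of inputs.
#' @param config An [pipeline_config()].
#' @param output_dir Optional directory for tidy CSV/JSON reports.
#' @return A list of class `rl_report` with the result tables, the
#'   config echo and any `failures`.
#' @export
run_pipeline <- function(input_dir, config = pipeline_config(),
                         output_dir = NULL) {
  if (!dir.exists(input_dir)) abort("Input directory not found.", class = "rl_error_input")
  report <- list(config = config, failures = character(0))

  prof_files <- list.files(file.path(input_dir, "profiles"), pattern = "\\.csv$",
                           full.names = TRUE)
  tit_files <- list.files(file.path(input_dir, "titrations"), pattern = "\\.csv$",
                          full.names = TRUE)
  inc_file <- file.path(input_dir, "incubations.csv")
  vol_dirs <- list.dirs(file.path(input_dir, "volumes"), recursive = FALSE)
  if (!length(prof_files) && !length(tit_files) && !file.exists(inc_file) &&
      !length(vol_dirs)) {
    abort("Nothing to do: no recognised inputs in the directory.",
          class = "rl_error_empty")
  }

  if (length(prof_files)) {
    got <- collect_safely(prof_files, read_microprofile)
    report$failures <- c(report$failures, got$failures)
    # group replicate runs by spot id (strip the _runN suffix)
    ids <- sub("_run\\d+\\.csv$", "", names(got$values))
    dbl_rows <- list()
    dph_rows <- list()
    for (id in unique(ids)) {
      runs <- got$values[ids == id]
      prof <- if (length(runs) > 1) average_profiles(runs) else runs[[1]]
      bulk <- attr(prof, "bulk") %||% estimate_bulk(prof)$bulk
      meta <- profile_meta(prof)
      if (meta$analyte == "oxygen") {
        res <- tryCatch({
          dbl <- estimate_dbl(prof, bulk, fit_window_um = config$fit_window_um)
          fl <- fick_flux(dbl, config$diffusion_coefficient)
          dplyr::bind_cols(tibble(profile = id, species = meta$species,
                                  location = meta$location,
                                  condition = meta$condition),
                           dbl[, c("thickness_um", "surface_value",
                                   "surface_gradient", "bulk_value", "fit_r2",
                                   "n_fit")], fl)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          report$failures <- c(report$failures, sprintf("%s: %s", id, conditionMessage(res)))
        } else dbl_rows[[id]] <- res
      } else {
        dph_rows[[id]] <- dplyr::bind_cols(tibble(profile = id),
                                           delta_ph(prof, bulk))
      }
    }
    report$dbl_flux <- bind_rows(dbl_rows)
    report$delta_ph <- bind_rows(dph_rows)
  }

  if (length(tit_files)) {
    got <- collect_safely(tit_files, read_titration)
    report$failures <- c(report$failures, got$failures)
    rows <- lapply(names(got$values), function(nm) {
      res <- tryCatch(gran_alkalinity(got$values[[nm]],
                                      ph_window = config$gran_ph_window),
                      error = function(e) e)
      if (inherits(res, "error")) {
        report$failures <<- c(report$failures,
                              sprintf("%s: %s", nm, conditionMessage(res)))
        return(NULL)
      }
      dplyr::bind_cols(tibble(tube = sub("\\.csv$", "", nm)), res)
    })
    at_tubes <- bind_rows(rows)
    if (nrow(at_tubes)) {
      at_tubes$sample <- sub("_tube\\d+$", "", at_tubes$tube)
      report$alkalinity <- at_tubes
      report$alkalinity_samples <- at_tubes %>%
        group_by(.data$sample) %>%
        summarise(at = mean(.data$at), at_sd = sd(.data$at),
                  n_tubes = n(), .groups = "drop")
    }
  }

  if (file.exists(inc_file)) {
    inc <- tryCatch(readr::read_csv(inc_file, show_col_types = FALSE),
                    error = function(e) e)
    if (inherits(inc, "error")) {
      report$failures <- c(report$failures,
                           sprintf("incubations.csv: %s", conditionMessage(inc)))
    } else {
      rates <- replicate_rates(inc, h_light = config$h_light,
                               h_dark = config$h_dark)
      report$rates <- rates
      report$rate_tables <- lapply(split(rates, rates$treatment),
                                   rate_table, alpha = config$alpha)
      if (length(unique(rates$treatment)) >= 2) {
        report$oa <- oa_comparison(rates, alpha = config$alpha)
      }
    }
  }

  if (length(vol_dirs)) {
    rows <- list()
    for (vd in vol_dirs) {
      res <- tryCatch({
        vol <- read_tiff_stack(vd)
        mask <- segment_volume(vol, method = "otsu")
        m <- measure_morphology(mask)
        sp_guess <- sub("_vol\\d+$", "", basename(vd))
        dplyr::bind_cols(tibble(volume_id = basename(vd), species = sp_guess), m)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        report$failures <- c(report$failures,
                             sprintf("%s: %s", basename(vd), conditionMessage(res)))
      } else rows[[vd]] <- res
    }
    report$morphometrics <- bind_rows(rows)
    if (!is.null(report$morphometrics) && nrow(report$morphometrics) &&
        length(unique(report$morphometrics$species)) > 1 &&
        all(table(report$morphometrics$species) >= 2)) {
      report$sa_v_letters <- newman_keuls(report$morphometrics, "sa_v_mm1",
                                          "species", alpha = config$alpha)
    }
  }

  # cross-stage regressions
  meta_file <- file.path(input_dir, "species_meta.csv")
  if (!is.null(report$dbl_flux) && nrow(report$dbl_flux %||% tibble()) &&
      file.exists(meta_file)) {
    meta <- readr::read_csv(meta_file, show_col_types = FALSE)
    base_dbl <- report$dbl_flux %>%
      filter(.data$location == "base") %>%
      group_by(.data$species) %>%
      summarise(dbl_um = mean(.data$thickness_um), .groups = "drop") %>%
      left_join(meta, by = "species")
    if (nrow(base_dbl) >= 3 && !anyNA(base_dbl$protuberance_length_mm)) {
      report$dbl_vs_length <- fit_regression(base_dbl, "protuberance_length_mm",
                                             "dbl_um")
    }
  }
  if (!is.null(report$delta_ph) && !is.null(report$rates)) {
    dph_mean <- report$delta_ph %>%
      group_by(.data$species, .data$condition) %>%
      summarise(delta_ph = mean(.data$delta_ph), .groups = "drop")
    g_mean <- report$rates %>%
      filter(.data$treatment == "ambient") %>%
      group_by(.data$species) %>%
      summarise(light = mean(.data$g_light), dark = mean(.data$g_dark),
                .groups = "drop") %>%
      tidyr::pivot_longer(c("light", "dark"), names_to = "condition",
                          values_to = "calcification")
    both <- left_join(dph_mean, g_mean, by = c("species", "condition"))
    if (nrow(both) >= 3 && !anyNA(both$calcification)) {
      report$delta_ph_vs_calcification <-
        fit_regression(both, "delta_ph", "calcification")
      report$delta_ph_calcification_points <- both
    }
  }

  class(report) <- "rl_report"
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.rl_report <- function(x, ...) {
  cat("rhodolith pipeline report with tables:",
      paste(setdiff(names(x), c("config", "failures")), collapse = ", "), "\n")
  if (length(x$failures)) {
    cat(sprintf("%d input(s) failed:\n", length(x$failures)))
    cat(paste(" -", x$failures, collapse = "\n"), "\n")
  }
  invisible(x)
}

write_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(tbl, name) {
    if (!is.null(tbl) && nrow(tbl)) {
      readr::write_csv(tbl, file.path(output_dir, paste0(name, ".csv")))
    }
  }
  wr(report$dbl_flux, "dbl_flux_um_umol_cm2_h")
  wr(report$delta_ph, "delta_ph_units")
  wr(report$alkalinity, "alkalinity_umol_kg_per_tube")
  wr(report$alkalinity_samples, "alkalinity_umol_kg_per_sample")
  wr(report$rates, "rates_umol_cm2_h")
  wr(report$morphometrics, "morphometrics_mm")
  summary_json <- list(
    config = unclass(report$config),
    failures = report$failures,
    regressions = list()
  )
  for (nm in c("dbl_vs_length", "delta_ph_vs_calcification")) {
    if (!is.null(report[[nm]])) {
      summary_json$regressions[[nm]] <- list(slope = report[[nm]]$slope,
                                             intercept = report[[nm]]$intercept,
                                             r2 = report[[nm]]$r2,
                                             p = report[[nm]]$p_value)
    }
  }
  jsonlite::write_json(summary_json, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}
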