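#' Net oxygen exchange rate from sealed-chamber endpoints
#'
#' Converts start/end oxygen concentrations of a closed incubation into a
#' surface-area-normalised rate, after subtracting the oxygen change of a
#' rhodolith-free control chamber run over the same duration.
#'
#' @param records Data frame with one row per chamber-phase and columns
#'   `o2_start`, `o2_end` (umol/L), `chamber_volume` (L), `surface_area`
#'   (cm^2), `duration` (h) and `control_delta_o2` (umol/L).
#' @param allow_missing_control If `TRUE`, a missing `control_delta_o2`
#'   column (or NA entries) is treated as zero with a warning instead of
#'   an error.
#' @return The input tibble with an `o2_rate` column
#'   (umol O2 cm^-2 h^-1, signed; dark rates come out negative).
#' @export
#' @examples
#' rec <- tibble::tibble(o2_start = 210, o2_end = 235, control_delta_o2 = 1,
#'                       chamber_volume = 0.15, surface_area = 10, duration = 0.5)
#' oxygen_rate(rec)$o2_rate  # 0.72
oxygen_rate <- function(records, allow_missing_control = FALSE) {
  records <- as_tibble(records)
  if (!all(c("o2_start", "o2_end", "chamber_volume", "surface_area", "duration")
           %in% names(records))) {
    abort("Missing incubation endpoint columns.", class = "rl_error_input")
  }
  if (any(records$duration <= 0) || any(records$chamber_volume <= 0) ||
      any(records$surface_area <= 0)) {
    abort("Durations, volumes and surface areas must be positive.",
          class = "rl_error_input")
  }
  ctl <- records[["control_delta_o2"]]
  if (is.null(ctl) || anyNA(ctl)) {
    if (!allow_missing_control) {
      abort("Control oxygen correction missing; set `allow_missing_control = TRUE` to proceed with zero correction.",
            class = "rl_error_missing_control")
    }
    warn("No control oxygen correction supplied; assuming zero.",
         class = "rl_warning_no_control")
    ctl <- ifelse(is.na(ctl %||% rep(NA_real_, nrow(records))), 0, ctl)
  }
  records$o2_rate <- ((records$o2_end - records$o2_start) - ctl) *
    records$chamber_volume / (records$surface_area * records$duration)
  records
}

#' Maximum gross photosynthesis from net rate and dark respiration
#'
#' Gross photosynthesis under saturating light is reconstructed as the
#' net light oxygen rate plus the magnitude of dark respiration
#' (`P_gross = P_net + DR`), assuming respiration continues unchanged in
#' the light.
#'
#' @param p_net Net light oxygen rate, umol O2 cm^-2 h^-1 (vectorised).
#' @param dark_respiration Dark respiration magnitude, >= 0.
#' @return Gross photosynthesis, same units.
#' @export
gross_photosynthesis <- function(p_net, dark_respiration) {
  if (any(dark_respiration < 0)) {
    abort("`dark_respiration` is a magnitude and must be >= 0.",
          class = "rl_error_input")
  }
  p_net + dark_respiration
}

#' Calcification rate by the alkalinity anomaly method
#'
#' Each mole of CaCO3 precipitated removes two equivalents of total
#' alkalinity, so `G = -dAT/2` converted to per-area, per-hour units via
#' the chamber water mass. Positive rates are net precipitation; negative
#' rates net dissolution.
#'
#' @param records Data frame with columns `at_start`, `at_end` (umol/kg),
#'   `chamber_volume` (L), `water_density` (kg/L), `surface_area` (cm^2),
#'   `duration` (h); optional `control_delta_at` (umol/kg, default 0 --
#'   alkalinity controls are rarely run).
#' @return The input tibble with a `calcification` column
#'   (umol CaCO3 cm^-2 h^-1).
#' @export
calcification_from_alkalinity <- function(records) {
  records <- as_tibble(records)
  need <- c("at_start", "at_end", "chamber_volume", "water_density",
            "surface_area", "duration")
  if (!all(need %in% names(records)) || anyNA(records$at_start) || anyNA(records$at_end)) {
    abort("Missing alkalinity endpoints or chamber geometry.",
          class = "rl_error_missing_alkalinity")
  }
  ctl <- records[["control_delta_at"]] %||% 0
  ctl <- ifelse(is.na(ctl), 0, ctl)
  records$calcification <- -((records$at_end - records$at_start) - ctl) / 2 *
    (records$chamber_volume * records$water_density) /
    (records$surface_area * records$duration)
  records
}

#' Daily net calcification from hourly light and dark rates
#'
#' Weights the hourly light and dark calcification rates by the
#' photoperiod (default 14 h light : 10 h dark).
#'
#' @param g_light,g_dark Hourly calcification rates, umol CaCO3 cm^-2 h^-1
#'   (vectorised).
#' @param h_light,h_dark Photoperiod, hours; must sum to 24.
#' @return Daily net calcification, umol CaCO3 cm^-2 day^-1.
#' @export
#' @examples
#' daily_net_calcification(0.12, 0.04)  # 2.08
daily_net_calcification <- function(g_light, g_dark, h_light = 14, h_dark = 10) {
  if (h_light + h_dark != 24) {
    abort("`h_light + h_dark` must equal 24 h.", class = "rl_error_input")
  }
  h_light * g_light + h_dark * g_dark
}

#' Per-replicate metabolic and calcification rates
#'
#' Takes tidy chamber records (one row per chamber-phase, light and dark
#' phases per replicate) and derives, per species x treatment x
#' replicate: net light photosynthesis, dark respiration, gross
#' photosynthesis, light and dark calcification and per-replicate daily
#' net calcification.
#'
#' @param records Data frame of chamber-phase rows with identifying
#'   columns `species`, `treatment`, `replicate`, `phase`
#'   (`"light"`/`"dark"`) plus the endpoint columns used by
#'   [oxygen_rate()] and [calcification_from_alkalinity()].
#' @param h_light,h_dark Photoperiod for the daily sum.
#' @param allow_missing_control Passed to [oxygen_rate()].
#' @return Tibble with one row per replicate: `p_net`, `dark_respiration`
#'   (positive magnitude), `p_max` (gross), `g_light`, `g_dark`,
#'   `g_net_daily`.
#' @export
replicate_rates <- function(records, h_light = 14, h_dark = 10,
                            allow_missing_control = FALSE) {
  records <- oxygen_rate(records, allow_missing_control = allow_missing_control)
  records <- calcification_from_alkalinity(records)
  wide <- records %>%
    select("species", "treatment", "replicate", "phase", "o2_rate", "calcification") %>%
    tidyr::pivot_wider(names_from = "phase",
                       values_from = c("o2_rate", "calcification"))
  wide %>%
    mutate(p_net = .data$o2_rate_light,
           dark_respiration = -.data$o2_rate_dark,
           p_max = gross_photosynthesis(.data$p_net, pmax(.data$dark_respiration, 0)),
           g_light = .data$calcification_light,
           g_dark = .data$calcification_dark,
           g_net_daily = daily_net_calcification(.data$g_light, .data$g_dark,
                                                 h_light, h_dark)) %>%
    select("species", "treatment", "replicate", "p_net", "dark_respiration",
           "p_max", "g_light", "g_dark", "g_net_daily")
}

#' Species comparison table of rates (mean +- SE, ANOVA, letters)
#'
#' Summarises per-replicate rates by species for one treatment, with a
#' one-way ANOVA across species and Newman-Keuls letters per parameter.
#' Daily net calcification is averaged per replicate (the mean of
#' per-replicate daily sums, not the daily sum of mean rates); the
#' mean-of-means variant is returned alongside.
#'
#' @param rates Output of [replicate_rates()], one treatment.
#' @param alpha Significance level for the post hoc letters.
#' @return A list with `summary` (species x parameter means, SE, letters)
#'   and `anova` (parameter, F, df, p).
#' @export
rate_table <- function(rates, alpha = 0.05) {
  if (length(unique(rates$treatment)) > 1) {
    abort("`rate_table()` summarises a single treatment; filter first or use `oa_comparison()`.",
          class = "rl_error_input")
  }
  params <- c("p_max", "dark_respiration", "g_light", "g_dark", "g_net_daily")
  summ <- list()
  anov <- list()
  for (p in params) {
    df <- tibble(species = rates$species, value = rates[[p]])
    a <- one_way_anova(df, "value", "species")
    nk <- newman_keuls(df, "value", "species", alpha = alpha)
    s <- df %>%
      group_by(.data$species) %>%
      summarise(mean = mean(.data$value), se = sd(.data$value) / sqrt(n()),
                n = n(), .groups = "drop") %>%
      mutate(parameter = p) %>%
      left_join(nk$letters[, c("group", "letter")], by = c(species = "group"))
    summ[[p]] <- s
    anov[[p]] <- tibble(parameter = p, F = a$terms$F[1], df1 = a$terms$df1[1],
                        df2 = a$terms$df2[1], p = a$terms$p[1])
  }
  out <- list(summary = bind_rows(summ), anova = bind_rows(anov),
              g_net_daily_mean_of_means = {
                m <- rates %>% group_by(.data$species) %>%
                  summarise(g_light = mean(.data$g_light), g_dark = mean(.data$g_dark),
                            .groups = "drop")
                m$g_net <- daily_net_calcification(m$g_light, m$g_dark)
                m[, c("species", "g_net")]
              })
  class(out) <- c("rl_rate_table", class(out))
  out
}

#' Two-way species x pH-treatment comparison of rates
#'
#' The ocean-acidification contrast: for each rate parameter, a two-way
#' ANOVA (species x treatment) plus per-species one-way treatment
#' contrasts with Newman-Keuls letters. Assumption checks (Shapiro-Wilk,
#' Levene) are reported but never gate the analysis.
#'
#' @param rates Output of [replicate_rates()] spanning two treatments.
#' @param alpha Significance level.
#' @return A list with `anova` (parameter x term table), `contrasts`
#'   (per-species treatment p-values) and `assumptions`.
#' @export
oa_comparison <- function(rates, alpha = 0.05) {
  if (length(unique(rates$treatment)) < 2) {
    abort("Need two treatments for an OA comparison.", class = "rl_error_input")
  }
  counts <- rates %>% dplyr::count(.data$species, .data$treatment)
  if (length(unique(counts$n)) > 1) {
    warn("Unbalanced species x treatment design.", class = "rl_warning_unbalanced")
  }
  params <- c("p_max", "dark_respiration", "g_light", "g_dark")
  anov <- list()
  contr <- list()
  assum <- list()
  for (p in params) {
    df <- tibble(species = rates$species, treatment = rates$treatment,
                 value = rates[[p]])
    a <- two_way_anova(df, "value", "species", "treatment")
    anov[[p]] <- mutate(a$terms, parameter = !!p)
    assum[[p]] <- tryCatch(
      mutate(assumption_checks(df, "value", "species"), parameter = !!p),
      error = function(e) NULL)
    for (sp in unique(df$species)) {
      sub <- filter(df, .data$species == sp)
      aa <- one_way_anova(sub, "value", "treatment")
      contr[[paste(p, sp)]] <- tibble(parameter = p, species = sp,
                                      F = aa$terms$F[1], p = aa$terms$p[1],
                                      significant = aa$terms$p[1] < alpha)
    }
  }
  list(anova = bind_rows(anov), contrasts = bind_rows(contr),
       assumptions = bind_rows(assum))
}
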