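#' Construct a microsensor depth profile
#'
#' A microprofile is a depth-resolved trace of oxygen concentration or pH
#' measured from the thallus surface (depth 0) outward into the overlying
#' water column. Depths are in micrometres and increase away from the
#' surface; oxygen is in umol/L, pH in pH units.
#'
#' @param depth_um Numeric vector of depths (um), strictly increasing,
#'   starting at 0 (the thallus surface).
#' @param value Measured values, same length as `depth_um`.
#' @param species Species label (free text).
#' @param location `"tip"` or `"base"` of a protuberance.
#' @param condition `"light"` or `"dark"`.
#' @param analyte `"oxygen"` or `"ph"`.
#' @param flow_note Optional free-text flow metadata (e.g. `"2 cm s-1"`).
#' @param bulk Optional known bulk-seawater value carried as metadata.
#'
#' @return A tibble of class `rl_profile` with columns `depth_um`, `value`
#'   and metadata stored as attributes (`species`, `location`, `condition`,
#'   `analyte`, `flow_note`, `bulk`).
#' @export
#' @examples
#' p <- microprofile(seq(0, 600, 100), c(300, 290, 280, 270, 260, 250, 250))
#' estimate_bulk(p)
microprofile <- function(depth_um, value, species = NA_character_,
                         location = c("tip", "base"),
                         condition = c("light", "dark"),
                         analyte = c("oxygen", "ph"),
                         flow_note = NULL, bulk = NULL) {
  location <- match.arg(location)
  condition <- match.arg(condition)
  analyte <- match.arg(analyte)
  depth_um <- as.numeric(depth_um)
  value <- as.numeric(value)
  if (length(depth_um) != length(value)) {
    abort("`depth_um` and `value` must have equal length.", class = "rl_error_input")
  }
  if (length(depth_um) < 5L) {
    abort("A microprofile needs at least 5 points.", class = "rl_error_input")
  }
  if (any(diff(depth_um) <= 0)) {
    abort("`depth_um` must be strictly increasing.", class = "rl_error_input")
  }
  if (depth_um[1] != 0) {
    abort("The first depth must be 0 (thallus surface).", class = "rl_error_input")
  }
  if (analyte == "oxygen" && any(value < 0)) {
    abort("Oxygen concentrations must be non-negative.", class = "rl_error_input")
  }
  out <- tibble(depth_um = depth_um, value = value)
  class(out) <- c("rl_profile", class(out))
  attr(out, "species") <- species
  attr(out, "location") <- location
  attr(out, "condition") <- condition
  attr(out, "analyte") <- analyte
  attr(out, "flow_note") <- flow_note
  attr(out, "bulk") <- bulk
  out
}

profile_meta <- function(profile) {
  list(species = attr(profile, "species"),
       location = attr(profile, "location"),
       condition = attr(profile, "condition"),
       analyte = attr(profile, "analyte"),
       flow_note = attr(profile, "flow_note"),
       bulk = attr(profile, "bulk"))
}

#' Average replicate microprofiles point-wise
#'
#' Consecutive profiles measured at the same spot are averaged after
#' aligning on the common depth grid; depths present in only some profiles
#' are dropped.
#'
#' @param ... Two or more `rl_profile` objects sharing metadata.
#' @return An `rl_profile` on the common grid.
#' @export
average_profiles <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && is.list(ps[[1]]) && !inherits(ps[[1]], "rl_profile")) {
    ps <- ps[[1]]
  }
  if (length(ps) < 2L) abort("Need at least two profiles.", class = "rl_error_input")
  m1 <- profile_meta(ps[[1]])
  for (p in ps[-1]) {
    m <- profile_meta(p)
    if (!identical(m$analyte, m1$analyte) || !identical(m$location, m1$location) ||
        !identical(m$condition, m1$condition)) {
      abort("Profiles to average must share analyte, location and condition.",
            class = "rl_error_mismatch")
    }
  }
  common <- Reduce(intersect, lapply(ps, function(p) p$depth_um))
  if (length(common) < 5L) {
    abort("Fewer than 5 common depths across profiles.", class = "rl_error_input")
  }
  vals <- vapply(ps, function(p) p$value[match(common, p$depth_um)], numeric(length(common)))
  microprofile(common, rowMeans(vals), species = m1$species, location = m1$location,
               condition = m1$condition, analyte = m1$analyte,
               flow_note = m1$flow_note, bulk = m1$bulk)
}

#' Estimate the bulk-seawater value from the outer end of a profile
#'
#' The bulk concentration (or pH) is taken as the mean of the outermost
#' points, with a regression-slope check that the tail is stationary.
#'
#' @param profile An `rl_profile`.
#' @param n_outer Number of outermost points to average (>= 2).
#' @param alpha Significance level for the tail-slope stationarity test.
#' @return One-row tibble with `bulk`, `stationary` (logical), `slope_p`,
#'   `n_outer`. A warning (not an error) is raised when the tail slope is
#'   significantly non-zero.
#' @export
estimate_bulk <- function(profile, n_outer = 3, alpha = 0.05) {
  if (!inherits(profile, "rl_profile")) abort("Not a microprofile.", class = "rl_error_input")
  if (n_outer < 2) abort("`n_outer` must be >= 2.", class = "rl_error_input")
  if (nrow(profile) < n_outer) {
    abort("Profile has fewer points than `n_outer`.", class = "rl_error_input")
  }
  tail_df <- profile[seq(nrow(profile) - n_outer + 1L, nrow(profile)), ]
  bulk <- mean(tail_df$value)
  slope_p <- 1
  if (n_outer >= 3 && sd(tail_df$value) > 0) {
    fit <- lm(value ~ depth_um, data = tail_df)
    slope_p <- suppressWarnings(summary(fit))$coefficients[2, 4]
  }
  stationary <- slope_p > alpha
  if (!stationary) {
    warn("Outer region of the profile is not stationary; bulk value may be biased.",
         class = "rl_warning_nonstationary")
  }
  tibble(bulk = bulk, stationary = stationary, slope_p = slope_p, n_outer = n_outer)
}

#' Effective diffusive boundary layer thickness from a microprofile
#'
#' Fits a straight line to the near-surface points (linear diffusive
#' gradient) and extrapolates it to the bulk value; the depth at which the
#' fitted line meets the bulk concentration is the effective DBL thickness.
#'
#' @param profile An `rl_profile`.
#' @param bulk Bulk value: a number, or the tibble returned by
#'   [estimate_bulk()].
#' @param fit_window_um Depth window (um) for the linear surface fit;
#'   must contain >= 3 points.
#' @param alpha Slope significance threshold below which the gradient is
#'   considered degenerate (no DBL definable).
#' @return One-row tibble of class `rl_dbl`: `thickness_um`,
#'   `surface_value`, `surface_gradient` (value per um), `bulk_value`,
#'   `fit_r2`, `n_fit`, `analyte`.
#' @export
estimate_dbl <- function(profile, bulk, fit_window_um = 100, alpha = 0.05) {
  if (!inherits(profile, "rl_profile")) abort("Not a microprofile.", class = "rl_error_input")
  if (is.data.frame(bulk)) bulk <- bulk$bulk[1]
  .assert_scalar(bulk, "bulk")
  near <- profile[profile$depth_um <= fit_window_um, ]
  if (nrow(near) < 3L) {
    abort("Fewer than 3 points inside the fit window.", class = "rl_error_input")
  }
  fit <- lm(value ~ depth_um, data = near)
  sm <- suppressWarnings(summary(fit))  # noise-free fits are legitimately perfect
  slope <- coef(fit)[[2]]
  intercept <- coef(fit)[[1]]
  slope_p <- sm$coefficients[2, 4]
  # a numerically perfect fit can yield an NaN t-test; treat a non-zero
  # slope with zero residual as unambiguous
  if (is.na(slope_p)) slope_p <- if (is.finite(slope) && slope != 0) 0 else 1
  if (!is.finite(slope) || slope == 0 || slope_p > alpha) {
    abort("Surface gradient indistinguishable from zero: no DBL definable.",
          class = "rl_error_degenerate")
  }
  thickness <- (bulk - intercept) / slope
  if (!is.finite(thickness) || thickness <= 0 || thickness > max(profile$depth_um)) {
    abort("Extrapolated DBL thickness falls outside the profiled depth range.",
          class = "rl_error_out_of_range")
  }
  out <- tibble(thickness_um = thickness,
                surface_value = intercept,
                surface_gradient = slope,
                bulk_value = bulk,
                fit_r2 = sm$r.squared,
                n_fit = nrow(near),
                analyte = attr(profile, "analyte"))
  class(out) <- c("rl_dbl", class(out))
  out
}

#' Diffusive oxygen flux across the DBL (Fick's first law)
#'
#' Converts the fitted surface concentration gradient to a diffusive flux
#' J = -D dC/dz. A gradient decreasing away from the surface (oxygen
#' accumulating at the thallus) gives a positive flux, i.e. net efflux /
#' net photosynthesis; dark respiratory uptake is negative.
#'
#' @param dbl An `rl_dbl` fitted from an oxygen profile.
#' @param diffusion_coefficient Molecular diffusion coefficient of O2 in
#'   seawater, m^2 s^-1.
#' @return One-row tibble: `flux` (umol O2 cm^-2 h^-1),
#'   `diffusion_coefficient` (m^2 s^-1).
#' @export
fick_flux <- function(dbl, diffusion_coefficient = 2.01e-9) {
  if (!inherits(dbl, "rl_dbl")) abort("Not an `rl_dbl` result.", class = "rl_error_input")
  if (!identical(dbl$analyte[1], "oxygen")) {
    abort("Fluxes are defined for oxygen profiles only.", class = "rl_error_analyte")
  }
  if (diffusion_coefficient <= 0) {
    abort("`diffusion_coefficient` must be positive.", class = "rl_error_input")
  }
  # gradient is in umol L-1 um-1; sign flip: decreasing outward => efflux
  flux <- -diffusion_coefficient * dbl$surface_gradient[1] * .FLUX_UNIT
  tibble(flux = flux, diffusion_coefficient = diffusion_coefficient)
}

#' Surface pH anomaly of a pH microprofile
#'
#' The pH difference between the thallus surface and the bulk seawater,
#' delta-pH = pH_S - pH_B, taken directly from the measured surface value.
#'
#' @param profile An `rl_profile` with `analyte = "ph"`.
#' @param bulk_ph Bulk seawater pH (number or [estimate_bulk()] result).
#' @return One-row tibble: `delta_ph`, `ph_surface`, `ph_bulk`, plus the
#'   profile's `species`, `location`, `condition`.
#' @export
delta_ph <- function(profile, bulk_ph) {
  if (!inherits(profile, "rl_profile")) abort("Not a microprofile.", class = "rl_error_input")
  if (!identical(attr(profile, "analyte"), "ph")) {
    abort("delta-pH is defined for pH profiles only.", class = "rl_error_analyte")
  }
  if (is.data.frame(bulk_ph)) bulk_ph <- bulk_ph$bulk[1]
  .assert_scalar(bulk_ph, "bulk_ph")
  ph_surface <- profile$value[profile$depth_um == 0][1]
  tibble(delta_ph = ph_surface - bulk_ph,
         ph_surface = ph_surface,
         ph_bulk = bulk_ph,
         species = attr(profile, "species"),
         location = attr(profile, "location"),
         condition = attr(profile, "condition"))
}

#' Total diel surface-pH swing at one spot
#'
#' Difference between the light and dark surface-pH anomalies of the same
#' species and thallus location; for a photosynthesising alga this is the
#' total day-night pH range its surface experiences.
#'
#' @param light,dark [delta_ph()] results for the light and dark condition.
#' @return The swing, in pH units.
#' @export
diel_ph_range <- function(light, dark) {
  same <- function(a, b) identical(a, b) || (is.na(a) && is.na(b))
  if (!same(light$species[1], dark$species[1]) ||
      !same(light$location[1], dark$location[1])) {
    abort("Light and dark delta-pH must come from the same species and location.",
          class = "rl_error_mismatch")
  }
  light$delta_ph[1] - dark$delta_ph[1]
}

#' Read / write a microprofile CSV
#'
#' The dialect is a `depth_um,value` table preceded by `# key: value`
#' comment lines carrying `species`, `location`, `condition`, `analyte`
#' and optionally `flow_note` and `bulk`.
#'
#' @param path File path.
#' @return [read_microprofile()] returns an `rl_profile`.
#' @export
read_microprofile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  body <- read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"))
  microprofile(body$depth_um, body$value,
               species = meta$species %||% NA_character_,
               location = meta$location %||% "tip",
               condition = meta$condition %||% "light",
               analyte = meta$analyte %||% "oxygen",
               flow_note = meta$flow_note,
               bulk = if (!is.null(meta$bulk)) as.numeric(meta$bulk))
}

#' @rdname read_microprofile
#' @param profile An `rl_profile` to write.
#' @export
write_microprofile <- function(profile, path) {
  m <- profile_meta(profile)
  hdr <- c(
    sprintf("# species: %s", m$species),
    sprintf("# location: %s", m$location),
    sprintf("# condition: %s", m$condition),
    sprintf("# analyte: %s", m$analyte),
    if (!is.null(m$flow_note)) sprintf("# flow_note: %s", m$flow_note),
    if (!is.null(m$bulk)) sprintf("# bulk: %.10g", m$bulk)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(as.data.frame(profile[, c("depth_um", "value")]), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
autoplot.rl_profile <- function(object, dbl = NULL, ...) {
  m <- profile_meta(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$depth_um)) +
    ggplot2::geom_path(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = if (m$analyte == "oxygen") "O2 (umol/L)" else "pH",
                  y = "Distance from thallus surface (um)",
                  title = sprintf("%s %s, %s", m$species, m$location, m$condition))
  if (!is.null(dbl)) {
    zz <- seq(0, dbl$thickness_um[1], length.out = 20)
    fitline <- tibble(depth_um = zz,
                      value = dbl$surface_value[1] + dbl$surface_gradient[1] * zz)
    p <- p +
      ggplot2::geom_line(data = fitline, colour = "firebrick", linetype = 2) +
      ggplot2::geom_hline(yintercept = dbl$thickness_um[1], linetype = 3)
  }
  p
}
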