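#' Seawater CO2-system equilibrium constants
#'
#' Evaluates the dissociation constants needed to partition total
#' alkalinity at a given temperature and salinity, on the total hydrogen
#' ion scale, in mol/kg-solution units: carbonic acid K1/K2 (Lueker et
#' al. 2000), boric acid KB (Dickson 1990), water Kw (Millero 1995),
#' calcite solubility Ksp (Mucci 1983), total borate (Uppstrom 1974) and
#' total calcium proportional to salinity.
#'
#' @param temp_c Temperature, degrees C (0-40).
#' @param salinity Practical salinity (0-45).
#' @return A list of class `rl_constants`: `K1`, `K2`, `KB`, `Kw`,
#'   `Ksp_calcite` (mol^2 kg^-2), `BT`, `CaT` (mol/kg), `temp_c`,
#'   `salinity`, `scale = "total"`.
#' @export
#' @examples
#' k <- carb_constants(25, 35)
#' -log10(k$K2)  # ~ 8.966
carb_constants <- function(temp_c, salinity) {
  .assert_scalar(temp_c, "temp_c")
  .assert_scalar(salinity, "salinity")
  if (temp_c < 0 || temp_c > 40 || salinity < 0 || salinity > 45) {
    abort("Constants are parameterised for 0-40 degC and salinity 0-45.",
          class = "rl_error_out_of_range")
  }
  TK <- temp_c + 273.15
  S <- salinity
  lnT <- log(TK)
  pK1 <- 3633.86 / TK - 61.2172 + 9.6777 * lnT - 0.011555 * S + 0.0001152 * S^2
  pK2 <- 471.78 / TK + 25.929 - 3.16967 * lnT - 0.01781 * S + 0.0001122 * S^2
  lnKB <- (-8966.90 - 2890.53 * sqrt(S) - 77.942 * S + 1.728 * S^1.5 - 0.0996 * S^2) / TK +
    (148.0248 + 137.1942 * sqrt(S) + 1.62142 * S) +
    (-24.4344 - 25.085 * sqrt(S) - 0.2474 * S) * lnT + 0.053105 * sqrt(S) * TK
  lnKw <- 148.9802 - 13847.26 / TK - 23.6521 * lnT +
    (-5.977 + 118.67 / TK + 1.0495 * lnT) * sqrt(S) - 0.01615 * S
  log10Ksp <- -171.9065 - 0.077993 * TK + 2839.319 / TK + 71.595 * log10(TK) +
    (-0.77712 + 0.0028426 * TK + 178.34 / TK) * sqrt(S) - 0.07711 * S + 0.0041249 * S^1.5
  structure(list(K1 = 10^-pK1, K2 = 10^-pK2, KB = exp(lnKB), Kw = exp(lnKw),
                 Ksp_calcite = 10^log10Ksp,
                 BT = 0.0004157 * S / 35,
                 CaT = 0.010282 * S / 35,
                 temp_c = temp_c, salinity = salinity, scale = "total"),
            class = "rl_constants")
}

#' Seawater density at one atmosphere
#'
#' International one-atmosphere equation of state (Millero & Poisson 1981).
#'
#' @param salinity Practical salinity.
#' @param temp_c Temperature, degrees C.
#' @return Density in kg/L.
#' @export
#' @examples
#' seawater_density(35, 25)  # 1.023343
seawater_density <- function(salinity, temp_c) {
  t <- temp_c
  S <- salinity
  rho0 <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 + 1.001685e-4 * t^3 -
    1.120083e-6 * t^4 + 6.536332e-9 * t^5
  A <- 8.24493e-1 - 4.0899e-3 * t + 7.6438e-5 * t^2 - 8.2467e-7 * t^3 + 5.3875e-9 * t^4
  B <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  C <- 4.8314e-4
  (rho0 + A * S + B * S^1.5 + C * S^2) / 1000
}

#' Solve the seawater CO2 system from pH and total alkalinity
#'
#' Given a measured pH and total alkalinity, partitions the alkalinity
#' into bicarbonate, carbonate, borate, hydroxide and hydrogen terms and
#' derives DIC and the calcite saturation state
#' Omega = \[Ca2+\]\[CO3 2-\]/Ksp.
#'
#' The measured pH is inserted against the total-scale constants after
#' adding `ph_scale_offset` (default 0); the default reproduces the
#' treatment saturation states this package's generators target, and the
#' Omega ratio between two treatments at equal alkalinity is insensitive
#' to the offset.
#'
#' @param ph Measured pH (vectorised).
#' @param at Total alkalinity, umol/kg (vectorised).
#' @param temp_c Temperature, degrees C.
#' @param salinity Practical salinity.
#' @param ph_scale_offset Additive pH-scale correction, pH units.
#' @return A tibble with one row per input: `ph`, `at`, `dic`, `co2`,
#'   `hco3`, `co3`, `boh4`, `oh` (all umol/kg), `h` (mol/kg),
#'   `omega_calcite`, `temp_c`, `salinity`.
#' @export
#' @examples
#' solve_carbonate(8.12, 2378, 25, 35)$omega_calcite  # ~ 6.0
solve_carbonate <- function(ph, at, temp_c = 25, salinity = 35, ph_scale_offset = 0) {
  if (any(!is.finite(ph)) || any(ph <= 6) || any(ph >= 9.5)) {
    abort("pH must lie in (6, 9.5).", class = "rl_error_out_of_range")
  }
  if (any(at <= 0)) abort("Alkalinity must be positive.", class = "rl_error_input")
  k <- carb_constants(temp_c, salinity)
  h <- 10^(-(ph + ph_scale_offset))
  at_mol <- at * 1e-6
  boh4 <- k$BT * k$KB / (k$KB + h)
  oh <- k$Kw / h
  ca <- at_mol - boh4 - oh + h
  if (any(ca <= 0)) {
    abort("Negative carbonate alkalinity: no physical solution.",
          class = "rl_error_no_solution")
  }
  hco3 <- ca / (1 + 2 * k$K2 / h)
  co3 <- k$K2 / h * hco3
  co2 <- hco3 * h / k$K1
  omega <- k$CaT * co3 / k$Ksp_calcite
  tibble(ph = ph, at = at,
         dic = (co2 + hco3 + co3) * 1e6,
         co2 = co2 * 1e6, hco3 = hco3 * 1e6, co3 = co3 * 1e6,
         boh4 = boh4 * 1e6, oh = oh * 1e6, h = h,
         omega_calcite = omega,
         temp_c = temp_c, salinity = salinity)
}

#' Construct an acid-titration record
#'
#' @param acid_ml Cumulative acid volume added, mL, strictly increasing.
#' @param ph pH readings at each step, overall decreasing.
#' @param sample_mass_kg Sample mass, kg; if omitted it is derived from
#'   `sample_volume_ml` and [seawater_density()].
#' @param sample_volume_ml Sample volume, mL.
#' @param acid_conc Acid concentration, mol/L.
#' @param temp_c,salinity Conditions of the titrated sample.
#' @return A tibble of class `rl_titration` with columns `acid_ml`, `ph`
#'   and metadata attributes.
#' @export
titration_curve <- function(acid_ml, ph, sample_mass_kg = NULL,
                            sample_volume_ml = NULL, acid_conc = 0.1,
                            temp_c = 25, salinity = 35) {
  if (length(acid_ml) != length(ph)) {
    abort("`acid_ml` and `ph` must have equal length.", class = "rl_error_input")
  }
  if (length(acid_ml) < 8L) abort("Need at least 8 titration points.", class = "rl_error_input")
  if (any(diff(acid_ml) <= 0)) {
    abort("`acid_ml` must be strictly increasing.", class = "rl_error_input")
  }
  # overall monotone decrease, with slack for reading noise
  if (ph[length(ph)] >= ph[1] || any(diff(ph) > 0.2)) {
    abort("pH readings must decrease over the titration.", class = "rl_error_non_monotone")
  }
  if (is.null(sample_mass_kg)) {
    if (is.null(sample_volume_ml)) {
      abort("Give `sample_mass_kg` or `sample_volume_ml`.", class = "rl_error_input")
    }
    sample_mass_kg <- sample_volume_ml / 1000 * seawater_density(salinity, temp_c)
  }
  out <- tibble(acid_ml = as.numeric(acid_ml), ph = as.numeric(ph))
  class(out) <- c("rl_titration", class(out))
  attr(out, "sample_mass_kg") <- sample_mass_kg
  attr(out, "acid_conc") <- acid_conc
  attr(out, "temp_c") <- temp_c
  attr(out, "salinity") <- salinity
  out
}

#' Total alkalinity by carbonate-corrected Gran titration
#'
#' Locates the alkalinity equivalence point by linearising the acid side
#' of the titration with the Gran function
#' `F(v) = (V0 + v) * (10^-pH - [HCO3-]est)`, where the small residual
#' bicarbonate term (order 10 umol/kg at pH 3-3.5) is estimated from K1
#' and a nominal seawater DIC; without this correction the classical Gran
#' extrapolation is biased low by roughly that amount. The fitted line's
#' root gives the equivalence volume and
#' `A_T = C_acid * v_eq / sample mass`.
#'
#' @param curve An `rl_titration`.
#' @param ph_window pH window whose points enter the linear fit.
#' @param dic_hint Nominal DIC of the sample (umol/kg) used only for the
#'   residual-bicarbonate correction; the result is insensitive to
#'   +-10% errors in it.
#' @return One-row tibble: `at` (umol/kg), `v_eq_ml`, `gran_fit_r2`,
#'   `n_used`.
#' @export
gran_alkalinity <- function(curve, ph_window = c(3.0, 3.5), dic_hint = 2000) {
  if (!inherits(curve, "rl_titration")) abort("Not a titration curve.", class = "rl_error_input")
  if (min(curve$ph) > 3.5) {
    abort("Titration does not reach the acid side (min pH > 3.5).",
          class = "rl_error_no_equivalence")
  }
  mass <- attr(curve, "sample_mass_kg")
  acid_conc <- attr(curve, "acid_conc")
  temp_c <- attr(curve, "temp_c")
  salinity <- attr(curve, "salinity")
  k <- carb_constants(temp_c, salinity)
  V0 <- mass / seawater_density(salinity, temp_c) * 1000
  sel <- which(curve$ph >= ph_window[1] & curve$ph <= ph_window[2])
  if (length(sel) < 5L) {
    # fallback: contiguous 5-point acid-side window with the smallest
    # residual from a straight-line Gran fit
    cand <- which(curve$ph <= ph_window[2] + 0.3)
    best <- NULL
    best_rss <- Inf
    if (length(cand) >= 5L) {
      for (s in seq_len(length(cand) - 4L)) {
        idx <- cand[s:(s + 4L)]
        Fv <- (V0 + curve$acid_ml[idx]) * 10^(-curve$ph[idx])
        fit <- lm(Fv ~ curve$acid_ml[idx])
        rss <- sum(residuals(fit)^2) / mean(Fv)^2
        if (rss < best_rss) { best_rss <- rss; best <- idx }
      }
    }
    if (is.null(best)) {
      abort("Too few acid-side points for a Gran fit.", class = "rl_error_no_equivalence")
    }
    sel <- best
  }
  v <- curve$acid_ml[sel]
  h <- 10^(-curve$ph[sel])
  m_tot <- mass + v / 1000  # acid density ~ 1 kg/L
  hco3 <- k$K1 * (dic_hint * 1e-6 * mass / m_tot) / h
  Fv <- (V0 + v) * (h - hco3)
  fit <- lm(Fv ~ v)
  v_eq <- -coef(fit)[[1]] / coef(fit)[[2]]
  if (!is.finite(v_eq) || v_eq <= 0 || v_eq > max(curve$acid_ml)) {
    abort("Equivalence volume outside the titrated range.",
          class = "rl_error_no_equivalence")
  }
  tibble(at = acid_conc * v_eq / 1000 / mass * 1e6,
         v_eq_ml = v_eq,
         gran_fit_r2 = summary(fit)$r.squared,
         n_used = length(sel))
}

#' Mean alkalinity over duplicate titrations
#'
#' Duplicate tubes of the same water sample are titrated independently;
#' each curve is processed by [gran_alkalinity()] and the results averaged.
#'
#' @param curves A list of `rl_titration` objects.
#' @param ... Passed to [gran_alkalinity()].
#' @return One-row tibble: `at` (mean), `at_sd`, `n_tubes`.
#' @export
mean_alkalinity <- function(curves, ...) {
  ats <- vapply(curves, function(cv) gran_alkalinity(cv, ...)$at, numeric(1))
  tibble(at = mean(ats), at_sd = if (length(ats) > 1) sd(ats) else NA_real_,
         n_tubes = length(ats))
}

#' Read / write a titration CSV
#'
#' Dialect: `acid_ml,ph` table preceded by `# sample_mass_kg:`,
#' `# acid_conc_M:`, `# temp_C:` and `# salinity:` comment lines.
#'
#' @param path File path.
#' @export
read_titration <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- as.numeric(val)
  }
  body <- read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"))
  titration_curve(body$acid_ml, body$ph,
                  sample_mass_kg = meta$sample_mass_kg,
                  acid_conc = meta$acid_conc_M %||% 0.1,
                  temp_c = meta$temp_C %||% 25,
                  salinity = meta$salinity %||% 35)
}

#' @rdname read_titration
#' @param curve An `rl_titration` to write.
#' @export
write_titration <- function(curve, path) {
  hdr <- c(sprintf("# sample_mass_kg: %.10g", attr(curve, "sample_mass_kg")),
           sprintf("# acid_conc_M: %.10g", attr(curve, "acid_conc")),
           sprintf("# temp_C: %.10g", attr(curve, "temp_c")),
           sprintf("# salinity: %.10g", attr(curve, "salinity")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(as.data.frame(curve[, c("acid_ml", "ph")]), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
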