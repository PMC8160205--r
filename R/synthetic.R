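#' Species presets for the three rhodolith morphotypes
#'
#' Geometry and physiology presets for the three coralline species the
#' generators emulate: protuberance dimensions, chamber rates, surface
#' pH anomalies at protuberance tips and bases, DBL thicknesses and
#' microscale oxygen fluxes. Tip/base delta-pH values are pinned so that
#' their tip/base means equal the reported species means under each
#' light condition, and base DBL thickness increases linearly with
#' protuberance length (20 um per mm above a 300 um offset).
#'
#' @return A tibble with one row per species.
#' @export
species_presets <- function() {
  tibble(
    species = c("L. crispatum", "L. atlanticum", "M. erubescens"),
    protuberance_length_mm = c(15, 7.5, 2.75),
    protuberance_diameter_mm = c(2, 3.5, 1.5),
    n_protuberances = c(12L, 8L, 25L),
    core_radius_mm = c(3, 4, 3),
    p_max = c(0.50, 0.61, 0.52),
    dark_respiration = c(0.10, 0.18, 0.14),
    g_light = c(0.12, 0.19, 0.08),
    g_dark = c(0.04, -0.06, -0.01),
    delta_ph_light_tip = c(0.30, 0.32, 0.28),
    delta_ph_light_base = c(0.42, 0.78, 0.38),
    delta_ph_dark_tip = c(0.04, -0.06, -0.04),
    delta_ph_dark_base = c(-0.0382, -0.40, -0.08),
    dbl_tip_um = c(280, 320, 300),
    dbl_base_um = c(600, 450, 355),
    flux_light_tip = c(0.55, 0.85, 0.60),
    flux_light_base = c(0.40, 0.80, 0.35),
    flux_dark_tip = c(-0.12, -0.22, -0.15),
    flux_dark_base = c(-0.12, -0.22, -0.15),
    o2_bulk = 210,
    ph_bulk = 8.12
  )
}

#' Default low-pH treatment effects
#'
#' Effect structure applied by the incubation generator under the low-pH
#' treatment: dark calcification shifts strongly negative in all species
#' (night-time dissolution), gross photosynthesis and dark respiration
#' increase in *L. atlanticum* only, and light calcification is
#' unchanged.
#'
#' @return A list of shifts and per-species factors.
#' @export
oa_effect_defaults <- function() {
  list(g_dark_shift = -0.15,
       g_light_shift = 0,
       p_max_factor = c("L. atlanticum" = 1.15),
       dark_respiration_factor = c("L. atlanticum" = 1.40))
}

apply_oa_effects <- function(preset, treatment, effects = oa_effect_defaults()) {
  if (treatment != "low_ph") return(preset)
  sp <- preset$species
  pf <- unname(effects$p_max_factor[sp])
  rf <- unname(effects$dark_respiration_factor[sp])
  preset$p_max <- preset$p_max * ifelse(is.na(pf), 1, pf)
  preset$dark_respiration <- preset$dark_respiration * ifelse(is.na(rf), 1, rf)
  preset$g_dark <- preset$g_dark + effects$g_dark_shift
  preset$g_light <- preset$g_light + effects$g_light_shift
  preset
}

#' Simulate a steady-state microsensor depth profile
#'
#' Steady-state diffusive boundary layer model with no reaction in the
#' water column: the trace is linear between the surface value and the
#' bulk value across the DBL, and constant beyond it. Sampling follows
#' the microprofiling grid: 25 um steps inside the DBL, 100 um steps
#' outside, down to at least `max_depth_um`. The imposed parameters are
#' stored in a `truth` attribute. An optional `curvature` bends the
#' in-DBL segment to stress-test the linear estimator.
#'
#' @param bulk Bulk value (umol/L for oxygen, pH units for pH).
#' @param dbl_thickness_um Imposed DBL thickness, um (>= 50).
#' @param flux Imposed flux (umol cm^-2 h^-1, positive = efflux); sets
#'   the in-DBL gradient via Fick's law. Ignored when `surface_value`
#'   is given.
#' @param diffusion_coefficient m^2 s^-1.
#' @param surface_value Optional explicit value at depth 0 (used for pH
#'   profiles, where a flux is not meaningful).
#' @param noise_sd Additive Gaussian noise, analyte units.
#' @param curvature 0 for the linear model; positive values bow the
#'   in-DBL segment toward the bulk.
#' @param analyte,species,location,condition Profile metadata.
#' @param max_depth_um Minimum profiling depth.
#' @param seed Optional seed (left untouched when `NULL` so a single
#'   upstream seed governs a whole simulated study).
#' @return An `rl_profile` with attribute `truth`.
#' @export
simulate_microprofile <- function(bulk, dbl_thickness_um, flux = 0,
                                  diffusion_coefficient = 2.01e-9,
                                  surface_value = NULL, noise_sd = 0,
                                  curvature = 0,
                                  analyte = c("oxygen", "ph"),
                                  species = NA_character_,
                                  location = "tip", condition = "light",
                                  max_depth_um = 600, seed = NULL) {
  analyte <- match.arg(analyte)
  if (!is.null(seed)) set.seed(seed)
  if (dbl_thickness_um < 50) {
    abort("DBL thinner than two 25-um grid steps cannot be sampled.",
          class = "rl_error_grid")
  }
  if (is.null(surface_value)) {
    # Fick: J = -D dC/dz, so the in-DBL slope (value per um) is -J/(D u)
    slope <- -flux / (diffusion_coefficient * .FLUX_UNIT)
    surface_value <- bulk - slope * dbl_thickness_um
  }
  slope <- (bulk - surface_value) / dbl_thickness_um
  inner <- seq(0, 25 * floor(dbl_thickness_um / 25), by = 25)
  out_start <- 100 * ceiling((dbl_thickness_um + 1e-9) / 100)
  outer <- seq(out_start, max(max_depth_um, out_start + 300), by = 100)
  depths <- c(inner, outer[outer > max(inner)])
  frac <- pmin(depths / dbl_thickness_um, 1)
  frac_curved <- frac + curvature * frac * (1 - frac)
  values <- surface_value + (bulk - surface_value) * frac_curved
  if (noise_sd > 0) values <- values + rnorm(length(values), 0, noise_sd)
  if (analyte == "oxygen") values <- pmax(values, 0)
  p <- microprofile(depths, values, species = species, location = location,
                    condition = condition, analyte = analyte, bulk = bulk)
  attr(p, "truth") <- list(bulk = bulk, dbl_thickness_um = dbl_thickness_um,
                           surface_value = surface_value,
                           flux = -slope * diffusion_coefficient * .FLUX_UNIT,
                           diffusion_coefficient = diffusion_coefficient,
                           noise_sd = noise_sd)
  p
}

#' Simulate a Gran acid titration of a seawater sample
#'
#' Forward closed-system model: after each cumulative acid addition the
#' remaining alkalinity, DIC and borate (all tracked through the mass
#' dilution) are re-equilibrated and the pH solved from the
#' proton/alkalinity balance with the same constants the analysis uses.
#' The titration stops shortly below pH `stop_ph`.
#'
#' @param at_true True total alkalinity, umol/kg.
#' @param dic Sample DIC, umol/kg.
#' @param sample_volume_ml Sample volume (mL); mass via the equation of
#'   state.
#' @param acid_conc Acid concentration, mol/L.
#' @param increment_ml Acid increment per step, mL.
#' @param noise_sd_ph Gaussian noise on each pH reading.
#' @param temp_c,salinity Sample conditions.
#' @param stop_ph Target end pH (default 2.85, past the Gran window).
#' @param seed Optional seed.
#' @return An `rl_titration` with attribute `truth`.
#' @export
simulate_titration <- function(at_true, dic = 2100, sample_volume_ml = 12,
                               acid_conc = 0.1, increment_ml = 0.01,
                               noise_sd_ph = 0, temp_c = 25, salinity = 35,
                               stop_ph = 2.85, seed = NULL) {
  if (at_true <= 0 || dic <= 0) {
    abort("`at_true` and `dic` must be positive.", class = "rl_error_input")
  }
  if (!is.null(seed)) set.seed(seed)
  k <- carb_constants(temp_c, salinity)
  mass <- sample_volume_ml / 1000 * seawater_density(salinity, temp_c)
  bt0 <- k$BT
  solve_ph <- function(at, dic_v, bt) {
    f <- function(lgh) {
      h <- 10^-lgh
      den <- h^2 + k$K1 * h + k$K1 * k$K2
      dic_v * k$K1 * h / den + 2 * dic_v * k$K1 * k$K2 / den +
        bt * k$KB / (k$KB + h) + k$Kw / h - h - at
    }
    uniroot(f, c(1.2, 12), tol = 1e-12)$root
  }
  max_steps <- ceiling(5 * at_true * 1e-6 * mass / (acid_conc * increment_ml / 1000)) + 50
  v <- ph <- numeric(0)
  vi <- 0
  repeat {
    m_acid <- vi / 1000  # acid density ~ 1 kg/L
    m <- mass + m_acid
    at_v <- (at_true * 1e-6 * mass - acid_conc * vi / 1000) / m
    phi <- solve_ph(at_v, dic * 1e-6 * mass / m, bt0 * mass / m)
    v <- c(v, vi)
    ph <- c(ph, phi)
    if (phi < stop_ph) break
    vi <- vi + increment_ml
    if (length(v) > max_steps) {
      abort("Acid range insufficient to pass the equivalence point.",
            class = "rl_error_insufficient_acid")
    }
  }
  if (min(ph) > 3.5) {
    abort("Acid range insufficient to pass the equivalence point.",
          class = "rl_error_insufficient_acid")
  }
  if (noise_sd_ph > 0) ph <- ph + rnorm(length(ph), 0, noise_sd_ph)
  cv <- titration_curve(v, ph, sample_mass_kg = mass, acid_conc = acid_conc,
                        temp_c = temp_c, salinity = salinity)
  attr(cv, "truth") <- list(at = at_true, dic = dic, sample_mass_kg = mass)
  cv
}

#' Simulate one sealed-chamber incubation phase
#'
#' Inverts the rate equations: endpoint oxygen and alkalinity are
#' generated from the preset's true rates over the incubation duration,
#' plus a control drift and optional Gaussian endpoint noise. Low-pH
#' treatments start from the low-pH water chemistry and apply the
#' configured treatment effects to the true rates.
#'
#' @param species One of the [species_presets()] names.
#' @param phase `"light"` or `"dark"`.
#' @param treatment `"ambient"` or `"low_ph"`.
#' @param replicate Replicate id carried into the record.
#' @param preset Optional preset row overriding the species lookup.
#' @param rate_multiplier Multiplies the true rates (biological
#'   between-replicate variation).
#' @param chamber_volume L; `surface_area` cm^2; `duration` h.
#' @param surface_area,duration See above.
#' @param o2_noise_sd,at_noise_sd Endpoint noise (umol/L, umol/kg).
#' @param control_delta_o2 Drift of the rhodolith-free control, umol/L.
#' @param temp_c,salinity Incubation conditions.
#' @param oa_effects See [oa_effect_defaults()].
#' @param seed Optional seed.
#' @return One-row tibble (an incubation record) including the true
#'   rates as `true_o2_rate` and `true_calcification`.
#' @export
simulate_incubation <- function(species = "L. crispatum",
                                phase = c("light", "dark"),
                                treatment = c("ambient", "low_ph"),
                                replicate = 1L, preset = NULL,
                                rate_multiplier = 1,
                                chamber_volume = 0.150, surface_area = 15,
                                duration = 0.5,
                                o2_noise_sd = 0, at_noise_sd = 0,
                                control_delta_o2 = 0,
                                temp_c = 24, salinity = 35,
                                oa_effects = oa_effect_defaults(),
                                seed = NULL) {
  phase <- match.arg(phase)
  treatment <- match.arg(treatment)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(preset)) {
    preset <- species_presets() %>% filter(.data$species == !!species)
    if (!nrow(preset)) abort("Unknown species.", class = "rl_error_input")
  }
  preset <- apply_oa_effects(preset, treatment, oa_effects)
  rho <- seawater_density(salinity, temp_c)
  o2_rate <- if (phase == "light") {
    (preset$p_max - preset$dark_respiration) * rate_multiplier
  } else {
    -preset$dark_respiration * rate_multiplier
  }
  g <- (if (phase == "light") preset$g_light else preset$g_dark) * rate_multiplier
  o2_start <- 210
  at_start <- if (treatment == "ambient") 2378 else 2377
  o2_end <- o2_start + o2_rate * surface_area * duration / chamber_volume +
    control_delta_o2
  at_end <- at_start - 2 * g * surface_area * duration / (chamber_volume * rho)
  if (o2_noise_sd > 0) o2_end <- o2_end + rnorm(1, 0, o2_noise_sd)
  if (at_noise_sd > 0) at_end <- at_end + rnorm(1, 0, at_noise_sd)
  tibble(species = preset$species, treatment = treatment, phase = phase,
         replicate = as.integer(replicate),
         o2_start = o2_start, o2_end = o2_end,
         at_start = at_start, at_end = at_end,
         duration = duration, chamber_volume = chamber_volume,
         water_density = rho, surface_area = surface_area,
         control_delta_o2 = control_delta_o2, control_delta_at = 0,
         temp_c = temp_c, salinity = salinity,
         true_o2_rate = o2_rate, true_calcification = g)
}

fibonacci_directions <- function(n, seed_rotation = TRUE) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  if (seed_rotation) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    dirs <- dirs %*% q
  }
  dirs
}

#' Simulate a branched rhodolith voxel volume
#'
#' Constructive solid geometry: a spherical core plus
#' cylinder-with-hemispherical-cap protuberances pointing along
#' quasi-uniform (Fibonacci lattice, seeded random rotation)
#' directions, rasterised on an isotropic voxel grid. Protuberance
#' directions are spaced so the protuberances never overlap each other,
#' which keeps the stored ground-truth surface area and volume exact
#' (sphere/cylinder intersection handled in closed form).
#'
#' @param protuberance_length_mm Length beyond the core surface.
#' @param protuberance_diameter_mm Cylinder diameter.
#' @param n_protuberances Count (>= 0).
#' @param core_radius_mm Core sphere radius.
#' @param voxel_size_um Voxel edge, um; protuberances must span >= 4
#'   voxels in diameter.
#' @param species Provenance label.
#' @param seed Optional seed (rotation of the direction set).
#' @return Binary `rl_volume` with attribute `truth` holding the
#'   analytic `surface_area_mm2`, `volume_mm3`, `sa_v_mm1` and an
#'   effective `dry_weight_g` (bulk skeletal density 1.5 g cm^-3).
#' @export
simulate_rhodolith_volume <- function(protuberance_length_mm,
                                      protuberance_diameter_mm,
                                      n_protuberances,
                                      core_radius_mm = 3,
                                      voxel_size_um = 250,
                                      species = NA_character_,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- core_radius_mm
  L <- protuberance_length_mm
  a <- protuberance_diameter_mm / 2
  if (R <= 0 || n_protuberances < 0) abort("Bad geometry.", class = "rl_error_input")
  vs <- voxel_size_um / 1000  # mm
  if (n_protuberances > 0 && protuberance_diameter_mm / vs < 4) {
    abort("Protuberance diameter below 4 voxels; refine the grid.",
          class = "rl_error_resolution")
  }
  if (n_protuberances > 0 && a >= R) {
    abort("Protuberance radius must be smaller than the core radius.",
          class = "rl_error_input")
  }
  dirs <- if (n_protuberances > 0) fibonacci_directions(n_protuberances) else
    matrix(numeric(0), 0, 3)
  if (n_protuberances > 1) {
    min_sep <- 2 * asin(a / R)
    cosmax <- max((dirs %*% t(dirs))[upper.tri(diag(n_protuberances))])
    if (acos(pmin(1, cosmax)) < min_sep) {
      abort("Protuberances too crowded to remain disjoint.",
            class = "rl_error_resolution")
    }
  }
  E <- R + (if (n_protuberances > 0) L else 0) + 3 * vs
  coords <- seq(-E, E, by = vs)
  n_side <- length(coords)
  mask <- array(FALSE, rep(n_side, 3))
  r2xy <- outer(coords^2, coords^2, "+")
  for (kk in seq_len(n_side)) {
    mask[, , kk] <- r2xy + coords[kk]^2 <= R^2
  }
  t_max <- R + L - a
  for (pp in seq_len(nrow(dirs))) {
    d <- dirs[pp, ]
    seg <- rbind(c(0, 0, 0), d * t_max)
    lo <- pmin(seg[1, ], seg[2, ]) - a - vs
    hi <- pmax(seg[1, ], seg[2, ]) + a + vs
    idx <- lapply(1:3, function(ax) which(coords >= lo[ax] & coords <= hi[ax]))
    if (any(lengths(idx) == 0)) next
    px <- coords[idx[[1]]]; py <- coords[idx[[2]]]; pz <- coords[idx[[3]]]
    dot_xy <- outer(px * d[1], py * d[2], "+")
    p2_xy <- outer(px^2, py^2, "+")
    for (kk in seq_along(pz)) {
      tt <- dot_xy + pz[kk] * d[3]
      tt <- pmin(pmax(tt, 0), t_max)
      dist2 <- p2_xy + pz[kk]^2 - 2 * tt * (dot_xy + pz[kk] * d[3]) + tt^2
      sub <- mask[idx[[1]], idx[[2]], idx[[3]][kk]]
      mask[idx[[1]], idx[[2]], idx[[3]][kk]] <- sub | (dist2 <= a^2)
    }
  }
  s <- if (n_protuberances > 0) sqrt(R^2 - a^2) else NA_real_
  sa <- 4 * pi * R^2
  vol <- 4 / 3 * pi * R^3
  if (n_protuberances > 0) {
    sa <- sa + n_protuberances *
      (2 * pi * a * (t_max - s) + 2 * pi * a^2 - 2 * pi * R * (R - s))
    vol <- vol + n_protuberances *
      (pi * a^2 * t_max + 2 / 3 * pi * a^3 - 2 * pi / 3 * (R^3 - s^3))
  }
  v <- voxel_volume(mask, voxel_size_um,
                    provenance = sprintf("synthetic rhodolith (%s)", species))
  attr(v, "truth") <- list(surface_area_mm2 = sa, volume_mm3 = vol,
                           sa_v_mm1 = sa / vol,
                           dry_weight_g = vol * 1.5e-3,
                           params = list(R = R, L = L, a = a,
                                         n = n_protuberances,
                                         voxel_size_um = voxel_size_um))
  v
}

#' Overlay a bimodal grayscale model on a binary mask
#'
#' Foreground and background voxels get Gaussian intensities around two
#' separated modes, emulating a reconstructed CT image of a segmented
#' object.
#'
#' @param mask Binary `rl_volume`.
#' @param fg_mean,bg_mean,sd Intensity model.
#' @param seed Optional seed.
#' @return Grayscale `rl_volume`.
#' @export
as_grayscale <- function(mask, fg_mean = 0.75, bg_mean = 0.25, sd = 0.05,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- array(rnorm(length(mask), bg_mean, sd), dim(mask))
  g[mask] <- rnorm(sum(mask), fg_mean, sd)
  g <- pmin(pmax(g, 0), 1)
  vol_like(mask, array(g, dim(mask)))
}

#' Simulate a complete study bundle
#'
#' Generates every input kind of the full study design from one seed:
#' microprofiles (3 species x tip/base x light/dark x individuals x
#' spots, O2 and pH, two consecutive traces per spot), chamber
#' incubations (replicates x 2 treatments x 2 phases), duplicate Gran
#' titration tubes per incubation endpoint, and voxel volumes per
#' species. `noise = 0` produces the deterministic noise-free bundle;
#' `noise = 1` the realistic noise level (O2 profile sd 1 umol/L, pH
#' profile sd 0.005, endpoint sd 1 umol/L O2 and 2 umol/kg A_T,
#' titration pH sd 0.003, 6% individual and 5% replicate variation).
#'
#' @param seed Single integer governing all randomness.
#' @param noise Noise scale (0 = none, 1 = realistic).
#' @param n_individuals,spots_per_individual Microprofiling design.
#' @param n_replicates Chambers per species x treatment.
#' @param volumes_per_species CT-style volumes per species.
#' @param voxel_size_um Rasterisation grid for the volumes.
#' @param include_titrations Generate titration curves for the
#'   alkalinity endpoints (slower).
#' @return A list of class `rl_study`: `profiles`, `incubations`,
#'   `titrations`, `volumes`, `truth`, `seed`, `noise`.
#' @export
simulate_study <- function(seed = 1, noise = 1, n_individuals = 3,
                           spots_per_individual = 2, n_replicates = 5,
                           volumes_per_species = 5, voxel_size_um = 300,
                           include_titrations = TRUE) {
  set.seed(seed)
  presets <- species_presets()
  sd_o2 <- 1 * noise
  sd_ph <- 0.005 * noise
  cv_ind <- 0.06 * noise
  cv_rep <- 0.05 * noise
  sd_end_o2 <- 1 * noise
  sd_end_at <- 2 * noise
  sd_tit_ph <- 0.003 * noise

  profiles <- list()
  truth_profiles <- list()
  for (si in seq_len(nrow(presets))) {
    pr <- presets[si, ]
    for (ind in seq_len(n_individuals)) {
      ind_mult <- exp(rnorm(1, 0, cv_ind))   # coherent individual effect
      for (spot in seq_len(spots_per_individual)) {
        for (loc in c("tip", "base")) {
          delta <- (if (loc == "tip") pr$dbl_tip_um else pr$dbl_base_um) * ind_mult
          for (cond in c("light", "dark")) {
            flux <- (if (cond == "light") {
              if (loc == "tip") pr$flux_light_tip else pr$flux_light_base
            } else {
              if (loc == "tip") pr$flux_dark_tip else pr$flux_dark_base
            }) * ind_mult
            dph <- pr[[paste0("delta_ph_", cond, "_", loc)]] * ind_mult
            id <- sprintf("%s_ind%d_spot%d_%s_%s",
                          gsub("[. ]+", "_", pr$species), ind, spot, loc, cond)
            # two consecutive traces per spot, averaged downstream
            o2_pair <- lapply(1:2, function(i) {
              simulate_microprofile(pr$o2_bulk, delta, flux = flux,
                                    noise_sd = sd_o2, analyte = "oxygen",
                                    species = pr$species, location = loc,
                                    condition = cond,
                                    max_depth_um = max(600, delta + 300))
            })
            ph_pair <- lapply(1:2, function(i) {
              simulate_microprofile(pr$ph_bulk, delta,
                                    surface_value = pr$ph_bulk + dph,
                                    noise_sd = sd_ph, analyte = "ph",
                                    species = pr$species, location = loc,
                                    condition = cond,
                                    max_depth_um = max(600, delta + 300))
            })
            profiles[[paste0(id, "_oxygen")]] <- o2_pair
            profiles[[paste0(id, "_ph")]] <- ph_pair
            truth_profiles[[id]] <- tibble(
              species = pr$species, individual = ind, spot = spot,
              location = loc, condition = cond,
              dbl_um = delta, flux = flux, delta_ph = dph)
          }
        }
      }
    }
  }

  inc_rows <- list()
  for (si in seq_len(nrow(presets))) {
    pr <- presets[si, ]
    for (tr in c("ambient", "low_ph")) {
      for (rep_i in seq_len(n_replicates)) {
        mult <- exp(rnorm(1, 0, cv_rep))
        for (ph_phase in c("light", "dark")) {
          inc_rows[[length(inc_rows) + 1]] <-
            simulate_incubation(preset = pr, phase = ph_phase, treatment = tr,
                                replicate = rep_i, rate_multiplier = mult,
                                o2_noise_sd = sd_end_o2,
                                at_noise_sd = sd_end_at,
                                control_delta_o2 = 0.5 * (if (ph_phase == "light") 1 else -0.6))
        }
      }
    }
  }
  incubations <- bind_rows(inc_rows)
  incubations$chamber_id <- paste(gsub("[. ]+", "_", incubations$species),
                                  incubations$treatment, incubations$replicate,
                                  sep = "_")

  titrations <- list()
  if (include_titrations) {
    ambient_dic <- solve_carbonate(8.12, 2378, 25, 35)$dic
    low_dic <- solve_carbonate(7.698, 2377, 25, 35)$dic
    for (r in seq_len(nrow(incubations))) {
      row <- incubations[r, ]
      dic0 <- if (row$treatment == "ambient") ambient_dic else low_dic
      for (endp in c("start", "end")) {
        at_v <- if (endp == "start") row$at_start else row$at_end
        for (tube in 1:2) {
          tid <- sprintf("%s_%s_%s_tube%d", row$chamber_id, row$phase, endp, tube)
          titrations[[tid]] <- simulate_titration(at_v, dic = dic0,
                                                  noise_sd_ph = sd_tit_ph)
        }
      }
    }
  }

  volumes <- list()
  truth_volumes <- list()
  for (si in seq_len(nrow(presets))) {
    pr <- presets[si, ]
    for (vv in seq_len(volumes_per_species)) {
      L <- pr$protuberance_length_mm * exp(rnorm(1, 0, cv_rep))
      vol <- simulate_rhodolith_volume(L, pr$protuberance_diameter_mm,
                                       pr$n_protuberances,
                                       core_radius_mm = pr$core_radius_mm,
                                       voxel_size_um = voxel_size_um,
                                       species = pr$species)
      vid <- sprintf("%s_vol%d", gsub("[. ]+", "_", pr$species), vv)
      volumes[[vid]] <- vol
      truth_volumes[[vid]] <- tibble(species = pr$species, volume_id = vid,
                                     !!!attr(vol, "truth")[c("surface_area_mm2",
                                                             "volume_mm3",
                                                             "sa_v_mm1",
                                                             "dry_weight_g")])
    }
  }

  out <- list(profiles = profiles,
              incubations = incubations,
              titrations = titrations,
              volumes = volumes,
              truth = list(presets = presets,
                           profiles = bind_rows(truth_profiles),
                           volumes = bind_rows(truth_volumes),
                           oa_effects = oa_effect_defaults()),
              seed = seed, noise = noise)
  class(out) <- "rl_study"
  out
}

#' @export
print.rl_study <- function(x, ...) {
  cat(sprintf("Simulated rhodolith study (seed %d, noise %.2g):\n", x$seed, x$noise))
  cat(sprintf("  %d profile spots (paired traces), %d incubation rows, %d titration tubes, %d volumes\n",
              length(x$profiles), nrow(x$incubations), length(x$titrations),
              length(x$volumes)))
  invisible(x)
}
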