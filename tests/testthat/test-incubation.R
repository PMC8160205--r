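chamber <- function(...) {
  defaults <- list(species = "sp", treatment = "ambient", replicate = 1L,
                   o2_start = 210, o2_end = 210, at_start = 2378, at_end = 2378,
                   control_delta_o2 = 0, control_delta_at = 0,
                   chamber_volume = 0.15, water_density = 1.0233,
                   surface_area = 10, duration = 0.5)
  args <- list(...)
  defaults[names(args)] <- args
  tibble::as_tibble(defaults)
}

test_that("oxygen rate applies the control correction and chamber geometry", {
  r <- oxygen_rate(chamber(o2_end = 235, control_delta_o2 = 1))
  expect_equal(r$o2_rate, 0.72)                      # (24 * 0.15) / (10 * 0.5)
  r0 <- oxygen_rate(chamber(o2_end = 211, control_delta_o2 = 1))
  expect_equal(r0$o2_rate, 0)                        # chamber change equals control
  dr <- oxygen_rate(chamber(o2_end = 210 - 3.33))
  expect_equal(dr$o2_rate, -0.0999)                  # dark respiration ~ -0.10
  expect_error(oxygen_rate(chamber(control_delta_o2 = NA)),
               class = "rl_error_missing_control")
  expect_warning(oxygen_rate(chamber(control_delta_o2 = NA),
                             allow_missing_control = TRUE),
                 class = "rl_warning_no_control")
})

test_that("gross photosynthesis is net light rate plus respiration magnitude", {
  expect_equal(gross_photosynthesis(0.40, 0.10), 0.50)
  expect_equal(gross_photosynthesis(0, 0), 0)
  expect_equal(gross_photosynthesis(0.43, 0.18), 0.61)
  expect_error(gross_photosynthesis(0.4, -0.1), class = "rl_error_input")
})

test_that("alkalinity anomaly converts to calcification with the 2:1 stoichiometry", {
  g <- calcification_from_alkalinity(chamber(at_end = 2378 - 20))
  expect_equal(g$calcification, 20 / 2 * (0.15 * 1.0233) / (10 * 0.5))
  expect_equal(round(g$calcification, 3), 0.307)
  expect_equal(calcification_from_alkalinity(chamber())$calcification, 0)
  gd <- calcification_from_alkalinity(chamber(at_end = 2378 + 3.91))
  expect_equal(round(gd$calcification, 2), -0.06)    # net dark dissolution
  expect_error(calcification_from_alkalinity(chamber(at_end = NA)),
               class = "rl_error_missing_alkalinity")
})

test_that("calcification scales linearly in delta-AT, volume and 1/SA", {
  base <- calcification_from_alkalinity(chamber(at_end = 2368))$calcification
  expect_equal(calcification_from_alkalinity(chamber(at_end = 2358))$calcification,
               2 * base)
  expect_equal(calcification_from_alkalinity(chamber(at_end = 2368,
                                                     chamber_volume = 0.30))$calcification,
               2 * base)
  expect_equal(calcification_from_alkalinity(chamber(at_end = 2368,
                                                     surface_area = 20))$calcification,
               base / 2)
})

test_that("closed-chamber stoichiometry round-trips through the estimator", {
  # precipitating N umol CaCO3 draws down AT by 2N/mass
  N <- 1.8
  mass <- 0.15 * 1.0233
  rec <- chamber(at_end = 2378 - 2 * N / mass)
  g <- calcification_from_alkalinity(rec)
  expect_equal(g$calcification, N / (10 * 0.5), tolerance = 1e-12)
})

test_that("daily net calcification weights rates by the photoperiod", {
  expect_equal(daily_net_calcification(0.12, 0.04), 2.08)
  expect_equal(daily_net_calcification(0, 0), 0)
  expect_equal(daily_net_calcification(0.10, -0.14), 0)  # exact cancellation
  expect_equal(daily_net_calcification(0.1, 0.1, 12, 12), 2.4)
  expect_error(daily_net_calcification(0.1, 0.1, 14, 11), class = "rl_error_input")
})

test_that("noise-free simulated incubations return the preset rates exactly", {
  inc <- dplyr::bind_rows(
    simulate_incubation("L. crispatum", phase = "light"),
    simulate_incubation("L. crispatum", phase = "dark"))
  rr <- replicate_rates(inc)
  expect_equal(rr$p_max, 0.50, tolerance = 1e-12)
  expect_equal(rr$dark_respiration, 0.10, tolerance = 1e-12)
  expect_equal(rr$g_light, 0.12, tolerance = 1e-12)
  expect_equal(rr$g_dark, 0.04, tolerance = 1e-12)
  expect_equal(rr$g_net_daily, 2.08, tolerance = 1e-12)
  # p_max identity holds by construction
  expect_equal(rr$p_max, rr$p_net + rr$dark_respiration)
})

test_that("noisy replicate recovery is unbiased with SEs comparable to the design", {
  set.seed(77)
  rows <- list()
  for (r in 1:5) {
    rows[[length(rows) + 1]] <- simulate_incubation("L. atlanticum", phase = "light",
                                                    replicate = r, o2_noise_sd = 1,
                                                    at_noise_sd = 2)
    rows[[length(rows) + 1]] <- simulate_incubation("L. atlanticum", phase = "dark",
                                                    replicate = r, o2_noise_sd = 1,
                                                    at_noise_sd = 2)
  }
  rr <- replicate_rates(dplyr::bind_rows(rows))
  # endpoint noise sd maps to rate sd ~0.02-0.03; allow 3 standard errors
  expect_lt(abs(mean(rr$p_max) - 0.61), 0.04)
  expect_lt(abs(mean(rr$g_light) - 0.19), 0.03)
  se <- sd(rr$g_light) / sqrt(5)
  expect_lt(se, 2 * 0.02)       # printed-scale SE (~0.01-0.02) at 5 replicates
})

test_that("species rate table reports means, SEs, ANOVA and letters", {
  set.seed(12)
  rows <- list()
  for (sp in species_presets()$species) for (r in 1:5) for (ph in c("light", "dark")) {
    rows[[length(rows) + 1]] <- simulate_incubation(sp, phase = ph, replicate = r,
                                                    o2_noise_sd = 1, at_noise_sd = 2)
  }
  rr <- replicate_rates(dplyr::bind_rows(rows))
  tab <- rate_table(rr)
  expect_setequal(unique(tab$summary$parameter),
                  c("p_max", "dark_respiration", "g_light", "g_dark", "g_net_daily"))
  gl <- dplyr::filter(tab$summary, parameter == "g_light")
  expect_equal(nrow(gl), 3)
  expect_true(all(gl$n == 5))
  # the fast light calcifier is always separated from the others
  at_letter <- gl$letter[gl$species == "L. atlanticum"]
  other_letters <- gl$letter[gl$species != "L. atlanticum"]
  expect_false(any(grepl(at_letter, other_letters, fixed = TRUE)))
  expect_lt(dplyr::filter(tab$anova, parameter == "g_light")$p, 0.001)
})

test_that("OA comparison flags the injected dark-calcification effect only", {
  set.seed(21)
  rows <- list()
  for (sp in species_presets()$species) for (tr in c("ambient", "low_ph")) {
    for (r in 1:5) for (ph in c("light", "dark")) {
      rows[[length(rows) + 1]] <-
        simulate_incubation(sp, phase = ph, treatment = tr, replicate = r,
                            o2_noise_sd = 1, at_noise_sd = 2)
    }
  }
  rr <- replicate_rates(dplyr::bind_rows(rows))
  oa <- oa_comparison(rr)
  ph_term <- dplyr::filter(oa$anova, term == "treatment")
  expect_lt(ph_term$p[ph_term$parameter == "g_dark"], 0.0001)
  expect_gt(ph_term$p[ph_term$parameter == "g_light"], 0.05)
  expect_true(all(c("anova", "contrasts", "assumptions") %in% names(oa)))
})

test_that("identical groups across treatments produce no spurious effects", {
  set.seed(3)
  rows <- list()
  for (r in 1:5) {
    base <- rnorm(4, c(0.5, 0.1, 0.12, 0.04), 0.02)
    for (tr in c("ambient", "low_ph")) {    # same values in both treatments
      rows[[length(rows) + 1]] <- tibble::tibble(
        species = c("a", "b"), treatment = tr, replicate = r,
        p_max = base[1], dark_respiration = base[2],
        g_light = base[3], g_dark = base[4], p_net = base[1] - base[2],
        g_net_daily = 14 * base[3] + 10 * base[4])
    }
  }
  rr <- dplyr::bind_rows(rows)
  oa <- oa_comparison(rr)
  expect_true(all(dplyr::filter(oa$anova, term == "treatment")$p > 0.99))
})
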