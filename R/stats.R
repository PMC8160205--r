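#' Ordinary least-squares regression with confidence band
#'
#' @param data Data frame.
#' @param x,y Column names (strings) of predictor and response.
#' @param conf_level Confidence level for the pointwise band.
#' @param n_band Number of x positions at which the band is evaluated.
#' @return An object of class `rl_regression` with `tidy()`, `glance()`
#'   and `autoplot()` methods; elements: `fit` (the `lm`), `coefficients`
#'   (slope/intercept tibble), `r2`, `p_value`, `band` (x, fit, lower,
#'   upper).
#' @export
fit_regression <- function(data, x, y, conf_level = 0.95, n_band = 80) {
  df <- tibble(x = data[[x]], y = data[[y]])
  if (nrow(df) < 3L) abort("Need at least 3 points.", class = "rl_error_input")
  if (sd(df$x) == 0) abort("Predictor has zero variance.", class = "rl_error_degenerate")
  fit <- lm(y ~ x, data = df)
  sm <- suppressWarnings(summary(fit))  # exact fits are a legitimate input
  grid <- tibble(x = seq(min(df$x), max(df$x), length.out = n_band))
  band <- as_tibble(predict(fit, grid, interval = "confidence",
                            level = conf_level))
  names(band) <- c("fit", "lower", "upper")
  out <- list(fit = fit,
              data = df,
              xlab = x, ylab = y,
              coefficients = tibble(term = c("intercept", "slope"),
                                    estimate = coef(fit),
                                    p_value = sm$coefficients[, 4]),
              slope = coef(fit)[[2]],
              intercept = coef(fit)[[1]],
              r2 = sm$r.squared,
              p_value = sm$coefficients[2, 4],
              conf_level = conf_level,
              band = dplyr::bind_cols(grid, band))
  class(out) <- "rl_regression"
  out
}

#' @export
print.rl_regression <- function(x, ...) {
  cat(sprintf("Linear regression %s ~ %s: slope %.4g, R2 = %.3f, p = %.4g\n",
              x$ylab, x$xlab, x$slope, x$r2, x$p_value))
  invisible(x)
}

#' @export
tidy.rl_regression <- function(x, ...) x$coefficients

#' @export
glance.rl_regression <- function(x, ...) {
  tibble(r.squared = x$r2, p.value = x$p_value, nobs = nrow(x$data))
}

#' @export
autoplot.rl_regression <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_ribbon(data = object$band,
                         ggplot2::aes(x = .data$x, y = .data$fit,
                                      ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2) +
    ggplot2::geom_line(data = object$band,
                       ggplot2::aes(x = .data$x, y = .data$fit)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = object$xlab, y = object$ylab,
                  subtitle = sprintf("R2 = %.2f, p = %.2g", object$r2, object$p_value))
}

#' One-way fixed-effects analysis of variance
#'
#' @param data Data frame.
#' @param response,group Column names (strings).
#' @return `rl_anova` with `terms` tibble (`term`, `F`, `df1`, `df2`,
#'   `p`), `design`, the underlying `aov` fit, and `mse`/`df_error` used
#'   by the post hoc procedure.
#' @export
one_way_anova <- function(data, response, group) {
  df <- tibble(value = data[[response]], g = factor(data[[group]]))
  if (nlevels(df$g) < 2) abort("Need >= 2 groups.", class = "rl_error_input")
  if (any(table(df$g) < 2)) {
    abort("Each group needs >= 2 replicates.", class = "rl_error_replication")
  }
  fit <- aov(value ~ g, data = df)
  tab <- summary(fit)[[1]]
  Fv <- tab$`F value`[1]
  pv <- tab$`Pr(>F)`[1]
  if (var(df$value) == 0) { Fv <- 0; pv <- 1 }  # identical data: 0/0 ratio
  out <- list(terms = tibble(term = group,
                             F = Fv,
                             df1 = tab$Df[1], df2 = tab$Df[2],
                             p = pv),
              design = "one_way",
              mse = tab$`Mean Sq`[2],
              df_error = tab$Df[2],
              fit = fit, data = df)
  class(out) <- "rl_anova"
  out
}

#' Two-way crossed analysis of variance
#'
#' Main effects and interaction for a fully crossed two-factor design;
#' with balanced data the sums of squares are identical across SS types.
#'
#' @param data Data frame.
#' @param response,factor_a,factor_b Column names (strings).
#' @return `rl_anova` with a three-row `terms` tibble.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  df <- tibble(value = data[[response]],
               a = factor(data[[factor_a]]), b = factor(data[[factor_b]]))
  if (any(table(df$a, df$b) == 0)) {
    abort("Missing cell in the crossed design.", class = "rl_error_missing_cell")
  }
  if (length(unique(table(df$a, df$b))) > 1) {
    warn("Unbalanced design: SS are sequential (type I).",
         class = "rl_warning_unbalanced")
  }
  fit <- aov(value ~ a * b, data = df)
  tab <- summary(fit)[[1]]
  terms <- tibble(term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b)),
                  F = tab$`F value`[1:3],
                  df1 = tab$Df[1:3], df2 = tab$Df[4],
                  p = tab$`Pr(>F)`[1:3])
  out <- list(terms = terms, design = "two_way",
              mse = tab$`Mean Sq`[4], df_error = tab$Df[4],
              fit = fit, data = df)
  class(out) <- "rl_anova"
  out
}

#' @export
print.rl_anova <- function(x, ...) {
  print(x$terms)
  invisible(x)
}

#' @export
tidy.rl_anova <- function(x, ...) x$terms

#' @export
glance.rl_anova <- function(x, ...) {
  tibble(design = x$design, mse = x$mse, df_error = x$df_error)
}

# studentized-range q for the difference of two of p ordered means
snk_q <- function(mean_i, mean_j, mse, n_i, n_j) {
  (mean_j - mean_i) / sqrt(mse / 2 * (1 / n_i + 1 / n_j))
}

#' Newman-Keuls stepwise multiple comparison with compact letters
#'
#' Student-Newman-Keuls procedure on the ordered group means: the range
#' spanning p means is tested against the studentized-range quantile
#' `qtukey(1 - alpha, p, df_error)`; ranges inside a non-significant
#' span are declared non-significant without testing (step-down
#' protection). The resulting significance relation is encoded as a
#' compact letter display (groups sharing a letter do not differ).
#'
#' @param data Data frame.
#' @param response,group Column names (strings).
#' @param alpha Significance level.
#' @return `rl_posthoc` with `letters` (group, mean, n, letter),
#'   `significant` (logical matrix) and `alpha`.
#' @export
newman_keuls <- function(data, response, group, alpha = 0.05) {
  a <- one_way_anova(data, response, group)
  df <- a$data
  stats_tbl <- df %>%
    group_by(.data$g) %>%
    summarise(mean = mean(.data$value), n = n(), .groups = "drop")
  # sort ascending by mean; ties keep input (factor) order
  ord <- order(stats_tbl$mean)
  m <- stats_tbl$mean[ord]
  ns <- stats_tbl$n[ord]
  labs <- as.character(stats_tbl$g[ord])
  k <- length(m)
  sig <- matrix(FALSE, k, k, dimnames = list(labs, labs))
  if (a$mse > 0) {
    status <- matrix(NA, k, k)  # TRUE sig, FALSE ns, NA untested
    test_range <- function(i, j) {
      if (j - i < 1 || !is.na(status[i, j])) return(invisible())
      p <- j - i + 1
      q_obs <- snk_q(m[i], m[j], a$mse, ns[i], ns[j])
      q_crit <- qtukey(1 - alpha, p, a$df_error)
      if (q_obs < q_crit) {
        # protection: everything inside a non-significant span is ns
        for (ii in i:j) for (jj in ii:j) status[ii, jj] <<- FALSE
      } else {
        status[i, j] <<- TRUE
        test_range(i, j - 1)
        test_range(i + 1, j)
      }
    }
    test_range(1, k)
    status[is.na(status)] <- FALSE
    sig <- status
    sig[lower.tri(sig)] <- t(status)[lower.tri(sig)]
    dimnames(sig) <- list(labs, labs)
  }
  letters_vec <- cld_letters(sig)
  out <- list(letters = tibble(group = labs, mean = m, n = ns,
                               letter = letters_vec),
              significant = sig, alpha = alpha)
  class(out) <- "rl_posthoc"
  out
}

# compact letter display by insert-and-absorb over the sorted means
cld_letters <- function(sig) {
  k <- nrow(sig)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (!sig[i, j]) next
    for (s in seq_along(sets)) {
      if (i %in% sets[[s]] && j %in% sets[[s]]) {
        sets[[length(sets) + 1]] <- setdiff(sets[[s]], i)
        sets[[s]] <- setdiff(sets[[s]], j)
      }
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(sets))
    for (s1 in seq_along(sets)) for (s2 in seq_along(sets)) {
      if (s1 != s2 && keep[s1] && keep[s2] &&
          all(sets[[s1]] %in% sets[[s2]])) keep[s1] <- FALSE
    }
    sets <- sets[keep]
  }
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  out <- character(k)
  for (s in seq_along(sets)) {
    for (g in sets[[s]]) out[g] <- paste0(out[g], letters[s])
  }
  out
}

#' @export
print.rl_posthoc <- function(x, ...) {
  print(x$letters)
  invisible(x)
}

#' @export
tidy.rl_posthoc <- function(x, ...) x$letters

#' Normality and homoscedasticity checks
#'
#' Shapiro-Wilk normality per group and Levene's test (via
#' [car::leveneTest()]) for equal variances across groups. Advisory
#' only: significant results are reported, never used to halt an
#' analysis.
#'
#' @param data Data frame.
#' @param response,group Column names (strings).
#' @return Tibble with one row per group (`test = "shapiro"`) plus one
#'   `"levene"` row; constant groups get `degenerate = TRUE` and NA
#'   p-values rather than an error.
#' @export
assumption_checks <- function(data, response, group) {
  df <- tibble(value = data[[response]], g = factor(data[[group]]))
  if (any(table(df$g) < 3)) {
    abort("Each group needs >= 3 values for assumption checks.",
          class = "rl_error_input")
  }
  rows <- df %>%
    group_by(.data$g) %>%
    summarise(p = if (sd(.data$value) == 0) NA_real_ else
                shapiro.test(.data$value)$p.value,
              degenerate = sd(.data$value) == 0, .groups = "drop") %>%
    mutate(test = "shapiro") %>%
    rename(group = "g")
  lev <- if (sd(df$value) == 0) {
    tibble(group = NA_character_, p = NA_real_, degenerate = TRUE, test = "levene")
  } else {
    lt <- suppressWarnings(car::leveneTest(value ~ g, data = df))
    tibble(group = NA_character_, p = lt$`Pr(>F)`[1], degenerate = FALSE,
           test = "levene")
  }
  bind_rows(rows, lev)
}
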