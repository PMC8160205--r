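# brute-force sum-of-squares oracles
ss_oneway <- function(values, groups) {
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- length(means) - 1
  df2 <- length(values) - length(means)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE))
}

ss_twoway_balanced <- function(values, a, b) {
  grand <- mean(values)
  ma <- tapply(values, a, mean); mb <- tapply(values, b, mean)
  mab <- tapply(values, interaction(a, b), mean)
  na <- tapply(values, a, length); nb <- tapply(values, b, length)
  nab <- tapply(values, interaction(a, b), length)
  ssa <- sum(na * (ma - grand)^2)
  ssb <- sum(nb * (mb - grand)^2)
  sscells <- sum(nab * (mab - grand)^2)
  ssab <- sscells - ssa - ssb
  sse <- sum((values - mab[interaction(a, b)])^2)
  dfa <- length(ma) - 1; dfb <- length(mb) - 1
  dfab <- dfa * dfb
  dfe <- length(values) - length(mab)
  mse <- sse / dfe
  list(F = c(ssa / dfa, ssb / dfb, ssab / dfab) / mse, dfe = dfe)
}

test_that("OLS regression matches closed-form estimates and brackets the fit", {
  d <- data.frame(x = 1:6, y = 2 * (1:6))
  r <- fit_regression(d, "x", "y")
  expect_equal(r$slope, 2)
  expect_equal(r$r2, 1)
  expect_lt(r$p_value, 1e-10)
  # band contains the fitted line
  expect_true(all(r$band$lower <= r$band$fit + 1e-12 &
                    r$band$fit <= r$band$upper + 1e-12))
  set.seed(14)
  d2 <- data.frame(x = rnorm(20), y = rnorm(20))
  r2 <- fit_regression(d2, "x", "y")
  # closed-form slope oracle
  want <- cov(d2$x, d2$y) / var(d2$x)
  expect_equal(r2$slope, want, tolerance = 1e-12)
  expect_error(fit_regression(data.frame(x = rep(1, 5), y = 1:5), "x", "y"),
               class = "rl_error_degenerate")
})

test_that("slope p-values are uniform under the null", {
  set.seed(202)
  ps <- replicate(400, {
    d <- data.frame(x = rnorm(8), y = rnorm(8))
    fit_regression(d, "x", "y")$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
})

test_that("one-way ANOVA equals the brute-force sums of squares exactly", {
  # textbook-style 3 x 5 table
  vals <- c(6.1, 5.8, 6.4, 6.0, 5.9,
            7.2, 7.0, 6.8, 7.3, 7.1,
            5.1, 5.4, 5.0, 5.3, 5.2)
  g <- rep(c("a", "b", "c"), each = 5)
  a <- one_way_anova(data.frame(v = vals, g = g), "v", "g")
  want <- ss_oneway(vals, g)
  expect_equal(a$terms$F, want$F, tolerance = 1e-12)
  expect_equal(a$terms$p, want$p, tolerance = 1e-12)
  # identical groups: zero between-group variance
  same <- data.frame(v = rep(5, 12), g = rep(c("a", "b", "c"), 4))
  expect_equal(one_way_anova(same, "v", "g")$terms$F, 0)
  expect_error(one_way_anova(data.frame(v = 1:3, g = c("a", "a", "b")), "v", "g"),
               class = "rl_error_replication")
})

test_that("two-way ANOVA on a balanced table equals the brute-force oracle", {
  set.seed(6)
  d <- expand.grid(a = c("x", "y"), b = c("p", "q", "r"), rep = 1:4)
  d$v <- rnorm(nrow(d)) + ifelse(d$a == "x", 0.5, 0) +
    ifelse(d$b == "q", 0.3, 0) + ifelse(d$a == "x" & d$b == "r", 0.8, 0)
  got <- two_way_anova(d, "v", "a", "b")
  want <- ss_twoway_balanced(d$v, d$a, d$b)
  expect_equal(got$terms$F, unname(want$F), tolerance = 1e-10)
  expect_equal(got$terms$df2[1], want$dfe)
  # injected interaction is detected
  expect_lt(got$terms$p[3], 0.05)
  # missing cell errors
  dd <- d[!(d$a == "x" & d$b == "p"), ]
  expect_error(two_way_anova(dd, "v", "a", "b"), class = "rl_error_missing_cell")
})

test_that("balanced null data give no significant two-way terms", {
  set.seed(123)
  d <- expand.grid(a = c("x", "y"), b = c("p", "q"), rep = 1:6)
  d$v <- rnorm(nrow(d))
  got <- two_way_anova(d, "v", "a", "b")
  expect_true(all(got$terms$p > 0.05))
})

test_that("Newman-Keuls letters match the all-pairs studentized-range oracle", {
  set.seed(15)
  # one far-outlying mean: letters a, a, b
  d <- data.frame(v = c(rnorm(5, 0, 0.5), rnorm(5, 0.3, 0.5), rnorm(5, 8, 0.5)),
                  g = rep(c("g1", "g2", "g3"), each = 5))
  nk <- newman_keuls(d, "v", "g")
  expect_equal(nk$letters$letter, c("a", "a", "b"))
  # oracle: all pairwise q at full span k vs qtukey(k); for clearly separated
  # or clearly equal means stepwise SNK and the full-span test agree
  a <- one_way_anova(d, "v", "g")
  means <- tapply(d$v, d$g, mean); ns <- tapply(d$v, d$g, length)
  k <- length(means)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    q_obs <- abs(means[i] - means[j]) / sqrt(a$mse / 2 * (1 / ns[i] + 1 / ns[j]))
    sig_full <- q_obs > qtukey(0.95, k, a$df_error)
    li <- nk$letters$letter[nk$letters$group == names(means)[i]]
    lj <- nk$letters$letter[nk$letters$group == names(means)[j]]
    share <- length(intersect(strsplit(li, "")[[1]], strsplit(lj, "")[[1]])) > 0
    if (sig_full) expect_false(share)
  }
})

test_that("Newman-Keuls on 4-5 groups encodes exactly the non-significant pairs", {
  set.seed(9)
  d <- data.frame(v = c(rnorm(6, 0), rnorm(6, 0.2), rnorm(6, 3), rnorm(6, 3.1),
                        rnorm(6, 9)),
                  g = rep(paste0("g", 1:5), each = 6))
  nk <- newman_keuls(d, "v", "g")
  # letters are transitive-consistent with the significance matrix
  labs <- nk$letters$group
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (i >= j) next
    share <- length(intersect(strsplit(nk$letters$letter[i], "")[[1]],
                              strsplit(nk$letters$letter[j], "")[[1]])) > 0
    expect_equal(share, !nk$significant[labs[i], labs[j]])
  }
  # identical data collapse to a single letter
  same <- data.frame(v = rep(1, 12), g = rep(c("a", "b", "c"), 4))
  expect_true(all(newman_keuls(same, "v", "g")$letters$letter == "a"))
})

test_that("letters reproduce the light-calcification species pattern in most seeds", {
  hits <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    d <- data.frame(v = c(rnorm(5, 0.12, sqrt(5) * 0.01),
                          rnorm(5, 0.19, sqrt(5) * 0.01),
                          rnorm(5, 0.08, sqrt(5) * 0.01)),
                    g = rep(c("cr", "at", "er"), each = 5))
    nk <- newman_keuls(d, "v", "g")
    if (length(unique(nk$letters$letter)) == 3) hits <- hits + 1
  }
  expect_gte(hits, 6)   # a/b/c separation in most seeds
})

test_that("assumption checks behave and never crash on degenerate input", {
  set.seed(33)
  ok <- data.frame(v = rnorm(100), g = rep(c("a", "b"), each = 50))
  rep1 <- assumption_checks(ok, "v", "g")
  expect_true(all(rep1$p[rep1$test == "shapiro"] > 0.05))
  het <- data.frame(v = c(rnorm(50, 0, 1), rnorm(50, 0, 10)),
                    g = rep(c("a", "b"), each = 50))
  rep2 <- assumption_checks(het, "v", "g")
  expect_lt(rep2$p[rep2$test == "levene"], 0.05)
  const <- data.frame(v = rep(1, 12), g = rep(c("a", "b"), each = 6))
  rep3 <- assumption_checks(const, "v", "g")
  expect_true(all(rep3$degenerate))
  expect_true(all(is.na(rep3$p)))
})

test_that("tidy and glance methods return the broom-style tables", {
  d <- data.frame(x = 1:8, y = (1:8) * 1.5 + rnorm(8, 0, 0.1))
  r <- fit_regression(d, "x", "y")
  expect_named(tidy(r), c("term", "estimate", "p_value"))
  expect_named(glance(r), c("r.squared", "p.value", "nobs"))
  a <- one_way_anova(data.frame(v = rnorm(12), g = rep(c("a", "b", "c"), 4)),
                     "v", "g")
  expect_true(all(c("term", "F", "p") %in% names(tidy(a))))
})
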