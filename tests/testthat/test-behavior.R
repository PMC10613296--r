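# Psychometric fitting, ambiguity grouping, modulation indices and group
# comparisons.

test_that("morph levels map onto the three ambiguity levels", {
  expect_equal(group_ambiguity(0), "anchor")
  expect_equal(group_ambiguity(100), "anchor")
  expect_equal(group_ambiguity(30), "intermediate")
  expect_equal(group_ambiguity(70), "intermediate")
  expect_equal(group_ambiguity(c(40, 50, 60)), rep("high", 3))
  expect_error(group_ambiguity(85), "off the task grid")
})

test_that("noise-free proportions recover the generating parameters", {
  x <- morph_grid()
  p <- 1 / (1 + exp(-0.2 * (x - 50)))
  fit <- fit_psychometric_props(x, p)
  expect_true(fit$converged)
  expect_lt(abs(fit$p_inf - 1), 1e-3)
  expect_lt(abs(fit$x_half - 50), 1e-3)
  expect_lt(abs(fit$alpha_slope - 0.2), 1e-3)
})

test_that("optimizer agrees with a dense grid-search oracle", {
  s <- gen_behavior(behavior_truth(p_inf = 1, x_half = 55,
                                   alpha_slope = 0.15,
                                   n_trials_per_level = 200, seed = 17))
  pr_x <- morph_grid()
  pr_p <- vapply(pr_x, function(m) {
    mean(s$choice[s$morph_pct == m] == "fear")
  }, numeric(1))
  fit <- fit_psychometric_props(pr_x, pr_p)
  # brute-force grid over (x_half, alpha) with the asymptote p_inf
  # profiled out in closed form (RSS is quadratic in p_inf); a coarse
  # pass is refined locally so the discrete argmin pins the optimum
  prof_rss <- function(xh, a) {
    L <- 1 / (1 + exp(-a * (pr_x - xh)))
    p_inf <- min(max(sum(pr_p * L) / sum(L^2), 1e-3), 1.05)
    sum((pr_p - p_inf * L)^2)
  }
  g1 <- expand.grid(x_half = seq(30, 70, by = 0.1),
                    alpha = seq(0.02, 1, by = 0.02))
  r1 <- mapply(prof_rss, g1$x_half, g1$alpha)
  b1 <- g1[which.min(r1), ]
  g2 <- expand.grid(
    x_half = seq(b1$x_half - 0.2, b1$x_half + 0.2, by = 0.005),
    alpha = seq(max(b1$alpha - 0.04, 1e-3), b1$alpha + 0.04, by = 0.001))
  r2 <- mapply(prof_rss, g2$x_half, g2$alpha)
  best <- g2[which.min(r2), ]
  expect_lt(abs(fit$x_half - best$x_half), 0.005 + 1e-9)
  expect_lt(abs(fit$alpha_slope - best$alpha), 0.001 + 1e-9)
  expect_lte(fit$rss, min(r2) + 1e-12)
})

test_that("degenerate sessions are reported as non-converged", {
  s <- gen_behavior(behavior_truth(seed = 2, n_trials_per_level = 10))
  s$choice <- "happy"
  fit <- fit_psychometric(s)
  expect_false(fit$converged)
  expect_match(fit$message, "unidentifiable")
})

test_that("fit is invariant to trial order and duplication, and monotone", {
  s <- gen_behavior(behavior_truth(seed = 19, n_trials_per_level = 60))
  f1 <- fit_psychometric(s)
  f2 <- fit_psychometric(s[sample.int(nrow(s)), ])
  f3 <- fit_psychometric(rbind(s, s))
  expect_equal(f1[c("p_inf", "x_half", "alpha_slope")],
               f2[c("p_inf", "x_half", "alpha_slope")])
  expect_equal(f1[c("p_inf", "x_half", "alpha_slope")],
               f3[c("p_inf", "x_half", "alpha_slope")])
  xx <- seq(0, 100, by = 0.25)
  curve <- f1$p_inf / (1 + exp(-f1$alpha_slope * (xx - f1$x_half)))
  expect_true(all(diff(curve) > 0))
})

test_that("parameter recovery sharpens with trials per level", {
  err_at <- function(n, seeds) {
    vapply(seeds, function(sd) {
      s <- gen_behavior(behavior_truth(x_half = 50, alpha_slope = 0.2,
                                       n_trials_per_level = n, seed = sd))
      abs(fit_psychometric(s)$x_half - 50)
    }, numeric(1))
  }
  e50 <- median(err_at(50, 1:15))
  e500 <- median(err_at(500, 1:15))
  expect_lt(e500, e50 + 0.5)   # no degradation
  expect_lt(e500, 1)           # tight at large n
})

test_that("modulation index follows its definition and scale invariance", {
  s <- gen_behavior(behavior_truth(seed = 23))
  # forced arithmetic on constructed RTs
  s$rt_s <- ifelse(group_ambiguity(s$morph_pct) == "high", 1.2,
                   ifelse(group_ambiguity(s$morph_pct) == "anchor", 1.0,
                          1.1))
  mi <- modulation_index(s, "rt")
  expect_equal(mi$value, 0.2, tolerance = 1e-12)
  expect_equal(mi$high_mean, 1.2)
  expect_equal(mi$anchor_mean, 1.0)

  # identity
  s$rt_s <- 1.3
  expect_equal(modulation_index(s, "rt")$value, 0)

  # scale invariance
  s2 <- gen_behavior(behavior_truth(seed = 24))
  v1 <- modulation_index(s2, "rt")$value
  s2$rt_s <- s2$rt_s * 7.5
  expect_equal(modulation_index(s2, "rt")$value, v1, tolerance = 1e-12)

  # division guard
  s$confidence <- 0L
  expect_error(modulation_index(s, "confidence"), "zero")
})

test_that("ambiguity sensitivity recovers the simulated RT gain", {
  s <- gen_behavior(behavior_truth(seed = 27))
  s$rt_s <- ifelse(group_ambiguity(s$morph_pct) == "high", 1.30, 1.10)
  expect_equal(ambiguity_sensitivity(s)$delta_rt, 0.20, tolerance = 1e-12)

  dr <- vapply(1:100, function(sd) {
    ambiguity_sensitivity(gen_behavior(behavior_truth(
      rt_ambiguity_gain = 0.15, n_trials_per_level = 40,
      seed = sd)))$delta_rt
  }, numeric(1))
  expect_lt(abs(mean(dr) - 0.15), 0.01)
})

test_that("group comparison matches closed-form statistics", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  res <- group_compare(g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  g2 <- list(a = c(1, 2, 3), b = c(11, 12, 13))
  res2 <- group_compare(g2)
  # closed form: diff 10, pooled sd 1, se = sqrt(2/3)
  expect_equal(res2$statistic, -10 / sqrt(2 / 3), tolerance = 1e-12)
  expect_lt(res2$p_value, 0.01)
  expect_equal(res2$effect_size, -10, tolerance = 1e-12)

  # three-group ANOVA null calibration at alpha = 0.05
  set.seed(91)
  hits <- vapply(1:1000, function(i) {
    v <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8))
    group_compare(v)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.07)
})
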