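test_that("the 5-95 range follows the linear-interpolation convention", {
  x <- seq(0.1, 1.0, by = 0.1)
  expected <- percentile_linear(x, 0.95) - percentile_linear(x, 0.05)
  expect_equal(delay_range(x), expected)
  expect_equal(delay_range(rep(0.3, 8)), 0)
  expect_error(delay_range(0.5), "two values")
  # inserting a value strictly between the current percentiles cannot widen it
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(15)
    r0 <- delay_range(x)
    mid <- mean(range(percentile_linear(x, 0.05), percentile_linear(x, 0.95)))
    expect_lte(delay_range(c(x, mid)), r0 + 1e-12)
  }
})

test_that("rm-ANOVA F statistics match the aov error-strata oracle", {
  set.seed(11)
  n <- 6
  d <- expand.grid(participant = factor(1:n), step = factor(1:2),
                   isi = factor(1:4))
  d$y <- rnorm(nrow(d)) + 0.5 * as.numeric(d$step) +
    rnorm(n)[as.integer(d$participant)]
  mine <- rm_anova(d, dv = "y", subject = "participant",
                   within = c("step", "isi"))
  oracle <- summary(aov(y ~ step * isi + Error(participant / (step * isi)),
                        data = d))
  get_f <- function(stratum, term) {
    tab <- oracle[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  expect_equal(mine$F[mine$effect == "step"],
               get_f("Error: participant:step", "step"), tolerance = 1e-9)
  expect_equal(mine$F[mine$effect == "isi"],
               get_f("Error: participant:isi", "isi"), tolerance = 1e-9)
  expect_equal(mine$F[mine$effect == "step:isi"],
               get_f("Error: participant:step:isi", "step:isi"),
               tolerance = 1e-9)
})

test_that("sphericity epsilons match car::Anova", {
  skip_if_not_installed("car")
  set.seed(3)
  n <- 8; kb <- 5
  Y <- matrix(rnorm(n * kb), n, kb)
  Y[, 1] <- Y[, 1] * 3
  Y[, 2] <- Y[, 2] * 0.2 + Y[, 1] * 0.9
  d <- data.frame(participant = factor(rep(1:n, kb)),
                  B = factor(rep(1:kb, each = n)), y = as.vector(Y))
  mine <- rm_anova(d, "y", "participant", "B")
  aa <- summary(car::Anova(lm(Y ~ 1), idata = data.frame(B = factor(1:kb)),
                           idesign = ~B, type = 3), multivariate = FALSE)
  adj <- aa$pval.adjustments
  expect_equal(mine$eps_gg, unname(adj[1, "GG eps"]), tolerance = 1e-6)
  expect_equal(mine$eps_hf, unname(adj[1, "HF eps"]), tolerance = 1e-6)
})

test_that("degenerate and two-level designs behave as contracts state", {
  # identical RT1 and RT2 in every cell: zero step effect, F = 0, p = 1
  d <- expand.grid(participant = factor(1:5), step = factor(1:2),
                   isi = factor(1:3))
  base <- rnorm(15)
  d$y <- base[as.integer(interaction(d$participant, d$isi))]
  res <- rm_anova(d, "y", "participant", c("step", "isi"))
  expect_equal(res$F[res$effect == "step"], 0)
  expect_equal(res$p[res$effect == "step"], 1)
  # a 2-level factor keeps its degrees of freedom (eps = 1)
  expect_equal(res$eps_used[res$effect == "step"], 1)
  expect_equal(res$df1_corr[res$effect == "step"], 1)
  # incomplete designs are rejected with the missing cell named
  d2 <- d[-1, ]
  expect_error(rm_anova(d2, "y", "participant", c("step", "isi")),
               "incomplete")
})

test_that("per-ISI post-hoc tests yield the contiguous-significance metric", {
  isis <- isi_grid(0)
  build <- function(effect_fun) {
    set.seed(12)
    do.call(rbind, lapply(1:8, function(p) {
      rt1 <- 0.18 + rnorm(length(isis), 0, 0.01)
      rt2 <- rt1 + effect_fun(isis) + rnorm(length(isis), 0, 0.01)
      data.frame(participant = p, isi = isis, rt1 = rt1, rt2 = rt2)
    }))
  }
  # elongation up to 250 ms: metric 0.25, interp midpoint 0.275
  ph <- posthoc_by_isi(build(function(i) ifelse(i <= 0.25, 0.15, 0)))
  expect_equal(ph$metric_anova, 0.25)
  expect_equal(ph$metric_interp, (0.25 + 0.30) / 2)
  expect_false(ph$unbounded)
  expect_setequal(ph$interfered_isis, isis[isis <= 0.25])
  # no elongation anywhere: metric 0
  ph0 <- posthoc_by_isi(build(function(i) 0))
  expect_equal(ph0$metric_anova, 0)
  # elongation everywhere: metric = largest ISI, flagged unbounded
  ph1 <- posthoc_by_isi(build(function(i) 0.2))
  expect_equal(ph1$metric_anova, 1.0)
  expect_true(ph1$unbounded)
  expect_error(posthoc_by_isi(data.frame(participant = 1:2, isi = 1,
                                         rt1 = 1, rt2 = 1)), "3 participants")
})

test_that("the RT2 regression reproduces the printed worked arithmetic", {
  # first-order reversed data: intercept 434 ms, mean RT1 230 ms -> 204 ms
  isis <- c(0.10, 0.15, 0.20, 0.25, 0.35)
  slope <- -0.55
  rt2 <- 0.434 + slope * isis
  reg <- fit_rt2_regression(isis, rt2, mean_rt1 = 0.230)
  expect_equal(reg$intercept, 0.434, tolerance = 1e-12)
  expect_equal(reg$max_increase, 0.204, tolerance = 1e-12)
})

test_that("points on RT2 = C - ISI give slope -1 and equal intercepts", {
  isis <- c(0.05, 0.10, 0.15, 0.20)
  C <- 0.49
  rt2 <- C - isis
  un <- fit_rt2_regression(isis, rt2, mean_rt1 = 0.14)
  co <- fit_rt2_regression(isis, rt2, mean_rt1 = 0.14, constrain_slope = -1)
  expect_equal(un$slope, -1, tolerance = 1e-12)
  expect_equal(un$intercept, C, tolerance = 1e-12)
  expect_equal(co$intercept, C, tolerance = 1e-12)
  # the constrained line crosses the RT1 baseline at the open-loop interval
  expect_equal(co$duration, 0.35, tolerance = 1e-12)
  # empty interfered set: metrics absent
  e <- fit_rt2_regression(numeric(0), numeric(0), 0.14)
  expect_true(is.na(e$max_increase))
})

test_that("the stage-2 battery flags refractory and null data correctly", {
  isis <- isi_grid(0)
  set.seed(13)
  refr <- do.call(rbind, lapply(1:8, function(p) {
    rt1 <- 0.18 + rnorm(length(isis), 0, 0.02)
    rt2 <- rt1 + pmax(0, 0.35 - isis) + rnorm(length(isis), 0, 0.02)
    data.frame(participant = p, isi = isis, rt1 = rt1, rt2 = rt2)
  }))
  s2 <- stage2_report(refr)
  expect_false(all(s2$no_refractoriness))
  expect_gt(s2$posthoc$metric_anova, 0)
  expect_false(is.na(s2$regression$max_increase))
  null <- do.call(rbind, lapply(1:8, function(p) {
    rt1 <- 0.18 + rnorm(length(isis), 0, 0.02)
    rt2 <- 0.18 + rnorm(length(isis), 0, 0.02)
    data.frame(participant = p, isi = isis, rt1 = rt1, rt2 = rt2)
  }))
  s0 <- stage2_report(null)
  expect_true(all(s0$no_refractoriness))
})
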