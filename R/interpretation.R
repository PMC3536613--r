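## Stage 3: model-based interpretation of the delay statistics.

#' Classify the triggering regime from the RT2-versus-ISI slope
#'
#' Under the single-channel intermittent-control model, events triggered
#' externally at one event per step give a slope of -1 over interfered ISIs;
#' events generated internally at the maximum rate permitted by the minimum
#' open-loop interval give -0.5; continuous control gives 0. The class is
#' decided by which canonical slope the 95% confidence interval covers;
#' boundary overlaps resolve to `"mixed"`.
#'
#' @param slope unconstrained regression slope.
#' @param slope_se its standard error.
#' @param df residual degrees of freedom of the regression (normal critical
#'   value used when unavailable).
#' @return One of `"external"`, `"internal_saturated"`, `"continuous"`,
#'   `"mixed"`.
#' @export
classify_triggering <- function(slope, slope_se, df = Inf) {
  if (is.na(slope)) return("continuous")
  crit <- if (is.finite(df) && df >= 1) stats::qt(0.975, df) else 1.96
  lo <- slope - crit * slope_se
  hi <- slope + crit * slope_se
  covers <- function(v) lo <= v && v <= hi
  if (covers(-1) && !covers(-0.5)) "external"
  else if (covers(-0.5) && !covers(-1)) "internal_saturated"
  else if (covers(0) && !covers(-0.5)) "continuous"
  else "mixed"
}

#' Detect an interior peak in mean RT2 over ISI
#'
#' With set-point low-pass filtering and a sampling delay, responses to very
#' closely spaced steps merge, so RT2 decreases again at the lowest ISIs and
#' peaks at an ISI equal to the sampling delay. The peak must strictly
#' exceed both neighbours; a monotone profile or a boundary maximum returns
#' absent (`NA`).
#'
#' @param isi ISI levels (s), sorted or not.
#' @param rt2 mean RT2 at each ISI (s).
#' @return The peak ISI (s), or `NA_real_` when absent.
#' @export
estimate_sampling_delay <- function(isi, rt2) {
  o <- order(isi)
  isi <- isi[o]; rt2 <- rt2[o]
  if (length(isi) < 3) stop("peak detection needs at least 3 ISI levels")
  i <- which.max(rt2)
  if (i == 1 || i == length(rt2)) return(NA_real_)
  if (rt2[i] > rt2[i - 1] && rt2[i] > rt2[i + 1]) isi[i] else NA_real_
}

#' Combine the four refractory-duration estimates and classify triggering
#'
#' Builds the per-condition report: the baseline mean RT1; the four
#' refractory-duration metrics — intercept of the unconstrained regression
#' minus mean RT1 (the maximum increase in RT2), intercept of the
#' slope-constrained (-1) fit minus mean RT1, the ANOVA metric, and the
#' 5-95 range of RT2 pooled over interfered ISIs — plus the triggering
#' class from the unconstrained slope and the sampling-delay peak estimate.
#'
#' @param stage2 a [stage2_report()] result.
#' @param condition optional condition descriptor (character).
#' @return List of class `refractory_report`.
#' @export
refractory_estimates <- function(stage2, condition = "") {
  if (!inherits(stage2, "stage2_report")) stop("'stage2' must be a stage2_report")
  interfered <- stage2$interfered_isis
  reg <- stage2$regression
  rng_rt2 <- if (length(interfered)) {
    pool <- stage2$pairs$rt2[stage2$pairs$isi %in% interfered]
    if (length(pool) >= 2) delay_range(pool) else NA_real_
  } else NA_real_
  cls <- if (!length(interfered)) "continuous"
         else classify_triggering(reg$slope, reg$slope_se, reg$df)
  peak <- estimate_sampling_delay(stage2$mean_rt2_by_isi$isi,
                                  stage2$mean_rt2_by_isi$rt2)
  structure(list(
    condition = condition,
    mean_rt1 = stage2$mean_rt1,
    mean_rt2_by_isi = stage2$mean_rt2_by_isi,
    range_rt1 = mean(stage2$ranges$range_rt1),
    range_rt2 = mean(stage2$ranges$range_rt2),
    anova = stage2$anova,
    metric_anova = stage2$posthoc$metric_anova,
    metric_interp = stage2$posthoc$metric_interp,
    slope_unconstrained = reg$slope,
    slope_se = reg$slope_se,
    intercept_unconstrained = reg$intercept,
    max_increase = reg$max_increase,
    intercept_constrained = stage2$regression_constrained$intercept,
    duration_constrained = stage2$regression_constrained$duration,
    metric_range_rt2 = rng_rt2,
    triggering_class = cls,
    sampling_delay_estimate = peak,
    no_refractoriness = stage2$no_refractoriness), class = "refractory_report")
}

#' @export
print.refractory_report <- function(x, ...) {
  cat("<refractory_report>", x$condition, "\n")
  cat(sprintf("  baseline mean RT1: %.0f ms\n", 1000 * x$mean_rt1))
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.0f ms", 1000 * v)
  cat("  refractory-duration estimates:\n")
  cat("    unconstrained-intercept: ", fmt(x$max_increase), "\n", sep = "")
  cat("    slope -1 intercept:      ", fmt(x$duration_constrained), "\n", sep = "")
  cat("    ANOVA metric:            ", fmt(x$metric_anova), "\n", sep = "")
  cat("    range in RT2:            ", fmt(x$metric_range_rt2), "\n", sep = "")
  cat(sprintf("  triggering class: %s (slope %.3f)\n", x$triggering_class,
              x$slope_unconstrained))
  if (!is.na(x$sampling_delay_estimate))
    cat(sprintf("  sampling-delay peak at ISI = %.0f ms\n",
                1000 * x$sampling_delay_estimate))
  invisible(x)
}

#' Markdown rendering of a refractory report
#'
#' @param x a `refractory_report`.
#' @return Character vector of Markdown lines.
#' @export
report_markdown <- function(x) {
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.0f ms", 1000 * v)
  c(paste0("## Refractory-duration estimates ", x$condition),
    "",
    sprintf("Baseline mean RT1: %.0f ms", 1000 * x$mean_rt1),
    "",
    "| metric | estimate |",
    "|---|---|",
    paste0("| intercept of the unconstrained fit minus mean RT1 | ",
           fmt(x$max_increase), " |"),
    paste0("| intercept of the slope -1 fit minus mean RT1 | ",
           fmt(x$duration_constrained), " |"),
    paste0("| ANOVA metric (contiguous significant ISIs) | ",
           fmt(x$metric_anova), " |"),
    paste0("| 5-95 range of interfered RT2 | ", fmt(x$metric_range_rt2), " |"),
    "",
    sprintf("Triggering class: **%s** (unconstrained slope %.3f, se %.3f)",
            x$triggering_class, x$slope_unconstrained, x$slope_se),
    if (!is.na(x$sampling_delay_estimate))
      sprintf("Sampling-delay peak at ISI = %.0f ms",
              1000 * x$sampling_delay_estimate) else character(0))
}
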