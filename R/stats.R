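## Stage 2: statistical quantification of refractoriness.

#' 5-95 percentile range of a delay distribution
#'
#' @param x delay values (s); at least two.
#' @param lo,hi percentile bounds (default 5 and 95), linear-interpolation
#'   convention (R quantile type 7).
#' @return `hi` percentile minus `lo` percentile, in the units of `x`.
#' @export
delay_range <- function(x, lo = 5, hi = 95) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("delay_range needs at least two values")
  diff(stats::quantile(x, c(lo, hi) / 100, names = FALSE, type = 7))
}

# orthonormal between-level contrasts for a k-level within factor
orthonorm_contrasts <- function(k) {
  cm <- stats::contr.helmert(k)
  t(cm %*% diag(1 / sqrt(colSums(cm^2)), ncol(cm)))
}

#' Repeated-measures ANOVA with averaged GG/HF sphericity correction
#'
#' Classical within-subject sums of squares for fully crossed within-subject
#' designs. For every effect with more than one numerator degree of freedom,
#' the degrees of freedom are multiplied by
#' `min(1, (eps_GG + eps_HF) / 2)` — the average of the Greenhouse-Geisser
#' and Huynh-Feldt sphericity estimates.
#'
#' @param data long-format data frame; repeated cells (e.g. repetitions) are
#'   averaged within subject before analysis.
#' @param dv name of the dependent-variable column.
#' @param subject name of the subject identifier column.
#' @param within character vector of within-subject factor columns.
#' @return Data frame with one row per effect: `effect`, `df1`, `df2`, `ss`,
#'   `ss_err`, `F`, `eps_gg`, `eps_hf`, `eps_used`, `df1_corr`, `df2_corr`,
#'   `p`.
#' @export
rm_anova <- function(data, dv, subject, within) {
  for (nm in c(dv, subject, within))
    if (!nm %in% names(data)) stop("column '", nm, "' not found")
  facs <- lapply(within, function(f) factor(data[[f]]))
  names(facs) <- within
  subj <- factor(data[[subject]])
  n <- nlevels(subj)
  if (n < 2) stop("rm_anova needs at least 2 subjects")
  klev <- vapply(facs, nlevels, integer(1))
  p_cells <- prod(klev)
  # cell index: first factor varies slowest (matches the kronecker ordering)
  cell <- rep(1L, nrow(data))
  for (f in seq_along(facs)) {
    mult <- prod(klev[-seq_len(f)], 1)
    cell <- cell + (as.integer(facs[[f]]) - 1L) * as.integer(mult)
  }
  Y <- matrix(NA_real_, n, p_cells)
  agg <- tapply(data[[dv]], list(subj, factor(cell, levels = seq_len(p_cells))),
                mean)
  Y[] <- agg
  if (any(is.na(Y))) {
    miss <- which(is.na(Y), arr.ind = TRUE)
    stop("incomplete design: ", nrow(miss), " missing subject x cell entries, ",
         "e.g. subject ", levels(subj)[miss[1, 1]], ", cell ", miss[1, 2])
  }
  tot_ss <- sum((Y - mean(Y))^2)
  effects <- unlist(lapply(seq_along(within), function(m)
    utils::combn(within, m, simplify = FALSE)), recursive = FALSE)
  out <- lapply(effects, function(eff) {
    Ms <- lapply(within, function(f) {
      k <- klev[[f]]
      if (f %in% eff) orthonorm_contrasts(k) else matrix(1 / sqrt(k), 1, k)
    })
    M <- Reduce(kronecker, Ms)
    Z <- Y %*% t(M)
    d <- nrow(M)
    mZ <- colMeans(Z)
    ss_eff <- n * sum(mZ^2)
    Zc <- sweep(Z, 2, mZ)
    ss_err <- sum(Zc^2)
    df2 <- d * (n - 1)
    null_eff <- ss_eff <= 1e-12 * max(tot_ss, .Machine$double.eps)
    Fv <- if (null_eff) 0 else (ss_eff / d) / (ss_err / df2)
    if (d > 1) {
      S <- stats::cov(Z)
      egg <- sum(diag(S))^2 / (d * sum(S^2))
      ehf <- (n * d * egg - 2) / (d * (n - 1 - d * egg))
      ehf <- max(egg, min(1, ehf))
      eps <- min(1, (egg + ehf) / 2)
    } else {
      egg <- ehf <- eps <- 1
    }
    pv <- if (null_eff) 1 else stats::pf(Fv, d * eps, df2 * eps,
                                         lower.tail = FALSE)
    data.frame(effect = paste(eff, collapse = ":"), df1 = d, df2 = df2,
               ss = ss_eff, ss_err = ss_err, F = Fv, eps_gg = egg,
               eps_hf = ehf, eps_used = eps, df1_corr = d * eps,
               df2_corr = df2 * eps, p = pv, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-ISI post-hoc comparison of RT1 and RT2
#'
#' Repetitions are averaged within participant, then a two-tailed paired
#' t-test compares RT2 with RT1 across participants at each ISI. The ANOVA
#' metric is the largest ISI such that it and every smaller ISI are
#' significant; a linear-interpolation variant (midpoint between the last
#' significant and the first non-significant ISI) is reported alongside.
#'
#' @param pairs data frame with columns `participant`, `isi`, `rt1`, `rt2`.
#' @param alpha significance level (default 0.05).
#' @param adjust p-value adjustment passed to [stats::p.adjust()]; default
#'   `"none"` (raw per-ISI p-values; `"holm"` available).
#' @return List: `table` (per-ISI means, t, p, significance), `metric_anova`
#'   (s), `metric_interp` (s), `unbounded` (all ISIs significant),
#'   `interfered_isis` (every ISI flagged significant).
#' @export
posthoc_by_isi <- function(pairs, alpha = 0.05, adjust = "none") {
  need <- c("participant", "isi", "rt1", "rt2")
  if (!all(need %in% names(pairs))) stop("'pairs' needs columns ",
                                         paste(need, collapse = ", "))
  if (length(unique(pairs$participant)) < 3)
    stop("per-ISI post-hoc tests need at least 3 participants")
  agg <- stats::aggregate(cbind(rt1, rt2) ~ participant + isi, data = pairs,
                          FUN = mean)
  isis <- sort(unique(agg$isi))
  rows <- lapply(isis, function(ii) {
    d <- agg[agg$isi == ii, ]
    diffs <- d$rt2 - d$rt1
    tt <- tryCatch(stats::t.test(d$rt2, d$rt1, paired = TRUE),
                   error = function(e) NULL)
    data.frame(isi = ii, n = nrow(d), mean_rt1 = mean(d$rt1),
               mean_rt2 = mean(d$rt2), mean_diff = mean(diffs),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- stats::p.adjust(tab$p, method = adjust)
  sig <- !is.na(tab$p_adj) & tab$p_adj < alpha & tab$mean_diff > 0
  tab$significant <- sig
  run <- 0L
  while (run < length(sig) && sig[run + 1L]) run <- run + 1L
  metric <- if (run == 0L) 0 else isis[run]
  unbounded <- run == length(isis)
  interp <- if (run == 0L) 0
            else if (unbounded) isis[run]
            else (isis[run] + isis[run + 1L]) / 2
  list(table = tab, metric_anova = metric, metric_interp = interp,
       unbounded = unbounded, interfered_isis = isis[sig])
}

#' RT2-versus-ISI regression over interfered ISIs
#'
#' Unconstrained: ordinary least squares of mean RT2 on ISI; the maximum
#' increase in RT2 is the intercept (ISI = 0) minus the average RT1.
#' Constrained (slope fixed at -1, the single-channel prediction): the
#' least-squares intercept is `mean(RT2 + ISI)` and the refractory duration
#' is that intercept minus the average RT1 — the ISI at which the line
#' crosses the RT1 baseline.
#'
#' @param isi interfered ISIs (s).
#' @param rt2 mean RT2 at each interfered ISI (s).
#' @param mean_rt1 average RT1 baseline (s).
#' @param constrain_slope `NULL` (default, unconstrained OLS) or a fixed
#'   slope, canonically -1.
#' @return Unconstrained: list with `slope`, `slope_se`, `df`, `intercept`,
#'   `max_increase`. Constrained: list with `slope`, `intercept`,
#'   `duration`. With an empty interfered set all fields are `NA` (the
#'   metrics are reported as absent).
#' @export
fit_rt2_regression <- function(isi, rt2, mean_rt1, constrain_slope = NULL) {
  stopifnot(length(isi) == length(rt2))
  if (length(isi) == 0) {
    return(if (is.null(constrain_slope))
      list(slope = NA_real_, slope_se = NA_real_, df = NA_integer_,
           intercept = NA_real_, max_increase = NA_real_)
      else list(slope = constrain_slope, intercept = NA_real_,
                duration = NA_real_))
  }
  if (is.null(constrain_slope)) {
    if (length(isi) < 2)
      stop("unconstrained regression needs at least 2 interfered ISIs")
    fit <- stats::lm(rt2 ~ isi)
    sm <- suppressWarnings(summary(fit))$coefficients
    list(slope = unname(stats::coef(fit)[2]),
         slope_se = if (nrow(sm) > 1) sm[2, 2] else NA_real_,
         df = fit$df.residual,
         intercept = unname(stats::coef(fit)[1]),
         max_increase = unname(stats::coef(fit)[1]) - mean_rt1)
  } else {
    intercept <- mean(rt2 - constrain_slope * isi)
    list(slope = constrain_slope, intercept = intercept,
         duration = intercept - mean_rt1)
  }
}

#' Stage-2 test battery for one condition
#'
#' Runs the six model-free tests that discriminate continuous from
#' refractory (intermittent) control on a table of reconstructed (RT1, RT2)
#' pairs: (1) equality of the 5-95 ranges of RT1 and RT2, (2) the Step
#' Number main effect, (3) the Step x ISI interaction, (4) independence of
#' RT1 from ISI, (5) the ISI up to which RT2 is significantly greater than
#' RT1 (the ANOVA metric), and (6) the maximum increase in RT2 from the
#' unconstrained regression over interfered ISIs (plus the slope-constrained
#' variant).
#'
#' @param pairs data frame with columns `participant`, `isi`, `rt1`, `rt2`
#'   (one condition; repetitions allowed).
#' @param alpha significance level (default 0.05).
#' @param range_tol absolute tolerance (s) under which RT1/RT2 ranges count
#'   as equal regardless of the test (default 0.02, one identification grid
#'   step).
#' @param adjust post-hoc p-value adjustment (default `"none"`).
#' @return List of class `stage2_report`: per-test results, the fitted
#'   regressions, and a logical vector `no_refractoriness` with one entry
#'   per test.
#' @export
stage2_report <- function(pairs, alpha = 0.05, range_tol = 0.02,
                          adjust = "none") {
  agg <- stats::aggregate(cbind(rt1, rt2) ~ participant + isi, data = pairs,
                          FUN = mean)
  long <- rbind(
    data.frame(participant = agg$participant, isi = agg$isi, step = "RT1",
               value = agg$rt1),
    data.frame(participant = agg$participant, isi = agg$isi, step = "RT2",
               value = agg$rt2))
  aov_tab <- rm_anova(long, dv = "value", subject = "participant",
                      within = c("step", "isi"))
  # (1) ranges, pooled over ISIs and repetitions within participant
  rng <- do.call(rbind, lapply(split(pairs, pairs$participant), function(d)
    data.frame(range_rt1 = delay_range(d$rt1), range_rt2 = delay_range(d$rt2))))
  rt_rng <- tryCatch(stats::t.test(rng$range_rt2, rng$range_rt1, paired = TRUE),
                     error = function(e) NULL)
  range_diff <- mean(rng$range_rt2) - mean(rng$range_rt1)
  range_p <- if (is.null(rt_rng)) NA_real_ else rt_rng$p.value
  ranges_equal <- abs(range_diff) < range_tol ||
    (!is.na(range_p) && range_p >= alpha)
  # (4) RT1 versus ISI
  rt1_aov <- rm_anova(data.frame(participant = agg$participant, isi = agg$isi,
                                 value = agg$rt1),
                      dv = "value", subject = "participant", within = "isi")
  m1 <- stats::aggregate(rt1 ~ isi, data = agg, FUN = mean)
  rt1_slope <- unname(stats::coef(stats::lm(rt1 ~ isi, data = m1))[2])
  # (5) post-hoc per ISI
  ph <- posthoc_by_isi(pairs, alpha = alpha, adjust = adjust)
  # (6) regressions over interfered ISIs
  mean_rt1 <- mean(agg$rt1)
  m2 <- stats::aggregate(rt2 ~ isi, data = agg, FUN = mean)
  interfered <- ph$interfered_isis
  m2i <- m2[m2$isi %in% interfered, ]
  reg_u <- if (nrow(m2i) >= 2)
    fit_rt2_regression(m2i$isi, m2i$rt2, mean_rt1) else
    fit_rt2_regression(numeric(0), numeric(0), mean_rt1)
  reg_c <- fit_rt2_regression(m2i$isi, m2i$rt2, mean_rt1, constrain_slope = -1)
  step_p <- aov_tab$p[aov_tab$effect == "step"]
  inter_p <- aov_tab$p[aov_tab$effect == "step:isi"]
  no_refr <- c(
    ranges_equal      = ranges_equal,
    rt2_equals_rt1    = step_p >= alpha,
    no_step_isi_inter = inter_p >= alpha,
    rt1_isi_indep     = rt1_aov$p[1] >= alpha,
    anova_metric_zero = ph$metric_anova == 0,
    no_max_increase   = is.na(reg_u$max_increase)
  )
  structure(list(
    anova = aov_tab, ranges = rng, range_diff = range_diff,
    range_p = range_p, ranges_equal = ranges_equal,
    rt1_by_isi = rt1_aov, rt1_slope = rt1_slope,
    posthoc = ph, mean_rt1 = mean_rt1, mean_rt2_by_isi = m2,
    interfered_isis = interfered, regression = reg_u,
    regression_constrained = reg_c, pairs = pairs,
    no_refractoriness = no_refr, alpha = alpha), class = "stage2_report")
}

#' @export
print.stage2_report <- function(x, ...) {
  cat("<stage2_report>\n")
  cat(sprintf("  mean RT1 %.0f ms; ANOVA metric %.0f ms (interp %.0f ms)\n",
              1000 * x$mean_rt1, 1000 * x$posthoc$metric_anova,
              1000 * x$posthoc$metric_interp))
  if (!is.na(x$regression$max_increase))
    cat(sprintf("  unconstrained: slope %.3f, intercept %.0f ms, max increase %.0f ms\n",
                x$regression$slope, 1000 * x$regression$intercept,
                1000 * x$regression$max_increase))
  if (!is.na(x$regression_constrained$duration))
    cat(sprintf("  slope -1 fit: intercept %.0f ms, refractory duration %.0f ms\n",
                1000 * x$regression_constrained$intercept,
                1000 * x$regression_constrained$duration))
  verdict <- if (all(x$no_refractoriness)) "no refractoriness"
             else "refractoriness detected"
  cat("  verdict: ", verdict, " (", sum(!x$no_refractoriness),
      "/6 tests positive)\n", sep = "")
  invisible(x)
}
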