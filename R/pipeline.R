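## Orchestration: virtual experiment end to end, plus trial CSV round trips.

#' Validate a virtual-experiment configuration
#'
#' @param order system order (0, 1 or 2).
#' @param stability `"not_applicable"`, `"marginally_stable"` or `"unstable"`.
#' @param controller `"intermittent"` or `"continuous"`.
#' @param params an [ic_params()] object.
#' @param participants number of virtual participants (>= 1).
#' @param repetitions repetitions per ISI x pattern combination.
#' @param amplitude step amplitude (screen units).
#' @param patterns step patterns included in each session.
#' @param seed mandatory integer seed.
#' @param dt simulation step (s).
#' @param dt_id identification (reconstruction) step (s).
#' @param arx_order ARX model order.
#' @param alpha significance level for stage 2.
#' @param gain,tau,display_limit forwarded to [system_spec()].
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(order, stability = if (order == 2) "marginally_stable" else "not_applicable",
                       controller = c("intermittent", "continuous"),
                       params = ic_params(), participants = 1L,
                       repetitions = 1L, amplitude = 1,
                       patterns = c("rev_LR", "rev_RL"),
                       seed, dt = 0.001, dt_id = 0.02, arx_order = 10,
                       alpha = 0.05, gain = 1, tau = 0.92,
                       display_limit = 1.5) {
  controller <- match.arg(controller)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("'seed' is mandatory")
  if (participants < 1) stop("'participants' must be >= 1")
  spec <- system_spec(order, stability, tau = tau, gain = gain,
                      display_limit = display_limit)  # validates order/stability
  if (!inherits(params, "ic_params")) stop("'params' must come from ic_params()")
  structure(list(spec = spec, controller = controller, params = params,
                 participants = as.integer(participants),
                 repetitions = as.integer(repetitions),
                 amplitude = amplitude, patterns = patterns,
                 seed = as.integer(seed), dt = dt, dt_id = dt_id,
                 arx_order = arx_order, alpha = alpha),
            class = "run_config")
}

config_json <- function(config) {
  cl <- config
  cl$spec <- unclass(cl$spec); cl$params <- unclass(cl$params)
  jsonlite::toJSON(unclass(cl), auto_unbox = TRUE, digits = NA)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(config_json(config)), tf)
  unname(tools::md5sum(tf))
}

#' Write / read trial records as CSV
#'
#' Columns: `t`, `w`, `u`, `u_e`, `d`, `y`, `event` (0/1 at the event
#' sample), `reset` (0/1). A metadata sidecar JSON is written alongside.
#' Externally recorded trials only need the `t`, `w`, `u_e` columns (plus
#' whichever of the others exist).
#'
#' @param trial a `trial_record`.
#' @param path CSV path; the sidecar is `<path>.meta.json`.
#' @return `write_trial`: the path, invisibly. `read_trial`: a
#'   `trial_record`.
#' @export
write_trial <- function(trial, path) {
  nT <- length(trial$w)
  tvec <- (seq_len(nT) - 1) * trial$dt
  ev <- integer(nT); ev[round(trial$event_times / trial$dt) + 1L] <- 1L
  rs <- integer(nT)
  if (length(trial$reset_times))
    rs[round(trial$reset_times / trial$dt) + 1L] <- 1L
  df <- data.frame(t = tvec, w = trial$w, u = trial$u, u_e = trial$u_e,
                   d = trial$d, y = trial$y, event = ev, reset = rs)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- trial$meta
  meta$dt <- trial$dt
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else unclass(x)
  jsonlite::write_json(strip(meta), paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "w", "u_e")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("trial CSV schema mismatch: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  dt <- if (nrow(df) > 1) df$t[2] - df$t[1] else 0.001
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    m <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(m$sequence)) {
      m$sequence <- structure(m$sequence, class = "step_sequence")
    }
    m
  } else list()
  get0c <- function(nm) if (nm %in% names(df)) df[[nm]] else numeric(nrow(df))
  ev <- if ("event" %in% names(df)) df$t[df$event == 1] else numeric(0)
  rs <- if ("reset" %in% names(df)) df$t[df$reset == 1] else numeric(0)
  new_trial_record(dt, df$w, get0c("u"), df$u_e, get0c("y"), get0c("d"),
                   ev, rs, meta)
}

#' Run a virtual experiment end to end
#'
#' Simulates every participant's randomized session, reconstructs the
#' per-step delays, runs the Stage-2 battery and the Stage-3 interpretation,
#' and writes all artifacts: session and delay-table CSVs, per-trial CSVs
#' (optional), the stage-2/3 JSON report, and a log with the config hash.
#' Deterministic given the config seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param write_trial_files write one CSV per trial (default FALSE; the
#'   delay table is always written).
#' @return Invisibly, a list with the delay table, the stage-2 report and
#'   the `refractory_report`.
#' @export
run_experiment <- function(config, out_dir, write_trial_files = FALSE) {
  if (!inherits(config, "run_config")) stop("'config' must come from run_config()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  writeLines(as.character(config_json(config)), file.path(out_dir, "config.json"))
  set.seed(config$seed)
  pseeds <- sample.int(.Machine$integer.max, config$participants)
  delays <- list()
  for (p in seq_len(config$participants)) {
    set.seed(pseeds[p])
    session <- build_session(config$spec$order, amplitude = config$amplitude,
                             repetitions = config$repetitions,
                             patterns = config$patterns)
    if (p == 1L)
      utils::write.csv(session_table(session),
                       file.path(out_dir, "session_participant1.csv"),
                       row.names = FALSE)
    trials <- run_virtual_participant(config$spec, session,
                                      controller = config$controller,
                                      params = config$params,
                                      seed = pseeds[p], dt = config$dt)
    if (write_trial_files) {
      td <- file.path(out_dir, sprintf("participant_%02d", p))
      dir.create(td, showWarnings = FALSE)
      for (i in seq_along(trials))
        write_trial(trials[[i]], file.path(td, sprintf("trial_%03d.csv", i)))
    }
    delays[[p]] <- reconstruct_session(trials, participant = p,
                                       dt_id = config$dt_id,
                                       order = config$arx_order)
  }
  delay_tab <- extract_rt_pairs(do.call(rbind, delays))
  utils::write.csv(format(delay_tab, digits = 15),
                   file.path(out_dir, "delay_table.csv"), row.names = FALSE)
  report <- NULL
  s2 <- NULL
  if (config$participants >= 3) {
    s2 <- stage2_report(delay_tab, alpha = config$alpha,
                        range_tol = config$dt_id)
    report <- refractory_estimates(s2, condition = sprintf(
      "order %d (%s), %s control", config$spec$order, config$spec$stability,
      config$controller))
    out <- list(
      mean_rt1 = report$mean_rt1,
      metric_anova = report$metric_anova,
      metric_interp = report$metric_interp,
      slope_unconstrained = report$slope_unconstrained,
      max_increase = report$max_increase,
      duration_constrained = report$duration_constrained,
      metric_range_rt2 = report$metric_range_rt2,
      triggering_class = report$triggering_class,
      no_refractoriness = as.list(report$no_refractoriness))
    jsonlite::write_json(out, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(report_markdown(report), file.path(out_dir, "report.md"))
  }
  log_lines <- c(
    sprintf("refractory %s", as.character(utils::packageVersion("refractory"))),
    sprintf("R %s", getRversion()),
    sprintf("config hash %s", hash),
    sprintf("participants %d, trials/participant %d",
            config$participants, length(delays[[1]]$trial_id)),
    sprintf("run completed %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(delay_table = delay_tab, stage2 = s2, report = report,
                 config_hash = hash))
}
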