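# Orchestration: one config drives generation (or ingestion), the group
# comparison, the event studies, and figure/table output, so a whole
# analysis is reproducible from a single call.

.default_run_config <- function() {
  list(generator = NULL, input_dir = NULL, out_dir = "beta2hr-results",
       seed = 1L, wear_min_minutes = 10080, pre = 180L, post = 600L,
       n_control = 50L, min_control_days = 10L, step_filter = TRUE,
       threshold = 5, span = 0.15, ci = "both", boot = 200L,
       write_data = FALSE, figures = TRUE, log_level = "INFO")
}

#' Assemble (and validate) a pipeline run configuration
#'
#' @param config A named list, or the path to a YAML file with the same
#'   keys. Either `generator` (a list of [cohort_config()] arguments) or
#'   `input_dir` (a directory holding `hr.csv`, `steps.csv`, `events.csv`,
#'   `medstatus.csv`) must be given. Remaining keys override the analysis
#'   defaults: `out_dir`, `seed`, `wear_min_minutes`, `pre`, `post`,
#'   `n_control`, `min_control_days`, `step_filter`, `threshold`, `span`,
#'   `ci`, `boot`, `write_data`, `figures`.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  base <- .default_run_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    .stopf("unknown run-config key(s): %s", paste(unknown, collapse = ", "),
           class = "beta2hr_config_error")
  base[names(config)] <- config
  if (is.null(base$generator) && is.null(base$input_dir))
    .stopf("run config needs 'generator' parameters or an 'input_dir'",
           class = "beta2hr_config_error")
  if (!is.null(base$generator)) {
    gen <- base$generator
    if (!inherits(gen, "cohort_config")) {
      if (!is.null(gen$saba_kernel) && !inherits(gen$saba_kernel,
                                                 "drug_kernel"))
        gen$saba_kernel <- do.call(drug_kernel, gen$saba_kernel)
      if (!is.null(gen$laba_acute_kernel) &&
          !inherits(gen$laba_acute_kernel, "drug_kernel"))
        gen$laba_acute_kernel <- do.call(drug_kernel, gen$laba_acute_kernel)
      base$generator <- do.call(cohort_config, gen)
    }
  }
  for (nm in c("pre", "post", "n_control", "min_control_days", "boot"))
    if (!.is_count(base[[nm]]))
      .stopf("run-config '%s' must be a non-negative integer", nm,
             class = "beta2hr_config_error")
  if (base$threshold <= 0 || base$span <= 0 || base$span > 1)
    .stopf("threshold must be positive and span in (0, 1]",
           class = "beta2hr_config_error")
  structure(base, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) a cohort bundle, fits the LABA group comparison and
#' the SABA and LABA event studies, and writes every result as plain
#' CSV/JSON artifacts plus figures and a run log under `out_dir`. The run is
#' deterministic given the config and seed; every patient- and event-level
#' exclusion is recorded with its reason.
#'
#' @param config A [run_config()], a named list, or a YAML path.
#' @return Invisibly, a list with `bundle`, `group` (the
#'   [group_comparison()] fit or NULL), `saba`, `laba` (the [event_study()]
#'   fits or NULL) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(fmt, ...) writeLines(sprintf(fmt, ...), log_con)

  if (!is.null(cfg$generator)) {
    say("INFO generating synthetic cohort (seed %d)", cfg$seed)
    bundle <- simulate_cohort(cfg$generator, cfg$seed)
  } else {
    say("INFO reading bundle from %s", cfg$input_dir)
    bundle <- read_bundle(cfg$input_dir)
  }
  say("INFO bundle: %d patients, %d HR minutes, %d actuations",
      length(bundle$patients), nrow(bundle$hr), nrow(bundle$events))
  if (isTRUE(cfg$write_data))
    write_bundle(bundle, file.path(cfg$out_dir, "data"))

  group <- tryCatch(
    group_comparison(bundle, cfg$wear_min_minutes, ci = cfg$ci,
                     boot = cfg$boot, seed = cfg$seed),
    error = function(e) { say("WARN group comparison failed: %s",
                              conditionMessage(e)); NULL })
  if (!is.null(group)) {
    utils::write.csv(group$curve,
                     file.path(cfg$out_dir, "hourly_group_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(group$wear_report,
                     file.path(cfg$out_dir, "wear_report.csv"),
                     row.names = FALSE)
    removed <- sum(group$wear_report$removed)
    say("INFO group comparison: %d segments LABA, %d non-LABA, %d low-wear patients removed",
        group$n_segments[["laba"]], group$n_segments[["non_laba"]], removed)
    summ <- list(overall_difference_bpm = group$overall)
    if (!is.null(group$pooled))
      summ$pooled <- as.list(group$pooled[c("estimate", "lower", "upper")])
    if (!is.null(group$boot))
      summ$bootstrap <- as.list(group$boot[c("lower", "upper")])
    jsonlite::write_json(summ, file.path(cfg$out_dir, "group_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  fit_es <- function(type) {
    tryCatch(
      event_study(bundle, type, pre = cfg$pre, post = cfg$post,
                  n_control = cfg$n_control,
                  min_control_days = cfg$min_control_days,
                  step_filter = cfg$step_filter, threshold = cfg$threshold,
                  span = cfg$span),
      beta2hr_no_events = function(e) {
        say("INFO event study (%s): no events", type); NULL },
      error = function(e) {
        say("WARN event study (%s) failed: %s", type,
            conditionMessage(e)); NULL })
  }
  saba <- fit_es("SABA")
  if (!is.null(saba)) {
    utils::write.csv(saba$curve,
                     file.path(cfg$out_dir, "difference_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(saba$accounting,
                     file.path(cfg$out_dir, "event_accounting.csv"),
                     row.names = FALSE)
    if (!is.null(saba$steps_curve))
      utils::write.csv(saba$steps_curve,
                       file.path(cfg$out_dir, "steps_curve.csv"),
                       row.names = FALSE)
    jsonlite::write_json(unclass(saba$crossings),
                         file.path(cfg$out_dir, "crossings.json"),
                         auto_unbox = TRUE, digits = NA)
    a <- stats::setNames(saba$accounting$n_events, saba$accounting$category)
    say("INFO SABA event study: %d/%d events included (%d steps, %d no controls, %d no wear)",
        a[["included"]], a[["total"]], a[["excluded_by_steps"]],
        a[["excluded_no_controls"]], a[["excluded_no_wear"]])
  }
  laba <- fit_es("LABA")
  if (!is.null(laba))
    utils::write.csv(laba$curve, file.path(cfg$out_dir, "laba_curve.csv"),
                     row.names = FALSE)

  results <- list(bundle = bundle, group = group, saba = saba, laba = laba,
                  out_dir = cfg$out_dir)
  if (isTRUE(cfg$figures)) render_report(results, cfg$out_dir, say = say)
  say("INFO done")
  invisible(results)
}

#' Render the report figures
#'
#' Writes the five standard figures (hourly group curve, inhalations by
#' hour, LABA event-aligned curve, steps around SABA actuations, SABA
#' difference curve with smooth) as both PDF (vector) and PNG (raster)
#' under `out_dir/figures`. Analyses absent from `results` are skipped with
#' a note; rendering is best-effort and never fails the pipeline.
#'
#' @param results Result list from [run_pipeline()] (elements `bundle`,
#'   `group`, `saba`, `laba` may each be NULL).
#' @param out_dir Output directory.
#' @param say Optional logging function `function(fmt, ...)`.
#' @return Invisibly, the figure directory.
#' @export
render_report <- function(results, out_dir, say = function(...) invisible()) {
  figdir <- file.path(out_dir, "figures")
  dir.create(figdir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(name, fun) {
    ok <- tryCatch({
      grDevices::pdf(file.path(figdir, paste0(name, ".pdf")), width = 7,
                     height = 5)
      fun()
      grDevices::dev.off()
      grDevices::png(file.path(figdir, paste0(name, ".png")), width = 900,
                     height = 640)
      fun()
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      try(grDevices::dev.off(), silent = TRUE)
      say("WARN figure %s failed: %s", name, conditionMessage(e))
      FALSE
    })
    if (ok) say("INFO wrote figure %s", name)
  }
  if (!is.null(results$group)) {
    emit("hourly_group_curve", function() plot(results$group))
  } else say("INFO figure hourly_group_curve skipped: no group comparison")
  if (!is.null(results$bundle) && nrow(results$bundle$events)) {
    emit("inhalations_by_hour", function() {
      ev <- results$bundle$events
      hour <- .hour_of_day(ev$time)
      tab <- table(factor(hour, levels = 0:23), ev$inhaler_type)
      graphics::barplot(t(tab), beside = TRUE, xlab = "hour of day",
                        ylab = "actuations",
                        legend.text = colnames(tab),
                        args.legend = list(bty = "n"))
    })
  } else say("INFO figure inhalations_by_hour skipped: no events")
  if (!is.null(results$laba)) {
    emit("laba_event_curve", function() plot(results$laba))
  } else say("INFO figure laba_event_curve skipped: no LABA event study")
  if (!is.null(results$saba) && !is.null(results$saba$steps_curve)) {
    emit("steps_around_saba", function() {
      sc <- results$saba$steps_curve
      rng <- range(c(sc$event_steps, sc$control_steps), na.rm = TRUE)
      graphics::plot(sc$relative_minute, sc$event_steps, type = "l",
                     col = "darkgreen", ylim = rng,
                     xlab = "minutes from actuation",
                     ylab = "mean steps per minute")
      graphics::lines(sc$relative_minute, sc$control_steps, col = "goldenrod")
      graphics::abline(v = 0, lty = 3)
      graphics::legend("topright", bty = "n",
                       col = c("darkgreen", "goldenrod"), lty = 1,
                       legend = c("event days", "control days"))
    })
  } else say("INFO figure steps_around_saba skipped: no steps data")
  if (!is.null(results$saba)) {
    emit("saba_difference_curve", function() plot(results$saba))
  } else say("INFO figure saba_difference_curve skipped: no SABA event study")
  invisible(figdir)
}
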