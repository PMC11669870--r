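# Primary outcome: mean heart rate per clock hour by LABA status, and the
# overall LABA minus non-LABA difference with uncertainty.

#' Cohort comparison of heart rate by LABA status
#'
#' Fits the primary-outcome estimator: after removing low-wear patients and
#' splitting person-time by self-reported LABA status, each patient's mean
#' heart rate per clock hour is computed first, group hour means are the
#' unweighted means of those patient profiles (so wear time does not weight
#' the estimate), and the overall difference is the unweighted mean of the 24
#' hourly LABA minus non-LABA differences (hours covered by both groups).
#'
#' Two 95% confidence intervals are reported, because with millions of pooled
#' minutes a minute-level normal interval degenerates to the point estimate:
#' a pooled-minute normal approximation (on the pooled minute-level
#' difference) and a nonparametric bootstrap that resamples patient profiles
#' within each group (the honest uncertainty for the patient-first
#' estimator).
#'
#' @param bundle A [cohort_bundle()].
#' @param min_wear_minutes Low-wear exclusion threshold, minutes
#'   (see [filter_low_wear()]).
#' @param ci `"both"`, `"pooled"` or `"bootstrap"`.
#' @param boot Number of bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Optional seed for the bootstrap resampling.
#' @return An object of class `group_comparison` with components
#'   `curve` (hour, group, mean_bpm, n_segments), `hourly` (hour, laba,
#'   non_laba, difference), `overall` (patient-first overall difference,
#'   bpm), `pooled` (estimate and CI from pooled minutes), `boot` (bootstrap
#'   CI, or NULL), `profiles`, `wear_report`, `n_segments`.
#' @export
group_comparison <- function(bundle, min_wear_minutes = 10080,
                             ci = c("both", "pooled", "bootstrap"),
                             boot = 200L, conf = 0.95, seed = NULL) {
  ci <- match.arg(ci)
  stopifnot(inherits(bundle, "cohort_bundle"))
  flt <- filter_low_wear(bundle, min_wear_minutes)
  pt <- split_laba_person_time(flt$bundle)
  profiles <- hourly_patient_means(pt)
  fit <- .group_fit(profiles)

  hr_known <- pt$hr[pt$hr$laba_status != "unknown", , drop = FALSE]
  pooled <- .pooled_minute_ci(hr_known, conf)
  bootci <- NULL
  if (ci %in% c("both", "bootstrap")) {
    n_by_group <- fit$n_segments
    if (any(n_by_group < 2L)) {
      warning("fewer than 2 patient segments in a group; ",
              "bootstrap CI skipped, pooled CI only")
    } else {
      if (!is.null(seed)) set.seed(as.integer(seed))
      bootci <- .boot_profile_ci(profiles, boot, conf)
    }
  }
  if (ci == "bootstrap") pooled_out <- NULL else pooled_out <- pooled
  structure(list(curve = fit$curve, hourly = fit$hourly,
                 overall = fit$overall,
                 pooled = pooled_out, boot = bootci,
                 profiles = profiles, wear_report = flt$report,
                 n_segments = fit$n_segments, conf = conf,
                 call = match.call()),
            class = "group_comparison")
}

# Patient-first curve and overall difference from hourly profiles.
.group_fit <- function(profiles) {
  if (!nrow(profiles) || length(unique(profiles$laba_status)) < 2L)
    .stopf("need at least one patient profile in each LABA group",
           class = "beta2hr_analysis_error")
  agg <- aggregate(list(mean_bpm = profiles$mean_bpm),
                   by = list(hour = profiles$hour,
                             group = profiles$laba_status), FUN = mean)
  n <- aggregate(list(n_segments = rep(1L, nrow(profiles))),
                 by = list(hour = profiles$hour,
                           group = profiles$laba_status), FUN = sum)
  curve <- merge(agg, n)
  curve <- curve[order(curve$group, curve$hour), c("hour", "group",
                                                   "mean_bpm", "n_segments")]
  rownames(curve) <- NULL
  laba <- curve[curve$group == "laba", ]
  non <- curve[curve$group == "non_laba", ]
  hours <- intersect(laba$hour, non$hour)
  if (!length(hours))
    .stopf("no clock hour is covered by both LABA groups",
           class = "beta2hr_analysis_error")
  hourly <- data.frame(hour = hours,
                       laba = laba$mean_bpm[match(hours, laba$hour)],
                       non_laba = non$mean_bpm[match(hours, non$hour)])
  hourly$difference <- hourly$laba - hourly$non_laba
  segs <- unique(profiles[c("patient_id", "laba_status")])
  n_segments <- c(laba = sum(segs$laba_status == "laba"),
                  non_laba = sum(segs$laba_status == "non_laba"))
  list(curve = curve, hourly = hourly,
       overall = mean(hourly$difference), n_segments = n_segments)
}

.pooled_minute_ci <- function(hr_known, conf) {
  g <- hr_known$laba_status
  v <- hr_known$value
  n1 <- sum(g == "laba"); n0 <- sum(g == "non_laba")
  if (n1 == 0L || n0 == 0L) return(NULL)
  m1 <- mean(v[g == "laba"]); m0 <- mean(v[g == "non_laba"])
  s1 <- stats::var(v[g == "laba"]); s0 <- stats::var(v[g == "non_laba"])
  se <- sqrt(s1 / n1 + s0 / n0)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(estimate = m1 - m0, lower = m1 - m0 - z * se, upper = m1 - m0 + z * se,
    n_laba = n1, n_non_laba = n0)
}

.boot_profile_ci <- function(profiles, boot, conf) {
  wide <- function(status) {
    sub <- profiles[profiles$laba_status == status, , drop = FALSE]
    ids <- unique(sub$patient_id)
    m <- matrix(NA_real_, length(ids), 24L,
                dimnames = list(ids, as.character(0:23)))
    m[cbind(match(sub$patient_id, ids), sub$hour + 1L)] <- sub$mean_bpm
    m
  }
  m1 <- wide("laba"); m0 <- wide("non_laba")
  stat <- function(a, b) {
    c1 <- colMeans(a, na.rm = TRUE); c0 <- colMeans(b, na.rm = TRUE)
    d <- c1 - c0
    mean(d[is.finite(d)])
  }
  reps <- vapply(seq_len(boot), function(i) {
    stat(m1[sample.int(nrow(m1), replace = TRUE), , drop = FALSE],
         m0[sample.int(nrow(m0), replace = TRUE), , drop = FALSE])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  c(lower = qs[1L], upper = qs[2L], n_boot = boot)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Heart rate by LABA status (patient-first hourly comparison)\n")
  cat(sprintf("  patient segments: %d LABA, %d non-LABA\n",
              x$n_segments[["laba"]], x$n_segments[["non_laba"]]))
  cat(sprintf("  overall LABA - non-LABA difference: %.2f bpm\n", x$overall))
  lvl <- round(100 * x$conf)
  if (!is.null(x$pooled))
    cat(sprintf("  pooled-minute estimate %.2f bpm, %d%% CI [%.2f, %.2f]\n",
                x$pooled[["estimate"]], lvl, x$pooled[["lower"]],
                x$pooled[["upper"]]))
  if (!is.null(x$boot))
    cat(sprintf("  patient bootstrap %d%% CI [%.2f, %.2f]\n", lvl,
                x$boot[["lower"]], x$boot[["upper"]]))
  invisible(x)
}

#' @export
summary.group_comparison <- function(object, ...) {
  cat(sprintf("Hourly group means (bpm), difference = laba - non_laba:\n"))
  print(object$hourly, digits = 4)
  removed <- object$wear_report[object$wear_report$removed, , drop = FALSE]
  if (nrow(removed))
    cat(sprintf("Removed %d low-wear patient(s): %s\n", nrow(removed),
                paste(removed$patient_id, collapse = ", ")))
  print(object)
  invisible(object)
}

#' @export
coef.group_comparison <- function(object, ...) {
  c(overall_difference = object$overall,
    stats::setNames(object$hourly$difference,
                    sprintf("hour_%02d", object$hourly$hour)))
}

#' @export
confint.group_comparison <- function(object, parm = "overall_difference",
                                     level = NULL, ...) {
  out <- NULL
  if (!is.null(object$pooled))
    out <- rbind(out, pooled = object$pooled[c("lower", "upper")])
  if (!is.null(object$boot))
    out <- rbind(out, bootstrap = object$boot[c("lower", "upper")])
  out
}

#' @export
plot.group_comparison <- function(x, ...) {
  laba <- x$curve[x$curve$group == "laba", ]
  non <- x$curve[x$curve$group == "non_laba", ]
  rng <- range(c(laba$mean_bpm, non$mean_bpm))
  graphics::plot(laba$hour, laba$mean_bpm, type = "b", pch = 16,
                 ylim = rng + c(-1, 1), xlab = "hour of day",
                 ylab = "mean heart rate (bpm)", col = "firebrick", ...)
  graphics::lines(non$hour, non$mean_bpm, type = "b", pch = 1,
                  col = "steelblue")
  graphics::legend("topleft", bty = "n", col = c("firebrick", "steelblue"),
                   pch = c(16, 1), legend = c("LABA", "non-LABA"))
  invisible(x)
}
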