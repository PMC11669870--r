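#' Parametric drug-effect kernel for inhaled beta-2 agonists
#'
#' Constructs the per-minute heart-rate response curve added around an inhaler
#' actuation in the synthetic cohort. The kernel is anchored at observable
#' landmarks of the event-study difference curve rather than at
#' pharmacokinetic constants: it is zero before `-onset_lead`, rises linearly
#' through the actuation minute (`value_at_t0`) to its maximum
#' (`peak_amp` at `peak_lag` minutes after actuation), and then decays
#' exponentially with the rate solved so that the curve equals `threshold`
#' exactly at `return_min` minutes after actuation.
#'
#' @param onset_lead Minutes before the actuation at which the effect/arousal
#'   ramp starts (the curve is exactly zero earlier). Must be positive.
#' @param peak_lag Minutes after actuation of the maximum effect.
#' @param peak_amp Maximum added heart rate, bpm.
#' @param value_at_t0 Added heart rate at the actuation minute, bpm; must be
#'   in `(0, peak_amp]`.
#' @param return_min Minutes after actuation at which the decaying limb equals
#'   `threshold` exactly; must exceed `peak_lag`.
#' @param threshold Clinical-relevance threshold in bpm (default 5), the level
#'   the decay is anchored to. Must be smaller than `peak_amp`.
#'
#' @return An object of class `drug_kernel`: a list with the parameters plus
#'   `decay_rate` (per minute) and the evaluation support `[t_min, t_max]`
#'   outside which the kernel is treated as zero (the decay is truncated once
#'   it falls below 0.01 bpm).
#'
#' @examples
#' k <- drug_kernel(onset_lead = 17, peak_lag = 9, peak_amp = 10,
#'                  value_at_t0 = 9, return_min = 138)
#' kernel_values(k, c(-30, -17, 0, 9, 138))
#' @seealso [saba_profile_kernel()] for the reference SABA profile,
#'   [kernel_values()] to evaluate the curve.
#' @export
drug_kernel <- function(onset_lead, peak_lag, peak_amp, value_at_t0,
                        return_min, threshold = 5) {
  for (nm in c("onset_lead", "peak_lag", "peak_amp", "value_at_t0",
               "return_min", "threshold")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      .stopf("kernel parameter '%s' must be a finite number", nm,
             class = "beta2hr_parameter_error")
  }
  if (onset_lead <= 0 || peak_lag <= 0)
    .stopf("onset_lead and peak_lag must be positive (-onset_lead < 0 < peak_lag)",
           class = "beta2hr_parameter_error")
  if (return_min <= peak_lag)
    .stopf("return_min (%g) must exceed peak_lag (%g)", return_min, peak_lag,
           class = "beta2hr_parameter_error")
  if (value_at_t0 <= 0 || value_at_t0 > peak_amp)
    .stopf("value_at_t0 must satisfy 0 < value_at_t0 <= peak_amp",
           class = "beta2hr_parameter_error")
  if (threshold <= 0 || threshold >= peak_amp)
    .stopf("threshold must satisfy 0 < threshold < peak_amp",
           class = "beta2hr_parameter_error")
  lambda <- log(peak_amp / threshold) / (return_min - peak_lag)
  t_max <- peak_lag + log(peak_amp / 0.01) / lambda
  structure(
    list(onset_lead = onset_lead, peak_lag = peak_lag, peak_amp = peak_amp,
         value_at_t0 = value_at_t0, return_min = return_min,
         threshold = threshold, decay_rate = lambda,
         t_min = -onset_lead, t_max = t_max),
    class = "drug_kernel")
}

#' Evaluate a drug-effect kernel on a relative-minute grid
#'
#' @param kernel A [drug_kernel()] object.
#' @param t Numeric vector of minutes relative to the actuation (minute 0 is
#'   the actuation minute itself).
#' @return Numeric vector of added heart rate in bpm, zero outside the
#'   kernel's support.
#' @export
kernel_values <- function(kernel, t) {
  stopifnot(inherits(kernel, "drug_kernel"))
  out <- numeric(length(t))
  rise_pre <- t >= -kernel$onset_lead & t <= 0
  out[rise_pre] <- kernel$value_at_t0 *
    (t[rise_pre] + kernel$onset_lead) / kernel$onset_lead
  rise_post <- t > 0 & t <= kernel$peak_lag
  out[rise_post] <- kernel$value_at_t0 +
    (kernel$peak_amp - kernel$value_at_t0) * t[rise_post] / kernel$peak_lag
  decay <- t > kernel$peak_lag & t <= kernel$t_max
  out[decay] <- kernel$peak_amp *
    exp(-kernel$decay_rate * (t[decay] - kernel$peak_lag))
  out
}

#' Reference SABA heart-rate effect kernel
#'
#' Builds the kernel whose observable landmarks match the reported
#' population-level SABA response: the difference curve first reaches the
#' clinical-relevance threshold `first_exceed_pre` minutes before inhalation,
#' equals `value_at_t0` bpm at the actuation minute, peaks at `peak_amp` bpm
#' `peak_lag` minutes after inhalation, and decays back to `threshold` bpm at
#' `return_min` minutes.
#'
#' Because the rising limb is linear through `(0, value_at_t0)`, the ramp must
#' start earlier than the threshold crossing: the onset is solved as
#' `onset_lead = first_exceed_pre * value_at_t0 / (value_at_t0 - threshold)`
#' so the pre-inhalation 5-bpm crossing lands exactly at
#' `-first_exceed_pre` minutes. Requires `value_at_t0 > threshold`.
#'
#' @param first_exceed_pre Minutes before inhalation of the first threshold
#'   exceedance (default 17).
#' @param value_at_t0,peak_lag,peak_amp,return_min,threshold As in
#'   [drug_kernel()]; defaults are the reference SABA profile
#'   (9 bpm at t0, 10 bpm peak at 9 min, back to 5 bpm at 138 min).
#' @return A `drug_kernel` object.
#' @export
saba_profile_kernel <- function(first_exceed_pre = 17, value_at_t0 = 9,
                                peak_lag = 9, peak_amp = 10,
                                return_min = 138, threshold = 5) {
  if (value_at_t0 <= threshold)
    .stopf("value_at_t0 must exceed threshold to place the pre-inhalation crossing",
           class = "beta2hr_parameter_error")
  onset <- first_exceed_pre * value_at_t0 / (value_at_t0 - threshold)
  drug_kernel(onset_lead = onset, peak_lag = peak_lag, peak_amp = peak_amp,
              value_at_t0 = value_at_t0, return_min = return_min,
              threshold = threshold)
}

#' @export
print.drug_kernel <- function(x, ...) {
  cat("Drug-effect kernel (bpm added to heart rate)\n")
  cat(sprintf("  onset: %.2f min before actuation\n", x$onset_lead))
  cat(sprintf("  value at t0: %.2f bpm\n", x$value_at_t0))
  cat(sprintf("  peak: %.2f bpm at +%.0f min\n", x$peak_amp, x$peak_lag))
  cat(sprintf("  decay rate: %.6f per min (reaches %.1f bpm at +%.0f min)\n",
              x$decay_rate, x$threshold, x$return_min))
  invisible(x)
}

#' @export
plot.drug_kernel <- function(x, t = seq(floor(x$t_min) - 10, 600), ...) {
  graphics::plot(t, kernel_values(x, t), type = "l", xlab = "minutes from actuation",
                 ylab = "added heart rate (bpm)", ...)
  graphics::abline(h = x$threshold, lty = 3)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Night-wear retention probability for a target nighttime data share
#'
#' Solves for the per-minute probability `p` that a nighttime minute
#' (00:00-06:00, 360 minutes) is recorded, given the daytime per-minute
#' retention `day_retention`, such that the expected share of recorded minutes
#' falling at night equals `target_fraction`:
#' `(360 p) / (360 p + 1080 day_retention) = target_fraction`, i.e.
#' `p = 3 * day_retention * f / (1 - f)`.
#'
#' @param target_fraction Desired share of recorded minutes between 12 AM and
#'   6 AM, in `(0, 1)`; must be achievable with `p <= 1`.
#' @param day_retention Per-minute retention probability outside 00:00-06:00
#'   (default 1).
#' @return The nighttime retention probability.
#' @examples
#' night_retention_for_fraction(0.25, 1)    # uniform wear: p = 1
#' night_retention_for_fraction(0.187, 1)   # ~0.690
#' @export
night_retention_for_fraction <- function(target_fraction, day_retention = 1) {
  if (!is.numeric(target_fraction) || length(target_fraction) != 1L ||
      !is.finite(target_fraction) || target_fraction <= 0 ||
      target_fraction >= 1)
    .stopf("target_fraction must be in (0, 1)",
           class = "beta2hr_parameter_error")
  if (!.is_prob(day_retention) || day_retention <= 0)
    .stopf("day_retention must be in (0, 1]",
           class = "beta2hr_parameter_error")
  p <- 3 * day_retention * target_fraction / (1 - target_fraction)
  if (p > 1)
    .stopf(paste("target_fraction %.3f is infeasible with day_retention %.3f",
                 "(required night retention %.3f > 1)"),
           target_fraction, day_retention, p,
           class = "beta2hr_parameter_error")
  p
}
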