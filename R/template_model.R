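#' Unit-peak double-exponential EPSP template
#'
#' The waveform `(exp(-t/tau_slow) - exp(-t/tau_fast)) / normfac`, with
#' `normfac = (tau_slow/tau_fast)^(tau_fast/(tau_fast - tau_slow))`, taken
#' with the standard sign convention so the EPSP is positive, and then
#' renormalized numerically so the sampled peak is exactly 1.
#'
#' @param tau_fast rise time constant, ms.
#' @param tau_slow decay time constant, ms (15 for the baseline EPSP, 23
#'   for the neuromodulated EPSP).
#' @param dt sample interval, ms (<= 0.1).
#' @param duration template length, ms (default `10 * tau_slow`).
#' @return A [trace_record()] with unit peak.
#' @export
epsp_template <- function(tau_fast = 2, tau_slow = 15, dt = 0.1,
                          duration = 10 * tau_slow) {
  stopifnot(tau_fast > 0, tau_fast < tau_slow, dt > 0, dt <= 0.1)
  t <- seq(0, duration, by = dt)
  normfac <- (tau_slow / tau_fast)^(tau_fast / (tau_fast - tau_slow))
  y <- (exp(-t / tau_slow) - exp(-t / tau_fast)) / normfac
  y <- y / max(y)  # exact unit peak on the sampled grid
  trace_record(y, dt, kind = "voltage", site = "template")
}

#' Convolve a template with an impulse train
#'
#' Convolution of the template with `n_events` unit impulses spaced `isi`
#' apart -- equivalently, the sum of shifted copies.  Purely linear: no
#' driving-force saturation.
#'
#' @param template a [trace_record()] (e.g. from [epsp_template()]).
#' @param isi inter-stimulus interval, ms (>= 0; rounded to the sample
#'   grid).
#' @param n_events number of impulses.
#' @return A [trace_record()] with the compound waveform.
#' @export
convolve_train <- function(template, isi, n_events = 5) {
  stopifnot(inherits(template, "trace_record"), isi >= 0, n_events >= 1)
  shift <- round(isi / template$dt)
  n <- length(template$samples) + shift * (n_events - 1)
  y <- numeric(n)
  for (k in seq_len(n_events)) {
    i0 <- (k - 1) * shift
    idx <- seq_along(template$samples) + i0
    y[idx] <- y[idx] + template$samples
  }
  trace_record(y, template$dt, template$t0, "voltage", "compound")
}

#' Summation-ratio curve of the convolution model
#'
#' For each ISI, convolves a slow-decay and a fast-decay unit-peak
#' template with a five-impulse train and reports the ratio of compound
#' maxima (slow over fast) -- the model's frequency-tuning curve for the
#' last-EPSP amplitude.
#'
#' @param isis ISI grid, ms (default integer 0..50).
#' @param tau_fast shared rise tau, ms.
#' @param tau_slow_baseline,tau_slow_modulated decay taus, ms.
#' @param n_events impulses per train.
#' @param dt sample interval, ms.
#' @return data.frame `isi`, `amp_baseline`, `amp_modulated`, `ratio`,
#'   with attribute `argmax_isi` (ISI of the maximal ratio).
#' @export
summation_ratio_curve <- function(isis = 0:50, tau_fast = 2,
                                  tau_slow_baseline = 15,
                                  tau_slow_modulated = 23,
                                  n_events = 5, dt = 0.1) {
  dur <- max(isis) * (n_events - 1) + 10 * tau_slow_modulated
  tb <- epsp_template(tau_fast, tau_slow_baseline, dt, dur)
  tm <- epsp_template(tau_fast, tau_slow_modulated, dt, dur)
  rows <- lapply(isis, function(isi) {
    ab <- max(convolve_train(tb, isi, n_events)$samples)
    am <- max(convolve_train(tm, isi, n_events)$samples)
    data.frame(isi = isi, amp_baseline = ab, amp_modulated = am,
               ratio = am / ab)
  })
  out <- do.call(rbind, rows)
  attr(out, "argmax_isi") <- out$isi[which.max(out$ratio)]
  out
}
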