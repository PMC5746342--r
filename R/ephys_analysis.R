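#' Ordered event times (spikes or IPSC events)
#'
#' @param times event times, ms (strictly increasing).
#' @param amplitudes optional per-event amplitudes.
#' @param threshold,method detection metadata.
#' @return An `event_series` object.
#' @export
event_series <- function(times, amplitudes = NULL, threshold = NA,
                         method = "constructed") {
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("event times must be strictly increasing")
  structure(list(times = as.numeric(times), amplitudes = amplitudes,
                 threshold = threshold, method = method),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("event_series: %d events (%s)\n", length(x$times), x$method))
  invisible(x)
}

#' Frequency-band definitions for inter-event-interval analysis
#'
#' Default bands: theta 4-8, alpha 8-12, beta 13-29, low gamma 39-59, high
#' gamma 61-100 Hz.  Gaps between bands (12-13, 29-39, 59-61 Hz) are
#' honoured literally; intervals falling in a gap are reported as
#' unassigned.  At a shared edge (8 Hz) the lower band wins.
#'
#' @param bands named list of `c(low, high)` Hz pairs.
#' @return A `band_definition` object.
#' @export
band_definition <- function(bands = list(theta = c(4, 8),
                                         alpha = c(8, 12),
                                         beta = c(13, 29),
                                         low_gamma = c(39, 59),
                                         high_gamma = c(61, 100))) {
  for (b in bands) stopifnot(length(b) == 2, b[1] < b[2])
  structure(bands[order(vapply(bands, `[`, 0, 1))],
            class = "band_definition")
}

#' Fit a single-exponential decay tau to an EPSP
#'
#' Least-squares fit of `A * exp(-(t - t_peak)/tau)` to the baseline-
#' subtracted decay, from the sample after the peak to the point of 95%
#' decay (or trace end).  Invariant to amplitude scaling and baseline
#' offset.
#'
#' @param trace a [trace_record()] containing one EPSP-like transient.
#' @param peak_window `c(t0, t1)` ms restricting the peak search (default:
#'   whole trace).
#' @param baseline baseline voltage; default: mean of samples before the
#'   peak window (or the first 10% of the trace).
#' @param decay_fraction fit end point as a fraction of decay (default
#'   0.95).
#' @return list: `tau` (ms), `amplitude`, `r_squared`, `n_points`.
#' @export
fit_decay_tau <- function(trace, peak_window = NULL, baseline = NULL,
                          decay_fraction = 0.95) {
  stopifnot(inherits(trace, "trace_record"))
  t <- trace_times(trace); y <- trace$samples
  if (is.null(peak_window)) peak_window <- range(t)
  win <- t >= peak_window[1] & t <= peak_window[2]
  if (is.null(baseline)) {
    pre <- t < peak_window[1]
    baseline <- if (any(pre)) mean(y[pre])
                else mean(y[seq_len(max(2, floor(length(y) / 10)))])
  }
  ipk <- which(win)[which.max(y[win])]
  amp <- y[ipk] - baseline
  if (amp <= 0) stop("no positive transient found in the peak window")
  after <- seq(ipk + 1L, length(y))
  dec <- y[after] - baseline
  stop_i <- which(dec <= (1 - decay_fraction) * amp)
  keep <- if (length(stop_i) > 0) after[seq_len(stop_i[1])] else after
  keep <- keep[y[keep] - baseline > 0]
  if (length(keep) < 4) stop("decay segment too short to fit")
  td <- t[keep] - t[ipk]
  yd <- y[keep] - baseline
  # log-linear start, then nonlinear least squares on the linear scale
  ll <- lm(log(yd) ~ td)
  tau0 <- unname(-1 / coef(ll)[2])
  if (!is.finite(tau0) || tau0 <= 0) stop("decay segment is not decaying")
  fit <- tryCatch(
    minpack.lm::nlsLM(yd ~ A * exp(-td / tau),
                      start = list(A = unname(amp), tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) {
    tau <- tau0; pred <- exp(predict(ll)); A <- exp(coef(ll)[1])
  } else {
    tau <- coef(fit)[["tau"]]; pred <- predict(fit); A <- coef(fit)[["A"]]
  }
  if (tau <= 0) stop("fitted tau is not positive (non-decaying segment)")
  r2 <- 1 - sum((yd - pred)^2) / sum((yd - mean(yd))^2)
  list(tau = unname(tau), amplitude = unname(A), r_squared = r2,
       n_points = length(keep))
}

#' Input resistance from a current step
#'
#' Ohm's law on a step response: `(V_steady - V_baseline) / I`, with the
#' steady level taken from the final 20% of the step window.
#'
#' @param trace voltage [trace_record()].
#' @param step_amp step current, nA (non-zero).
#' @param step_window `c(onset, offset)` ms of the step.
#' @return list: `rin` (MOhm), `v_baseline`, `v_steady`, `short_step`
#'   (TRUE when the step is shorter than 5 fitted membrane taus).
#' @export
input_resistance_from_step <- function(trace, step_amp,
                                       step_window) {
  stopifnot(step_amp != 0, length(step_window) == 2)
  t <- trace_times(trace); y <- trace$samples
  vb <- mean(y[t < step_window[1]])
  dur <- diff(step_window)
  steady <- t >= step_window[2] - 0.2 * dur & t <= step_window[2]
  vs <- mean(y[steady])
  # crude settling check: fit tau to the onset transient
  short_step <- FALSE
  on <- t >= step_window[1] & t <= step_window[2]
  yt <- y[on] - vs
  if (sign(step_amp) != 0 && abs(yt[1]) > 1e-9) {
    rel <- yt / yt[1]
    i63 <- which(rel < exp(-1))[1]
    if (!is.na(i63)) {
      taum <- (t[on][i63] - step_window[1])
      short_step <- dur < 5 * taum
    }
  }
  list(rin = (vs - vb) / step_amp, v_baseline = vb, v_steady = vs,
       short_step = short_step)
}

#' Pointwise difference of two I-V curves
#'
#' Subtracts `base` from `post` on `base`'s voltage grid (the post curve
#' is linearly interpolated when the grids differ), isolating the current
#' removed or added by a manipulation.
#'
#' @param base,post [iv_curve()] objects.
#' @return An [iv_curve()] of `post - base`.
#' @export
iv_difference <- function(base, post) {
  stopifnot(inherits(base, "iv_curve"), inherits(post, "iv_curve"))
  if (max(post$v) < min(base$v) || min(post$v) > max(base$v))
    stop("I-V curves have non-overlapping voltage ranges")
  ip <- if (isTRUE(all.equal(base$v, post$v))) post$i
        else approx(post$v, post$i, xout = base$v, rule = 1)$y
  keep <- !is.na(ip)
  if (sum(keep) < 2) stop("I-V curves have insufficient grid overlap")
  iv_curve(base$v[keep], ip[keep] - base$i[keep],
           condition = "difference",
           duration_ms = attr(base, "duration_ms"))
}

#' Reversal potential of an I-V curve
#'
#' Linear interpolation between the two samples bracketing the single
#' interior zero crossing.
#'
#' @param curve an [iv_curve()].
#' @return Reversal potential, mV.
#' @export
estimate_reversal <- function(curve) {
  v <- curve$v; i <- curve$i
  s <- sign(i)
  cross <- which(s[-1] * s[-length(s)] < 0)
  exact <- which(i == 0 & seq_along(i) > 1 & seq_along(i) < length(i))
  cross <- sort(unique(c(cross, exact - 1L)))
  if (length(cross) == 0) stop("I-V curve has no interior zero crossing")
  if (length(cross) > 1)
    stop("I-V curve crosses zero more than once (near ",
         paste(round(v[cross], 1), collapse = ", "), " mV)")
  k <- cross[1]
  v[k] + (0 - i[k]) * (v[k + 1] - v[k]) / (i[k + 1] - i[k])
}

#' Slope-conductance change between two I-V curves
#'
#' Ordinary least-squares line slope of each curve over a voltage range;
#' the difference (post minus base) is the conductance change, in uS
#' (nA/mV).
#'
#' @param base,post [iv_curve()] objects.
#' @param fit_range `c(v_lo, v_hi)` mV.
#' @return list: `slope_base`, `slope_post`, `delta_g` (uS).
#' @export
slope_conductance_change <- function(base, post, fit_range) {
  sl <- function(cv) {
    sel <- cv$v >= fit_range[1] & cv$v <= fit_range[2]
    if (sum(sel) < 5) stop("fewer than 5 I-V points in the fit range")
    unname(coef(lm(cv$i[sel] ~ cv$v[sel]))[2])
  }
  b <- sl(base); p <- sl(post)
  list(slope_base = b, slope_post = p, delta_g = p - b)
}

#' Charge transfer of a current trace or ramp difference current
#'
#' Trapezoidal integral of current over time, sign preserved; an
#' [iv_curve()] is integrated over the ramp duration it represents.
#'
#' @param x a current [trace_record()] or an [iv_curve()] with a
#'   `duration_ms` attribute.
#' @return Charge, nC.
#' @export
charge_transfer <- function(x) {
  if (inherits(x, "iv_curve")) {
    dur <- attr(x, "duration_ms")
    if (is.na(dur)) stop("iv_curve has no ramp duration attached")
    tsec <- (x$v - x$v[1]) / (x$v[length(x$v)] - x$v[1]) * dur / 1000
    y <- x$i
  } else {
    stopifnot(inherits(x, "trace_record"))
    tsec <- trace_times(x) / 1000
    y <- x$samples
  }
  sum(diff(tsec) * (y[-1] + y[-length(y)]) / 2)
}

#' Compound-EPSP summation metrics
#'
#' Last-EPSP amplitude: compound-trace maximum within `[last onset,
#' last onset + 30 ms]` minus the pre-train baseline.  Integral: area of
#' `(V - baseline)` over `[first onset, last onset + 200 ms]` (mV ms).
#'
#' @param compound voltage [trace_record()] of the train response.
#' @param onsets stimulus onset times, ms.
#' @param baseline_window ms of pre-train trace averaged for the baseline.
#' @return list: `last_amplitude` (mV), `integral` (mV ms), `baseline`,
#'   `baseline_contaminated` flag.
#' @export
summation_metrics <- function(compound, onsets, baseline_window = 20) {
  stopifnot(inherits(compound, "trace_record"), length(onsets) >= 1)
  t <- trace_times(compound); y <- compound$samples
  on1 <- min(onsets); onN <- max(onsets)
  pre <- t >= on1 - baseline_window & t < on1
  contaminated <- !any(pre)
  v0 <- if (contaminated) y[1] else mean(y[pre])
  if (!contaminated && (max(y[pre]) - min(y[pre])) > 0.5)
    contaminated <- TRUE  # pre-train window not quiescent
  amp_win <- t >= onN & t <= onN + 30
  last_amplitude <- max(y[amp_win]) - v0
  int_win <- t >= on1 & t <= onN + 200
  ti <- t[int_win]; yi <- y[int_win] - v0
  integral <- sum(diff(ti) * (yi[-1] + yi[-length(yi)]) / 2)
  list(last_amplitude = last_amplitude, integral = integral,
       baseline = v0, baseline_contaminated = contaminated)
}

#' Detect spikes by threshold crossing
#'
#' Upward threshold crossings, merged within a refractory window; each
#' event is timed at the local maximum of its suprathreshold excursion.
#'
#' @param trace voltage [trace_record()].
#' @param threshold detection threshold, mV (default -10).
#' @param refractory merge window, ms.
#' @return An [event_series()] with peak times and amplitudes.
#' @export
detect_spikes <- function(trace, threshold = -10, refractory = 1) {
  t <- trace_times(trace); y <- trace$samples
  above <- y >= threshold
  ups <- which(!above[-length(above)] & above[-1]) + 1L
  times <- numeric(0); amps <- numeric(0)
  last_t <- -Inf
  for (u in ups) {
    if (t[u] - last_t < refractory) next
    j <- u
    while (j < length(y) && above[j + 1L]) j <- j + 1L
    pk <- u - 1L + which.max(y[u:j])
    times <- c(times, t[pk]); amps <- c(amps, y[pk])
    last_t <- t[u]
  }
  event_series(times, amps, threshold = threshold, method = "threshold")
}

#' Peristimulus firing-rate histogram
#'
#' @param events an [event_series()].
#' @param bin bin width, ms.
#' @param window `c(t0, t1)` ms analysis window.
#' @return data.frame: `t` (bin left edge, ms), `count`, `rate_hz`.
#' @export
firing_rate_psth <- function(events, bin, window) {
  stopifnot(bin > 0, length(window) == 2)
  edges <- seq(window[1], window[2], by = bin)
  if (edges[length(edges)] < window[2]) edges <- c(edges, window[2])
  counts <- if (length(events$times)) {
    tabulate(findInterval(events$times, edges, rightmost.closed = TRUE,
                          left.open = FALSE),
             nbins = length(edges) - 1)
  } else rep(0L, length(edges) - 1)
  data.frame(t = edges[-length(edges)], count = counts,
             rate_hz = counts / diff(edges) * 1000)
}

#' Fraction of spikes following stimuli of each inter-stimulus interval
#'
#' Each spike is assigned to the nearest preceding stimulus when it falls
#' within the response window; percentages are over assigned spikes and
#' sum to 100.
#'
#' @param events spike [event_series()].
#' @param stim_times stimulus times, ms.
#' @param stim_isi ISI label of each stimulus (same length).
#' @param window response window after each stimulus, ms (default 10).
#' @return list: `percent` (named per ISI label), `n_assigned`,
#'   `n_unassigned`, `empty` flag, `overlap_flagged` (TRUE when response
#'   windows overlap, resolved to the nearest preceding stimulus).
#' @export
spike_fraction_by_isi <- function(events, stim_times, stim_isi,
                                  window = 10) {
  stopifnot(length(stim_times) == length(stim_isi))
  labels <- sort(unique(stim_isi))
  counts <- setNames(numeric(length(labels)), as.character(labels))
  overlap <- any(diff(sort(stim_times)) < window)
  n_un <- 0L
  for (ts in events$times) {
    prev <- which(stim_times <= ts)
    if (length(prev) == 0) { n_un <- n_un + 1L; next }
    k <- prev[which.max(stim_times[prev])]
    if (ts - stim_times[k] <= window)
      counts[as.character(stim_isi[k])] <-
        counts[as.character(stim_isi[k])] + 1
    else n_un <- n_un + 1L
  }
  tot <- sum(counts)
  list(percent = if (tot > 0) 100 * counts / tot else counts,
       n_assigned = tot, n_unassigned = n_un, empty = tot == 0,
       overlap_flagged = overlap)
}

#' Remove spikes from a voltage trace
#'
#' Detects spikes, excises a window around each peak, linearly
#' interpolates across the gaps, and median-filters the result -- the
#' standard way to recover the subthreshold envelope (e.g. a slow
#' neuromodulator depolarization) from a spiking recording.
#'
#' @param trace voltage [trace_record()].
#' @param threshold spike threshold, mV.
#' @param excise half-width removed around each spike peak, ms.
#' @param filter_width median filter width, ms.
#' @return list: `trace` (filtered [trace_record()]), `mean_vm`,
#'   `n_spikes`.
#' @export
subthreshold_from_spiking <- function(trace, threshold = -10, excise = 2,
                                      filter_width = 5) {
  t <- trace_times(trace); y <- trace$samples
  ev <- detect_spikes(trace, threshold = threshold)
  drop <- rep(FALSE, length(y))
  for (tp in ev$times)
    drop <- drop | (t >= tp - excise & t <= tp + excise)
  if (mean(drop) > 0.5)
    stop("more than 50% of the trace would be removed as spikes")
  yc <- y
  if (any(drop)) {
    yc[drop] <- NA
    yc <- approx(t[!drop], y[!drop], xout = t, rule = 2)$y
  }
  k <- max(3L, 2L * floor(filter_width / trace$dt / 2) + 1L)
  if (k < length(yc)) yc <- as.numeric(stats::runmed(yc, k))
  out <- trace_record(yc, trace$dt, trace$t0, "voltage", trace$site)
  list(trace = out, mean_vm = mean(yc), n_spikes = length(ev$times))
}

#' Inter-event-interval frequency-band probabilities
#'
#' Successive inter-event intervals are mapped to frequencies
#' (`1000 / IEI` Hz) and assigned to the first band (in order of
#' increasing lower edge) whose range contains the frequency; band gaps
#' leave intervals unassigned.  Assigned and unassigned probabilities sum
#' to 1 exactly.
#'
#' @param events an [event_series()] (>= 2 events).
#' @param bands a [band_definition()].
#' @return list: `probability` (named per band), `unassigned`,
#'   `ieis` (ms), `frequencies` (Hz), `n`.
#' @export
iei_band_probabilities <- function(events, bands = band_definition()) {
  if (length(events$times) < 2)
    stop("need at least 2 events to form inter-event intervals")
  ieis <- diff(events$times)
  freq <- 1000 / ieis
  p <- setNames(numeric(length(bands)), names(bands))
  un <- 0L
  for (fq in freq) {
    hit <- FALSE
    for (b in names(bands)) {
      if (fq >= bands[[b]][1] && fq <= bands[[b]][2]) {
        p[b] <- p[b] + 1; hit <- TRUE; break
      }
    }
    if (!hit) un <- un + 1L
  }
  n <- length(freq)
  list(probability = p / n, unassigned = un / n, ieis = ieis,
       frequencies = freq, n = n)
}

#' Exponential space-constant fit
#'
#' Least-squares fit of `A * exp(-d / lambda)` to response-versus-distance
#' data (e.g. the firing-rate change against neuromodulator application
#' distance).
#'
#' @param distances um.
#' @param responses same length, positive trend expected.
#' @param min_points minimum points (default 3).
#' @return list: `lambda` (um; `Inf` with `flag = "non_decaying"` when the
#'   data do not decay), `A`, `r_squared`, `flag`.
#' @export
fit_space_constant <- function(distances, responses, min_points = 3) {
  stopifnot(length(distances) == length(responses))
  if (length(distances) < min_points) stop("need at least 3 points")
  pos <- responses > 0
  if (sum(pos) < min_points) stop("need at least 3 positive responses")
  d <- distances[pos]; r <- responses[pos]
  sl <- coef(lm(log(r) ~ d))[2]
  if (!is.finite(sl) || sl >= 0)
    return(list(lambda = Inf, A = mean(r), r_squared = NA_real_,
                flag = "non_decaying"))
  lam0 <- unname(-1 / sl)
  fit <- minpack.lm::nlsLM(r ~ A * exp(-d / lambda),
                           start = list(A = unname(max(r)), lambda = lam0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  pr <- predict(fit)
  r2 <- 1 - sum((r - pr)^2) / sum((r - mean(r))^2)
  list(lambda = coef(fit)[["lambda"]], A = coef(fit)[["A"]],
       r_squared = r2, flag = "ok")
}

#' Nernst equilibrium potential
#'
#' `(R T / z F) * ln(c_out / c_in)`, in mV.  The default temperature is
#' 306.15 K (33 C, the midpoint of the 32-34 C recording range).
#'
#' @param c_out,c_in ion concentrations (same units, > 0).
#' @param temperature absolute temperature, K.
#' @param z ionic valence.
#' @return Equilibrium potential, mV.
#' @export
nernst_potential <- function(c_out, c_in, temperature = 306.15, z = 1) {
  stopifnot(c_out > 0, c_in > 0, temperature > 0, z != 0)
  R <- 8.31446; FARADAY <- 96485.33
  1000 * R * temperature / (z * FARADAY) * log(c_out / c_in)
}
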