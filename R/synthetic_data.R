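#' Synthetic current-clamp trace with known EPSPs
#'
#' Baseline voltage plus double-exponential EPSPs of known amplitude and
#' taus, optional stereotyped spikes, and optional additive Gaussian
#' noise.  The exact generating parameters are returned as ground truth,
#' so every analysis routine can be validated by round-trip recovery.
#'
#' @param onsets EPSP onset times, ms.
#' @param amplitude EPSP peak amplitude, mV.
#' @param tau_rise,tau_decay EPSP time constants, ms (defaults 1 and 10.4,
#'   the baseline single-EPSP decay).
#' @param baseline resting voltage, mV.
#' @param duration,dt trace length and sampling, ms.
#' @param noise_sd additive Gaussian noise SD, mV.
#' @param spike_times optional times of stereotyped spikes, ms.
#' @param spike_peak spike peak voltage, mV.
#' @param spike_width spike half-width at the base, ms (triangular wave).
#' @param seed RNG seed (recorded in the ground truth).
#' @return list: `trace` ([trace_record()]) and `truth` (generating
#'   parameters).
#' @export
gen_current_clamp_trace <- function(onsets = 100, amplitude = 2,
                                    tau_rise = 1, tau_decay = 10.4,
                                    baseline = -71, duration = 300,
                                    dt = 0.1, noise_sd = 0,
                                    spike_times = numeric(0),
                                    spike_peak = 30, spike_width = 2,
                                    seed = 1) {
  stopifnot(tau_rise > 0, tau_rise < tau_decay, noise_sd >= 0)
  set.seed(seed)
  t <- seq(0, duration, by = dt)
  tp <- syn_peak_time(tau_rise, tau_decay)
  norm <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  y <- rep(baseline, length(t))
  for (on in onsets) {
    u <- t - on; a <- u >= 0
    y[a] <- y[a] + amplitude *
      (exp(-u[a] / tau_decay) - exp(-u[a] / tau_rise)) / norm
  }
  for (ts in spike_times) {
    u <- abs(t - ts)
    w <- u <= spike_width / 2
    y[w] <- pmax(y[w], baseline +
                   (spike_peak - baseline) * (1 - u[w] / (spike_width / 2)))
  }
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  list(trace = trace_record(y, dt, kind = "voltage", site = "synthetic"),
       truth = list(onsets = onsets, amplitude = amplitude,
                    tau_rise = tau_rise, tau_decay = tau_decay,
                    baseline = baseline, noise_sd = noise_sd,
                    spike_times = spike_times, seed = seed))
}

#' Synthetic voltage-ramp current pair (baseline and Kir-reduced)
#'
#' `I(V) = g_leak (V - E_leak) + g_kir m(V) (V - E_K)` on a voltage grid,
#' with the reduced condition scaling the Kir conductance by a known
#' factor -- emulating the ramp I-V before and after a neuromodulator that
#' suppresses the inward rectifier.
#'
#' @param v voltage grid, mV.
#' @param g_leak leak conductance, uS.
#' @param e_leak leak reversal, mV.
#' @param g_kir maximal Kir conductance, uS.
#' @param e_k K+ reversal, mV (the difference current reverses here).
#' @param v_half,k_slope Kir Boltzmann parameters.
#' @param kir_reduction fractional Kir reduction in the second curve.
#' @param noise_sd additive current noise SD, nA.
#' @param duration_ms ramp duration represented, ms.
#' @param seed RNG seed.
#' @return list: `baseline`, `reduced` ([iv_curve()]s) and `truth`.
#' @export
gen_vc_ramp_current <- function(v = seq(-150, -50, 0.5), g_leak = 0.004,
                                e_leak = -65, g_kir = 0.01, e_k = -101,
                                v_half = -85, k_slope = 12,
                                kir_reduction = 0.7, noise_sd = 0,
                                duration_ms = 3000, seed = 1) {
  stopifnot(kir_reduction >= 0, kir_reduction <= 1, noise_sd >= 0)
  set.seed(seed)
  m <- 1 / (1 + exp((v - v_half) / k_slope))
  ikir <- g_kir * m * (v - e_k)
  ileak <- g_leak * (v - e_leak)
  nz <- function() if (noise_sd > 0) rnorm(length(v), 0, noise_sd) else 0
  list(baseline = iv_curve(v, ileak + ikir + nz(), "baseline",
                           duration_ms),
       reduced = iv_curve(v, ileak + (1 - kir_reduction) * ikir + nz(),
                          "reduced", duration_ms),
       truth = list(g_leak = g_leak, e_leak = e_leak, g_kir = g_kir,
                    e_k = e_k, v_half = v_half, k_slope = k_slope,
                    kir_reduction = kir_reduction, noise_sd = noise_sd,
                    seed = seed))
}

#' Synthetic IPSC event train with band-structured intervals
#'
#' Inter-event intervals are drawn from a weighted mixture over frequency
#' bands, uniform in frequency within each band; interval randomness is
#' the signal, so no additional noise is applied.
#'
#' @param n_events number of events.
#' @param band_weights named weights over the bands (must sum to 1).
#' @param bands a [band_definition()].
#' @param t0 time of the first event, ms.
#' @param amplitude_mean,amplitude_sd log-normal event amplitudes (pA).
#' @param seed RNG seed.
#' @return list: `events` ([event_series()]) and `truth`.
#' @export
gen_ipsc_events <- function(n_events = 500,
                            band_weights = c(theta = 0.1, alpha = 0.1,
                                             beta = 0.3, low_gamma = 0.25,
                                             high_gamma = 0.25),
                            bands = band_definition(), t0 = 0,
                            amplitude_mean = 30, amplitude_sd = 10,
                            seed = 1) {
  stopifnot(abs(sum(band_weights) - 1) < 1e-9,
            all(names(band_weights) %in% names(bands)))
  set.seed(seed)
  picks <- sample(names(band_weights), n_events - 1, replace = TRUE,
                  prob = band_weights)
  freq <- vapply(picks, function(b)
    runif(1, bands[[b]][1], bands[[b]][2]), 0)
  ieis <- 1000 / freq
  times <- t0 + c(0, cumsum(ieis))
  sdlog <- sqrt(log(1 + (amplitude_sd / amplitude_mean)^2))
  amps <- stats::rlnorm(n_events, log(amplitude_mean) - sdlog^2 / 2, sdlog)
  list(events = event_series(times, amps, method = "synthetic"),
       truth = list(band_weights = band_weights, n_events = n_events,
                    seed = seed))
}

#' Synthetic exponentially decaying distance-response data
#'
#' `A * exp(-d / lambda)` with multiplicative log-normal noise, emulating
#' a response that falls off with distance from a focal application site.
#'
#' @param distances um.
#' @param A response at distance 0.
#' @param lambda space constant, um (default 3.13).
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param seed RNG seed.
#' @return list: `distances`, `responses`, `truth`.
#' @export
gen_distance_response <- function(distances = seq(0, 15, 1), A = 10,
                                  lambda = 3.13, noise_cv = 0, seed = 1) {
  stopifnot(lambda > 0, noise_cv >= 0)
  set.seed(seed)
  r <- A * exp(-distances / lambda)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    r <- r * stats::rlnorm(length(r), -sdlog^2 / 2, sdlog)
  }
  list(distances = distances, responses = r,
       truth = list(A = A, lambda = lambda, noise_cv = noise_cv,
                    seed = seed))
}
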