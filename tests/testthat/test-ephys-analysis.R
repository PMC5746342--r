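test_that("decay-tau fitting recovers generator truth and is affine-invariant", {
  # pure exponential: self-fit to within 0.1 ms
  tr <- trace_record(-70 + 2 * exp(-seq(0, 120, 0.1) / 15), 0.1)
  f <- fit_decay_tau(tr, baseline = -70)
  expect_equal(f$tau, 15, tolerance = 0.1 / 15)
  # synthetic EPSP with the baseline experimental decay
  g <- gen_current_clamp_trace(onsets = 50, tau_decay = 10.4,
                               duration = 200, seed = 3)
  f2 <- fit_decay_tau(g$trace, peak_window = c(50, 80))
  expect_equal(f2$tau, 10.4, tolerance = 0.05 * 10.4)
  # double-exponential rise excluded: tau within 10%
  g3 <- gen_current_clamp_trace(onsets = 50, tau_rise = 2, tau_decay = 15,
                                duration = 250, seed = 3)
  f3 <- fit_decay_tau(g3$trace, peak_window = c(50, 90))
  expect_equal(f3$tau, 15, tolerance = 0.1 * 15)
  # invariance to amplitude scaling and offset
  y <- g$trace$samples
  tr_s <- trace_record((y + 71) * 7 + 12, g$trace$dt)
  f4 <- fit_decay_tau(tr_s, peak_window = c(50, 80))
  expect_equal(f4$tau, f2$tau, tolerance = 1e-6)
  # non-decaying input errors
  expect_error(fit_decay_tau(trace_record(seq(0, 1, 0.01), 0.1),
                             baseline = 0), "decay")
})

test_that("step-based input resistance recovers the generating resistance", {
  # ideal RC response with R = 92.9 MOhm, tau 10 ms, -50 pA step at 100 ms
  t <- seq(0, 600, 0.1)
  v <- -71 + ifelse(t < 100, 0, -0.05 * 92.9 * (1 - exp(-(t - 100) / 10)))
  r <- input_resistance_from_step(trace_record(v, 0.1), -0.05, c(100, 600))
  expect_equal(r$rin, 92.9, tolerance = 0.01 * 92.9)
  expect_false(r$short_step)
  # the printed deflection: -4.645 mV at -50 pA is 92.9 MOhm
  v2 <- c(rep(-71, 100), rep(-71 - 4.645, 400))
  r2 <- input_resistance_from_step(trace_record(v2, 1), -0.05, c(100, 500))
  expect_equal(r2$rin, 92.9, tolerance = 1e-9)
  # zero deflection gives zero resistance; short steps are flagged
  v3 <- rep(-71, 500)
  expect_equal(input_resistance_from_step(trace_record(v3, 1), -0.05,
                                          c(100, 500))$rin, 0)
  v4 <- -71 + ifelse(t < 100, 0, -4.645 * (1 - exp(-(t - 100) / 200)))
  expect_true(input_resistance_from_step(trace_record(v4, 0.1), -0.05,
                                         c(100, 600))$short_step)
})

test_that("I-V subtraction isolates a conductance difference that reverses at its E", {
  v <- seq(-150, -50, 1)
  a <- iv_curve(v, 0.010 * (v + 99))
  b <- iv_curve(v, 0.008 * (v + 99))
  d <- iv_difference(a, b)
  expect_equal(d$i, -0.002 * (v + 99), tolerance = 1e-12)
  expect_equal(estimate_reversal(d), -99, tolerance = 1e-9)
  # identical curves cancel identically; grids interpolate linearly
  expect_true(all(iv_difference(a, a)$i == 0))
  b2 <- iv_curve(seq(-150, -50, 0.7), 0.008 * (seq(-150, -50, 0.7) + 99))
  d2 <- iv_difference(a, b2)
  expect_equal(d2$i, (0.008 - 0.010) * (d2$v + 99), tolerance = 1e-9)
  # reversal estimation refuses curves without a single interior crossing
  expect_error(estimate_reversal(iv_curve(v, abs(v + 90) + 1)), "no interior")
  expect_error(estimate_reversal(iv_curve(v, sin(v / 5))), "more than once")
})

test_that("slope-conductance change is the OLS slope difference, offset-invariant", {
  v <- seq(-120, -60, 1)
  base <- iv_curve(v, 0.010 * v + 0.3)
  post <- iv_curve(v, 0.008 * v - 0.2)
  s <- slope_conductance_change(base, post, c(-110, -70))
  expect_equal(s$delta_g, -0.002, tolerance = 1e-12)
  expect_error(slope_conductance_change(base, post, c(-61, -60)), "fewer than 5")
  set.seed(9)
  noisy <- iv_curve(v, 0.010 * v + rnorm(length(v), 0, 0.01))
  sn <- slope_conductance_change(base, noisy, c(-120, -60))
  se <- 0.01 / sqrt(sum((v - mean(v))^2))
  expect_lt(abs(sn$slope_post - 0.010), 2 * se)
})

test_that("charge transfer integrates current over time", {
  tr <- trace_record(rep(0.1, 10001), 0.1, kind = "current")
  expect_equal(charge_transfer(tr), 0.1 * 1, tolerance = 1e-12)   # 0.1 nC
  expect_equal(charge_transfer(trace_record(rep(0, 100), 1,
                                            kind = "current")), 0)
  t <- seq(0, 1000, 0.1)
  s <- trace_record(sin(2 * pi * t / 1000), 0.1, kind = "current")
  expect_equal(charge_transfer(s), 0, tolerance = 1e-6)
  # an iv ramp of constant current carries I * duration
  ivc <- iv_curve(seq(-150, -50, 1), rep(0.2, 101), duration_ms = 3000)
  expect_equal(charge_transfer(ivc), 0.2 * 3, tolerance = 1e-12)
})

test_that("summation metrics match the template model on template-built traces", {
  tpl <- epsp_template(2, 15, dt = 0.1, duration = 200)
  pad <- trace_record(c(rep(0, 500), convolve_train(tpl, 10, 5)$samples),
                      0.1)
  m <- summation_metrics(pad, onsets = 50 + (0:4) * 10)
  comp <- convolve_train(tpl, 10, 5)
  expect_equal(m$last_amplitude,
               max(comp$samples[trace_times(comp) >= 40 &
                                trace_times(comp) <= 70]),
               tolerance = 1e-9)
  expect_false(m$baseline_contaminated)
  # ISI 0 stacks five aligned copies
  pad0 <- trace_record(c(rep(0, 500), convolve_train(tpl, 0, 5)$samples), 0.1)
  m0 <- summation_metrics(pad0, onsets = rep(50, 5))
  expect_equal(m0$last_amplitude, 5, tolerance = 1e-9)
  # integral of well-separated events is additive
  single <- trace_record(c(rep(0, 500), tpl$samples, rep(0, 2000)), 0.1)
  ms <- summation_metrics(single, onsets = 50)
  pads <- trace_record(c(rep(0, 500), convolve_train(tpl, 180, 2)$samples),
                       0.1)
  m2 <- summation_metrics(pads, onsets = c(50, 230))
  expect_equal(m2$integral, 2 * ms$integral, tolerance = 0.01 * ms$integral)
})

test_that("spike detection, PSTH and ISI-resolved spike fractions recover ground truth", {
  truth_times <- c(120, 300, 301.5, 472)
  g <- gen_current_clamp_trace(onsets = numeric(0), duration = 600,
                               spike_times = truth_times, seed = 5)
  ev2 <- detect_spikes(g$trace)
  expect_equal(length(ev2$times), 4L)
  expect_lt(max(abs(ev2$times - truth_times)), 0.2)
  # a wide refractory window merges the 1.5 ms doublet
  ev <- detect_spikes(g$trace, refractory = 2)
  expect_equal(length(ev$times), 3L)
  expect_lt(max(abs(ev$times - c(120, 300, 472))), 0.2)
  # subthreshold trace yields no events
  g2 <- gen_current_clamp_trace(onsets = 100, duration = 300, seed = 5)
  expect_equal(length(detect_spikes(g2$trace)$times), 0L)

  # PSTH counts conserve events
  ps <- firing_rate_psth(ev2, bin = 100, window = c(0, 600))
  expect_equal(sum(ps$count), 4)
  uniform <- event_series(seq(50, 950, 100))
  pu <- firing_rate_psth(uniform, bin = 100, window = c(0, 1000))
  expect_true(all(pu$rate_hz == 10))
  expect_true(all(firing_rate_psth(event_series(numeric(0)), 100,
                                   c(0, 1000))$count == 0))

  # ISI-resolved fractions: known per-ISI spike probabilities
  set.seed(21)
  isis <- c(5, 10, 20, 50, 100)
  p_spike <- c(0.1, 0.6, 0.4, 0.15, 0.1)
  stim_times <- cumsum(sample(rep(isis, 40)))
  stim_isi <- rep(NA_real_, length(stim_times))
  stim_isi[-1] <- diff(stim_times); stim_isi[1] <- 100
  fire <- runif(length(stim_times)) <
    p_spike[match(stim_isi, isis)]
  sp <- event_series(stim_times[fire] + 2)
  fr <- spike_fraction_by_isi(sp, stim_times, stim_isi, window = 4)
  expect_equal(sum(fr$percent), 100, tolerance = 1e-9)
  exp_counts <- 40 * p_spike
  exp_pct <- 100 * exp_counts / sum(exp_counts)
  for (k in seq_along(isis)) {
    n_i <- 40
    ci <- 100 * 1.96 * sqrt(p_spike[k] * (1 - p_spike[k]) / n_i) * n_i /
      sum(exp_counts)
    expect_lt(abs(fr$percent[as.character(isis[k])] - exp_pct[k]), 3 * ci + 5)
  }
  # all spikes after one ISI
  sp10 <- event_series(stim_times[stim_isi == 10] + 1)
  fr10 <- spike_fraction_by_isi(sp10, stim_times, stim_isi, window = 4)
  expect_equal(unname(fr10$percent["10"]), 100)
  expect_true(spike_fraction_by_isi(event_series(numeric(0)), stim_times,
                                    stim_isi)$empty)
})

test_that("spike filtering recovers a DC depolarization independent of rate", {
  for (rate in c(5, 50)) {
    set.seed(rate)
    n_sp <- round(rate * 2)   # 2 s trace
    sp_times <- sort(runif(n_sp, 50, 1950))
    sp_times <- sp_times[c(TRUE, diff(sp_times) > 8)]
    g <- gen_current_clamp_trace(onsets = numeric(0), baseline = -71 + 1.19,
                                 duration = 2000, spike_times = sp_times,
                                 noise_sd = 0.1, seed = rate)
    out <- subthreshold_from_spiking(g$trace)
    expect_lt(abs(out$mean_vm - (-71 + 1.19)), 0.3)
    expect_equal(out$n_spikes, length(sp_times))
  }
  # a spike-free trace passes through nearly unchanged
  flat <- gen_current_clamp_trace(onsets = numeric(0), duration = 500,
                                  seed = 2)
  out2 <- subthreshold_from_spiking(flat$trace)
  expect_lt(max(abs(out2$trace$samples - flat$trace$samples)), 0.05)
})

test_that("IEI band probabilities honour the published band edges and gaps", {
  b <- band_definition()
  # all IEIs at 15 ms = 66.7 Hz -> high gamma
  e15 <- event_series(seq(0, 1500, 15))
  p15 <- iei_band_probabilities(e15, b)
  expect_equal(unname(p15$probability["high_gamma"]), 1)
  # 25 ms = 40 Hz -> low gamma
  p25 <- iei_band_probabilities(event_series(seq(0, 2500, 25)), b)
  expect_equal(unname(p25$probability["low_gamma"]), 1)
  # 35 ms = 28.6 Hz -> beta; 33 ms = 30.3 Hz falls in the 29-39 Hz gap
  p35 <- iei_band_probabilities(event_series(seq(0, 3500, 35)), b)
  expect_equal(unname(p35$probability["beta"]), 1)
  p33 <- iei_band_probabilities(event_series(seq(0, 3300, 33)), b)
  expect_equal(p33$unassigned, 1)
  # 8 Hz shared edge goes to theta (lower band wins)
  p125 <- iei_band_probabilities(event_series(seq(0, 1250, 125)), b)
  expect_equal(unname(p125$probability["theta"]), 1)
  expect_equal(unname(p125$probability["alpha"]), 0)
  # probabilities always sum to one
  set.seed(4)
  ge <- gen_ipsc_events(n_events = 300, seed = 4)
  pg <- iei_band_probabilities(ge$events, b)
  expect_equal(sum(pg$probability) + pg$unassigned, 1, tolerance = 1e-12)
})

test_that("space-constant fitting recovers the generating constant", {
  g <- gen_distance_response(lambda = 3.13, noise_cv = 0)
  f <- fit_space_constant(g$distances, g$responses)
  expect_equal(f$lambda, 3.13, tolerance = 1e-6)
  expect_equal(f$flag, "ok")
  # constant responses flag as non-decaying
  fc <- fit_space_constant(0:9, rep(5, 10))
  expect_true(is.infinite(fc$lambda))
  expect_equal(fc$flag, "non_decaying")
  # 20% multiplicative noise, n = 16: median recovery within 25%
  lams <- vapply(1:100, function(s) {
    gs <- gen_distance_response(distances = seq(0, 15, 1), lambda = 3.13,
                                noise_cv = 0.2, seed = s)
    fit_space_constant(gs$distances, gs$responses)$lambda
  }, 0)
  expect_lt(abs(median(lams) - 3.13) / 3.13, 0.25)
})

test_that("the Nernst equation reproduces the predicted K+ reversal", {
  expect_equal(nernst_potential(10, 10), 0)
  # printed solutions: 3 mM K+ out, 140 mM in (130 KGluconate + 10 KCl)
  ek <- nernst_potential(3, 140, temperature = 306.15)
  expect_equal(round(ek), -101)
  expect_equal(nernst_potential(140, 3, temperature = 306.15), -ek)
  expect_error(nernst_potential(-1, 140), "c_out")
})
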