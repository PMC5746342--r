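test_that("a passive compartment relaxes with the analytic RC time constant", {
  mod <- soma_only_model(leak = leak_spec(1e-4, 5e-5))
  arr <- fsikir:::model_arrays(mod)
  g_tot <- sum(arr$gk + arr$gna)           # uS
  c_tot <- sum(arr$cm)                      # nF
  tau_m <- c_tot / g_tot                    # ms
  v_inf0 <- (sum(arr$gk) * arr$ek + sum(arr$gna) * arr$ena) / g_tot
  tr <- run_current_clamp(mod, 100, stim = list(amp = -0.05, onset = 20,
                                                dur = 80))
  t <- trace_times(tr)
  v_inf1 <- v_inf0 - 0.05 / g_tot
  pred <- ifelse(t <= 20, v_inf0,
                 v_inf1 + (v_inf0 - v_inf1) * exp(-(t - 20) / tau_m))
  seg <- t > 20 & t < 100
  expect_lt(max(abs(tr$samples[seg] - pred[seg])) /
              abs(v_inf1 - v_inf0), 0.01)
})

test_that("zero-stimulus passive rest equals the conductance-weighted reversal mean", {
  mod <- soma_only_model(leak = leak_spec(1e-4, 5e-5))
  arr <- fsikir:::model_arrays(mod)
  expected <- (sum(arr$gk) * arr$ek + sum(arr$gna) * arr$ena) /
    sum(arr$gk + arr$gna)
  st <- measure_resting_state(mod)
  expect_equal(st$vm, expected, tolerance = 1e-9)
  expect_equal(st$rin, 1 / sum(arr$gk + arr$gna), tolerance = 1e-6)
  # doubling all densities halves Rin
  mod2 <- soma_only_model(leak = leak_spec(2e-4, 1e-4))
  expect_equal(measure_resting_state(mod2)$rin, st$rin / 2,
               tolerance = 0.01)
})

test_that("steady-state attenuation along a sealed cable matches the cosh solution", {
  m <- build_reduced_fsi(n_dendrites = 1, dendrite_length = 400,
                         dendrite_diameter = 2, soma_length = 2,
                         soma_diameter = 2)
  tree <- discretize(m, max_len = 2)
  mod <- fsi_model(tree, leak = leak_spec(1e-4, 0, e_k = -70, e_na = 53),
                   kir = NULL)
  rec <- c(fsikir:::soma_root(tree),
           site_to_compartment(tree, 100), site_to_compartment(tree, 300))
  trs <- run_current_clamp(mod, 600, stim = list(amp = 0.02, onset = 100,
                                                 dur = 500), record = rec)
  vend <- vapply(trs, function(tr) tr$samples[length(tr$samples)], 0) + 70
  lambda <- sqrt((1 / 1e-4) * 2e-4 / (4 * 172)) * 1e4   # um
  att <- function(x) cosh((400 - x) / lambda) / cosh(400 / lambda)
  expect_lt(abs(vend[2] / vend[1] - att(100) / att(0)), 0.02 * att(100))
  expect_lt(abs(vend[3] / vend[1] - att(300) / att(0)), 0.02 * att(300))
})

test_that("axial charge is conserved in a two-compartment model", {
  # at steady state the injected current equals the summed membrane current,
  # which requires the axial current leaving the soma to enter the dendrite
  m <- build_reduced_fsi(n_dendrites = 1, dendrite_length = 50,
                         dendrite_diameter = 2, soma_length = 20,
                         soma_diameter = 20)
  tree <- discretize(m, max_len = 50)
  mod <- fsi_model(tree, leak = leak_spec(1e-4, 5e-5), kir = NULL)
  arr <- fsikir:::model_arrays(mod)
  rec <- seq_len(nrow(tree))
  trs <- run_current_clamp(mod, 400, stim = list(amp = -0.05, onset = 100,
                                                 dur = 300), record = rec)
  v <- vapply(trs, function(tr) tr$samples[length(tr$samples)], 0)
  i_mem <- sum(arr$gk * (v - arr$ek) + arr$gna * (v - arr$ena))
  expect_equal(i_mem, -0.05, tolerance = 1e-6)
})

test_that("integration is deterministic and dt-converged", {
  tree <- default_tree()
  mk <- function(dt) {
    mod <- fsi_model(tree, leak = leak_spec(7e-5, 2.5e-5),
                     kir = kir_spec(5e-5), config = engine_config(dt = dt))
    mod <- place_synapse_group(mod)
    mod$synapses <- list(local({ s <- mod$synapses[[1]]; s$onsets <- 100; s }))
    run_current_clamp(mod, 200)
  }
  a <- mk(0.025); b <- mk(0.025)
  expect_identical(a$samples, b$samples)   # bit-exact without noise
  c50 <- mk(0.05)
  # compare at common sample times
  expect_lt(max(abs(a$samples[seq(1, length(a$samples), 2)] - c50$samples)),
            0.05)
})

test_that("noise runs are reproducible under a fixed seed", {
  tree <- default_tree()
  mod <- fsi_model(tree, leak = leak_spec(7e-5, 2.5e-5),
                   kir = kir_spec(5e-5),
                   noise = noise_spec(noise_compartments(tree)))
  set.seed(42); a <- run_current_clamp(mod, 100)
  set.seed(42); b <- run_current_clamp(mod, 100)
  set.seed(43); c <- run_current_clamp(mod, 100)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c$samples))
})

test_that("voltage clamp of a linear compartment gives a line through the reversal", {
  mod <- soma_only_model(leak = leak_spec(1e-4, 5e-5))
  arr <- fsikir:::model_arrays(mod)
  g_tot <- sum(arr$gk + arr$gna)
  e_rest <- (sum(arr$gk) * arr$ek + sum(arr$gna) * arr$ena) / g_tot
  iv <- run_voltage_clamp_ramp(mod, -150, -50, duration = 3000)
  fit <- lm(i ~ v, data = iv)
  expect_equal(unname(coef(fit)[2]), g_tot, tolerance = 1e-3)
  # capacitive command current biases the crossing by C (dV/dt) / g
  bias <- sum(arr$cm) * (100 / 3000) / g_tot
  expect_equal(estimate_reversal(iv), e_rest + bias, tolerance = 0.05)
})

test_that("clamping at the resting potential draws no steady current", {
  mod <- soma_only_model(leak = leak_spec(1e-4, 5e-5))
  arr <- fsikir:::model_arrays(mod)
  e_rest <- (sum(arr$gk) * arr$ek + sum(arr$gna) * arr$ena) /
    sum(arr$gk + arr$gna)
  iv <- run_voltage_clamp_ramp(mod, e_rest, e_rest + 1, duration = 500)
  expect_lt(abs(iv$i[1]), 1e-3)  # < 1 pA at the rest-potential end
})

test_that("a Kir-bearing membrane rectifies and its K+ current reverses at e_K", {
  mod <- soma_only_model(leak = leak_spec(7e-5, 2.5e-5),
                         kir = kir_spec(2e-4))
  iv <- run_voltage_clamp_ramp(mod, -150, -50, duration = 3000)
  # slope decreases with V above E_K (inward rectification)
  lo <- iv$v > -105 & iv$v < -90
  hi <- iv$v > -65 & iv$v < -50
  slope <- function(sel) unname(coef(lm(iv$i[sel] ~ iv$v[sel]))[2])
  expect_gt(slope(lo), slope(hi))
  # zero crossing between e_K and e_Na
  vr <- estimate_reversal(iv)
  expect_gt(vr, -107); expect_lt(vr, 53)
  # the subtracted current (all-K pool scaled) reverses at e_K exactly
  ivr <- run_voltage_clamp_ramp(scale_gk(mod, 0.7), -150, -50,
                                duration = 3000)
  dv <- iv_difference(iv, ivr)
  expect_equal(estimate_reversal(dv), -107, tolerance = 1e-3)
  # and is larger inward than outward at matched 20 mV offsets
  inw <- abs(approx(dv$v, dv$i, -127)$y)
  outw <- abs(approx(dv$v, dv$i, -87)$y)
  expect_gt(inw, outw)
})

test_that("reducing the K+ pool raises Vm and Rin monotonically (shallow Kir)", {
  mod <- soma_only_model(leak = leak_spec(7e-5, 2.5e-5),
                         kir = kir_spec(7e-5))
  fs <- c(0, 0.15, 0.3, 0.45, 0.6)
  st <- lapply(fs, function(f) measure_resting_state(scale_gk(mod, f)))
  vms <- vapply(st, `[[`, 0, "vm"); rins <- vapply(st, `[[`, 0, "rin")
  expect_true(all(diff(vms) > 0))
  expect_true(all(diff(rins) > 0))
})
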