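#' Uniformly sampled trace
#'
#' @param samples numeric vector (length >= 2).
#' @param dt sample interval, ms.
#' @param t0 time of the first sample, ms.
#' @param kind one of `"voltage"` (mV), `"current"` (nA), `"conductance"`
#'   (uS).
#' @param site label of the recording site.
#' @return A `trace_record` object.
#' @export
trace_record <- function(samples, dt, t0 = 0, kind = "voltage",
                         site = "soma") {
  stopifnot(length(samples) >= 2, dt > 0,
            kind %in% c("voltage", "current", "conductance"))
  structure(list(samples = as.numeric(samples), dt = dt, t0 = t0,
                 kind = kind, site = site), class = "trace_record")
}

#' @export
print.trace_record <- function(x, ...) {
  cat(sprintf("trace_record: %d samples @ dt %g ms (%s, site %s)\n",
              length(x$samples), x$dt, x$kind, x$site))
  invisible(x)
}

#' Trace sample times
#' @param trace a `trace_record`.
#' @return Numeric vector of sample times, ms.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) * trace$dt
}

#' @export
as.data.frame.trace_record <- function(x, ...) {
  data.frame(time_ms = trace_times(x), value = x$samples)
}

#' Engine configuration
#'
#' @param dt integration step, ms (in (0, 0.1]; default 0.025).
#' @param cm specific membrane capacitance, uF/cm^2.
#' @param temperature_c bath temperature, degrees C (documentation only; the
#'   passive model has no temperature-dependent rates).
#' @return An `engine_config` object.
#' @export
engine_config <- function(dt = 0.025, cm = 1.0, temperature_c = 33) {
  stopifnot(dt > 0, dt <= 0.1, cm > 0)
  structure(list(dt = dt, cm = cm, temperature_c = temperature_c),
            class = "engine_config")
}

#' Assemble a compartmental FSI model
#'
#' Combines a compartment tree with membrane mechanisms.  Conductance
#' densities can be modulated per compartment through the `gk_scale` /
#' `gna_scale` / `gkir_scale` vectors (used by the reduction protocols).
#'
#' @param tree an `fsi_comptree` from [discretize()].
#' @param leak a [leak_spec()].
#' @param kir a [kir_spec()] (or `NULL` for no Kir).
#' @param synapses list of [synapse_spec()].
#' @param noise a [noise_spec()] or `NULL`.
#' @param config an [engine_config()].
#' @return An `fsi_model` object.
#' @export
fsi_model <- function(tree, leak = leak_spec(), kir = kir_spec(),
                      synapses = list(), noise = NULL,
                      config = engine_config()) {
  stopifnot(inherits(tree, "fsi_comptree"))
  n <- nrow(tree)
  structure(list(tree = tree, leak = leak, kir = kir, synapses = synapses,
                 noise = noise, config = config,
                 gk_scale = rep(1, n), gna_scale = rep(1, n),
                 gkir_scale = rep(1, n)),
            class = "fsi_model")
}

#' @export
print.fsi_model <- function(x, ...) {
  cat(sprintf("fsi_model: %d compartments, %d synapse(s)%s\n",
              nrow(x$tree), length(x$synapses),
              if (is.null(x$noise)) "" else ", background noise attached"))
  invisible(x)
}

#' Scale the K+ conductance pool of a model
#'
#' Scales K+ leak and Kir densities together by `1 - fraction` in the
#' scoped compartments (the serotonin-sensitive pool; a `"kir"` pool
#' restricted to the rectifier alone is also available).
#'
#' @param model an `fsi_model`.
#' @param fraction reduction fraction in `[0, 0.95]`.
#' @param scope `"both"`, `"soma"`, or `"dendrites"`.
#' @param pool `"k_all"` (K leak + Kir, default) or `"kir"`.
#' @param weights optional per-compartment weight in `[0, 1]` multiplying
#'   `fraction` (used by the local-modulation scan).
#' @return The modulated model.
#' @export
scale_gk <- function(model, fraction, scope = "both", pool = "k_all",
                     weights = NULL) {
  stopifnot(inherits(model, "fsi_model"), fraction >= 0, fraction <= 0.95)
  sel <- switch(scope,
    both = rep(TRUE, nrow(model$tree)),
    soma = model$tree$is_soma,
    dendrites = !model$tree$is_soma,
    stop("scope must be one of 'both', 'soma', 'dendrites'"))
  if (!any(sel)) stop("scope selects zero compartments")
  w <- if (is.null(weights)) 1 else weights[sel]
  fac <- 1 - fraction * w
  model$gkir_scale[sel] <- model$gkir_scale[sel] * fac
  if (pool == "k_all") model$gk_scale[sel] <- model$gk_scale[sel] * fac
  else if (pool != "kir") stop("pool must be 'k_all' or 'kir'")
  model
}

# per-compartment absolute conductances (uS) and capacitances (nF)
model_arrays <- function(model) {
  tr <- model$tree
  area <- tr$area                       # um^2; S/cm^2 * um^2 * 1e-2 -> uS
  gkir_d <- if (is.null(model$kir)) 0 else model$kir$g_density
  list(
    parent = as.integer(tr$parent),
    cm = model$config$cm * area * 1e-5,  # uF/cm^2 * um^2 -> nF
    ga = ifelse(tr$parent == 0, 0, 1 / tr$r_axial),
    gk = model$leak$g_k_density * area * 1e-2 * model$gk_scale,
    gna = model$leak$g_na_density * area * 1e-2 * model$gna_scale,
    gkir = gkir_d * area * 1e-2 * model$gkir_scale,
    ek = model$leak$e_k, ena = model$leak$e_na,
    kir_vhalf = if (is.null(model$kir)) 0 else model$kir$v_half,
    kir_k = if (is.null(model$kir)) 1 else model$kir$k_slope)
}

syn_matrix <- function(synapses) {
  rows <- lapply(synapses, function(s) {
    if (length(s$onsets) == 0) return(NULL)
    cbind(s$compartment, s$onsets, s$tau_rise, s$tau_decay, s$weight,
          s$e_syn)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(matrix(numeric(0), ncol = 6))
  do.call(rbind, rows)
}

soma_root <- function(tree) tree$index[tree$is_soma][1]

# initial voltage: conductance-weighted passive reversal (Kir at the guess)
initial_voltage <- function(model) {
  arr <- model_arrays(model)
  v <- -70
  for (i in 1:20) {
    m <- 1 / (1 + exp((v - arr$kir_vhalf) / arr$kir_k))
    gk <- sum(arr$gk) + sum(arr$gkir) * m
    v <- (gk * arr$ek + sum(arr$gna) * arr$ena) / (gk + sum(arr$gna))
  }
  v
}

#' Run a current-clamp simulation
#'
#' Semi-implicit backward-Euler integration (conductances frozen over each
#' step) of the branched cable equation, with an optional piecewise-constant
#' somatic current and the model's synapses.  Deterministic given the R RNG
#' state when noise is attached.
#'
#' @param model an `fsi_model`.
#' @param duration simulated time, ms.
#' @param stim `NULL` or a list with `amp` (nA), `onset` and `dur` (ms), or
#'   a numeric vector of per-step currents.
#' @param record compartment indices to record (default: the somatic root).
#' @param v_init initial voltage (default: the passive fixed point).
#' @return A `trace_record` (single site) or list of them.
#' @export
run_current_clamp <- function(model, duration, stim = NULL, record = NULL,
                              v_init = NULL) {
  cfg <- model$config
  nsteps <- as.integer(round(duration / cfg$dt))
  arr <- model_arrays(model)
  n <- length(arr$parent)
  if (is.null(record)) record <- soma_root(model$tree)
  stim_comp <- 0L
  stim_vec <- numeric(nsteps)
  if (!is.null(stim)) {
    stim_comp <- soma_root(model$tree)
    if (is.numeric(stim) && length(stim) == nsteps) {
      stim_vec <- stim
    } else {
      t_step <- (seq_len(nsteps)) * cfg$dt
      on <- t_step > stim$onset & t_step <= stim$onset + stim$dur
      stim_vec[on] <- stim$amp
      if (!is.null(stim$comp)) stim_comp <- stim$comp
    }
  }
  if (is.null(v_init)) v_init <- initial_voltage(model)
  v0 <- rep(v_init, n)
  out <- cable_integrate(arr$parent, arr$cm, arr$ga, arr$gk, arr$gna,
                         arr$gkir, arr$ek, arr$ena, arr$kir_vhalf,
                         arr$kir_k, syn_matrix(model$synapses),
                         noise_matrix(model$noise), stim_comp, stim_vec,
                         rep(FALSE, n), numeric(nsteps + 1), cfg$dt,
                         nsteps, v0, as.integer(record), FALSE)
  traces <- lapply(seq_along(record), function(r)
    trace_record(out$v[, r], cfg$dt, 0, "voltage",
                 site = paste0("comp", record[r])))
  if (length(traces) == 1) traces[[1]] else traces
}

#' I-V curve container
#'
#' @param v command voltage grid, mV (strictly increasing).
#' @param i current, nA.
#' @param condition label.
#' @param duration_ms ramp duration represented by the sweep (for charge
#'   transfer), or `NA`.
#' @return An `iv_curve` object (data.frame `v`, `i`).
#' @export
iv_curve <- function(v, i, condition = "", duration_ms = NA_real_) {
  stopifnot(length(v) == length(i), all(diff(v) > 0))
  structure(data.frame(v = v, i = i),
            condition = condition, duration_ms = duration_ms,
            class = c("iv_curve", "data.frame"))
}

#' Run an ideal somatic voltage-clamp ramp
#'
#' The soma section is held exactly at a linear command from `v_start` to
#' `v_end` (zero series resistance) after a settling hold at `v_start`.
#' The clamp current is the somatic membrane current plus axial current
#' into the dendrites plus the (negligible, but included) capacitive
#' command current.
#'
#' @param model an `fsi_model`.
#' @param v_start,v_end command range, mV (default -150 to -50; a -130 mV
#'   start can be configured instead).
#' @param duration ramp duration, ms (default 3000).
#' @param settle pre-ramp hold at `v_start`, ms.
#' @param n_points number of points retained on the output grid.
#' @return An [iv_curve()] of command voltage vs clamp current.
#' @export
run_voltage_clamp_ramp <- function(model, v_start = -150, v_end = -50,
                                   duration = 3000, settle = 200,
                                   n_points = 500) {
  stopifnot(duration > 0, v_end > v_start)
  cfg <- model$config
  nsettle <- as.integer(round(settle / cfg$dt))
  nramp <- as.integer(round(duration / cfg$dt))
  nsteps <- nsettle + nramp
  arr <- model_arrays(model)
  n <- length(arr$parent)
  cmd <- c(rep(v_start, nsettle + 1),
           v_start + (v_end - v_start) * seq_len(nramp) / nramp)
  clamped <- model$tree$is_soma
  v0 <- rep(v_start, n)
  out <- cable_integrate(arr$parent, arr$cm, arr$ga, arr$gk, arr$gna,
                         arr$gkir, arr$ek, arr$ena, arr$kir_vhalf,
                         arr$kir_k, syn_matrix(model$synapses),
                         noise_matrix(model$noise), 0L, numeric(nsteps),
                         clamped, cmd, cfg$dt, nsteps,
                         v0, as.integer(soma_root(model$tree)), TRUE)
  keep <- seq(nsettle + 2L, nsteps + 1L)
  vcmd <- cmd[keep]
  icl <- out$i_clamp[keep]
  idx <- unique(round(seq(1, length(vcmd), length.out = n_points)))
  iv_curve(vcmd[idx], icl[idx], duration_ms = duration)
}

#' Measure resting potential and input resistance
#'
#' Settles the model for `settle` ms (resting Vm = mean somatic voltage
#' over the final 100 ms), then applies a somatic current step (default
#' -50 pA for 500 ms); Rin = delta V(steady) / I by Ohm's law, steady state
#' from the final 100 ms of the step.
#'
#' @param model an `fsi_model`.
#' @param step_amp step amplitude, nA (default -0.05).
#' @param settle,step_dur durations, ms.
#' @param mean_window window for steady-state means, ms.
#' @return A list with `vm` (mV), `rin` (MOhm), and the somatic `trace`.
#' @export
measure_resting_state <- function(model, step_amp = -0.05, settle = 500,
                                  step_dur = 500, mean_window = 100) {
  if (step_dur <= 0) {  # settle-only: report Vm, skip the step
    tr <- run_current_clamp(model, settle)
    t <- trace_times(tr)
    vm <- mean(tr$samples[t > settle - mean_window & t <= settle])
    if (!is.finite(vm)) stop("model did not reach a stable rest")
    return(list(vm = vm, rin = NA_real_, trace = tr))
  }
  tr <- run_current_clamp(model, settle + step_dur,
                          stim = list(amp = step_amp, onset = settle,
                                      dur = step_dur))
  t <- trace_times(tr)
  vm <- mean(tr$samples[t > settle - mean_window & t <= settle])
  vstep <- mean(tr$samples[t > settle + step_dur - mean_window &
                           t <= settle + step_dur])
  if (!is.finite(vm) || !is.finite(vstep))
    stop("model did not reach a stable rest")
  list(vm = vm, rin = (vstep - vm) / step_amp, trace = tr)
}
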