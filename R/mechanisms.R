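#' Membrane mechanism specifications
#'
#' The model membrane carries two ohmic leaks (K+ and Na+), an
#' instantaneous inward-rectifier K+ (Kir) conductance, double-exponential
#' synapses reversing at 0 mV, and optional fluctuating (point-conductance)
#' background synaptic conductances.
#'
#' `leak_spec` holds the passive densities.  The K+/Na+ split replaces a
#' single passive mechanism so that potassium-selective modulation can be
#' expressed: reducing the K+ pool both depolarizes the cell and raises its
#' input resistance.
#'
#' @param g_k_density,g_na_density leak conductance densities, S/cm^2.
#' @param e_k,e_na reversal potentials, mV (defaults -107 and +53).
#' @return A `leak_spec` object.
#' @export
leak_spec <- function(g_k_density = 1.4e-4, g_na_density = 4e-5,
                      e_k = -107, e_na = 53) {
  stopifnot(g_k_density >= 0, g_na_density >= 0, e_k < e_na)
  structure(list(g_k_density = g_k_density, g_na_density = g_na_density,
                 e_k = e_k, e_na = e_na), class = "leak_spec")
}

#' Inward-rectifier K+ conductance
#'
#' Rectification is modelled as an instantaneous Boltzmann open fraction,
#' `1 / (1 + exp((v - v_half) / k_slope))`: fully open well below `v_half`,
#' closing with depolarization.  This reproduces the hallmark subtracted
#' ramp-current shape (a large inward limb below E_K, a smaller outward
#' limb above it) without modelling Mg2+/polyamine block kinetics.
#'
#' @param g_density maximal Kir density, S/cm^2.
#' @param e_k K+ reversal, mV.
#' @param v_half half-open voltage, mV.
#' @param k_slope slope factor, mV (> 0).
#' @return A `kir_spec` object.
#' @export
kir_spec <- function(g_density = 1e-4, e_k = -107, v_half = -85,
                     k_slope = 12) {
  stopifnot(g_density >= 0, k_slope > 0)
  structure(list(g_density = g_density, e_k = e_k, v_half = v_half,
                 k_slope = k_slope), class = "kir_spec")
}

#' Kir open fraction at a voltage
#'
#' @param v membrane potential, mV (vectorized).
#' @param spec a [kir_spec()].
#' @return Open fraction in (0, 1), strictly decreasing in `v`.
#' @export
kir_open_fraction <- function(v, spec) {
  stopifnot(inherits(spec, "kir_spec"))
  1 / (1 + exp((v - spec$v_half) / spec$k_slope))
}

#' Double-exponential synapse
#'
#' Conductance waveform `w * (exp(-t/tau_decay) - exp(-t/tau_rise)) /
#' peak_norm`, normalized so the peak equals `weight`.  Multiple onsets sum
#' linearly.
#'
#' @param compartment compartment index the synapse contacts.
#' @param tau_rise,tau_decay time constants, ms (`0 < tau_rise < tau_decay`).
#' @param weight peak conductance, uS.
#' @param e_syn synaptic reversal, mV.
#' @param onsets onset times, ms.
#' @return A `synapse_spec` object.
#' @export
synapse_spec <- function(compartment, tau_rise = 0.3, tau_decay = 2,
                         weight = 1e-3, e_syn = 0, onsets = numeric(0)) {
  if (!(tau_rise > 0 && tau_rise < tau_decay))
    stop("require 0 < tau_rise < tau_decay")
  stopifnot(weight >= 0)
  structure(list(compartment = compartment, tau_rise = tau_rise,
                 tau_decay = tau_decay, weight = weight, e_syn = e_syn,
                 onsets = onsets), class = "synapse_spec")
}

#' Evaluate synaptic conductance at times since protocol start
#'
#' @param t time, ms (vectorized); onsets come from the spec.
#' @param spec a [synapse_spec()].
#' @return Conductance, uS.
#' @export
synaptic_conductance <- function(t, spec) {
  stopifnot(inherits(spec, "synapse_spec"))
  tp <- syn_peak_time(spec$tau_rise, spec$tau_decay)
  norm <- exp(-tp / spec$tau_decay) - exp(-tp / spec$tau_rise)
  g <- numeric(length(t))
  for (on in spec$onsets) {
    u <- t - on
    a <- u >= 0
    g[a] <- g[a] + spec$weight *
      (exp(-u[a] / spec$tau_decay) - exp(-u[a] / spec$tau_rise)) / norm
  }
  g
}

#' Peak time of a double exponential
#' @param tau_rise,tau_decay time constants, ms.
#' @return `tau_rise*tau_decay/(tau_decay-tau_rise) * log(tau_decay/tau_rise)`.
#' @export
syn_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

#' Point-conductance background noise
#'
#' Independent Ornstein-Uhlenbeck excitatory and inhibitory conductances on
#' target compartments, after the standard point-conductance model of
#' in-vivo-like synaptic bombardment.  `scale` multiplies the excitatory
#' and inhibitory levels together (means and SDs); it is the single knob
#' used to press input resistance down toward in-vivo values.  The default
#' mean conductances are balanced so the net background current vanishes
#' near a -71 mV rest (`ge0 * 71 = gi0 * 4`): background activity then
#' acts primarily as a shunt (an input-resistance reduction), which is how
#' its level is specified.  SD-to-mean ratios follow the point-conductance
#' literature.
#'
#' @param compartments target compartment indices (each gets an e and an i
#'   process).
#' @param ge0,sigma_e,tau_e excitatory mean (uS), SD (uS), correlation time
#'   (ms).
#' @param gi0,sigma_i,tau_i inhibitory counterparts.
#' @param e_exc,e_inh reversals, mV.
#' @param scale common scale factor applied to the means and SDs.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(compartments, ge0 = 1.2e-3, sigma_e = 3e-4,
                       tau_e = 2.7, gi0 = 2.13e-2, sigma_i = 2.5e-3,
                       tau_i = 10.5, e_exc = 0, e_inh = -75, scale = 1) {
  stopifnot(tau_e > 0, tau_i > 0, sigma_e >= 0, sigma_i >= 0, scale >= 0)
  structure(list(compartments = compartments, ge0 = ge0, sigma_e = sigma_e,
                 tau_e = tau_e, gi0 = gi0, sigma_i = sigma_i, tau_i = tau_i,
                 e_exc = e_exc, e_inh = e_inh, scale = scale),
            class = "noise_spec")
}

#' One exact Ornstein-Uhlenbeck conductance step
#'
#' Exact discretization `g' = g0 + (g - g0) exp(-dt/tau) +
#' sigma sqrt(1 - exp(-2 dt/tau)) N(0,1)`, clipped at zero (conductances
#' are physically non-negative).  Uses R's global RNG, so sequences are
#' reproducible under `set.seed()`.
#'
#' @param g current conductance, uS.
#' @param dt step, ms (> 0).
#' @param g0 stationary mean, uS.
#' @param sigma stationary SD, uS.
#' @param tau correlation time, ms.
#' @return Updated conductance, uS.
#' @export
ou_conductance_step <- function(g, dt, g0, sigma, tau) {
  stopifnot(dt > 0, tau > 0)
  a <- exp(-dt / tau)
  gn <- g0 + (g - g0) * a + sigma * sqrt(1 - exp(-2 * dt / tau)) * rnorm(1)
  max(gn, 0)
}

#' Background-noise target compartments on a subset of dendrites
#'
#' Returns the compartment at a relative position along every other
#' dendrite (the convention used for in-vivo-like background bombardment:
#' distributed, but not on every branch).
#'
#' @param tree an `fsi_comptree`.
#' @param every pick every `every`-th dendritic section (default 2).
#' @param position relative position along each dendrite in (0, 1).
#' @return Integer compartment indices.
#' @export
noise_compartments <- function(tree, every = 2, position = 0.5) {
  secs <- sort(unique(tree$section_id[!tree$is_soma]))
  secs <- secs[seq(1, length(secs), by = every)]
  vapply(secs, function(sid) {
    d <- tree[!tree$is_soma & tree$section_id == sid, ]
    site_to_compartment(tree, position * sum(d$length), sid)
  }, 0L)
}

# flatten a noise_spec into the engine's (comp, g0, sigma, tau, erev) matrix
noise_matrix <- function(spec) {
  if (is.null(spec) || length(spec$compartments) == 0 || spec$scale == 0)
    return(matrix(numeric(0), ncol = 5))
  s <- spec$scale
  rbind(
    cbind(spec$compartments, spec$ge0 * s, spec$sigma_e * s, spec$tau_e,
          spec$e_exc),
    cbind(spec$compartments, spec$gi0 * s, spec$sigma_i * s, spec$tau_i,
          spec$e_inh))
}
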