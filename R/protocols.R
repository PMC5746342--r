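#' Place the uncaging-style synapse group on a dendrite
#'
#' Five (by default) synapses 1 um apart ending at the given distance from
#' the soma, mirroring the multi-site glutamate uncaging arrangement.
#'
#' @param model an `fsi_model`.
#' @param site most proximal site, um from the soma (default 96).
#' @param n_sites number of sites (default 5, spaced `spacing` um apart,
#'   extending distally from `site`).
#' @param spacing spacing between sites, um.
#' @param section_id dendrite section (default: first dendrite).
#' @param ... passed to [synapse_spec()] (tau_rise, tau_decay, weight...).
#' @return The model with synapses attached (no onsets assigned yet).
#' @export
place_synapse_group <- function(model, site = 96, n_sites = 5, spacing = 1,
                                section_id = NULL, ...) {
  dists <- site + spacing * (seq_len(n_sites) - 1)
  model$synapses <- lapply(dists, function(d)
    synapse_spec(site_to_compartment(model$tree, d, section_id), ...))
  attr(model$synapses, "distances") <- dists
  model
}

# run a single-EPSP stimulation and measure somatic amplitude and decay tau
single_epsp_metrics <- function(model, settle = 300, record_dur = 250) {
  syn <- model$synapses
  if (length(syn) == 0) stop("model has no synapses")
  model$synapses <- list(local({ s <- syn[[1]]; s$onsets <- settle; s }))
  tr <- run_current_clamp(model, settle + record_dur)
  t <- trace_times(tr)
  v0 <- mean(tr$samples[t > settle - 20 & t <= settle])
  amp <- max(tr$samples[t >= settle]) - v0
  fit <- fit_decay_tau(tr, peak_window = c(settle, settle + 50),
                       baseline = v0)
  list(amplitude = amp, tau = fit$tau, r_squared = fit$r_squared,
       trace = tr)
}

#' K+ conductance reduction sweep
#'
#' For each reduction fraction, scales the K+ pool by `1 - f` in the scoped
#' compartments, re-measures rest (Vm, Rin), and stimulates a single
#' synapse at `synapse_site`, reporting somatic EPSP amplitude and decay
#' tau.
#'
#' @param model an `fsi_model` (typically the calibrated baseline).
#' @param fractions reduction fractions in `[0, 0.95]`.
#' @param scope `"both"`, `"soma"`, or `"dendrites"`.
#' @param synapse_site um from soma (default 96).
#' @param pool K+ pool passed to [scale_gk()].
#' @param ... synapse parameters for [place_synapse_group()].
#' @return A data.frame: `fraction`, `scope`, `vm`, `rin`, `epsp_amplitude`,
#'   `epsp_tau`.
#' @export
run_gk_sweep <- function(model, fractions = seq(0, 0.8, 0.1),
                         scope = "both", synapse_site = 96,
                         pool = "k_all", ...) {
  stopifnot(all(fractions >= 0), all(fractions <= 0.95))
  model <- place_synapse_group(model, site = synapse_site, n_sites = 1, ...)
  rows <- lapply(fractions, function(f) {
    m <- if (f == 0) model else scale_gk(model, f, scope = scope,
                                         pool = pool)
    st <- measure_resting_state(m)
    ep <- single_epsp_metrics(m)
    data.frame(fraction = f, scope = scope, vm = st$vm, rin = st$rin,
               epsp_amplitude = ep$amplitude, epsp_tau = ep$tau)
  })
  do.call(rbind, rows)
}

#' Inter-stimulus-interval summation series
#'
#' Activates the synapse group sequentially (most distal site first,
#' matching the uncaging order) at each ISI, in the baseline and reduced
#' conditions, and measures the last-EPSP amplitude (compound-trace
#' maximum within 30 ms of the last onset, minus the pre-train baseline)
#' and the compound integral over `[first onset, last onset + 200 ms]`.
#'
#' @param model baseline `fsi_model` with a synapse group attached (see
#'   [place_synapse_group()]).
#' @param isis inter-stimulus intervals, ms.
#' @param reduction fraction defining the reduced condition.
#' @param scope,pool how the reduction is applied (see [scale_gk()]).
#' @param settle pre-train settling time, ms.
#' @param distal_first activate the most distal site first (default TRUE).
#' @return A `summation_result` data.frame: per ISI, `amp_baseline`,
#'   `amp_reduced`, `integral_baseline`, `integral_reduced`, `amp_ratio`,
#'   `integral_ratio`.
#' @export
run_summation <- function(model, isis = c(0.12, 5, 10, 20, 50),
                          reduction = 0.1, scope = "both", pool = "k_all",
                          settle = 300, distal_first = TRUE) {
  syn <- model$synapses
  if (length(syn) < 2) stop("attach a synapse group first")
  dists <- attr(syn, "distances")
  ord <- order(dists, decreasing = distal_first)
  reduced <- scale_gk(model, reduction, scope = scope, pool = pool)
  # with background noise attached, baseline and reduced runs at each ISI
  # share the same noise stream so the condition ratio is paired
  noisy <- !is.null(model$noise) && model$noise$scale > 0
  isi_seeds <- if (noisy) sample.int(.Machine$integer.max, length(isis))
  run_one <- function(m, isi, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(syn)
    onsets <- settle + (seq_len(n) - 1) * isi
    m$synapses <- lapply(seq_len(n), function(i) {
      s <- syn[[ord[i]]]; s$onsets <- onsets[i]; s
    })
    last_on <- onsets[n]
    tr <- run_current_clamp(m, last_on + 230)
    summation_metrics(tr, onsets = onsets, baseline_window = 20)
  }
  rows <- lapply(seq_along(isis), function(k) {
    isi <- isis[k]
    sd_k <- if (noisy) isi_seeds[k]
    b <- run_one(model, isi, sd_k)
    r <- run_one(reduced, isi, sd_k)
    data.frame(isi = isi,
               amp_baseline = b$last_amplitude,
               amp_reduced = r$last_amplitude,
               integral_baseline = b$integral,
               integral_reduced = r$integral,
               amp_ratio = r$last_amplitude / b$last_amplitude,
               integral_ratio = r$integral / b$integral)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summation_result", "data.frame")
  out
}

#' ISI summation series under background noise
#'
#' Runs the summation protocol with point-conductance noise attached,
#' replicated under independent seeds; compound traces are averaged across
#' replicates per (ISI, condition) before the metrics are computed (trial
#' averaging, as in noisy recordings), with seeds paired between the
#' baseline and reduced conditions.
#'
#' @param model baseline `fsi_model` with a synapse group attached.
#' @param noise a [noise_spec()] (already scaled; see
#'   [find_noise_scale()]).
#' @param isis inter-stimulus intervals, ms.
#' @param reduction reduced-condition fraction for [scale_gk()].
#' @param n_replicates noise replicates averaged (default 10).
#' @param seeds one seed per replicate (default derived from `seed0`).
#' @param seed0 base seed offset.
#' @param scope,pool,settle as in [run_summation()].
#' @param smooth_ms median-filter width applied to the replicate-averaged
#'   traces before measurement, ms (0 disables).
#' @return A `summation_result` data.frame (as [run_summation()]) plus
#'   attributes `seeds` and `rin_per_replicate` (noise-condition Rin).
#' @export
run_summation_noisy <- function(model, noise, isis = c(0.12, 5, 10, 20, 50),
                                reduction = 0.1, n_replicates = 10,
                                seeds = NULL, seed0 = 1000,
                                scope = "both", pool = "k_all",
                                settle = 300, smooth_ms = 3) {
  syn <- model$synapses
  if (length(syn) < 2) stop("attach a synapse group first")
  if (is.null(seeds)) seeds <- seed0 + seq_len(n_replicates)
  dists <- attr(syn, "distances")
  ord <- order(dists, decreasing = TRUE)
  noisy <- model; noisy$noise <- noise
  reduced <- scale_gk(noisy, reduction, scope = scope, pool = pool)
  run_one <- function(m, isi) {
    n <- length(syn)
    onsets <- settle + (seq_len(n) - 1) * isi
    m$synapses <- lapply(seq_len(n), function(i) {
      s <- syn[[ord[i]]]; s$onsets <- onsets[i]; s
    })
    run_current_clamp(m, max(onsets) + 230)$samples
  }
  rins <- vapply(seeds, function(sd) {
    set.seed(sd)
    measure_resting_state(noisy, mean_window = 250)$rin
  }, 0)
  rows <- lapply(isis, function(isi) {
    accb <- accr <- 0
    for (j in seq_len(n_replicates)) {
      set.seed(seeds[j] * 13 + round(isi * 100))
      accb <- accb + run_one(noisy, isi)
      set.seed(seeds[j] * 13 + round(isi * 100))
      accr <- accr + run_one(reduced, isi)
    }
    n <- length(syn)
    onsets <- settle + (seq_len(n) - 1) * isi
    dt <- model$config$dt
    smooth <- function(y) {
      if (smooth_ms <= 0) return(y)
      k <- max(3L, 2L * floor(smooth_ms / dt / 2) + 1L)
      as.numeric(stats::runmed(y, k))
    }
    b <- summation_metrics(trace_record(smooth(accb / n_replicates), dt),
                           onsets = onsets)
    r <- summation_metrics(trace_record(smooth(accr / n_replicates), dt),
                           onsets = onsets)
    data.frame(isi = isi,
               amp_baseline = b$last_amplitude,
               amp_reduced = r$last_amplitude,
               integral_baseline = b$integral,
               integral_reduced = r$integral,
               amp_ratio = r$last_amplitude / b$last_amplitude,
               integral_ratio = r$integral / b$integral)
  })
  out <- do.call(rbind, rows)
  attr(out, "seeds") <- seeds
  attr(out, "rin_per_replicate") <- rins
  class(out) <- c("summation_result", "data.frame")
  out
}

#' Replicate a protocol under seeded background noise
#'
#' Attaches the point-conductance noise to the model, runs the wrapped
#' protocol under independent seeds, and reports per-replicate outputs
#' plus the noise-condition input resistance (measured with noise active,
#' averaged over replicates).
#'
#' @param model an `fsi_model` (noise from `noise` replaces any attached).
#' @param noise a [noise_spec()].
#' @param protocol function of one argument (the noisy model) returning a
#'   data.frame; called once per replicate.
#' @param n_replicates number of replicates (default 10).
#' @param seeds integer seeds, one per replicate (default `1:n + seed0`).
#' @param seed0 base seed offset used when `seeds` is NULL.
#' @return list with `replicates` (list of protocol outputs), `seeds`,
#'   `rin_per_replicate`, `rin_mean`, and `mean` (element-wise mean of the
#'   numeric protocol outputs).
#' @export
run_noise_replicates <- function(model, noise, protocol, n_replicates = 10,
                                 seeds = NULL, seed0 = 1000) {
  stopifnot(n_replicates >= 1)
  if (is.null(seeds)) seeds <- seed0 + seq_len(n_replicates)
  stopifnot(length(seeds) == n_replicates)
  noisy <- model
  noisy$noise <- noise
  reps <- vector("list", n_replicates)
  rins <- numeric(n_replicates)
  for (i in seq_len(n_replicates)) {
    set.seed(seeds[i])
    rins[i] <- measure_resting_state(noisy, mean_window = 250)$rin
    reps[[i]] <- protocol(noisy)
  }
  mean_df <- NULL
  if (is.data.frame(reps[[1]])) {
    mean_df <- reps[[1]]
    num <- vapply(mean_df, is.numeric, TRUE)
    for (j in which(num))
      mean_df[[j]] <- rowMeans(matrix(vapply(reps, function(r)
        as.numeric(r[[j]]), numeric(nrow(mean_df))), nrow = nrow(mean_df)))
  }
  list(replicates = reps, seeds = seeds, rin_per_replicate = rins,
       rin_mean = mean(rins), mean = mean_df)
}

#' Find the noise scale producing a target Rin reduction
#'
#' Root-finds the common scale factor of the background conductances so
#' that the noise-condition Rin (averaged over a few fixed probe seeds)
#' is `1 - target_reduction` of the noise-free Rin.
#'
#' @param model an `fsi_model`.
#' @param noise a [noise_spec()] (its `scale` is ignored).
#' @param target_reduction fractional Rin reduction (default 0.33).
#' @param bracket scale search interval.
#' @param probe_seeds seeds averaged per evaluation.
#' @return The fitted scale factor.
#' @export
find_noise_scale <- function(model, noise, target_reduction = 0.33,
                             bracket = c(0.05, 20), probe_seeds = 1:3) {
  rin0 <- measure_resting_state(model)$rin
  target <- (1 - target_reduction) * rin0
  f <- function(s) {
    noisy <- model
    noise$scale <- s
    noisy$noise <- noise
    r <- vapply(probe_seeds, function(sd) {
      set.seed(sd)
      measure_resting_state(noisy, mean_window = 250)$rin
    }, 0)
    mean(r) - target
  }
  uniroot(f, bracket, tol = 1e-2)$root
}

#' Local dendritic modulation scan
#'
#' Emulates focal neuromodulator application: the K+ pool is scaled by
#' `1 - f * w(d)` with a Gaussian spatial weight (`sigma = extent`) centred
#' at each scan position on a dendrite, and the steady somatic
#' depolarization is reported per position.
#'
#' @param model an `fsi_model`.
#' @param centers scan positions, um from the soma.
#' @param extent Gaussian sigma of the modulated zone, um.
#' @param f peak reduction fraction at the centre.
#' @param section_id dendrite scanned (default: first dendrite).
#' @param pool K+ pool (see [scale_gk()]).
#' @return data.frame: `center`, `dvm` (somatic depolarization, mV).
#' @export
run_local_modulation_scan <- function(model, centers = seq(30, 300, 30),
                                      extent = 10, f = 0.8,
                                      section_id = NULL, pool = "k_all") {
  stopifnot(extent > 0)
  tree <- model$tree
  if (is.null(section_id))
    section_id <- min(tree$section_id[!tree$is_soma])
  vm0 <- measure_resting_state(model, step_dur = 0)$vm
  rows <- lapply(centers, function(ctr) {
    w <- ifelse(!tree$is_soma & tree$section_id == section_id,
                exp(-(tree$path_dist - ctr)^2 / (2 * extent^2)), 0)
    m <- scale_gk(model, f, scope = "both", pool = pool, weights = w)
    vm <- measure_resting_state(m, step_dur = 0)$vm
    data.frame(center = ctr, dvm = vm - vm0)
  })
  do.call(rbind, rows)
}
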