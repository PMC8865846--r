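#' Point-neuron parameter presets
#'
#' Parameters of the adaptive exponential integrate-and-fire (AdExpIF)
#' neuron model `Cm dV/dt = -(gL (V - Vrest) - gL DeltaT exp((V - vth)/DeltaT)
#' + Isyn + w)`, `tauw dw/dt = a (V - Vrest) - w`, with reset to `Vreset`
#' and refractory clamp when `V` crosses the detection threshold `theta`,
#' and `w <- w + b` at each spike. Three presets are built in, obtained by
#' fitting the models to somatic current-step recordings of the two CA3 cell
#' classes: `"PC"` (adapting pyramidal cell), `"PC_ExpIF"` (pyramidal cell
#' refit without any adaptation mechanism, `a = b = 0`) and `"PVBC"`
#' (fast-spiking parvalbumin-positive basket cell).
#'
#' @param preset One of `"PC"`, `"PC_ExpIF"`, `"PVBC"`.
#' @param ... Named overrides of individual parameters (`Cm` pF, `gL` nS,
#'   `Vrest` mV, `DeltaT` mV, `vth` mV (exponential threshold), `theta` mV
#'   (spike detection), `Vreset` mV, `tref` ms, `tauw` ms, `a` nS, `b` pA).
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(preset = c("PC", "PC_ExpIF", "PVBC"), ...) {
  preset <- match.arg(preset)
  p <- switch(preset,
    PC = list(Cm = 180.13, gL = 4.31, Vrest = -75.19, DeltaT = 4.23,
              vth = -24.42, theta = -3.25, Vreset = -29.74, tref = 5.96,
              tauw = 84.93, a = -0.27, b = 206.84, has_w = 1),
    PC_ExpIF = list(Cm = 344.18, gL = 4.88, Vrest = -75.19, DeltaT = 10.78,
                    vth = -28.77, theta = 25.13, Vreset = -58.82, tref = 1.07,
                    tauw = 1, a = 0, b = 0, has_w = 0),
    PVBC = list(Cm = 118.52, gL = 7.51, Vrest = -74.74, DeltaT = 4.58,
                vth = -57.71, theta = -34.78, Vreset = -64.99, tref = 1.15,
                tauw = 178.58, a = 3.05, b = 0.91, has_w = 1))
  over <- list(...)
  p[names(over)] <- over
  stopifnot(p$Cm > 0, p$gL > 0, p$DeltaT > 0, p$tref > 0)
  structure(c(list(preset = preset), p), class = "neuron_params")
}

#' Biexponential synapse normalization
#'
#' For the conductance time course `g(t) = ghat A (exp(-t/tau_d) -
#' exp(-t/tau_r))`, returns the peak time `t_p = tau_d tau_r / (tau_d -
#' tau_r) log(tau_d / tau_r)` and the normalization `A` such that
#' `g(t_p) = ghat`.
#'
#' @param tau_r,tau_d Rise and decay time constants, ms (`tau_d > tau_r`).
#' @return list with `A` (dimensionless, here returned as the peak value of
#'   the unnormalized difference, so increments are divided by it) and `t_p`
#'   (ms).
#' @export
double_exp_normalization <- function(tau_r, tau_d) {
  stopifnot(tau_d > tau_r, tau_r > 0)
  t_p <- tau_d * tau_r / (tau_d - tau_r) * log(tau_d / tau_r)
  A <- exp(-t_p / tau_d) - exp(-t_p / tau_r)
  list(A = A, t_p = t_p)
}

#' Synaptic parameter presets (per pathway)
#'
#' Peak conductances, biexponential kinetics, axonal delays and connection
#' probabilities of the five pathway types. The mossy-fiber (`GC_PC`) drive
#' has no delay and its weight depends on the learning kernel used for the
#' recurrent weights (19.15 nS for the symmetric kernel, 21.5 nS for the
#' asymmetric one) and is doubled (38.3 nS) for the non-adapting ExpIF
#' pyramidal-cell variant, which needs a stronger drive to reach comparable
#' rates.
#'
#' @param pathway One of `"PC_PC"`, `"PC_PVBC"`, `"PVBC_PC"`, `"PVBC_PVBC"`,
#'   `"GC_PC"`.
#' @param ... Named overrides (`ghat` nS, `tau_r`, `tau_d`, `delay` ms, `p`
#'   connection probability, `E` reversal mV).
#' @return list of parameters with the normalization of
#'   [double_exp_normalization()] attached.
#' @export
synapse_params <- function(pathway = c("PC_PC", "PC_PVBC", "PVBC_PC",
                                       "PVBC_PVBC", "GC_PC"), ...) {
  pathway <- match.arg(pathway)
  p <- switch(pathway,
    PC_PC =     list(ghat = NA,   tau_r = 1.3,  tau_d = 9.5, delay = 2.2, p = 0.1,  E = 0),
    PC_PVBC =   list(ghat = 0.85, tau_r = 1.0,  tau_d = 4.1, delay = 0.9, p = 0.1,  E = 0),
    PVBC_PC =   list(ghat = 0.65, tau_r = 0.3,  tau_d = 3.3, delay = 1.1, p = 0.25, E = -70),
    PVBC_PVBC = list(ghat = 5.0,  tau_r = 0.25, tau_d = 1.2, delay = 0.6, p = 0.25, E = -70),
    GC_PC =     list(ghat = 19.15, tau_r = 0.65, tau_d = 5.4, delay = 0,  p = NA,   E = 0))
  over <- list(...)
  p[names(over)] <- over
  stopifnot(p$tau_d > p$tau_r, p$tau_r > 0)
  norm <- double_exp_normalization(p$tau_r, p$tau_d)
  c(list(pathway = pathway), p, norm)
}

#' Offline network configuration
#'
#' Sizes, connection probabilities, external drive and structural variant of
#' the offline (resting-state) network. Every pyramidal cell receives one
#' independent 15 Hz Poisson mossy-fiber train; the recurrent excitatory
#' weights come from the learned [weight matrix][learn_weights()], all other
#' pathways use their fixed preset conductances on freshly sampled random
#' graphs.
#'
#' Variants: `"baseline"`; `"no_PVBC_PVBC"` removes the recurrent inhibitory
#' synapses; `"ExpIF_PC"` replaces pyramidal cells with the non-adapting
#' ExpIF fit (mossy weight doubled); `"PVBC_only"` keeps only the basket
#' cells, replacing the pyramidal drive with independent Poisson sources
#' (rate `pvbc_only_rate`, weight `pvbc_only_weight`) connected through the
#' PC to PVBC synapse with probability 0.1.
#'
#' @param n_pc,n_pvbc Population sizes.
#' @param variant Structural variant flag (mutually exclusive).
#' @param ee_scale Multiplier applied to the recurrent excitatory weights.
#' @param mf_rate Mossy-fiber Poisson rate, Hz.
#' @param mf_weight Mossy-fiber peak conductance, nS; `NULL` picks the
#'   preset for the variant / `kernel_preset`.
#' @param kernel_preset Which learning kernel the weights came from
#'   (selects 19.15 vs 21.5 nS mossy weight).
#' @param pvbc_only_rate,pvbc_only_weight Drive parameters of the
#'   `"PVBC_only"` variant (rate per source in Hz, peak conductance in nS).
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_pc = 8000, n_pvbc = 150,
                           variant = c("baseline", "no_PVBC_PVBC",
                                       "PVBC_only", "ExpIF_PC"),
                           ee_scale = 1, mf_rate = 15, mf_weight = NULL,
                           kernel_preset = c("symmetric", "asymmetric"),
                           pvbc_only_rate = 2.5, pvbc_only_weight = 0.85) {
  variant <- match.arg(variant)
  kernel_preset <- match.arg(kernel_preset)
  if (is.null(mf_weight)) {
    mf_weight <- if (variant == "ExpIF_PC") 38.3
                 else if (kernel_preset == "asymmetric") 21.5 else 19.15
  }
  structure(list(n_pc = as.integer(n_pc), n_pvbc = as.integer(n_pvbc),
                 variant = variant, ee_scale = ee_scale, mf_rate = mf_rate,
                 mf_weight = mf_weight, kernel_preset = kernel_preset,
                 pvbc_only_rate = pvbc_only_rate,
                 pvbc_only_weight = pvbc_only_weight),
            class = "network_config")
}

# CSR (per presynaptic neuron) edge arrays from a weight_matrix, with a
# global index offset for targets and a weight transform
wm_to_csr <- function(W, n_pre_total, pre_offset = 0L, tgt_offset = 0L,
                      w_fun = identity) {
  g <- W$graph
  e_pre <- rep(seq_len(g$n_post), diff(g$col_ptr))  # post per CSC entry
  pre <- g$row_ind + 1L                              # 1-based pre
  o <- order(pre)
  counts <- tabulate(pre, nbins = g$n_pre)
  ptr <- integer(n_pre_total + 1)
  ptr[(pre_offset + 1):(pre_offset + g$n_pre) + 1L] <- counts
  ptr <- cumsum(ptr)
  list(ptr = as.integer(ptr),
       targets = as.integer(e_pre[o] - 1L + tgt_offset),
       w = w_fun(W$w[o]))
}

graph_to_csr <- function(graph, n_pre_total, pre_offset = 0L, tgt_offset = 0L,
                         w_scalar = 1) {
  W <- new_weight_matrix(graph, rep(w_scalar, length(graph$row_ind)), Inf)
  wm_to_csr(W, n_pre_total, pre_offset, tgt_offset)
}

#' Build an offline network specification
#'
#' Assembles the neuron populations, conductance kinetics, synaptic
#' pathways (recurrent excitation from the learned weight matrix, all other
#' pathways freshly sampled with their preset probabilities) and the
#' external drive for one structural variant.
#'
#' @param config A [network_config()].
#' @param W A `weight_matrix` of recurrent PC to PC conductances (ignored by
#'   the `"PVBC_only"` variant).
#' @param seed Integer seed for the connectivity sampling (separate
#'   substreams per pathway so variants are comparable across seeds).
#' @return A `network_spec` consumed by [simulate_network()].
#' @export
build_network <- function(config, W = NULL, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  n_pc <- config$n_pc; n_pvbc <- config$n_pvbc
  base <- abs(as.integer(seed) %% 500009L) * 4001L

  syn <- list(ee = synapse_params("PC_PC"), epv = synapse_params("PC_PVBC"),
              ipc = synapse_params("PVBC_PC"), ii = synapse_params("PVBC_PVBC"),
              mf = synapse_params("GC_PC"))
  slots <- lapply(syn, function(s) list(tau_r = s$tau_r, tau_d = s$tau_d, E = s$E))
  slot_id <- stats::setNames(seq_along(slots) - 1L, names(slots))

  if (config$variant == "PVBC_only") {
    N <- n_pvbc
    params <- replicate_params(neuron_params("PVBC"), n_pvbc)
    g_ii <- sample_connectivity(n_pvbc, n_pvbc, syn$ii$p, FALSE, base + 3L)
    pathways <- list(ii = c(graph_to_csr(g_ii, N, 0L, 0L, syn$ii$ghat / syn$ii$A),
                            list(slot = slot_id[["ii"]], delay = syn$ii$delay)))
    g_drv <- sample_connectivity(n_pc, n_pvbc, syn$epv$p, TRUE, base + 4L)
    ext <- list(drive = list(n_src = n_pc, rate_hz = config$pvbc_only_rate,
                             t_on = 0, t_off = Inf,
                             ptr = graph_to_csr(g_drv, n_pc)$ptr,
                             targets = graph_to_csr(g_drv, n_pc)$targets,
                             w = config$pvbc_only_weight / syn$epv$A,
                             slot = slot_id[["epv"]]))
    ext$drive$ptr <- ext$drive$ptr[seq_len(n_pc + 1)]
    return(structure(list(config = config, N = N, n_pc = 0L, n_pvbc = n_pvbc,
                          params = params, slots = unname(slots),
                          pathways = pathways, ext = ext, seed = seed),
                     class = "network_spec"))
  }

  if (is.null(W)) stop("W is required for variants with pyramidal cells")
  if (W$graph$n_pre != n_pc || W$graph$n_post != n_pc)
    stop("W dimension mismatch: expected ", n_pc, " x ", n_pc)
  N <- n_pc + n_pvbc
  pc_preset <- if (config$variant == "ExpIF_PC") "PC_ExpIF" else "PC"
  params <- combine_params(replicate_params(neuron_params(pc_preset), n_pc),
                           replicate_params(neuron_params("PVBC"), n_pvbc))

  g_epv <- sample_connectivity(n_pc, n_pvbc, syn$epv$p, TRUE, base + 1L)
  g_ipc <- sample_connectivity(n_pvbc, n_pc, syn$ipc$p, TRUE, base + 2L)
  pathways <- list(
    ee = c(wm_to_csr(W, N, 0L, 0L, function(w) w * config$ee_scale / syn$ee$A),
           list(slot = slot_id[["ee"]], delay = syn$ee$delay)),
    epv = c(graph_to_csr(g_epv, N, 0L, n_pc, syn$epv$ghat / syn$epv$A),
            list(slot = slot_id[["epv"]], delay = syn$epv$delay)),
    ipc = c(graph_to_csr(g_ipc, N, n_pc, 0L, syn$ipc$ghat / syn$ipc$A),
            list(slot = slot_id[["ipc"]], delay = syn$ipc$delay)))
  if (config$variant != "no_PVBC_PVBC") {
    g_ii <- sample_connectivity(n_pvbc, n_pvbc, syn$ii$p, FALSE, base + 3L)
    pathways$ii <- c(graph_to_csr(g_ii, N, n_pc, n_pc, syn$ii$ghat / syn$ii$A),
                     list(slot = slot_id[["ii"]], delay = syn$ii$delay))
  }
  identity_ptr <- as.integer(0:n_pc)
  ext <- list(mf = list(n_src = n_pc, rate_hz = config$mf_rate, t_on = 0,
                        t_off = Inf, ptr = identity_ptr,
                        targets = as.integer(seq_len(n_pc) - 1L),
                        w = config$mf_weight / syn$mf$A,
                        slot = slot_id[["mf"]]))
  structure(list(config = config, N = N, n_pc = n_pc, n_pvbc = n_pvbc,
                 params = params, slots = unname(slots), pathways = pathways,
                 ext = ext, seed = seed),
            class = "network_spec")
}

replicate_params <- function(p, n) {
  fields <- c("Cm", "gL", "Vrest", "DeltaT", "vth", "theta", "Vreset",
              "tref", "tauw", "a", "b", "has_w")
  lapply(stats::setNames(fields, fields), function(f) rep(p[[f]], n))
}

combine_params <- function(p1, p2) {
  Map(c, p1, p2)
}

#' Cued-stimulation protocol
#'
#' Extra Poisson stimulation of a selected subset of pyramidal cells,
#' delivered through the mossy-fiber synapse; used to cue replay from a
#' chosen track location.
#'
#' @param cells PC indices (1-based) to stimulate.
#' @param onset,duration Stimulation window, s (default 200 ms).
#' @param rate Poisson rate per cell, Hz.
#' @param weight Peak conductance, nS; default the mossy-fiber weight.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(cells, onset = 0.05, duration = 0.2, rate = 20,
                              weight = NULL) {
  structure(list(cells = as.integer(cells), onset = onset,
                 duration = duration, rate = rate, weight = weight),
            class = "stimulus_protocol")
}

#' Simulate the offline network
#'
#' Forward-Euler integration (default dt = 0.1 ms) of the spiking network:
#' event-driven conductance increments with per-pathway delays, independent
#' mossy-fiber Poisson drive, optional cued stimulation, and recording of
#' spikes plus the separate excitatory/inhibitory synaptic currents of a
#' random subset of pyramidal cells for the LFP estimate.
#'
#' @param spec A `network_spec` from [build_network()].
#' @param duration Simulated time, s.
#' @param dt Integration step, ms.
#' @param seed Integer seed (drives the Poisson inputs and the LFP-subset
#'   sampling; the simulation is deterministic given the seed).
#' @param stimulus Optional [stimulus_protocol()].
#' @param lfp_n Number of cells whose summed synaptic currents are recorded
#'   for the LFP estimate (0 disables).
#' @param probe_cells Optional global cell indices (1-based) whose voltage
#'   and current traces are recorded.
#' @return A `simulation_result` with `spike_t` (s), `spike_cell` (1-based),
#'   population sizes, `lfp` (summed currents in pA at `fs = 1000/dt` Hz)
#'   and probe traces.
#' @export
simulate_network <- function(spec, duration, dt = 0.1, seed = 1L,
                             stimulus = NULL, lfp_n = 400,
                             probe_cells = integer(0)) {
  stopifnot(inherits(spec, "network_spec"), duration > 0, dt > 0)
  set.seed(seed)
  pop_n <- if (spec$n_pc > 0) spec$n_pc else spec$n_pvbc
  lfp_cells <- if (lfp_n > 0) sort(sample.int(pop_n, min(lfp_n, pop_n))) - 1L
               else integer(0)
  ext <- spec$ext
  if (!is.null(stimulus)) {
    stopifnot(inherits(stimulus, "stimulus_protocol"))
    mfp <- synapse_params("GC_PC")
    wstim <- (stimulus$weight %||% spec$config$mf_weight) / mfp$A
    n_stim <- length(stimulus$cells)
    ext$stim <- list(n_src = n_stim, rate_hz = stimulus$rate,
                     t_on = stimulus$onset * 1000,
                     t_off = (stimulus$onset + stimulus$duration) * 1000,
                     ptr = as.integer(0:n_stim),
                     targets = as.integer(stimulus$cells - 1L),
                     w = wstim, slot = which_mf_slot(spec))
  }
  pw <- lapply(spec$pathways, function(p) {
    list(ptr = p$ptr, targets = p$targets, w = p$w, slot = p$slot,
         delay_steps = as.integer(round(p$delay / dt)))
  })
  res <- cpp_simulate_network(spec$params, spec$slots, unname(pw),
                              unname(ext), duration * 1000, dt,
                              lfp_cells, as.integer(probe_cells - 1L), 0)
  structure(list(spike_t = res$spike_t / 1000,
                 spike_cell = res$spike_cell + 1L,
                 n_pc = spec$n_pc, n_pvbc = spec$n_pvbc,
                 duration = duration, dt = dt, seed = seed,
                 variant = spec$config$variant,
                 lfp = list(exc = res$lfp_exc, inh = res$lfp_inh,
                            fs = 1000 / dt, cells = lfp_cells + 1L),
                 probes = list(cells = as.integer(probe_cells),
                               V = res$probe_V, exc = res$probe_exc,
                               inh = res$probe_inh)),
            class = "simulation_result")
}

which_mf_slot <- function(spec) {
  # mossy-fiber kinetics slot index (0-based); slot list order is fixed
  4L
}

#' @export
print.simulation_result <- function(x, ...) {
  n_pc_spk <- sum(x$spike_cell <= x$n_pc)
  cat(sprintf(
    "simulation_result: %.1f s, variant %s; PC spikes %d (%.2f Hz), PVBC spikes %d (%.2f Hz)\n",
    x$duration, x$variant, n_pc_spk,
    if (x$n_pc) n_pc_spk / x$n_pc / x$duration else NA,
    length(x$spike_t) - n_pc_spk,
    if (x$n_pvbc) (length(x$spike_t) - n_pc_spk) / x$n_pvbc / x$duration else NA))
  invisible(x)
}

#' Simulate a single neuron with injected current
#'
#' @param params A [neuron_params()].
#' @param injected_current Current time series, pA (positive depolarizes).
#' @param dt Integration step, ms.
#' @return list with `V` (mV), `w` (pA), `spikes` (s), `dt`.
#' @export
simulate_cell <- function(params, injected_current, dt = 0.1) {
  stopifnot(inherits(params, "neuron_params"), dt > 0)
  res <- cpp_simulate_cell(params, injected_current, dt)
  list(V = res$V, w = res$w, spikes = res$spikes / 1000, dt = dt)
}

#' Population firing rate
#'
#' Spike count per time bin divided by `bin_width * population size`, in Hz.
#'
#' @param sim A `simulation_result` (or a list with `spike_t`, `spike_cell`).
#' @param bin_width Bin width, s.
#' @param population `"PC"` or `"PVBC"`.
#' @return list with `t` (bin centers, s), `rate` (Hz), `bin_width`, `n`.
#' @export
population_rate <- function(sim, bin_width = 0.02,
                            population = c("PC", "PVBC")) {
  population <- match.arg(population)
  if (population == "PC") {
    keep <- sim$spike_cell <= sim$n_pc
    n <- sim$n_pc
  } else {
    keep <- sim$spike_cell > sim$n_pc
    n <- sim$n_pvbc
  }
  if (n == 0) stop("empty population")
  edges <- seq(0, sim$duration + bin_width * 1e-9, by = bin_width)
  if (edges[length(edges)] < sim$duration - 1e-12) edges <- c(edges, sim$duration)
  tt <- sim$spike_t[keep]
  idx <- findInterval(tt, edges, left.open = TRUE)
  idx[idx == 0L] <- 1L   # a spike recorded exactly at t = 0
  idx[idx > length(edges) - 1L] <- length(edges) - 1L
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  widths <- diff(edges)
  list(t = edges[-length(edges)] + widths / 2, rate = counts / (widths * n),
       bin_width = bin_width, n = n)
}
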