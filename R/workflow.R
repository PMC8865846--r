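#' Analyze one offline simulation
#'
#' Runs the standard post-processing chain on a [simulate_network()]
#' result: event detection on the 20 ms pyramidal population rate,
#' in-event / between-event firing-rate statistics, event-restricted ripple
#' and gamma analysis of the PVBC population rate, and (optionally)
#' Bayesian decoding with constant-velocity path fitting and shuffle
#' significance for every event.
#'
#' @param sim A `simulation_result`.
#' @param map The `place_field_map` of the learned environment (needed for
#'   replay decoding; may be `NULL` with `decode = FALSE`).
#' @param decode Run replay decoding per event.
#' @param n_shuffles Identity shuffles per event.
#' @param seed Seed for the shuffles.
#' @param threshold,min_duration Event-detection parameters
#'   ([detect_high_activity()]).
#' @param max_decode_duration Cap (s) on the decoded portion of an event;
#'   replay fitting uses at most the first `max_decode_duration` of very
#'   long events (baseline events end well below it; only degenerate
#'   stationary-activity variants exceed it). Duration statistics are
#'   unaffected.
#' @return An `analysis_report` list: `events` (with replay columns when
#'   decoded), `rates` (mean/in-event/between-event PC rate, in-event PVBC
#'   rate, Hz), `min_isi_in_events` (s), `max_event_duration` (s), `ripple`
#'   and `gamma` (`spectrum_peak_test`s of the in-event PVBC rate),
#'   `ripple_pc` (same for the PC rate) and `ripple_lfp` (same for the LFP
#'   estimate, the indicator used in the scaling scans).
#' @export
analyze_simulation <- function(sim, map = NULL, decode = TRUE,
                               n_shuffles = 100, seed = 1L, threshold = 2,
                               min_duration = 0.26, max_decode_duration = 1) {
  has_pc <- sim$n_pc > 0
  pop <- if (has_pc) "PC" else "PVBC"
  rate20 <- population_rate(sim, 0.02, pop)
  events <- detect_high_activity(rate20, threshold, min_duration)
  is_pc <- sim$spike_cell <= sim$n_pc
  in_event <- rep(FALSE, length(sim$spike_t))
  for (i in seq_len(nrow(events)))
    in_event <- in_event |
      (sim$spike_t >= events$start[i] & sim$spike_t < events$end[i])
  ev_time <- sum(events$duration)
  out_time <- sim$duration - ev_time
  rates <- list(
    mean_pc = if (has_pc) sum(is_pc) / sim$n_pc / sim$duration else NA_real_,
    in_event_pc = if (has_pc && ev_time > 0)
      sum(is_pc & in_event) / sim$n_pc / ev_time else NA_real_,
    out_event_pc = if (has_pc && out_time > 0)
      sum(is_pc & !in_event) / sim$n_pc / out_time else NA_real_,
    in_event_pvbc = if (sim$n_pvbc > 0 && ev_time > 0)
      sum(!is_pc & in_event) / sim$n_pvbc / ev_time else NA_real_,
    mean_pvbc = if (sim$n_pvbc > 0)
      sum(!is_pc) / sim$n_pvbc / sim$duration else NA_real_)

  min_isi <- Inf
  if (has_pc && nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      sel <- is_pc & sim$spike_t >= events$start[i] & sim$spike_t < events$end[i]
      if (!any(sel)) next
      isis <- unlist(lapply(split(sim$spike_t[sel], sim$spike_cell[sel]), diff),
                     use.names = FALSE)
      if (length(isis)) min_isi <- min(min_isi, isis)
    }
  }

  ripple <- gamma <- ripple_pc <- ripple_lfp <- NULL
  spec_pop <- if (sim$n_pvbc > 0) "PVBC" else "PC"
  rate1k <- population_rate(sim, 0.001, spec_pop)
  ev <- if (nrow(events) > 0) events else NULL
  ba <- try(band_analysis(rate1k$rate, 1000, events = ev), silent = TRUE)
  if (!inherits(ba, "try-error")) {
    ripple <- ba$ripple
    gamma <- ba$gamma
  }
  if (has_pc && sim$n_pvbc > 0) {
    rate1k_pc <- population_rate(sim, 0.001, "PC")
    ba_pc <- try(band_analysis(rate1k_pc$rate, 1000, events = ev),
                 silent = TRUE)
    if (!inherits(ba_pc, "try-error")) ripple_pc <- ba_pc$ripple
  }
  # LFP-based ripple indicator (robust also when spiking is sparse)
  if (!is.null(sim$lfp) && length(sim$lfp$exc)) {
    lfp <- estimate_lfp(sim$lfp)
    seg <- if (is.null(ev)) 4096L else 2048L
    ba_lfp <- try(band_analysis(lfp$lfp, lfp$fs, events = ev,
                                segment_length = seg), silent = TRUE)
    if (!inherits(ba_lfp, "try-error")) ripple_lfp <- ba_lfp$ripple
  }

  if (decode && has_pc && nrow(events) > 0) {
    stopifnot(!is.null(map))
    tcm <- tuning_curve_matrix(map)
    res <- lapply(seq_len(nrow(events)), function(i) {
      dec_end <- min(events$end[i], events$start[i] + max_decode_duration)
      rt <- try(shuffle_significance(sim$spike_t, sim$spike_cell,
                                     events$start[i], dec_end, map,
                                     n_shuffles = n_shuffles,
                                     seed = seed + i, tcm = tcm),
                silent = TRUE)
      if (inherits(rt, "try-error"))
        return(data.frame(v = NA_real_, x0 = NA_real_, R = NA_real_,
                          significant = FALSE, direction = NA_character_))
      data.frame(v = rt$fit$v, x0 = rt$fit$x0, R = rt$fit$R,
                 significant = rt$significant, direction = rt$fit$direction)
    })
    events <- cbind(events, do.call(rbind, res))
  }

  structure(list(events = events, rates = rates,
                 min_isi_in_events = if (is.finite(min_isi)) min_isi else NA_real_,
                 max_event_duration = if (nrow(events)) max(events$duration)
                                      else NA_real_,
                 ripple = ripple, gamma = gamma, ripple_pc = ripple_pc,
                 ripple_lfp = ripple_lfp,
                 seed = sim$seed, variant = sim$variant,
                 duration = sim$duration),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("analysis_report (%s, seed %s): %d events", x$variant,
              x$seed, nrow(x$events)))
  if (nrow(x$events)) {
    cat(sprintf("; PC in/out %.2f/%.2f Hz, PVBC in-event %.1f Hz",
                x$rates$in_event_pc, x$rates$out_event_pc,
                x$rates$in_event_pvbc))
    if ("significant" %in% names(x$events))
      cat(sprintf("; %d significant replays (%d fwd, %d bwd)",
                  sum(x$events$significant, na.rm = TRUE),
                  sum(x$events$significant & x$events$direction == "forward",
                      na.rm = TRUE),
                  sum(x$events$significant & x$events$direction == "backward",
                      na.rm = TRUE)))
  }
  if (!is.null(x$ripple))
    cat(sprintf("; ripple: %s (%.1f Hz, p = %.3g)",
                if (x$ripple$significant) "significant" else "ns",
                x$ripple$peak_freq, x$ripple$p))
  cat("\n")
  invisible(x)
}

#' Fitness features of an offline simulation
#'
#' The six-feature multiobjective fitness used to tune the non-learned
#' synaptic weights: (1) Gaussian score of the mean pyramidal rate around
#' 2 Hz (SD 0.5 Hz); (2) indicator that the PVBC rate has no significant
#' gamma peak; (3) Gaussian score of the PC ripple peak frequency around
#' 180 Hz (SD 20 Hz); (4) twice the same score for the PVBC rate; (5) the
#' PC ripple/gamma band-power ratio clipped to \[0, 5\]; (6) twice the
#' clipped PVBC ratio. Spectral features are computed on event-restricted
#' spectra; the peak-frequency scores use the band argmax whether or not
#' the peak is significant. With no detected events the whole trace is
#' analysed, with a warning.
#'
#' @param sim A `simulation_result`.
#' @param report Optional precomputed [analyze_simulation()] report (with
#'   `decode = FALSE` is enough).
#' @return list with `f1`..`f6` and `total` (their sum).
#' @export
compute_fitness <- function(sim, report = NULL) {
  if (is.null(report)) report <- analyze_simulation(sim, decode = FALSE)
  if (nrow(report$events) == 0)
    warning("no high-activity events; fitness computed on the whole trace")
  ev <- if (nrow(report$events)) report$events else NULL
  rate_pc <- population_rate(sim, 0.001, "PC")
  rate_pv <- population_rate(sim, 0.001, "PVBC")
  ba_pc <- band_analysis(rate_pc$rate, 1000, events = ev)
  ba_pv <- band_analysis(rate_pv$rate, 1000, events = ev)
  ratio <- function(ba) {
    r <- ba$ripple$power_fraction / ba$gamma$power_fraction
    min(max(r, 0), 5)
  }
  nu <- report$rates$mean_pc
  f <- list(
    f1 = exp(-(nu - 2)^2 / (2 * 0.5^2)),
    f2 = as.numeric(!ba_pv$gamma$significant),
    f3 = exp(-(ba_pc$ripple$peak_freq - 180)^2 / (2 * 20^2)),
    f4 = 2 * exp(-(ba_pv$ripple$peak_freq - 180)^2 / (2 * 20^2)),
    f5 = ratio(ba_pc),
    f6 = 2 * ratio(ba_pv))
  f$total <- sum(unlist(f))
  f
}

#' Run the full pipeline for one experimental condition
#'
#' Exploration, learning, weight manipulation, offline simulation and
#' analysis in one call. Expensive stages can be supplied precomputed
#' (e.g. to reuse one learned weight matrix across scaling factors and
#' seeds).
#'
#' @param kernel_preset `"symmetric"` or `"asymmetric"`.
#' @param variant Structural network variant ([network_config()]).
#' @param ee_scale Recurrent-excitation scaling factor.
#' @param weight_mod `"none"`, `"binarized"` (two-group means) or
#'   `"shuffled"` (column shuffle).
#' @param sim_seeds Integer seeds; one simulation per seed.
#' @param exploration_seed Seed of the exploration / learning stage.
#' @param sim_duration Offline simulation length, s.
#' @param config [exploration_config()] of the learning stage.
#' @param stimulus Optional [stimulus_protocol()].
#' @param decode,n_shuffles Replay analysis controls.
#' @param map,spikes,W Optional precomputed stage outputs.
#' @param dt Integration step, ms.
#' @return list with the stage artifacts (`map`, `W`) and `reports`, one
#'   [analyze_simulation()] report per seed.
#' @export
run_pipeline <- function(kernel_preset = c("symmetric", "asymmetric"),
                         variant = "baseline", ee_scale = 1,
                         weight_mod = c("none", "binarized", "shuffled"),
                         sim_seeds = 1:3, exploration_seed = 42L,
                         sim_duration = 10, config = exploration_config(),
                         stimulus = NULL, decode = TRUE, n_shuffles = 100,
                         map = NULL, spikes = NULL, W = NULL, dt = 0.1) {
  kernel_preset <- match.arg(kernel_preset)
  weight_mod <- match.arg(weight_mod)
  kernel <- stdp_kernel(kernel_preset)
  if (is.null(map)) map <- assign_place_fields(config, exploration_seed)
  if (is.null(W)) {
    if (is.null(spikes)) spikes <- generate_spike_trains(map, config,
                                                         exploration_seed)
    graph <- sample_connectivity(config$n_cells, config$n_cells, 0.1,
                                 FALSE, exploration_seed)
    W <- learn_weights(spikes, graph, kernel)
  }
  W_used <- switch(weight_mod, none = W, binarized = binarize_weights(W),
                   shuffled = shuffle_postsynaptic(W, exploration_seed))
  ncfg <- network_config(n_pc = config$n_cells,
                         n_pvbc = max(2L, round(config$n_cells * 150 / 8000)),
                         variant = variant, ee_scale = ee_scale,
                         kernel_preset = kernel_preset)
  reports <- lapply(sim_seeds, function(s) {
    spec <- build_network(ncfg, W_used, seed = s)
    sim <- simulate_network(spec, sim_duration, dt = dt, seed = s,
                            stimulus = stimulus)
    analyze_simulation(sim, map, decode = decode, n_shuffles = n_shuffles,
                       seed = s)
  })
  list(map = map, W = W, W_used = W_used, kernel = kernel, reports = reports)
}

#' Learn the same connectivity in two environments sequentially
#'
#' Draws an independent place-field assignment for each environment (a
#' different overlapping random half of the cells), generates exploration
#' spike trains in both, and applies STDP sequentially: the second
#' environment's learning starts from the weights left by the first. The
#' post-learning scale is applied once, at the end of each stage's
#' returned matrix.
#'
#' @param config [exploration_config()].
#' @param kernel [stdp_kernel()].
#' @param graph `connectivity_graph` over the population.
#' @param seeds Length-2 integer vector, one seed per environment.
#' @return list with `maps` (per environment), `W1` (after environment 1)
#'   and `W2` (after both).
#' @export
learn_two_environments <- function(config, kernel, graph, seeds = c(42L, 43L)) {
  map1 <- assign_place_fields(config, seeds[1], environment_id = 1L)
  map2 <- assign_place_fields(config, seeds[2], environment_id = 2L)
  sp1 <- generate_spike_trains(map1, config, seeds[1])
  sp2 <- generate_spike_trains(map2, config, seeds[2])
  W1 <- learn_weights(sp1, graph, kernel)
  W2 <- learn_weights(sp2, graph, kernel, w_start = W1$w_raw)
  list(maps = list(map1, map2), W1 = W1, W2 = W2)
}

#' Miniature pipeline fixture
#'
#' Generates a proportionally scaled-down exploration + learning dataset
#' (cell counts, exploration duration) with all pipeline artifacts, for
#' fast tests. `scale = 1` reproduces the production sizes.
#'
#' @param scale Linear scale factor on population size and exploration
#'   duration.
#' @param seed Integer seed.
#' @param learn Run the learning stage too.
#' @return list with `config`, `map`, `spikes`, `graph`, `kernel`, `W`
#'   (the last two `NULL` unless `learn = TRUE`).
#' @export
make_fixture <- function(scale = 0.1, seed = 1L, learn = TRUE) {
  config <- exploration_config(n_cells = max(10L, round(8000 * scale)),
                               duration = max(20, 400 * scale))
  map <- assign_place_fields(config, seed)
  spikes <- generate_spike_trains(map, config, seed)
  graph <- sample_connectivity(config$n_cells, config$n_cells, 0.1, FALSE,
                               seed)
  kernel <- stdp_kernel("symmetric")
  W <- if (learn) learn_weights(spikes, graph, kernel) else NULL
  list(config = config, map = map, spikes = spikes, graph = graph,
       kernel = kernel, W = W)
}

#' Scenario configuration and execution
#'
#' Sweeps recurrent-excitation scaling grids for the named experimental
#' scenario and aggregates the per-point indicators (mean PC/PVBC rates,
#' ripple significance, peak frequency and power fraction, counts of
#' significant forward/backward replays) over simulation seeds.
#'
#' Default scaling grids per scenario: baseline 0.8-1.2, two_env 0.7-1.1,
#' binarized 0.9-1.3, shuffled 1.0-4.0, no_ii 0.8-1.6 (step 0.1; pass
#' `scale_grid` for finer scans).
#'
#' @param scenario Scenario name.
#' @param seeds Simulation seeds per grid point.
#' @param scale_grid Scaling factors; `NULL` picks the scenario default.
#' @param sim_duration Offline simulation length, s.
#' @param config [exploration_config()].
#' @param exploration_seed Learning-stage seed.
#' @param n_shuffles Shuffles per event for replay significance.
#' @param dt Integration step, ms.
#' @return An `experiment_config` (from `experiment_config()`) or, from
#'   [run_scenario()], a data.frame with one row per (scale, seed) and the
#'   aggregated indicators as attributes.
#' @export
experiment_config <- function(scenario = c("baseline", "scaling_scan",
                                           "two_env", "asym_stdp",
                                           "binarized", "shuffled", "expif",
                                           "pvbc_only", "no_ii", "cued"),
                              seeds = 1:5, scale_grid = NULL,
                              sim_duration = 10,
                              config = exploration_config(),
                              exploration_seed = 42L, n_shuffles = 100,
                              dt = 0.1) {
  scenario <- match.arg(scenario)
  if (is.null(scale_grid))
    scale_grid <- switch(scenario,
                         scaling_scan = seq(0.8, 1.2, by = 0.1),
                         two_env = seq(0.7, 1.1, by = 0.1),
                         binarized = seq(0.9, 1.3, by = 0.1),
                         shuffled = seq(1.0, 4.0, by = 0.5),
                         no_ii = seq(0.8, 1.6, by = 0.2),
                         1.0)
  structure(list(scenario = scenario, seeds = seeds, scale_grid = scale_grid,
                 sim_duration = sim_duration, config = config,
                 exploration_seed = exploration_seed,
                 n_shuffles = n_shuffles, dt = dt),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param ec An `experiment_config`.
#' @export
run_scenario <- function(ec) {
  stopifnot(inherits(ec, "experiment_config"))
  kernel_preset <- if (ec$scenario == "asym_stdp") "asymmetric" else "symmetric"
  variant <- switch(ec$scenario, expif = "ExpIF_PC", no_ii = "no_PVBC_PVBC",
                    pvbc_only = "PVBC_only", "baseline")
  weight_mod <- switch(ec$scenario, binarized = "binarized",
                       shuffled = "shuffled", "none")
  kernel <- stdp_kernel(kernel_preset)
  config <- ec$config
  if (ec$scenario == "two_env") {
    graph <- sample_connectivity(config$n_cells, config$n_cells, 0.1, FALSE,
                                 ec$exploration_seed)
    env2 <- learn_two_environments(config, kernel, graph,
                                   seeds = c(ec$exploration_seed,
                                             ec$exploration_seed + 1L))
    map <- env2$maps[[2]]
    W <- env2$W2
  } else if (variant == "PVBC_only") {
    map <- NULL
    W <- NULL
  } else {
    map <- assign_place_fields(config, ec$exploration_seed)
    spikes <- generate_spike_trains(map, config, ec$exploration_seed)
    graph <- sample_connectivity(config$n_cells, config$n_cells, 0.1, FALSE,
                                 ec$exploration_seed)
    W <- learn_weights(spikes, graph, kernel)
  }
  stim <- if (ec$scenario == "cued" && !is.null(map)) {
    ordered <- order(map$field_middle[map$has_field])
    cells <- which(map$has_field)[ordered][seq_len(100)]
    stimulus_protocol(cells)
  } else NULL

  rows <- list()
  for (sc in ec$scale_grid) {
    for (s in ec$seeds) {
      if (variant == "PVBC_only") {
        ncfg <- network_config(variant = "PVBC_only",
                               pvbc_only_rate = sc)
        spec <- build_network(ncfg, NULL, seed = s)
        sim <- simulate_network(spec, ec$sim_duration, dt = ec$dt, seed = s)
        rep <- analyze_simulation(sim, NULL, decode = FALSE)
      } else {
        W_used <- switch(weight_mod, none = W,
                         binarized = binarize_weights(W),
                         shuffled = shuffle_postsynaptic(W,
                                                         ec$exploration_seed))
        ncfg <- network_config(n_pc = config$n_cells,
                               n_pvbc = max(2L, round(config$n_cells * 150 / 8000)),
                               variant = variant, ee_scale = sc,
                               kernel_preset = kernel_preset)
        spec <- build_network(ncfg, W_used, seed = s)
        sim <- simulate_network(spec, ec$sim_duration, dt = ec$dt, seed = s,
                                stimulus = stim)
        rep <- analyze_simulation(sim, map, decode = !is.null(map),
                                  n_shuffles = ec$n_shuffles, seed = s)
      }
      has_rep <- "significant" %in% names(rep$events)
      rows[[length(rows) + 1]] <- data.frame(
        scale = sc, seed = s, n_events = nrow(rep$events),
        mean_pc = rep$rates$mean_pc, in_event_pc = rep$rates$in_event_pc,
        in_event_pvbc = rep$rates$in_event_pvbc,
        mean_pvbc = rep$rates$mean_pvbc,
        ripple_sig = if (!is.null(rep$ripple)) rep$ripple$significant else NA,
        ripple_freq = if (!is.null(rep$ripple)) rep$ripple$peak_freq else NA,
        ripple_power = if (!is.null(rep$ripple)) rep$ripple$power_fraction
                       else NA,
        lfp_ripple_sig = if (!is.null(rep$ripple_lfp))
          rep$ripple_lfp$significant else NA,
        lfp_ripple_power = if (!is.null(rep$ripple_lfp))
          rep$ripple_lfp$power_fraction else NA,
        n_replay_fwd = if (has_rep)
          sum(rep$events$significant & rep$events$direction == "forward",
              na.rm = TRUE) else NA,
        n_replay_bwd = if (has_rep)
          sum(rep$events$significant & rep$events$direction == "backward",
              na.rm = TRUE) else NA)
    }
  }
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(out[, setdiff(names(out), c("seed"))],
                          by = list(scale = out$scale),
                          FUN = function(v) mean(as.numeric(v), na.rm = TRUE))
  attr(out, "aggregated") <- agg
  attr(out, "scenario") <- ec$scenario
  out
}

#' Serialize an analysis report to JSON
#'
#' @param report An [analyze_simulation()] report (or any list of plain
#'   values / data.frames).
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  cleaned <- rapply(unclass(report), function(x) x, how = "replace")
  jsonlite::write_json(cleaned, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  invisible(path)
}
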