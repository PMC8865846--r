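#' Configuration of the simulated exploration stage
#'
#' Bundles the parameters of the linear-track exploration model that
#' generates the "teaching" spike trains: a population of cells runs along a
#' linear track at constant speed, half of them with Gaussian place fields,
#' their firing modulated by the theta rhythm with phase precession.
#'
#' @param track_length Track length in m.
#' @param run_speed Constant running speed in m/s.
#' @param theta_freq Theta modulation frequency in Hz.
#' @param lambda_max Maximum in-field firing rate in Hz.
#' @param baseline_rate Constant rate of cells without a place field, Hz.
#' @param place_field_length Place-field length in m (start to end).
#' @param field_edge_fraction Fraction of the peak rate that defines the
#'   field edges; sets the common tuning-curve width `sigma` through
#'   `exp(-(l_PF/2)^2 / (2 sigma^2)) = field_edge_fraction`.
#' @param refractory Absolute refractory period of the generated spike
#'   trains, in s. Spikes closer than this to the previous accepted spike are
#'   always rejected.
#' @param duration Duration of the exploration phase in s.
#' @param n_cells Number of cells.
#' @param place_cell_fraction Fraction of cells that receive a place field.
#'
#' @return An object of class `exploration_config`.
#' @export
exploration_config <- function(track_length = 3, run_speed = 0.325,
                               theta_freq = 7, lambda_max = 20,
                               baseline_rate = 0.1, place_field_length = 0.3,
                               field_edge_fraction = 0.1, refractory = 0.005,
                               duration = 400, n_cells = 8000,
                               place_cell_fraction = 0.5) {
  stopifnot(track_length > 0, run_speed > 0, theta_freq > 0, lambda_max > 0,
            baseline_rate > 0, place_field_length > 0, refractory > 0,
            duration > 0, n_cells >= 1,
            place_cell_fraction >= 0, place_cell_fraction <= 1,
            field_edge_fraction > 0, field_edge_fraction < 1,
            place_field_length < track_length)
  structure(list(track_length = track_length, run_speed = run_speed,
                 theta_freq = theta_freq, lambda_max = lambda_max,
                 baseline_rate = baseline_rate,
                 place_field_length = place_field_length,
                 field_edge_fraction = field_edge_fraction,
                 refractory = refractory, duration = duration,
                 n_cells = as.integer(n_cells),
                 place_cell_fraction = place_cell_fraction),
            class = "exploration_config")
}

#' Tuning-curve width from the field-edge definition
#'
#' Solves `exp(-(l_PF/2)^2 / (2 sigma^2)) = edge_fraction` for `sigma`; all
#' place cells share this width.
#'
#' @param config An [exploration_config()].
#' @return sigma in m.
#' @export
tuning_sigma <- function(config) {
  (config$place_field_length / 2) / sqrt(-2 * log(config$field_edge_fraction))
}

#' Randomly assign place fields on the track
#'
#' Exactly `round(n_cells * place_cell_fraction)` cells receive a place
#' field, with field middles drawn independently and uniformly along the
#' track. Fields extending past the track edges are truncated by the track
#' (the track is linear, with a teleport back to the start, so there is no
#' circular wrap-around). The remaining cells fire at the spatially uniform
#' baseline rate.
#'
#' @param config An [exploration_config()].
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @param environment_id Label stored with the map, used when several
#'   environments are learned in sequence.
#' @return A `place_field_map`: list with logical `has_field`, numeric
#'   `field_middle` (m, `NA` for non-place cells), `field_start`
#'   (`field_middle - l_PF/2`), shared `sigma`, and the config.
#' @export
assign_place_fields <- function(config, seed, environment_id = 1L) {
  stopifnot(inherits(config, "exploration_config"))
  n <- config$n_cells
  n_field <- round(n * config$place_cell_fraction)
  set.seed(seed)
  idx <- sort(sample.int(n, n_field))
  middle <- rep(NA_real_, n)
  middle[idx] <- runif(n_field, 0, config$track_length)
  has_field <- logical(n)
  has_field[idx] <- TRUE
  structure(list(has_field = has_field, field_middle = middle,
                 field_start = middle - config$place_field_length / 2,
                 sigma = tuning_sigma(config), seed = seed,
                 environment_id = environment_id, config = config),
            class = "place_field_map")
}

#' @export
print.place_field_map <- function(x, ...) {
  cat("place_field_map:", sum(x$has_field), "place cells /",
      length(x$has_field), "cells,",
      sprintf("sigma = %.4f m, environment %s\n", x$sigma, x$environment_id))
  invisible(x)
}

#' Position on the track at a given time
#'
#' The animal runs at constant speed and is teleported back to the start on
#' reaching the end, giving a sawtooth trajectory
#' `x(t) = (run_speed * t) mod track_length`.
#'
#' @param t Time(s) in s, non-negative.
#' @param config An [exploration_config()].
#' @return Position(s) in m.
#' @export
position_at_time <- function(t, config) {
  if (any(t < 0)) stop("t must be non-negative")
  (config$run_speed * t) %% config$track_length
}

#' Spatial tuning curves
#'
#' Gaussian tuning `tau_i(x) = exp(-(x - m_i)^2 / (2 sigma^2))`, the spatial
#' factor of the firing-rate model; dimensionless with peak 1 at the field
#' middle. Non-place cells return 0.
#'
#' @param x Positions in m (vector).
#' @param cell Cell index.
#' @param map A `place_field_map`.
#' @return Tuning value(s) in \[0, 1\].
#' @export
tuning_curve <- function(x, cell, map) {
  if (!map$has_field[cell]) return(rep(0, length(x)))
  exp(-(x - map$field_middle[cell])^2 / (2 * map$sigma^2))
}

#' Instantaneous firing rate of a cell during exploration
#'
#' For place cells, the rate is the product of the spatial tuning curve, the
#' theta modulation and the phase-precession offset,
#' `lambda_i(t) = lambda_max * tau_i(x(t)) *
#'   cos(2 pi f_theta t + (pi / l_PF) (x(t) - s_i))`,
#' with negative values clipped to zero so it can serve as an acceptance
#' probability for thinning. The spatial offset advances the preferred theta
#' phase by 180 degrees across the field. Non-place cells fire at the
#' constant baseline rate (no theta modulation).
#'
#' @param cell Cell index.
#' @param t Time(s) in s.
#' @param map A `place_field_map`.
#' @param config An [exploration_config()]; defaults to the one in `map`.
#' @return Rate(s) in Hz.
#' @export
instantaneous_rate <- function(cell, t, map, config = map$config) {
  if (!map$has_field[cell]) return(rep(config$baseline_rate, length(t)))
  x <- position_at_time(t, config)
  lam <- config$lambda_max * tuning_curve(x, cell, map) *
    cos(2 * pi * config$theta_freq * t +
          pi / config$place_field_length * (x - map$field_start[cell]))
  pmax(lam, 0)
}

# deterministic per-cell substream seed (independent streams per cell so a
# subset of cells is reproducible regardless of the other cells)
cell_seed <- function(seed, cell) {
  (abs(as.integer(seed) %% 1000003L) * 2011L + cell * 7L) %% 2147483647L
}

#' Generate exploration spike trains
#'
#' Place cells are simulated as inhomogeneous Poisson processes by thinning:
#' a homogeneous Poisson proposal at `lambda_max` is accept-reject sampled
#' with acceptance probability `lambda_i(t) / lambda_max`. Non-place cells
#' are homogeneous Poisson at the baseline rate. In both cases, spikes within
#' the refractory period of the previously accepted spike are always
#' rejected. Each cell uses an independent random substream derived from
#' `seed`, so the set is deterministic given the seed and stable under
#' subsetting.
#'
#' @param map A `place_field_map`.
#' @param config An [exploration_config()]; defaults to the one in `map`.
#' @param seed Integer seed.
#' @return A `spike_train_set`: list with `spikes` (list of strictly
#'   increasing spike-time vectors, s), `duration`, `seed`,
#'   `environment_id`, `n_cells`.
#' @export
generate_spike_trains <- function(map, config = map$config, seed = 1L) {
  n <- config$n_cells
  spikes <- vector("list", n)
  dur <- config$duration
  for (cell in seq_len(n)) {
    set.seed(cell_seed(seed, cell))
    if (map$has_field[cell]) {
      n_prop <- ceiling(config$lambda_max * dur + 10 * sqrt(config$lambda_max * dur))
      prop <- cumsum(rexp(n_prop, config$lambda_max))
      while (prop[length(prop)] < dur)  # top up in the rare short draw
        prop <- c(prop, prop[length(prop)] + cumsum(rexp(1000, config$lambda_max)))
      prop <- prop[prop <= dur]
      acc <- instantaneous_rate(cell, prop, map, config) / config$lambda_max
      kept <- prop[runif(length(prop)) < acc]
    } else {
      n_prop <- ceiling(config$baseline_rate * dur + 10 * sqrt(config$baseline_rate * dur) + 5)
      prop <- cumsum(rexp(n_prop, config$baseline_rate))
      kept <- prop[prop <= dur]
    }
    spikes[[cell]] <- cpp_refractory_filter(kept, config$refractory)
  }
  structure(list(spikes = spikes, duration = dur, seed = seed,
                 environment_id = map$environment_id, n_cells = n),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  ns <- lengths(x$spikes)
  cat("spike_train_set:", x$n_cells, "cells,", sum(ns), "spikes over",
      x$duration, "s (mean rate", sprintf("%.3f Hz)\n", mean(ns) / x$duration))
  invisible(x)
}

#' Write / read spike trains as two-column text
#'
#' Plain-text exchange format: one row per spike, columns `cell` (1-based)
#' and `t` (s), sorted by time.
#'
#' @param x A `spike_train_set`.
#' @param path File path.
#' @export
write_spike_trains <- function(x, path) {
  cell <- rep(seq_len(x$n_cells), lengths(x$spikes))
  t <- unlist(x$spikes, use.names = FALSE)
  o <- order(t, cell)
  df <- data.frame(cell = cell[o], t = t[o])
  write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_spike_trains
#' @param n_cells Number of cells (cells with no spikes are kept as empty
#'   trains).
#' @param duration,seed,environment_id Metadata to attach.
#' @export
read_spike_trains <- function(path, n_cells, duration, seed = NA_integer_,
                              environment_id = 1L) {
  df <- read.table(path, header = TRUE)
  spikes <- split(df$t, factor(df$cell, levels = seq_len(n_cells)))
  spikes <- lapply(spikes, function(v) sort(as.numeric(v)))
  structure(list(spikes = spikes, duration = duration, seed = seed,
                 environment_id = environment_id, n_cells = n_cells),
            class = "spike_train_set")
}
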