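#' Detect high-activity (sharp-wave) periods
#'
#' Candidate replay events are maximal runs of consecutive population-rate
#' bins strictly above the threshold, kept when the run is at least
#' `min_duration` long. Runs separated by even a single sub-threshold bin
#' are not merged.
#'
#' @param rate A rate series from [population_rate()] (20 ms bins), or a
#'   list with `t`, `rate`, `bin_width`.
#' @param threshold Rate threshold, Hz.
#' @param min_duration Minimum event duration, s.
#' @return data.frame with `start`, `end`, `duration` (s), one row per
#'   event.
#' @export
detect_high_activity <- function(rate, threshold = 2, min_duration = 0.26) {
  above <- rate$rate > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * rate$bin_width >= min_duration - 1e-12)
  bw <- rate$bin_width
  out <- data.frame(start = (starts[keep] - 1L) * bw, end = ends[keep] * bw)
  out$duration <- out$end - out$start
  out
}

#' Tuning-curve matrix for decoding
#'
#' Evaluates the Gaussian tuning curves of all place cells at the decoding
#' bin centres, floored at a tiny rate so likelihoods stay finite when a
#' cell spikes far outside its field.
#'
#' @param map A `place_field_map`.
#' @param n_bins Number of position bins over the track.
#' @param rate_floor Lower floor on the tuning value.
#' @return list with `tau` (place cells x position bins), `centers` (m),
#'   `bin_width` (m), `cells` (indices of the place cells).
#' @export
tuning_curve_matrix <- function(map, n_bins = 50, rate_floor = 1e-10) {
  L <- map$config$track_length
  bw <- L / n_bins
  centers <- (seq_len(n_bins) - 0.5) * bw
  cells <- which(map$has_field)
  tau <- outer(map$field_middle[cells], centers,
               function(m, x) exp(-(x - m)^2 / (2 * map$sigma^2)))
  tau[tau < rate_floor] <- rate_floor
  list(tau = tau, centers = centers, bin_width = bw, cells = cells)
}

#' Memoryless Bayesian place decoding of an event
#'
#' Decodes the position in nonoverlapping `delta_t` bins from the spikes of
#' the place cells, under independent Poisson likelihoods with the same
#' tuning curves used to generate the exploration spike trains:
#' `log Pr(spikes | x) = sum_i n_i log(delta_t tau_i(x)) - delta_t sum_i
#' tau_i(x)` (the `log(n_i!)` term is constant per time bin and cancels
#' under normalization). Each posterior column is normalized to 1 over the
#' position bins.
#'
#' @param spike_t,spike_cell Spike times (s) and 1-based cell indices (the
#'   whole simulation may be passed; only spikes inside the window and from
#'   place cells are used).
#' @param t_start,t_end Event window, s.
#' @param map A `place_field_map` (decoding environment).
#' @param delta_t Time bin, s.
#' @param n_bins Number of position bins.
#' @param tcm Optional precomputed [tuning_curve_matrix()] for `map`.
#' @return A `posterior_matrix`: list with `P` (position bins x time bins,
#'   columns sum to 1), `counts` (active cells x time bins), `active_cells`,
#'   `centers`, `bin_width`, `delta_t`, `t_start`, `n_time`.
#' @export
decode_posterior <- function(spike_t, spike_cell, t_start, t_end, map,
                             delta_t = 0.01, n_bins = 50, tcm = NULL) {
  n_time <- floor((t_end - t_start) / delta_t + 1e-9)
  if (n_time < 1) stop("empty event")
  if (is.null(tcm)) tcm <- tuning_curve_matrix(map, n_bins)
  keep <- spike_t >= t_start & spike_t < t_start + n_time * delta_t &
    map$has_field[spike_cell]
  st <- spike_t[keep]
  sc <- spike_cell[keep]
  tb <- pmin(floor((st - t_start) / delta_t) + 1L, n_time)
  cell_pos <- match(sc, tcm$cells)
  active <- sort(unique(cell_pos))
  counts <- matrix(0L, length(active), n_time)
  if (length(st)) {
    ij <- cbind(match(cell_pos, active), tb)
    for (k in seq_len(nrow(ij)))
      counts[ij[k, 1], ij[k, 2]] <- counts[ij[k, 1], ij[k, 2]] + 1L
  }
  occupancy <- delta_t * colSums(tcm$tau)     # same for every time bin
  loglik <- crossprod_counts(counts, log(delta_t * tcm$tau[active, , drop = FALSE])) -
    matrix(occupancy, n_time, length(occupancy), byrow = TRUE)
  P <- apply(loglik, 1, function(l) {
    l <- l - max(l)
    e <- exp(l)
    e / sum(e)
  })
  structure(list(P = matrix(P, ncol = n_time), counts = counts,
                 active_cells = tcm$cells[active], centers = tcm$centers,
                 bin_width = tcm$bin_width, delta_t = delta_t,
                 t_start = t_start, n_time = n_time),
            class = "posterior_matrix")
}

crossprod_counts <- function(counts, logtau) {
  if (nrow(counts) == 0) return(matrix(0, ncol(counts), ncol(logtau)))
  t(counts) %*% logtau
}

#' Constant-velocity path fit on a posterior matrix
#'
#' Exhaustive search over candidate constant-velocity trajectories
#' `x(k) = x0 + v k delta_t`: the score `R(v, x0)` is the average posterior
#' probability mass within `d` of the trajectory across the event's time
#' bins. The scan covers `v` in \[-18, 18\] m/s in 0.3 m/s steps (slow
#' trajectories with `|v| <= 0.3` excluded) and `x0` in \[-1.5, 4.5\] m in
#' 3 cm steps; positions outside the track carry no posterior mass, the
#' intercept range extends beyond it only so bands can enter and leave.
#' Ties are broken deterministically towards the smallest `|v|`, then the
#' smallest `x0`.
#'
#' @param posterior A `posterior_matrix`.
#' @param d Band half-width, m.
#' @param v_range,v_step,v_exclude Velocity scan range, step and excluded
#'   slow band (m/s).
#' @param x0_range,x0_step Intercept scan, m.
#' @return A `path_fit`: list with `v` (m/s), `x0` (m), `R`, `d`,
#'   `direction` (`"forward"` or `"backward"`), `n_time`.
#' @export
fit_linear_path <- function(posterior, d = 0.18,
                            v_range = c(-18, 18), v_step = 0.3,
                            v_exclude = 0.3,
                            x0_range = c(-1.5, 4.5), x0_step = 0.03) {
  vs <- seq(v_range[1], v_range[2], by = v_step)
  vs <- vs[abs(vs) > v_exclude + 1e-9]
  x0s <- seq(x0_range[1], x0_range[2], by = x0_step)
  n <- posterior$n_time
  bw <- posterior$bin_width
  n_pos <- length(posterior$centers)
  Pc <- rbind(0, apply(posterior$P, 2, cumsum))      # (n_pos + 1) x n
  tk <- (seq_len(n) - 1) * posterior$delta_t
  # order candidates by |v| then x0 so the first maximum wins ties
  grid <- expand.grid(x0 = x0s, v = vs)
  grid <- grid[order(abs(grid$v), grid$x0, grid$v), ]
  ctr <- outer(grid$v, tk) + grid$x0                  # combos x n
  eps <- 1e-9
  lo <- pmax(ceiling((ctr - d) / bw + 0.5 - eps), 1)
  hi <- pmin(floor((ctr + d) / bw + 0.5 + eps), n_pos)
  valid <- lo <= hi
  lo[!valid] <- 1
  hi[!valid] <- 0
  colidx <- matrix(rep(seq_len(n), each = nrow(grid)), nrow(grid), n)
  mass <- matrix(0, nrow(grid), n)
  mass[valid] <- Pc[cbind(hi[valid] + 1L, colidx[valid])] -
    Pc[cbind(lo[valid], colidx[valid])]
  R <- rowMeans(mass)
  best <- which.max(R)
  v <- grid$v[best]
  structure(list(v = v, x0 = grid$x0[best], R = R[best], d = d,
                 direction = if (v > 0) "forward" else "backward",
                 n_time = n),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("path_fit: v = %.2f m/s (%s), x0 = %.2f m, R = %.3f over %d bins\n",
              x$v, x$direction, x$x0, x$R, x$n_time))
  invisible(x)
}

#' Replay significance by cell-identity shuffling
#'
#' Compares the best constant-velocity fit of the true event against the
#' distribution of best fits after shuffling the identities of the cells
#' active in the event (permuting which tuning curve each active cell
#' carries; spike times and counts are untouched). The event is a
#' significant replay when its `R_max` exceeds the 95th percentile of its
#' own shuffled distribution.
#'
#' @inheritParams decode_posterior
#' @param n_shuffles Number of identity shuffles.
#' @param alpha Significance level (compared at the `1 - alpha` percentile).
#' @param seed Integer seed for the shuffles.
#' @param ... Passed to [fit_linear_path()].
#' @return list with `significant`, `fit` (the true [fit_linear_path()]),
#'   `R_shuffled` (vector), `p_rank` (fraction of shuffles with
#'   `R >= R_max`), `posterior`.
#' @export
shuffle_significance <- function(spike_t, spike_cell, t_start, t_end, map,
                                 delta_t = 0.01, n_bins = 50,
                                 n_shuffles = 100, alpha = 0.05, seed = 1L,
                                 tcm = NULL, ...) {
  if (is.null(tcm)) tcm <- tuning_curve_matrix(map, n_bins)
  post <- decode_posterior(spike_t, spike_cell, t_start, t_end, map,
                           delta_t, n_bins, tcm)
  n_active <- length(post$active_cells)
  if (n_active < 2) stop("fewer than 2 active cells in event")
  fit <- fit_linear_path(post, ...)
  act_rows <- match(post$active_cells, tcm$cells)
  occupancy <- delta_t * colSums(tcm$tau)
  logtau <- log(delta_t * tcm$tau)
  set.seed(seed)
  R_shuf <- vapply(seq_len(n_shuffles), function(s) {
    perm <- sample.int(n_active)
    ll <- crossprod_counts(post$counts, logtau[act_rows[perm], , drop = FALSE]) -
      matrix(occupancy, post$n_time, length(occupancy), byrow = TRUE)
    P <- apply(ll, 1, function(l) {
      l <- l - max(l)
      e <- exp(l)
      e / sum(e)
    })
    p2 <- post
    p2$P <- matrix(P, ncol = post$n_time)
    fit_linear_path(p2, ...)$R
  }, numeric(1))
  structure(list(significant = fit$R > quantile(R_shuf, 1 - alpha,
                                                names = FALSE),
                 fit = fit, R_shuffled = R_shuf,
                 p_rank = mean(R_shuf >= fit$R), posterior = post),
            class = "replay_test")
}

#' @export
print.replay_test <- function(x, ...) {
  cat(sprintf("replay_test: R = %.3f vs shuffle 95th pct %.3f -> %s (%s, v = %.2f m/s)\n",
              x$fit$R, quantile(x$R_shuffled, 0.95, names = FALSE),
              if (x$significant) "significant replay" else "not significant",
              x$fit$direction, x$fit$v))
  invisible(x)
}

#' Decoded step-size analysis
#'
#' Estimates the decoded position in each time bin as the posterior-weighted
#' average, takes successive differences as the observed step sizes, and
#' builds the per-event constant-step prediction from the ratio of the
#' replayed path length to the event duration.
#'
#' @param posterior A `posterior_matrix`.
#' @return list with `positions` (m), `observed` (m per time bin),
#'   `predicted` (constant step, same length).
#' @export
step_size_analysis <- function(posterior) {
  xhat <- colSums(posterior$P * posterior$centers)
  steps <- diff(xhat)
  n_steps <- max(1L, posterior$n_time - 1L)
  path_len <- abs(xhat[posterior$n_time] - xhat[1])
  list(positions = xhat, observed = steps,
       predicted = rep(path_len / n_steps, length(steps)))
}
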