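# Independent oracles used to validate the optimized implementations.

# Explicit O(n^2) all-to-all pairwise STDP double sum for a single edge
# (no clipping). Times in ms; returns the final weight in nS.
stdp_pairwise_oracle <- function(pre_ms, post_ms, kernel, w_init = kernel$w_init) {
  dw <- 0
  for (tp in pre_ms) for (tq in post_ms) {
    d <- tq - tp
    dw <- dw + if (d > 0) kernel$A_plus * exp(-d / kernel$tau_plus)
    else if (d < 0) kernel$A_minus * exp(d / kernel$tau_minus)
    else kernel$A_plus
  }
  w_init + dw * kernel$unit_scale
}

# Brute-force Bayesian decoder: direct product of Poisson pmfs over all
# place cells, normalized per time bin.
decode_oracle <- function(counts_full, tau, delta_t) {
  # counts_full: place cells x time bins; tau: place cells x position bins
  n_time <- ncol(counts_full)
  n_pos <- ncol(tau)
  P <- matrix(0, n_pos, n_time)
  for (k in seq_len(n_time)) {
    lik <- vapply(seq_len(n_pos), function(j) {
      prod(stats::dpois(counts_full[, k], delta_t * tau[, j]))
    }, numeric(1))
    P[, k] <- lik / sum(lik)
  }
  P
}

# Independent band-score evaluation for a single (v, x0) candidate:
# plain per-bin masking, no cumulative sums.
band_score_oracle <- function(posterior, v, x0, d = 0.18) {
  n <- posterior$n_time
  tk <- (seq_len(n) - 1) * posterior$delta_t
  mean(vapply(seq_len(n), function(k) {
    ctr <- x0 + v * tk[k]
    sel <- abs(posterior$centers - ctr) <= d + 1e-9
    sum(posterior$P[sel, k])
  }, numeric(1)))
}

# Small deterministic spike_train_set builder for plasticity tests.
make_spike_set <- function(spike_list, duration = 10) {
  structure(list(spikes = lapply(spike_list, as.numeric),
                 duration = duration, seed = NA_integer_,
                 environment_id = 1L, n_cells = length(spike_list)),
            class = "spike_train_set")
}

# Dense-matrix view of a weight_matrix for small tests.
wm_dense <- function(W) {
  as.matrix(swrnet::as_sparse_matrix(W))
}

# Two-cell fully-connected graph helper (edge 1->2 and 2->1).
two_cell_graph <- function() {
  swrnet::sample_connectivity(2, 2, 1, allow_self = FALSE, seed = 1)
}

# miniature all-place-cell environment for decoding tests
local_map <- function(n_cells = 120, seed = 8) {
  cfg <- swrnet::exploration_config(n_cells = n_cells,
                                    place_cell_fraction = 1, duration = 20)
  swrnet::assign_place_fields(cfg, seed)
}

# spikes along a known constant-velocity trajectory: each cell fires
# Poisson spikes while the trajectory crosses its field
trajectory_spikes <- function(map, v, x0, t_end, rate = 60, seed = 1) {
  set.seed(seed)
  st <- numeric(0); sc <- integer(0)
  tt <- seq(0, t_end, by = 1e-3)
  x <- x0 + v * tt
  for (cell in which(map$has_field)) {
    lam <- rate * exp(-(x - map$field_middle[cell])^2 / (2 * map$sigma^2))
    fire <- stats::runif(length(tt)) < lam * 1e-3
    st <- c(st, tt[fire]); sc <- c(sc, rep(cell, sum(fire)))
  }
  o <- order(st)
  list(t = st[o], cell = sc[o])
}
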