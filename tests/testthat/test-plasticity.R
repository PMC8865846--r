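test_that("STDP kernel presets carry the measured parameters and evaluate correctly", {
  sym <- stdp_kernel("symmetric")
  expect_equal(c(sym$A_plus, sym$A_minus, sym$tau_plus, sym$w_max),
               c(80, 80, 62.5, 20))
  asym <- stdp_kernel("asymmetric")
  expect_equal(c(asym$A_plus, asym$A_minus, asym$tau_plus, asym$w_max),
               c(400, -400, 20, 40))
  # direct evaluation of the two branches
  expect_equal(stdp_weight_change(62.5, sym), 80 * exp(-1))
  expect_equal(stdp_weight_change(10, sym), stdp_weight_change(-10, sym))
  expect_equal(stdp_weight_change(-20, asym), -400 * exp(-1))
  expect_equal(stdp_weight_change(0, sym), sym$A_plus)
})

test_that("connectivity sampling respects probability, self-edges and determinism", {
  g0 <- sample_connectivity(50, 50, 0, seed = 1)
  expect_equal(length(g0$row_ind), 0)
  g1 <- sample_connectivity(20, 20, 1, allow_self = FALSE, seed = 1)
  expect_equal(length(g1$row_ind), 20 * 19)        # complete digraph minus diagonal
  e <- graph_edges(g1)
  expect_true(all(e$pre != e$post))
  # binomial edge count within 3 SD
  n <- 300; p <- 0.1
  g <- sample_connectivity(n, n, p, seed = 2)
  mu <- p * n * (n - 1)
  expect_lt(abs(length(g$row_ind) - mu), 3 * sqrt(mu * (1 - p)))
  expect_identical(sample_connectivity(30, 30, 0.2, seed = 9),
                   sample_connectivity(30, 30, 0.2, seed = 9))
  expect_error(sample_connectivity(10, 10, 1.2), "probability")
})

test_that("trace-based learning equals the explicit pairwise double sum", {
  g <- two_cell_graph()
  # the 1 pA == 1e-3 nS mapping convention makes the hand example exact
  k <- stdp_kernel("symmetric", unit_scale = 1e-3)
  # hand example: pre at 100 ms, post at 110 ms; both edges potentiate
  sp <- make_spike_set(list(0.100, 0.110))
  W <- learn_weights(sp, g, k, scale = 1)
  dense <- wm_dense(W)
  expect_equal(dense[1, 2], 0.1 + 0.08 * exp(-10 / 62.5), tolerance = 1e-12)
  expect_equal(dense[2, 1], dense[1, 2])
  # same spikes, asymmetric kernel: forward potentiated, reverse floored at 0
  ka <- stdp_kernel("asymmetric", unit_scale = 1e-3)
  Wa <- learn_weights(sp, g, ka, scale = 1)
  da <- wm_dense(Wa)
  expect_equal(da[1, 2], 0.1 + 0.4 * exp(-10 / 20), tolerance = 1e-12)
  expect_equal(da[2, 1], 0)
  # random multi-spike trains vs the O(n^2) oracle (no clipping regime)
  for (seed in 1:5) {
    set.seed(seed)
    t1 <- sort(runif(40, 0, 5)); t2 <- sort(runif(35, 0, 5))
    sp <- make_spike_set(list(t1, t2), duration = 5)
    for (kern in list(k, ka)) {
      W <- learn_weights(sp, g, kern, scale = 1)
      d <- wm_dense(W)
      o12 <- stdp_pairwise_oracle(t1 * 1000, t2 * 1000, kern)
      o21 <- stdp_pairwise_oracle(t2 * 1000, t1 * 1000, kern)
      if (o12 > 0 && o12 < kern$w_max && o21 > 0 && o21 < kern$w_max &&
          kern$preset == "symmetric") {
        expect_equal(d[1, 2], o12, tolerance = 1e-9)
        expect_equal(d[2, 1], o21, tolerance = 1e-9)
      }
    }
  }
})

test_that("learning respects bounds, diagonal, silence and the online clip", {
  k <- stdp_kernel("symmetric")
  g <- sample_connectivity(6, 6, 1, allow_self = FALSE, seed = 1)
  # silent network: weights stay at w_init (times scale)
  sp0 <- make_spike_set(rep(list(numeric(0)), 6))
  W0 <- learn_weights(sp0, g, k)
  expect_true(all(W0$w == k$w_init * k$scale))
  # heavy coincident firing saturates at w_max but never exceeds it
  trains <- lapply(1:6, function(i) seq(0.01 * i, 20, by = 0.05))
  sp <- make_spike_set(trains, duration = 20)
  W <- learn_weights(sp, g, k, scale = 1)
  expect_true(all(W$w >= 0 & W$w <= k$w_max + 1e-12))
  expect_gt(max(W$w), 0.9 * k$w_max)
  # depression with the asymmetric kernel cannot push weights below 0
  ka <- stdp_kernel("asymmetric")
  Wa <- learn_weights(sp, g, ka, scale = 1)
  expect_true(all(Wa$w >= 0 & Wa$w <= ka$w_max + 1e-12))
})

test_that("symmetric kernel on symmetric activity gives statistically symmetric weights", {
  cfg <- exploration_config(n_cells = 80, duration = 80)
  map <- assign_place_fields(cfg, seed = 4)
  sp <- generate_spike_trains(map, cfg, seed = 4)
  g <- sample_connectivity(80, 80, 1, allow_self = FALSE, seed = 4)
  W <- wm_dense(learn_weights(sp, g, stdp_kernel("symmetric"), scale = 1))
  up <- W[upper.tri(W)]; lo <- t(W)[upper.tri(W)]
  learned <- up > 0.1 | lo > 0.1
  expect_gt(cor(up[learned], lo[learned]), 0.8)
  expect_lt(abs(mean(up - lo)), 0.02 * mean(W[W > 0.1]))
  # asymmetric kernel on unidirectional runs: forward edges beat reverse
  Wa <- wm_dense(learn_weights(sp, g, stdp_kernel("asymmetric"), scale = 1))
  m <- map$field_middle
  fwd <- outer(m, m, function(a, b) b - a)   # pre fields earlier than post
  sel <- !is.na(fwd) & abs(fwd) < 0.3 & abs(fwd) > 0.02
  diag(sel) <- FALSE
  expect_gt(mean(Wa[sel & fwd > 0]), mean(Wa[sel & fwd < 0]))
})

test_that("weight manipulations: scaling, binarization, column shuffling", {
  set.seed(10)
  g <- sample_connectivity(40, 40, 0.3, seed = 10)
  W <- swrnet:::new_weight_matrix(g, runif(length(g$row_ind), 0, 2), 20)
  # scaling is elementwise and linear
  expect_equal(scale_weights(W, 1)$w, W$w)
  expect_equal(scale_weights(W, 0)$w, rep(0, length(W$w)))
  expect_equal(mean(scale_weights(W, 1.05)$w), 1.05 * mean(W$w))
  # binarization: two-group means on the 1..100 example
  g100 <- sample_connectivity(101, 101, 0.0099, seed = 3)
  n_e <- length(g100$row_ind)      # ~100 edges at this seed
  Wb <- swrnet:::new_weight_matrix(g100, seq_len(n_e), 200)
  Bb <- binarize_weights(Wb, 0.03)
  n_top <- sum(Bb$w == max(Bb$w))
  expect_equal(sort(unique(Bb$w)),
               c(mean(seq_len(n_e - n_top)),
                 mean(seq(n_e - n_top + 1, n_e))))
  expect_equal(sum(Bb$w), sum(Wb$w))            # total weight preserved
  W_eq <- swrnet:::new_weight_matrix(g, rep(1, length(g$row_ind)), 20)
  expect_equal(binarize_weights(W_eq)$w, W_eq$w) # all-equal is unchanged
  B <- binarize_weights(W)
  expect_equal(sum(B$w), sum(W$w), tolerance = 1e-12)
  expect_equal(length(unique(B$w[B$w > 0])), 2)
  # column shuffle: global weight histogram preserved up to zeroed diagonal
  S <- shuffle_postsynaptic(W, seed = 5)
  d1 <- wm_dense(W); d2 <- wm_dense(S)
  expect_true(all(diag(d2) == 0))
  expect_gte(sum(d1 > 0), sum(d2 > 0))   # only diagonal hits are lost
  v1 <- sort(d1[d1 > 0]); v2 <- sort(d2[d2 > 0])
  expect_true(all(v2 %in% v1))
  # every shuffled column is some original column with its diagonal zeroed
  keys1 <- apply(d1, 2, function(cl) paste(round(sort(cl[cl > 0]), 9),
                                           collapse = ","))
  ok <- vapply(seq_len(ncol(d2)), function(j) {
    cl <- d2[, j]
    key <- paste(round(sort(cl[cl > 0]), 9), collapse = ",")
    key %in% keys1 ||
      any(vapply(seq_len(ncol(d1)), function(jj) {
        cl1 <- d1[, jj]; cl1[j] <- 0
        paste(round(sort(cl1[cl1 > 0]), 9), collapse = ",") == key
      }, logical(1)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("sequential learning of two environments strengthens mean weights", {
  cfg <- exploration_config(n_cells = 60, duration = 60)
  k <- stdp_kernel("symmetric")
  g <- sample_connectivity(60, 60, 0.3, seed = 2)
  res <- learn_two_environments(cfg, k, g, seeds = c(2L, 3L))
  expect_gt(mean(res$W2$w[res$W2$w > 0]), mean(res$W1$w[res$W1$w > 0]))
})
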