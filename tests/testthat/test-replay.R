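test_that("high-activity detection keeps only long-enough supra-threshold runs", {
  mk <- function(rates) list(rate = rates, bin_width = 0.02,
                             t = seq_along(rates) * 0.02 - 0.01)
  # 3 Hz for 300 ms (15 bins) flanked by zeros -> one event
  ev <- detect_high_activity(mk(c(rep(0, 5), rep(3, 15), rep(0, 5))))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 0.3)
  expect_equal(ev$start, 5 * 0.02)
  # 240 ms (12 bins) is below the minimum duration
  expect_equal(nrow(detect_high_activity(mk(c(rep(3, 12), rep(0, 8))))), 0)
  # two runs separated by one sub-threshold bin stay two events
  ev2 <- detect_high_activity(mk(c(rep(3, 13), 1, rep(3, 13))))
  expect_equal(nrow(ev2), 2)
  # threshold is strict: exactly 2 Hz does not count
  expect_equal(nrow(detect_high_activity(mk(rep(2, 30)))), 0)
})

test_that("decoder equals the brute-force Poisson-product posterior", {
  map <- local_map(25)
  tcm <- tuning_curve_matrix(map, n_bins = 50)
  set.seed(3)
  for (rep_i in 1:4) {
    n_spk <- 40
    st <- sort(runif(n_spk, 0, 0.08))
    sc <- sample(which(map$has_field), n_spk, replace = TRUE)
    post <- decode_posterior(st, sc, 0, 0.08, map, delta_t = 0.01)
    # oracle: full counts over all place cells, direct dpois product
    counts_full <- matrix(0L, length(tcm$cells), post$n_time)
    tb <- pmin(floor(st / 0.01) + 1L, post$n_time)
    for (k in seq_along(st)) {
      i <- match(sc[k], tcm$cells)
      counts_full[i, tb[k]] <- counts_full[i, tb[k]] + 1L
    }
    P_oracle <- decode_oracle(counts_full, tcm$tau, 0.01)
    expect_equal(post$P, P_oracle, tolerance = 1e-12)
    expect_equal(colSums(post$P), rep(1, post$n_time), tolerance = 1e-12)
  }
})

test_that("decoder handles empty bins, silent cells and single-cell events", {
  map <- local_map(30)
  # one cell spiking once: MAP position is its field's bin
  cell <- which(map$has_field)[5]
  post <- decode_posterior(0.005, cell, 0, 0.01, map)
  expect_equal(which.max(post$P[, 1]),
               findInterval(map$field_middle[cell], seq(0, 3, by = 0.06)))
  # a no-spike bin gives the prior-like exp(-dt sum tau) shape
  post2 <- decode_posterior(numeric(0), integer(0), 0, 0.02, map)
  tcm <- tuning_curve_matrix(map)
  prior <- exp(-0.01 * colSums(tcm$tau))
  expect_equal(post2$P[, 1], prior / sum(prior), tolerance = 1e-12)
  # adding silent cells to the map does not change the posterior shape
  expect_error(decode_posterior(0.005, cell, 0, 0.005, map), "empty event")
})

test_that("path fitting recovers clean constant-velocity posteriors", {
  map <- local_map()
  # synthetic posterior with all mass on x = 0.5 + 2 t
  n <- 40
  P <- matrix(0, 50, n)
  for (k in 1:n) {
    x <- 0.5 + 2 * (k - 1) * 0.01
    P[findInterval(x, seq(0, 3, by = 0.06)), k] <- 1
  }
  post <- structure(list(P = P, centers = (1:50 - 0.5) * 0.06,
                         bin_width = 0.06, delta_t = 0.01, n_time = n),
                    class = "posterior_matrix")
  fit <- fit_linear_path(post)
  # several lines inside the +/- 18 cm band cover all the mass (R = 1) and
  # ties break towards slow velocities, so assert full coverage plus
  # geometric agreement of the fitted band with the true line
  expect_equal(fit$R, 1, tolerance = 1e-9)
  expect_equal(fit$direction, "forward")
  expect_lte(abs(fit$x0 - 0.5), fit$d + 0.06)
  expect_lte(abs(fit$x0 + fit$v * 0.39 - (0.5 + 2 * 0.39)), fit$d + 0.06)
  # uniform posterior: R equals the interior band fraction 2d / L
  Pu <- matrix(1 / 50, 50, 20)
  postu <- structure(list(P = Pu, centers = (1:50 - 0.5) * 0.06,
                          bin_width = 0.06, delta_t = 0.01, n_time = 20),
                     class = "posterior_matrix")
  Ru <- band_score_oracle(postu, 0.6, 1.5)
  expect_gt(Ru, 0.11)   # 6-7 bins x 0.02 each, band fully interior
  expect_lt(Ru, 0.15)
  # grid scores agree with the independent per-bin oracle
  set.seed(4)
  for (i in 1:5) {
    Pr <- matrix(rexp(50 * 15), 50, 15)
    Pr <- sweep(Pr, 2, colSums(Pr), "/")
    postr <- structure(list(P = Pr, centers = (1:50 - 0.5) * 0.06,
                            bin_width = 0.06, delta_t = 0.01, n_time = 15),
                       class = "posterior_matrix")
    fit <- fit_linear_path(postr)
    expect_equal(fit$R, band_score_oracle(postr, fit$v, fit$x0),
                 tolerance = 1e-9)
    # no on-grid candidate from a coarse independent scan beats the optimum
    for (v in seq(-17.7, 17.7, by = 6)) {
      if (abs(v) <= 0.3) next
      for (x0 in seq(-1.5, 4.5, by = 0.39)) {
        expect_lte(band_score_oracle(postr, v, x0), fit$R + 1e-9)
      }
    }
  }
  # the slow-velocity band is excluded from the scan
  expect_gte(abs(fit_linear_path(postu)$v), 0.6 - 1e-9)
})

test_that("end-to-end parameter recovery on synthetic constant-velocity events", {
  map <- local_map(150, seed = 12)
  for (case in list(c(v = 4, x0 = 0.3), c(v = -6, x0 = 2.6))) {
    dur <- min(2.4 / abs(case["v"]), 0.4)
    spk <- trajectory_spikes(map, case["v"], case["x0"], dur, seed = 5)
    post <- decode_posterior(spk$t, spk$cell, 0, dur, map)
    fit <- fit_linear_path(post)
    expect_lte(abs(fit$v - case["v"]), 0.3 + 1e-9)       # one velocity step
    expect_lte(abs(fit$x0 - case["x0"]), 0.06 + 1e-9)    # two intercept steps
    expect_equal(fit$direction,
                 if (case["v"] > 0) "forward" else "backward")
  }
})

test_that("identity shuffling separates sequences from scrambled activity", {
  map <- local_map(150, seed = 12)
  # positive control: clean trajectory event is significant
  spk <- trajectory_spikes(map, 5, 0.4, 0.4, seed = 7)
  rt <- shuffle_significance(spk$t, spk$cell, 0, 0.4, map, n_shuffles = 60,
                             seed = 2)
  expect_true(rt$significant)
  expect_lt(rt$p_rank, 0.05)
  # spike counts are preserved under every shuffle by construction
  expect_equal(sum(rt$posterior$counts), length(spk$t))
  # negative control: independent Poisson firing with no sequence
  set.seed(9)
  cells <- sample(which(map$has_field), 40)
  st <- sort(runif(400, 0, 0.4))
  sc <- sample(cells, 400, replace = TRUE)
  rt0 <- shuffle_significance(st, sc, 0, 0.4, map, n_shuffles = 60, seed = 3)
  expect_gt(rt0$p_rank, 0.05)
  expect_error(shuffle_significance(0.01, cells[1], 0, 0.3, map),
               "fewer than 2")
})

test_that("step-size analysis measures decoded movement against a constant-step null", {
  # perfect linear posterior at v = 2 m/s, dt = 10 ms -> all steps 2 cm
  n <- 30
  P <- matrix(0, 50, n)
  centers <- (1:50 - 0.5) * 0.06
  for (k in 1:n) {
    x <- 0.5 + 2 * (k - 1) * 0.01
    w <- exp(-(centers - x)^2 / (2 * 0.02^2))
    P[, k] <- w / sum(w)
  }
  post <- structure(list(P = P, centers = centers, bin_width = 0.06,
                         delta_t = 0.01, n_time = n),
                    class = "posterior_matrix")
  ss <- step_size_analysis(post)
  expect_equal(mean(ss$observed), 0.02, tolerance = 0.03)
  expect_equal(ss$predicted[1], mean(ss$observed), tolerance = 1e-9)
  expect_true(all(abs(ss$observed - 0.02) < 0.02))  # near-constant 2 cm steps
  # stationary posterior: all steps zero
  Ps <- matrix(rep(P[, 1], n), 50, n)
  posts <- structure(list(P = Ps, centers = centers, bin_width = 0.06,
                          delta_t = 0.01, n_time = n),
                     class = "posterior_matrix")
  ss0 <- step_size_analysis(posts)
  expect_true(all(abs(ss0$observed) < 1e-12))
  expect_true(all(ss0$predicted == 0))
})

test_that("R is invariant under time reversal with mirrored fit parameters", {
  set.seed(6)
  P <- matrix(rexp(50 * 12), 50, 12)
  P <- sweep(P, 2, colSums(P), "/")
  post <- structure(list(P = P, centers = (1:50 - 0.5) * 0.06,
                         bin_width = 0.06, delta_t = 0.01, n_time = 12),
                    class = "posterior_matrix")
  postr <- post
  postr$P <- P[, 12:1]
  for (v in c(2.1, -3.6)) {
    for (x0 in c(0.4, 1.9)) {
      r1 <- band_score_oracle(post, v, x0)
      r2 <- band_score_oracle(postr, -v, x0 + v * 11 * 0.01)
      expect_equal(r1, r2, tolerance = 1e-12)
    }
  }
})
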