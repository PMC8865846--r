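test_that("biexponential normalization has the closed-form peak time", {
  d <- double_exp_normalization(1.3, 9.5)            # PC->PC kinetics
  expect_equal(d$t_p, 9.5 * 1.3 / (9.5 - 1.3) * log(9.5 / 1.3),
               tolerance = 1e-12)
  expect_equal(d$t_p, 2.996, tolerance = 1e-3)
  # numeric maximization oracle: g(t_p) = ghat exactly after normalization
  for (tau in list(c(1.3, 9.5), c(0.3, 3.3), c(0.25, 1.2), c(0.65, 5.4))) {
    dn <- double_exp_normalization(tau[1], tau[2])
    tt <- seq(0, 20 * tau[2], by = 1e-4)
    gt <- (exp(-tt / tau[2]) - exp(-tt / tau[1])) / dn$A
    expect_equal(max(gt), 1, tolerance = 1e-6)
    expect_equal(tt[which.max(gt)], dn$t_p, tolerance = 1e-3)
  }
  # slow-decay limit: peak approaches 1 at t ~ tau_r * log(tau_d / tau_r)
  dn <- double_exp_normalization(1, 1e4)
  expect_equal(dn$A, 1, tolerance = 1e-2)
})

test_that("single-cell dynamics: rest is a fixed point, steps reproduce the protocol", {
  pc <- neuron_params("PC")
  # zero input: V stays at rest, no spikes, w -> 0
  res <- simulate_cell(pc, rep(0, 5000), dt = 0.1)
  # rest sits a whisker above Vrest (the exponential term at -75 mV is
  # ~1e-4 pA), so state stays within numerical-rest bounds
  expect_equal(res$V[5000], pc$Vrest, tolerance = 1e-4)
  expect_length(res$spikes, 0)
  expect_lt(max(abs(res$w)), 1e-3)
  # -0.04 nA, 800 ms: hyperpolarizing relaxation, no spikes
  res <- simulate_cell(pc, rep(-40, 8000), dt = 0.1)
  expect_length(res$spikes, 0)
  expect_lt(min(res$V), pc$Vrest)
  expect_true(all(diff(res$V[1:4000]) <= 1e-12))  # monotone relaxation down
  # 0.6 nA step: repetitive firing; spike count matches a fine-dt oracle
  res <- simulate_cell(pc, rep(600, 8000), dt = 0.1)
  expect_gt(length(res$spikes), 3)
  fine <- simulate_cell(pc, rep(600, 800 / 0.005), dt = 0.005)
  expect_lte(abs(length(res$spikes) - length(fine$spikes)), 1)
  # refractoriness at the single-cell level
  expect_true(all(diff(res$spikes) >= pc$tref / 1000 - 1e-9))
})

test_that("adaptation produces progressive ISI lengthening, ExpIF does not", {
  pc <- neuron_params("PC")
  ex <- neuron_params("PC_ExpIF")
  s_ad <- simulate_cell(pc, rep(600, 8000), dt = 0.05)$spikes
  s_ex <- simulate_cell(ex, rep(600, 8000), dt = 0.05)$spikes
  isi_ad <- diff(s_ad)
  isi_ex <- diff(s_ex)
  slope <- function(x) coef(lm(x ~ seq_along(x)))[2]
  expect_gt(slope(isi_ad), 0)            # ISIs lengthen with adaptation
  expect_lt(abs(slope(isi_ex)), 0.1 * abs(slope(isi_ad)))
})

test_that("network variants assemble the requested pathways", {
  g <- sample_connectivity(100, 100, 0.2, FALSE, 1)
  W <- swrnet:::new_weight_matrix(g, rep(0.5, length(g$row_ind)), 20)
  base <- build_network(network_config(n_pc = 100, n_pvbc = 10), W, seed = 1)
  expect_setequal(names(base$pathways), c("ee", "epv", "ipc", "ii"))
  noii <- build_network(network_config(n_pc = 100, n_pvbc = 10,
                                       variant = "no_PVBC_PVBC"), W, seed = 1)
  expect_false("ii" %in% names(noii$pathways))
  pv <- build_network(network_config(n_pc = 100, n_pvbc = 10,
                                     variant = "PVBC_only"), seed = 1)
  expect_equal(names(pv$pathways), "ii")
  expect_equal(pv$N, 10)
  expect_equal(names(pv$ext), "drive")
  expect_error(build_network(network_config(n_pc = 99, n_pvbc = 10), W, 1),
               "dimension mismatch")
  # ExpIF variant swaps cell model and doubles the mossy weight
  exif <- build_network(network_config(n_pc = 100, n_pvbc = 10,
                                       variant = "ExpIF_PC"), W, seed = 1)
  expect_equal(exif$config$mf_weight, 38.3)
  expect_equal(exif$params$has_w[1], 0)
  expect_equal(exif$params$has_w[101], 1)  # PVBCs keep adaptation
})

test_that("simulated network conserves basic invariants", {
  g <- sample_connectivity(80, 80, 0.2, FALSE, 3)
  W <- swrnet:::new_weight_matrix(g, rep(1, length(g$row_ind)), 20)
  spec <- build_network(network_config(n_pc = 80, n_pvbc = 8), W, seed = 3)
  sim <- simulate_network(spec, duration = 2, seed = 3, lfp_n = 20,
                          probe_cells = c(1L, 81L))
  expect_true(all(sim$spike_t >= 0 & sim$spike_t <= sim$duration))
  # refractoriness per cell (PC tref 5.96 ms, PVBC 1.15 ms)
  for (cell in unique(sim$spike_cell)) {
    s <- sim$spike_t[sim$spike_cell == cell]
    tref <- if (cell <= 80) 5.96 else 1.15
    if (length(s) > 1) expect_gte(min(diff(s)) * 1000, tref - 1e-6)
  }
  # determinism given seed
  sim2 <- simulate_network(spec, duration = 2, seed = 3, lfp_n = 20,
                           probe_cells = c(1L, 81L))
  expect_identical(sim$spike_t, sim2$spike_t)
  expect_identical(sim$lfp$exc, sim2$lfp$exc)
  # recordings have the right shapes
  expect_length(sim$lfp$exc, 2 / 0.1 * 1000)
  expect_equal(dim(sim$probes$V), c(2, 20000))
  # silent network without weights or drive
  W0 <- swrnet:::new_weight_matrix(g, rep(0, length(g$row_ind)), 20)
  spec0 <- build_network(network_config(n_pc = 80, n_pvbc = 8), W0, seed = 3)
  spec0$ext <- list()
  sim0 <- simulate_network(spec0, duration = 0.5, seed = 1, lfp_n = 0)
  expect_length(sim0$spike_t, 0)
})

test_that("population rate counts spikes per bin per cell", {
  sim <- list(spike_t = c(rep(0.015, 40), 0.05), spike_cell = c(1:40, 5L),
              n_pc = 40, n_pvbc = 0, duration = 0.1)
  r <- population_rate(sim, 0.02, "PC")
  # 40 cells firing once inside one 20 ms bin -> 50 Hz in that bin
  expect_equal(r$rate[1], 40 / (0.02 * 40))
  expect_equal(r$rate[3], 1 / (0.02 * 40))
  # total spikes conserved under rebinning
  r2 <- population_rate(sim, 0.01, "PC")
  expect_equal(sum(r$rate) * 0.02 * 40, sum(r2$rate) * 0.01 * 40)
})

test_that("cued stimulation drives the targeted subgroup", {
  g <- sample_connectivity(60, 60, 0.1, FALSE, 5)
  W <- swrnet:::new_weight_matrix(g, rep(0.1, length(g$row_ind)), 20)
  spec <- build_network(network_config(n_pc = 60, n_pvbc = 6), W, seed = 5)
  spec$ext <- list()   # isolate the stimulus
  stim <- stimulus_protocol(cells = 1:10, onset = 0.1, duration = 0.2,
                            rate = 100)
  sim <- simulate_network(spec, duration = 0.5, seed = 2, stimulus = stim,
                          lfp_n = 0)
  expect_true(all(sim$spike_cell %in% 1:10))
  expect_true(all(sim$spike_t >= 0.1 & sim$spike_t <= 0.35))
  expect_gt(length(sim$spike_t), 10)
})
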