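test_that("small end-to-end fixture builds with the stated constraints", {
  fx <- small_fixture()
  expect_gt(nrow(fx$nodes), 100)
  expect_true(all(c("Rt_RC", "VPL_TC") %in% fx$nodes$mtype))
  expect_true(all(fx$synapses$pre_mtype != "VPL_TC" |
                  fx$synapses$post_mtype != "VPL_TC"))
  # same seed -> identical circuit
  fx2 <- suppressWarnings(
    make_fixture_circuit(density_scale = 0.04, seed = 1, pool_size = 6))
  expect_identical(fx$nodes, fx2$nodes)
  expect_identical(dim(fx$synapses), dim(fx2$synapses))
})

test_that("network runs are reproducible and silent without input", {
  fx <- small_fixture()
  net <- fx$network
  # zero background, zero minis -> zero spikes
  sim0 <- run_simulation(net, sim_config(duration = 800, seed = 3))
  expect_equal(nrow(sim0$spikes), 0)
  # identical seeds -> identical spike trains
  cfg <- protocol_wakefulness(sim_config(duration = 800, seed = 5))
  a <- run_simulation(net, cfg)
  b <- run_simulation(net, cfg)
  expect_identical(a$spikes, b$spikes)
  # different seed -> different realization
  cfg2 <- cfg; cfg2$seed <- 6
  c_ <- run_simulation(net, cfg2)
  expect_false(identical(a$spikes, c_$spikes))
})

test_that("Poisson fiber backgrounds have the configured rate", {
  fx <- small_fixture()
  cfg <- protocol_wakefulness(sim_config(duration = 2000, seed = 9))
  sim <- run_simulation(fx$network, cfg)
  fs <- sim$fiber_spikes
  ml_ids <- fx$network$fiber_offset[["ML"]] +
    seq_len(fx$network$n_fibers[["ML"]]) - 1
  n_ml <- sum(fs$fiber %in% ml_ids)
  expected <- fx$network$n_fibers[["ML"]] * 25 * 2
  expect_lt(abs(n_ml - expected), 4 * sqrt(expected))
})

test_that("protocol builders set the stated conditions", {
  cfg <- sim_config(duration = 3000)
  w <- protocol_wakefulness(cfg)
  expect_equal(w$ml_blocks$rate, 25)
  expect_equal(w$ct_blocks$rate, 4)
  expect_equal(w$ca_mM, 1.2)
  a <- protocol_wakefulness(cfg, anesthetized = TRUE)
  expect_equal(a$ml_blocks$rate, 10)
  v <- protocol_in_vitro(cfg)
  expect_equal(v$ml_blocks$rate, 0)
  expect_equal(v$ca_mM, 2.0)
  expect_true(v$minis_on)
  # up/down: CT rate alternates 0 / baseline in 500 ms blocks
  ud <- protocol_updown(protocol_wakefulness(cfg), 500, 500,
                        start_ms = 1000)
  expect_equal(ud$ct_blocks$rate, c(4, 0, 4, 0, 4))
  expect_equal(ud$ct_blocks$t0, c(0, 1000, 1500, 2000, 2500))
  # down_ms = 0 -> constant background
  ud0 <- protocol_updown(protocol_wakefulness(cfg), 0, 500)
  expect_equal(nrow(ud0$ct_blocks), 1)
})

test_that("up/down protocol gates the CT fiber population", {
  fx <- small_fixture()
  cfg <- protocol_updown(protocol_wakefulness(sim_config(duration = 3000,
                                                         seed = 4)),
                         500, 500, start_ms = 1000)
  sim <- run_simulation(fx$network, cfg)
  fs <- sim$fiber_spikes
  ct_ids <- fx$network$fiber_offset[["CT"]] +
    seq_len(fx$network$n_fibers[["CT"]]) - 1
  ct <- fs$time[fs$fiber %in% ct_ids]
  in_down <- sum(ct >= 1000 & ct < 1500) + sum(ct >= 2000 & ct < 2500)
  expect_equal(in_down, 0)
  expect_gt(sum(ct >= 1500 & ct < 2000), 0)
})

test_that("sensory train stimulus selects central fibers at pulse times", {
  fx <- small_fixture()
  net <- fx$network
  cfg <- stimulus_sensory_train(sim_config(duration = 2000), net,
                                n_fibers = 10, n_pulses = 8, freq_hz = 8,
                                t0 = 500, jitter_ms = 0)
  expect_equal(attr(cfg, "stim_times"), 500 + (0:7) * 125)
  ev <- cfg$fiber_events
  expect_equal(nrow(ev), 80)
  # fibers are the nearest to the axis
  fib <- net$fibers$ML
  ord <- order(fib$x^2 + fib$z^2)
  chosen <- unique(ev$fiber) - net$fiber_offset[["ML"]] + 1
  expect_setequal(chosen, ord[1:10])
})

test_that("Rt pulse drives the stimulated subset", {
  fx <- small_fixture()
  net <- fx$network
  cfg <- protocol_in_vitro(sim_config(duration = 1500, seed = 2))
  cfg$minis_on <- FALSE
  cfg0 <- stimulus_rt_pulse(cfg, net, fraction = 0.2, amplitude_nA = 0,
                            t0 = 1000)
  sim_zero <- run_simulation(net, cfg0)
  base <- run_simulation(net, cfg)
  expect_identical(sim_zero$spikes, base$spikes) # amplitude 0 = control
  cfg1 <- stimulus_rt_pulse(cfg, net, fraction = 0.2, amplitude_nA = 0.5,
                            t0 = 1000)
  sim1 <- run_simulation(net, cfg1)
  stim_cells <- attr(cfg1, "rt_pulse")$cells
  resp <- sim1$spikes[sim1$spikes$time >= 1000 & sim1$spikes$time <= 1060, ]
  expect_gt(sum(resp$gid %in% stim_cells), 0)
  # stimulated cells fire earlier than unstimulated responders
  lat_stim <- min(resp$time[resp$gid %in% stim_cells])
  others <- resp$time[!(resp$gid %in% stim_cells)]
  if (length(others)) expect_lte(lat_stim, min(others))
})

test_that("population polarization reaches the target baseline", {
  fx <- small_fixture()
  net <- fx$network
  cfg <- protocol_in_vitro(sim_config(duration = 700, seed = 3))
  cfg$minis_on <- FALSE
  rt_idx <- which(net$nodes$mtype == "Rt_RC")
  cfg$record_cells <- rt_idx[1:5] - 1L
  cfg <- set_population_polarization(cfg, net, "Rt", -80)
  sim <- run_simulation(net, cfg)
  late <- sim$traces$time > 500
  vm <- colMeans(sim$traces$v[late, , drop = FALSE])
  # within a couple of mV of target (gap junctions load the in-network
  # cells relative to the isolated solve)
  expect_lt(abs(mean(vm) + 80), 3)
})

test_that("circuit tables round-trip through the SONATA-style writer", {
  fx <- small_fixture()
  dir <- tempfile()
  write_circuit(fx$nodes, fx$synapses[1:500, ], dir, fx$gap_junctions[1:50, ])
  back <- read_circuit(dir)
  expect_equal(nrow(back$nodes), nrow(fx$nodes))
  expect_equal(back$edges$post, fx$synapses$post[1:500])
  expect_equal(nrow(back$gj), 50)
  # dangling edge reference is rejected
  bad <- fx$synapses[1:5, ]
  bad$post[1] <- max(fx$nodes$id) + 999
  write_circuit(fx$nodes, bad, dir)
  expect_error(read_circuit(dir), "dangling")
})
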