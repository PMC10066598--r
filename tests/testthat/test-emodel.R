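test_that("leak-only model obeys the closed-form input resistance", {
  em <- emodel(g_na = 0, g_kd = 0, g_ka = 0, g_cat_s = 0, g_cat_d = 0,
               g_sk_s = 0, g_sk_d = 0, g_ih_s = 0, g_ih_d = 0, g_cah = 0,
               e_leak = -70, v_init = -70)
  tr <- simulate_neuron(em, protocol_spec(duration = 800, step_nA = -0.05,
                                          step_t0 = 100, step_t1 = 700))
  vss <- mean(tr$v[tr$time > 600 & tr$time < 700])
  # two-compartment soma input resistance
  gs <- em$g_leak_s * em$area_s * 1e6
  gd <- em$g_leak_d * em$area_d * 1e6
  gc <- em$g_couple
  r_in <- 1 / (gs + gc * gd / (gc + gd))
  expect_equal((vss + 70) / (-0.05), r_in, tolerance = 0.01 * r_in)
})

test_that("reference e-models: silent at rest, burst and tonic modes", {
  ems <- default_emodels()
  for (nm in names(ems)) {
    rest <- simulate_neuron(ems[[nm]],
                            protocol_spec(duration = 1000, step_nA = 0))
    expect_length(rest$spikes, 0)
    expect_true(all(rest$v > -120 & rest$v < 60))
  }
  # low-threshold burst from the hyperpolarized holding (both TC and Rt)
  for (nm in c("VPL_TC_cAD", "Rt_RC_cAD")) {
    em <- ems[[nm]]
    ht <- find_holding_threshold(em, -84)
    tr <- simulate_neuron(em, protocol_spec(duration = 900,
                                            holding_nA = ht$holding_nA,
                                            step_nA = 2 * ht$threshold_nA,
                                            step_t0 = 300, step_t1 = 800))
    sp <- tr$spikes[tr$spikes >= 300]
    expect_gte(length(sp), 2)
    expect_lte(diff(sp)[1], 15) # burst: first ISI <= 15 ms
    # tonic from the depolarized holding
    dp <- find_holding_threshold(em, -64)
    tr2 <- simulate_neuron(em, protocol_spec(duration = 900,
                                             holding_nA = dp$holding_nA,
                                             step_nA = 2 * dp$threshold_nA,
                                             step_t0 = 300, step_t1 = 800))
    expect_gt(length(tr2$spikes[tr2$spikes >= 300]), 3)
  }
})

test_that("Rt post-burst afterhyperpolarization is deeper than TC", {
  ems <- default_emodels()
  sahp <- vapply(c("VPL_TC_cAD", "Rt_RC_cAD"), function(nm) {
    em <- ems[[nm]]
    ht <- find_holding_threshold(em, -84)
    tr <- simulate_neuron(em, protocol_spec(duration = 900,
                                            holding_nA = ht$holding_nA,
                                            step_nA = 2 * ht$threshold_nA,
                                            step_t0 = 300, step_t1 = 800))
    extract_features(tr)[["initburst_sahp"]]
  }, numeric(1))
  expect_lt(sahp[["Rt_RC_cAD"]], sahp[["VPL_TC_cAD"]])
})

test_that("dt refinement does not change the spike pattern", {
  em <- default_emodels()$VPL_TC_cAD
  p <- protocol_spec(duration = 600, holding_nA = 0.05, step_nA = 0.1,
                     step_t0 = 200, step_t1 = 500)
  s1 <- simulate_neuron(em, p, dt = 0.025)$spikes
  s2 <- simulate_neuron(em, p, dt = 0.0125)$spikes
  expect_equal(length(s1), length(s2))
  if (length(s1)) expect_lt(max(abs(s1 - s2)), 1)
})

test_that("feature extraction matches constructed traces", {
  # synthetic trace with 3 spikes
  tm <- seq(0.1, 1200, by = 0.1)
  v <- rep(-70, length(tm))
  for (s in c(400, 500, 600)) v[tm >= s & tm < s + 1] <- 10
  tr <- structure(list(time = tm, v = v, spikes = detect_spikes(v, tm),
                       protocol = protocol_spec(), dt = 0.1),
                  class = "trace")
  f <- extract_features(tr)
  expect_equal(f[["spike_count"]], 3)
  expect_equal(f[["resting_potential"]], -70)
  # sag from a constructed exponential relaxation
  p <- protocol_spec(step_nA = -0.05)
  vv <- rep(-70, length(tm))
  win <- tm >= 300 & tm <= 900
  t0 <- tm[win] - 300
  vv[win] <- -80 + 5 * (1 - exp(-t0 / 100)) # trough -80, steady -75
  tr2 <- structure(list(time = tm, v = vv, spikes = numeric(0),
                        protocol = p, dt = 0.1), class = "trace")
  f2 <- extract_features(tr2)
  expect_equal(f2[["sag_amplitude"]], 5, tolerance = 0.1)
  expect_equal(f2[["input_resistance"]], (-75 + 70) / -0.05, tolerance = 2)
  # adaptation: ISIs 10, 20, 40 -> ratio 0.25
  vv3 <- rep(-70, length(tm))
  for (s in c(400, 410, 430, 470)) vv3[tm >= s & tm < s + 1] <- 10
  tr3 <- structure(list(time = tm, v = vv3,
                        spikes = detect_spikes(vv3, tm),
                        protocol = protocol_spec(), dt = 0.1),
                   class = "trace")
  expect_equal(extract_features(tr3)[["adaptation_index"]], 0.25,
               tolerance = 0.01)
})

test_that("z-scores follow the definition with missing -> Inf", {
  expect_equal(zscore(13, 10, 2), 1.5)
  expect_equal(zscore(10, 10, 2), 0)
  expect_equal(zscore(NA, 10, 2), Inf)
  expect_error(zscore(1, 0, 0), "positive")
})

test_that("holding and threshold search", {
  # passive closed form: I = (V_target - E_L) * G_in
  em <- emodel(g_na = 0.05, g_kd = 0.005, g_ka = 0, g_cat_s = 0,
               g_cat_d = 0, g_sk_s = 0, g_sk_d = 0, g_ih_s = 0,
               g_ih_d = 0, e_leak = -70, v_init = -70)
  ht <- find_holding_threshold(em, -84)
  gs <- em$g_leak_s * em$area_s * 1e6
  gd <- em$g_leak_d * em$area_d * 1e6
  g_in <- gs + em$g_couple * gd / (em$g_couple + gd)
  expect_equal(ht$holding_nA, (-84 + 70) * g_in, tolerance = 0.01)
  # binary-search threshold equals a 1% grid scan
  spikes_at <- function(step) {
    tr <- simulate_neuron(em, protocol_spec(duration = 900,
                                            holding_nA = ht$holding_nA,
                                            step_nA = step, step_t0 = 300,
                                            step_t1 = 800), dt = 0.05)
    length(tr$spikes[tr$spikes >= 300])
  }
  grid <- seq(0.8, 1.2, by = 0.01) * ht$threshold_nA
  firing <- vapply(grid, function(s) spikes_at(s) >= 1, logical(1))
  grid_thr <- grid[which(firing)[1]]
  expect_equal(ht$threshold_nA, grid_thr, tolerance = 0.02 * grid_thr)
  # both holdings converge for an active model
  em2 <- default_emodels()$Rt_RC_cNAD
  expect_no_error(find_holding_threshold(em2, -84))
  expect_no_error(find_holding_threshold(em2, -64))
})

test_that("e-model fitting recovers a reference model's behavior", {
  base <- default_emodels()$VPL_TC_cAD
  protos <- standard_protocols(base, dt = 0.05)
  targets <- feature_targets_from_model(base, protocols = protos, dt = 0.05)
  targets <- targets[targets$protocol %in% c("tonic_200", "burst_200"), ]
  # bounds collapsed to the true point -> returns that model, z = 0
  b0 <- list(g_na = c(base$g_na, base$g_na))
  fit0 <- fit_emodel(targets, b0, base = base, protocols = protos, seed = 1)
  expect_lt(fit0$max_z, 0.5)
  # small search around the truth recovers behavior (z < 3)
  b1 <- list(g_na = c(0.8, 1.2) * base$g_na,
             g_kd = c(0.8, 1.2) * base$g_kd)
  fit1 <- fit_emodel(targets, b1, base = base, protocols = protos,
                     seed = 2, mu = 3, lambda = 5, generations = 4)
  expect_lt(fit1$max_z, 3)
  expect_true(fit1$converged)
})

test_that("me-model acceptance gate", {
  base <- default_emodels()$VPL_TC_cAD
  protos <- standard_protocols(base, dt = 0.05)
  targets <- feature_targets_from_model(base, protocols = protos, dt = 0.05)
  acc <- accept_memodel(base, targets, protos)
  expect_true(acc$pass)          # the exemplar passes its own targets
  expect_false(acc$spontaneous)
  # zeroed sodium conductance: no spikes -> fail
  dead <- emodel(g_na = 0)
  for (f in setdiff(names(base), c("g_na", "etype")))
    dead[[f]] <- base[[f]]
  acc2 <- accept_memodel(dead, targets, protos)
  expect_false(acc2$pass)
})

test_that("cAD targets produce an adapting tonic train, cNAD less so", {
  ems <- default_emodels()
  ad <- vapply(c("VPL_TC_cAD", "VPL_TC_cNAD"), function(nm) {
    em <- ems[[nm]]
    dp <- find_holding_threshold(em, -64)
    tr <- simulate_neuron(em, protocol_spec(duration = 1100,
                                            holding_nA = dp$holding_nA,
                                            step_nA = 1.5 * dp$threshold_nA,
                                            step_t0 = 300, step_t1 = 1000))
    extract_features(tr)[["adaptation_index"]]
  }, numeric(1))
  expect_lt(ad[["VPL_TC_cAD"]], ad[["VPL_TC_cNAD"]])
})
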