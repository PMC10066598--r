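test_that("stochastic TM release matches the deterministic recursion", {
  # limiting case: U = 1, D -> Inf: second spike releases nothing
  rel <- tm_release(1, 1e12, 1, c(0, 10), n_sites = 1, seed = 1)
  expect_equal(rel, c(1L, 0L))

  # ensemble mean over trials equals the recursion within 3 MC sd
  spikes <- seq(0, by = 25, length.out = 8)
  for (p in list(c(0.5, 700, 20), c(0.09, 138, 670))) {
    det <- tm_deterministic(p[1], p[2], p[3], spikes)$amplitude
    n_tr <- 600
    acc <- matrix(0, n_tr, length(spikes))
    for (k in seq_len(n_tr))
      acc[k, ] <- tm_release(p[1], p[2], p[3], spikes, n_sites = 1, seed = k)
    m <- colMeans(acc)
    se <- apply(acc, 2, sd) / sqrt(n_tr)
    expect_true(all(abs(m - det) <= 3 * se + 1e-9))
  }

  # depressing parameters: monotone decreasing mean amplitudes at 40 Hz;
  # facilitating: increasing
  dep <- tm_deterministic(0.45, 700, 21, spikes)$amplitude
  expect_true(all(diff(dep) < 0))
  fac <- tm_deterministic(0.09, 138, 670, spikes)$amplitude
  expect_gt(fac[8], fac[1])
})

test_that("conductance waveform and NMDA block", {
  tp <- 0.2 * 1.74 / (1.74 - 0.2) * log(1.74 / 0.2)
  expect_equal(syn_conductance(tp, 2.5, 0.2, 1.74), 2.5, tolerance = 1e-9)
  expect_equal(syn_conductance(-1, 2.5, 0.2, 1.74), 0)
  expect_gt(nmda_block(60), 0.95)
  expect_lt(nmda_block(-80), 0.1)
  v <- seq(-90, 40, by = 1)
  expect_true(all(diff(nmda_block(v)) > 0))
})

test_that("U/D/F fitting recovers generating parameters", {
  times <- c(seq(0, by = 25, length.out = 8), 550)
  peaks <- tm_deterministic(0.5, 700, 20, times)$amplitude
  fit <- fit_udf(peaks, times, seed = 2)
  expect_lt(abs(fit$U - 0.5) / 0.5, 0.10)
  expect_lt(abs(fit$D - 700) / 700, 0.20)
  expect_identical(fit$class, "E2/I2")
  # facilitating train classified E1
  fac <- tm_deterministic(0.09, 138, 670, times)$amplitude
  expect_identical(fit_udf(fac, times, seed = 2)$class, "E1")
  # flat train: degenerate flag
  expect_warning(f0 <- fit_udf(rep(1, 9), times), "identifiable")
  expect_true(f0$degenerate)
  expect_error(fit_udf(1:3, times), "equal length")
})

test_that("calcium scaling is anchored and monotone", {
  expect_equal(calcium_scale(2.0), 1, tolerance = 1e-12)
  expect_lt(calcium_scale(1.2), 1)
  ca <- seq(0.5, 3, by = 0.1)
  expect_true(all(diff(calcium_scale(ca)) > 0))
})

test_that("minis are a Poisson process per synapse", {
  expect_equal(nrow(apply_minis(100, 1000, rate_hz = 0, seed = 1)), 0)
  # mean event count ~ n * rate * T
  n_ev <- vapply(1:40, function(s)
    nrow(apply_minis(500, 60000, rate_hz = 0.01, seed = s)), numeric(1))
  expected <- 500 * 0.01 * 60
  expect_equal(mean(n_ev), expected, tolerance = 0.1 * expected)
})

test_that("gap-junction algebra: compensation and coupling coefficient", {
  # zero junctions -> unchanged
  expect_equal(compensate_input_resistance(c(1, 2), matrix(0, 0, 2),
                                           numeric(0)), c(1, 2))
  # two-cell symmetric closed form: R = 118 MOhm, G = 0.2 nS
  gcell <- rep(1 / 118, 2)   # uS
  pairs <- matrix(c(1, 2), 1)
  gg <- 0.2e-3               # uS
  cc <- coupling_coefficient(gcell, pairs, gg, 1, 2)
  gr <- gg * 118
  expect_equal(cc, gr / (1 + gr), tolerance = 1e-9)
  expect_equal(cc, 0.023, tolerance = 0.005)
  # uncoupled -> 0
  expect_equal(coupling_coefficient(gcell, pairs, 0, 1, 2), 0)
  # CC monotone in G
  ccs <- vapply(c(0.1, 0.2, 0.4, 0.8) * 1e-3, function(g)
    coupling_coefficient(gcell, pairs, g, 1, 2), numeric(1))
  expect_true(all(diff(ccs) > 0))

  # closed-form compensation for the symmetric pair:
  # R_in with junction = (g + G) ... solved by the iterative routine
  comp <- compensate_input_resistance(gcell, pairs, gg)
  r_after <- gj_input_resistance(comp, pairs, gg)
  expect_true(all(abs(r_after * gcell - 1) < 0.01))

  # random 100-cell network: post-compensation R_in error < 1%
  set.seed(9)
  n <- 100
  g0 <- runif(n, 4e-3, 6e-3)
  pr <- cbind(sample(n, 80, TRUE), sample(n, 80, TRUE))
  pr <- pr[pr[, 1] != pr[, 2], ]
  gj <- rep(0.2e-3, nrow(pr))
  comp <- compensate_input_resistance(g0, pr, gj, clamp_frac = 0.3)
  r <- gj_input_resistance(comp, pr, gj)
  expect_true(all(abs(r * g0 - 1) < 0.01))
})

test_that("conductance calibration converges to the PSP target", {
  # analytic linear PSP stand-in: psp = 0.8 mV per nS with noise
  psp_fun <- function(g, seed) {
    set.seed(seed)
    abs(rnorm(50, mean = 0.8 * g, sd = 0.05 * g))
  }
  cal <- calibrate_conductance(psp_fun, target_mV = 1.2, g_init = 0.5,
                               seed = 1)
  expect_equal(cal$psp_mV, 1.2, tolerance = 0.06)
  expect_equal(cal$g_nS, 1.5, tolerance = 0.15)
  # fixed point: target equal to measured at g_init returns g_init
  cal2 <- calibrate_conductance(psp_fun, target_mV = 0.8 * 2, g_init = 2,
                                seed = 1)
  expect_equal(cal2$g_nS, 2, tolerance = 0.1)
  # doubling g doubles the PSP in the linear regime
  m1 <- mean(psp_fun(1, 3)); m2 <- mean(psp_fun(2, 4))
  expect_equal(m2 / m1, 2, tolerance = 0.2)
})

test_that("per-synapse parameter draws respect truncation", {
  p <- pathway_physiology()[1, ]
  d <- draw_synapse_params(500, p, seed = 3)
  expect_true(all(d$U > 0 & d$U <= 1))
  expect_true(all(d$D > 0 & d$F > 0 & d$g_nS > 0))
  expect_equal(mean(d$U), p$U, tolerance = 0.1)
})

test_that("pathway map: intrathalamic and ML depressing, CT facilitating", {
  pw <- pathway_physiology()
  intra <- pw$pre %in% c("Rt_RC", "VPL_TC", "VPL_IN") | pw$pre == "ML"
  expect_true(all(pw$class[intra] %in% c("E2", "I2")))
  expect_true(all(pw$class[pw$pre == "CT"] == "E1"))
  # class consistency with U/D/F dynamics at 40 Hz
  for (i in seq_len(nrow(pw))) {
    amp <- tm_deterministic(pw$U[i], pw$D[i], pw$F[i],
                            seq(0, by = 25, length.out = 8))$amplitude
    if (pw$class[i] == "E1") expect_gt(amp[8] / amp[1], 1)
    else expect_lt(amp[8] / amp[1], 1)
  }
})
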