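test_that("touch rule arithmetic on crafted segment pairs", {
  # two parallel segments, radii 0.5, centerlines 1.8 um apart -> gap 0.8
  seg <- matrix(c(0, 0, 0, 10, 0, 0, 0.5,
                  0, 1.8, 0, 10, 1.8, 0, 0.5), 2, 7, byrow = TRUE)
  tt <- thalamosim:::cpp_detect_touches(seg, c(1L, 2L), c(1L, 2L),
                           c(TRUE, FALSE), c(FALSE, TRUE), 1)
  expect_equal(nrow(tt), 1)
  expect_equal(tt$gap, 0.8, tolerance = 1e-9)
  # centerlines 2.6 apart -> gap 1.6 > 1 -> no touch
  seg[2, c(2, 5)] <- 2.6
  tt2 <- thalamosim:::cpp_detect_touches(seg, c(1L, 2L), c(1L, 2L),
                            c(TRUE, FALSE), c(FALSE, TRUE), 1)
  expect_equal(nrow(tt2), 0)
})

test_that("spatial-index touch detection equals brute force", {
  g <- build_geometry()
  pools <- list(Rt_RC = morphology_pool("Rt_RC", 2, g, seed = 1),
                VPL_TC = morphology_pool("VPL_TC", 2, g, seed = 2),
                VPL_IN = morphology_pool("VPL_IN", 2, g, seed = 3))
  spec <- density_spec(0.004)
  nodes <- assign_identities(place_somata(g, spec, seed = 2), spec, seed = 2)
  nodes <- suppressWarnings(place_morphology(nodes, pools, g, seed = 2))
  nodes <- nodes[!is.na(nodes$morphology), ]
  nodes <- nodes[seq_len(min(14, nrow(nodes))), ]
  circ <- circuit_segments(nodes, pools)
  s <- circ$segments
  pre_ok <- s$type == 2L | (s$mtype == "VPL_IN" & s$type == 3L)
  post_ok <- s$type %in% c(1L, 3L)
  seg_mat <- as.matrix(s[, c("x0", "y0", "z0", "x1", "y1", "z1", "radius")])
  fast <- thalamosim:::cpp_detect_touches(seg_mat, as.integer(s$cell), as.integer(s$node),
                             pre_ok, post_ok, 1)
  slow <- brute_force_touches(seg_mat, s$cell, pre_ok, post_ok, 1)
  key_fast <- sort(paste(fast$pre, fast$pre_node, fast$post, fast$post_node))
  key_slow <- sort(paste(s$cell[slow[, 1]], s$node[slow[, 1]],
                         s$cell[slow[, 2]], s$node[slow[, 2]]))
  expect_identical(key_fast, key_slow)
})

test_that("pathway filtering removes forbidden touches", {
  apps <- data.frame(
    pre = 1:5, post = 6:10,
    pre_mtype = c("VPL_TC", "VPL_IN", "Rt_RC", "Rt_RC", "VPL_TC"),
    post_mtype = c("VPL_TC", "Rt_RC", "VPL_IN", "VPL_TC", "Rt_RC"))
  out <- filter_touches(apps)
  expect_equal(out$pre_mtype, c("Rt_RC", "VPL_TC"))
  expect_equal(out$post_mtype, c("VPL_TC", "Rt_RC"))
  expect_equal(nrow(filter_touches(apps[0, ])), 0)
  # tally: removed = forbidden
  forb <- with(apps, (pre_mtype == "VPL_TC" & post_mtype == "VPL_TC") |
                 (pre_mtype == "VPL_IN" & post_mtype == "Rt_RC") |
                 (pre_mtype == "Rt_RC" & post_mtype == "VPL_IN"))
  expect_equal(nrow(apps) - nrow(out), sum(forb))
})

test_that("pruning toy instance matches the stated removal semantics", {
  # one axon, 100 um, 30 appositions in 10 connections, target 0.1/um
  set.seed(4)
  napp <- c(6, 5, 4, 4, 3, 2, 2, 2, 1, 1) # 30 total
  apps <- data.frame(
    pre = 1, post = rep(1:10 + 100, napp),
    pre_mtype = "Rt_RC", post_mtype = "VPL_TC",
    pre_node = 1, post_node = 1, gap = 0)
  axlen <- c("1" = 100)
  syn <- prune_to_constraints(apps, axlen,
                              bouton_density_target = c(Rt_RC = 0.1),
                              cv_target = 0.9, seed = 1)
  # target: 10 synapses on 100 um
  expect_equal(nrow(syn), 10, tolerance = 0)
  expect_true(all(table(syn$post) >= 1))
  # target at/above current density -> identity
  syn2 <- prune_to_constraints(apps, axlen,
                               bouton_density_target = c(Rt_RC = 0.5),
                               cv_target = 10, seed = 1)
  expect_equal(nrow(syn2), nrow(apps))
  # below-density warning
  expect_warning(
    prune_to_constraints(apps, c("1" = 1000),
                         bouton_density_target = c(Rt_RC = 0.1),
                         cv_target = 10, seed = 1),
    "below target")
})

test_that("gap-junction prediction and dye injection", {
  set.seed(2)
  n <- 400
  dendro <- data.frame(pre = sample(1:40, n, TRUE))
  dendro$post <- ((dendro$pre + sample(1:5, n, TRUE) - 1) %% 40) + 1
  dendro <- dendro[dendro$pre != dendro$post, ]
  a <- pmin(dendro$pre, dendro$post); b <- pmax(dendro$pre, dendro$post)
  dendro$pre <- a; dendro$post <- b
  # retention 1 keeps everything
  gj_all <- predict_gap_junctions(dendro, retention = 1, seed = 1)
  expect_equal(nrow(gj_all), nrow(dendro))
  expect_true(all(gj_all$conductance_nS == 0.2))
  # binomial thinning expectation at 30%
  ks <- replicate(40, nrow(predict_gap_junctions(dendro, retention = 0.3,
                                                 seed = sample.int(1e6, 1))))
  expect_equal(mean(ks) / nrow(dendro), 0.3, tolerance = 0.05)
  # divergence targeting reaches the requested mean partner count
  gj_t <- predict_gap_junctions(dendro, seed = 3, divergence_target = 4)
  cells <- unique(c(dendro$pre, dendro$post))
  partners <- vapply(cells, function(cc)
    length(unique(c(gj_t$post[gj_t$pre == cc], gj_t$pre[gj_t$post == cc]))),
    numeric(1))
  expect_equal(mean(partners), 4, tolerance = 1.2)

  # dye injection: empty table -> zeros; slab restriction honored
  nodes <- data.frame(id = 1:40, x = runif(40, -300, 300),
                      y = runif(40, 550, 800), z = runif(40, -200, 200),
                      region = "Rt")
  dye0 <- suppressWarnings(
    in_silico_dye_injection(gj_all[0, ], nodes, n_cells = 10))
  expect_true(all(dye0$divergence == 0))
  dye <- suppressWarnings(in_silico_dye_injection(gj_all, nodes,
                                                  n_cells = 10, seed = 2))
  expect_true(all(abs(nodes$x[match(dye$cells, nodes$id)]) <= 45))
  # sample mean comparable to full-population mean (binomial CI, loose)
  full_partners <- vapply(nodes$id, function(cc)
    length(unique(c(gj_all$post[gj_all$pre == cc],
                    gj_all$pre[gj_all$post == cc]))), numeric(1))
  expect_lt(abs(mean(dye$divergence) - mean(full_partners)),
            4 * sd(full_partners) / sqrt(length(dye$divergence)) + 1)
})

test_that("afferent fiber mapping follows the Gaussian kernel", {
  # closed form: fibers at lateral distances 0 and 25, sigma 25
  # -> odds exp(0.5) ~ 1.65 : 1 under the 2 sigma^2 convention
  odds <- exp(-0 / (2 * 25^2)) / exp(-25^2 / (2 * 25^2))
  expect_equal(odds, exp(0.5), tolerance = 1e-12)
  # Monte-Carlo assignment frequencies match the normalized kernel
  g <- build_geometry()
  pools <- list(VPL_TC = morphology_pool("VPL_TC", 2, g, seed = 2),
                Rt_RC = morphology_pool("Rt_RC", 1, g, seed = 1),
                VPL_IN = morphology_pool("VPL_IN", 1, g, seed = 1))
  spec <- density_spec(0.01)
  nodes <- assign_identities(place_somata(g, spec, seed = 6), spec, seed = 6)
  nodes <- suppressWarnings(place_morphology(nodes, pools, g, seed = 6))
  nodes <- nodes[!is.na(nodes$morphology), ]
  circ <- circuit_segments(nodes, pools)
  af <- build_afferent_synapses(circ, nodes, g, "ML",
                                volumetric_density = 4e-6,
                                n_fibers = 40, seed = 3)
  expect_equal(nrow(af$fibers), 40)
  expect_true(all(af$synapses$fiber %in% seq_len(40)))
  # synapses near each other share fibers more often than distant ones
  syn <- af$synapses
  if (nrow(syn) > 200) syn <- syn[sample(nrow(syn), 200), ]
  dmat <- as.matrix(dist(syn[, c("x", "z")]))
  same <- outer(syn$fiber, syn$fiber, "==")
  near <- dmat < 50 & upper.tri(dmat)
  far <- dmat > 200 & upper.tri(dmat)
  expect_gt(mean(same[near]), mean(same[far]))
  # empirical frequencies for one synapse position vs analytic kernel
  fib <- af$fibers
  sx <- 0; sz <- 0
  d2 <- (fib$x - sx)^2 + (fib$z - sz)^2
  w <- exp(-d2 / (2 * 25^2)); w <- w / sum(w)
  draws <- table(factor(replicate(3000, {
    near_i <- which(d2 < (5 * 25)^2)
    near_i[sample.int(length(near_i), 1, prob = exp(-d2[near_i] / (2 * 25^2)))]
  }), levels = seq_len(nrow(fib))))
  top <- order(w, decreasing = TRUE)[1:3]
  expect_equal(as.numeric(draws[top] / 3000), w[top], tolerance = 0.05)
  expect_error(build_afferent_synapses(circ, nodes, g, "ML", n_fibers = 0),
               "n_fibers")
})
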