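test_that("generator determinism and shape profiles", {
  m1 <- generate_morphology("Rt_RC", seed = 9)
  m2 <- generate_morphology("Rt_RC", seed = 9)
  expect_identical(m1$nodes, m2$nodes)
  # laterally elongated dendrites: x/z extent exceeds y extent
  d <- m1$nodes[m1$nodes$type == 3, ]
  expect_gt(diff(range(d$x)), diff(range(d$y)))
  expect_gt(diff(range(d$z)), diff(range(d$y)))
  expect_error(generate_morphology("Rt_RC",
    modifyList(morphgen_params("Rt_RC"), list(n_stems = 0))), "stems")

  # all generated VPL_TC have annotated collateral nodes in a band
  for (k in 1:15) {
    m <- generate_morphology("VPL_TC", seed = 100 + k)
    expect_gt(length(m$annotations$rt_collaterals), 0)
  }
})

test_that("unraveling straightens while preserving section lengths", {
  # straight section is unchanged
  nodes <- data.frame(id = 1:6, type = c(1L, rep(3L, 5)),
                      x = c(0, 1, 2, 3, 4, 5) * 10, y = 0, z = 0,
                      radius = 1, parent = c(-1L, 1:5))
  m <- thalamosim:::new_morphology(nodes)
  mu <- unravel(m)
  expect_equal(mu$nodes$x, m$nodes$x, tolerance = 1e-9)

  # planar zig-zag: tortuosity strictly decreases, length preserved
  ang <- rep(c(30, -30), 8) * pi / 180
  xs <- cumsum(cos(ang) * 10); ys <- cumsum(sin(ang) * 10)
  nz <- data.frame(id = 1:17, type = c(1L, rep(3L, 16)),
                   x = c(0, xs), y = c(0, ys), z = 0,
                   radius = 1, parent = c(-1L, 1:16))
  mz <- thalamosim:::new_morphology(nz)
  mzu <- unravel(mz, window = 5)
  expect_equal(sum(section_lengths(mzu)), sum(section_lengths(mz)),
               tolerance = 1e-3 * sum(section_lengths(mz)))
  expect_lt(mean(section_tortuosity(mzu), na.rm = TRUE),
            mean(section_tortuosity(mz), na.rm = TRUE))

  # realistic morphology: per-section lengths preserved to 0.1%,
  # near-idempotent on second application
  m3 <- generate_morphology("VPL_IN", seed = 4)
  m3u <- unravel(m3)
  expect_equal(section_lengths(m3u), section_lengths(m3),
               tolerance = 1e-3)
  m3uu <- unravel(m3u)
  t1 <- mean(section_tortuosity(m3u), na.rm = TRUE)
  t2 <- mean(section_tortuosity(m3uu), na.rm = TRUE)
  expect_lt(abs(t2 - t1) / t1, 0.01)
  validate_morphology(m3u)
})

test_that("cut detection flags terminals at the top slice plane", {
  # fixture: 3 terminals at z_max, 5 interior terminals
  mk_branch <- function(id0, parent, z_end) {
    data.frame(id = id0 + 0:2, type = 3L,
               x = runif(3, -5, 5), y = runif(3, -5, 5),
               z = c(z_end - 20, z_end - 10, z_end),
               radius = 1, parent = c(parent, id0, id0 + 1))
  }
  set.seed(1)
  nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                      radius = 5, parent = -1L)
  zs <- c(100, 100, 100, 50, 60, 40, 30, 20)
  for (k in seq_along(zs)) nodes <- rbind(nodes, mk_branch(1 + 3 * (k - 1) + 1, 1L, zs[k]))
  m <- thalamosim:::new_morphology(nodes)
  cut <- detect_cut_points(m, tolerance = 15)
  expect_length(cut, 3)
  expect_true(all(m$nodes$z[match(cut, m$nodes$id)] == 100))
  # terminals 20 um below z_max are not flagged at tolerance 15
  expect_false(any(m$nodes$z[match(cut, m$nodes$id)] <= 85))
  # tolerance 0 with a unique maximum flags exactly 1
  m$nodes$z[m$nodes$id == 4] <- 101
  expect_length(detect_cut_points(m, tolerance = 0), 1)
})

test_that("dendrite repair follows the reference statistics", {
  pool <- lapply(1:5, function(k) generate_morphology("VPL_TC", seed = k))
  stats <- build_repair_stats(pool)
  m <- pool[[1]]
  cut <- detect_cut_points(m, tolerance = 15)
  # termination probability 1 everywhere -> no growth
  stats_term <- stats
  stats_term$counts[, , "continue"] <- 0L
  stats_term$counts[, , "bifurcate"] <- 0L
  stats_term$counts[, , "terminate"] <- 1L
  m_t <- repair_dendrites(m, cut, stats_term, seed = 1)
  expect_equal(nrow(m_t$nodes), nrow(m$nodes))

  # regrown diameters equal the mean diameter of the last intact section
  m_r <- suppressWarnings(repair_dendrites(m, cut, stats, seed = 1))
  new_rows <- m_r$nodes[!(m_r$nodes$id %in% m$nodes$id), ]
  if (nrow(new_rows) > 0) {
    secs <- morphology_sections(m)
    for (cid in unique(intersect(cut, new_rows$parent))) {
      ci <- match(cid, m$nodes$id)
      sec <- NULL
      for (s in secs) if (ci %in% s[-1]) { sec <- s; break }
      expected_r <- mean(m$nodes$radius[sec[-1]])
      first_new <- new_rows[new_rows$parent == cid, ][1, ]
      expect_equal(first_new$radius, expected_r, tolerance = 1e-9)
    }
  }
  validate_morphology(m_r)

  # ensemble: repairing a cut morphology recovers dendritic mass
  # (scaled-down version of the distribution comparison: the repaired
  # length must exceed the cut length and move toward the intact one)
  intact_len <- total_length(m, 3L)
  cut_plane <- quantile(m$nodes$z, 0.8)
  # slice both neurite types so the top plane is the true z extent
  keep <- m$nodes$z <= cut_plane | m$nodes$type == 1L
  # drop subtrees above the plane
  nodes_cut <- m$nodes
  drop <- rep(FALSE, nrow(nodes_cut))
  pidx <- match(nodes_cut$parent, nodes_cut$id)
  for (i in seq_len(nrow(nodes_cut)))
    drop[i] <- (!keep[i]) || (!is.na(pidx[i]) && drop[pidx[i]])
  nodes_cut <- nodes_cut[!drop, ]
  mc <- thalamosim:::new_morphology(nodes_cut, mtype = m$mtype)
  cut2 <- detect_cut_points(mc, tolerance = 15)
  lens <- vapply(1:10, function(s) {
    total_length(suppressWarnings(repair_dendrites(mc, cut2, stats,
                                                   seed = s)), 3L)
  }, numeric(1))
  expect_gt(mean(lens), total_length(mc, 3L))
  expect_true(all(lens >= total_length(mc, 3L)))
})

test_that("diversification perturbs geometry but not topology", {
  m <- generate_morphology("VPL_IN", seed = 6)
  # sd 0 -> identity
  m0 <- diversify(m, seed = 1, length_sd = 0, angle_sd_deg = 0)
  expect_equal(as.matrix(m0$nodes[, c("x", "y", "z")]),
               as.matrix(m$nodes[, c("x", "y", "z")]), tolerance = 1e-9)
  # topology invariant
  md <- diversify(m, seed = 2)
  expect_identical(topology_hash(md), topology_hash(m))
  # section-length ratios have sd ~ 0.20 across an ensemble
  base_len <- section_lengths(m)
  ratios <- unlist(lapply(1:60, function(s) {
    section_lengths(diversify(m, seed = s)) / base_len
  }))
  expect_equal(sd(ratios), 0.20, tolerance = 0.04)
  expect_equal(mean(ratios), 1, tolerance = 0.02)
})

test_that("vertical scaling acts about the soma on y only", {
  m <- generate_morphology("Rt_RC", seed = 7)
  expect_equal(scale_vertical(m, 1)$nodes$y, m$nodes$y)
  ms <- scale_vertical(m, 1.025)
  expect_equal(diff(range(ms$nodes$y)) / diff(range(m$nodes$y)), 1.025,
               tolerance = 1e-12)
  expect_equal(ms$nodes$x, m$nodes$x)
  mss <- scale_vertical(ms, 1 / 1.025)
  expect_equal(mss$nodes$y, m$nodes$y, tolerance = 1e-9)
})

test_that("annotations are carried through the processing pipeline", {
  m <- generate_morphology("VPL_TC", seed = 11)
  out <- scale_vertical(diversify(unravel(m), seed = 1), 1.025)
  expect_identical(names(out$annotations), names(m$annotations))
  expect_identical(out$annotations$rt_collaterals,
                   m$annotations$rt_collaterals)
  validate_morphology(out)
})
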