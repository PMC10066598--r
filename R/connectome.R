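#' Build the segment table of a placed circuit
#'
#' Applies each cell's rotation and soma translation to its assigned
#' morphology and concatenates segment tables.
#'
#' @param nodes cell table from [place_morphology()].
#' @param pools named list of morphology pools per m-type.
#' @return list with `segments` (data.frame incl. cell, mtype) and
#'   `axon_length` (named per-cell total axon length, um).
#' @export
circuit_segments <- function(nodes, pools) {
  keep <- !is.na(nodes$morphology)
  segs <- vector("list", sum(keep))
  axlen <- numeric(nrow(nodes))
  j <- 0
  for (i in which(keep)) {
    m <- pools[[nodes$mtype[i]]][[nodes$morphology[i]]]
    mt <- transform_morphology(m, c(nodes$x[i], nodes$y[i], nodes$z[i]),
                               nodes$rotation[i])
    s <- morphology_segments(mt)
    s$cell <- nodes$id[i]
    s$mtype <- nodes$mtype[i]
    j <- j + 1
    segs[[j]] <- s
    axlen[i] <- total_length(mt, SWC_AXON)
  }
  list(segments = do.call(rbind, segs[seq_len(j)]),
       axon_length = stats::setNames(axlen, nodes$id))
}

#' Detect touches (appositions) in a placed circuit
#'
#' A touch is a pair of segments whose surface gap (centerline distance
#' minus both radii, clamped at 0) is at most `touch_distance`.
#' For `kind = "chemical"` the presynaptic element is an axon segment
#' (additionally, VPL_IN dendrites act presynaptically, since thalamic
#' interneurons largely connect through presynaptic dendrites) and the
#' postsynaptic element a dendrite or soma. For `kind = "dendrodendritic"`
#' (gap-junction candidates) both elements are Rt_RC dendrites or somata
#' and the default touch distance is 0.
#'
#' @param circ circuit segments from [circuit_segments()].
#' @param touch_distance maximum surface gap in um (default 1 for
#'   chemical, 0 for dendrodendritic).
#' @param kind "chemical" or "dendrodendritic".
#' @return apposition data.frame: pre, post, pre_node, post_node, gap,
#'   synapse midpoint x/y/z, pre_mtype, post_mtype, kind.
#' @export
detect_touches <- function(circ, touch_distance = NULL,
                           kind = c("chemical", "dendrodendritic")) {
  kind <- match.arg(kind)
  s <- circ$segments
  if (is.null(touch_distance))
    touch_distance <- if (kind == "chemical") 1 else 0
  if (kind == "chemical") {
    pre_ok <- s$type == SWC_AXON | (s$mtype == "VPL_IN" & s$type == SWC_DEND)
    post_ok <- s$type == SWC_DEND | s$type == SWC_SOMA
  } else {
    rt <- s$mtype == "Rt_RC"
    pre_ok <- rt & (s$type == SWC_DEND | s$type == SWC_SOMA)
    post_ok <- pre_ok
  }
  seg_mat <- as.matrix(s[, c("x0", "y0", "z0", "x1", "y1", "z1", "radius")])
  tt <- cpp_detect_touches(seg_mat, as.integer(s$cell), as.integer(s$node),
                           pre_ok, post_ok, touch_distance)
  if (nrow(tt) == 0) {
    tt$pre_mtype <- character(0)
    tt$post_mtype <- character(0)
    tt$kind <- character(0)
    return(tt)
  }
  mt <- s$mtype[match(tt$pre, s$cell)]
  tt$pre_mtype <- mt
  tt$post_mtype <- s$mtype[match(tt$post, s$cell)]
  if (kind == "dendrodendritic") {
    # dendrodendritic pairs are unordered: keep each pair once
    a <- pmin(tt$pre, tt$post)
    b <- pmax(tt$pre, tt$post)
    tt <- tt[!duplicated(data.frame(a, b, tt$pre_node, tt$post_node)) &
             tt$pre < tt$post, ]
  }
  tt$kind <- kind
  tt
}

#' Filter touches by pathway rules
#'
#' Removes forbidden pathways: interneuron-reticular touches in either
#' direction (INs do not extend into the Rt) and touches between VPL
#' relay cells (TC-TC connections are lost during development).
#'
#' @param apps apposition table from [detect_touches()].
#' @return filtered apposition table.
#' @export
filter_touches <- function(apps) {
  if (nrow(apps) == 0) return(apps)
  forb <- (apps$pre_mtype == "VPL_IN" & apps$post_mtype == "Rt_RC") |
          (apps$pre_mtype == "Rt_RC" & apps$post_mtype == "VPL_IN") |
          (apps$pre_mtype == "VPL_TC" & apps$post_mtype == "VPL_TC")
  apps[!forb, , drop = FALSE]
}

#' Prune appositions to biological constraints
#'
#' Three-step pruning. Steps 1-2 match the coefficient-of-variation
#' structure of synapses per connection: while the pooled CV of N_func
#' (sd/mean over connected pairs, per presynaptic m-type) exceeds
#' `cv_target`, one synapse is removed from the currently largest
#' connection. Step 3 removes whole (preferentially multi-synaptic)
#' connections at random until the mean axonal bouton density (kept
#' synapses per unit axon length over presynaptic axons) matches the
#' per-m-type target. N_func = 1 x N_app: every surviving apposition is a
#' functional synapse.
#'
#' @param apps filtered apposition table.
#' @param axon_length named per-cell total axon length (um) from
#'   [circuit_segments()].
#' @param bouton_density_target named vector, boutons/um per presynaptic
#'   m-type (defaults: Rt_RC 0.124, VPL_TC 0.102 from 3D axon
#'   reconstructions).
#' @param cv_target generalized coefficient of variation of N_func
#'   (default 0.9).
#' @param seed integer seed.
#' @return pruned apposition table (the synapse table).
#' @export
prune_to_constraints <- function(apps, axon_length,
                                 bouton_density_target =
                                   c(Rt_RC = 0.124, VPL_TC = 0.102),
                                 cv_target = 0.9, seed = 1) {
  set.seed(seed)
  if (nrow(apps) == 0) return(apps)
  apps$pair <- paste(apps$pre, apps$post)
  keep <- rep(TRUE, nrow(apps))

  for (mt in unique(apps$pre_mtype)) {
    rows <- which(apps$pre_mtype == mt)
    # steps 1-2: trim the largest connections until the pooled CV of
    # synapses per connection is at most cv_target; the per-connection
    # cap is the largest one achieving it (minimal pruning)
    pair_f <- factor(apps$pair[rows])
    nf <- tabulate(pair_f)
    if (length(nf) >= 2) {
      cv_of <- function(cap) {
        v <- pmin(nf, cap)
        stats::sd(v) / mean(v)
      }
      if (is.finite(cv_of(Inf)) && cv_of(Inf) > cv_target) {
        cap <- max(nf)
        while (cap > 1 && cv_of(cap) > cv_target) cap <- cap - 1
        over <- which(nf > cap)
        for (k in over) {
          cand <- rows[as.integer(pair_f) == k]
          keep[sample(cand, nf[k] - cap)] <- FALSE
        }
      }
    }
    # step 3: remove whole connections until the bouton density target
    if (!(mt %in% names(bouton_density_target))) next
    tgt <- bouton_density_target[[mt]]
    if (is.na(tgt)) next
    pres <- unique(apps$pre[rows])
    total_len <- sum(axon_length[as.character(pres)])
    if (!is.finite(total_len) || total_len <= 0) next
    dens <- sum(keep[rows]) / total_len
    if (dens <= tgt) {
      if (dens < tgt)
        warning(sprintf(
          "pre m-type %s: apposition density %.3f below target %.3f; keeping all",
          mt, dens, tgt))
      next
    }
    pr <- split(rows[keep[rows]], apps$pair[rows[keep[rows]]])
    sizes <- lengths(pr)
    # multi-synaptic connections removed first, random order within class
    ord <- order(-(sizes > 1), stats::runif(length(pr)))
    n_remove <- 0
    target_n <- tgt * total_len
    n_cur <- sum(keep[rows])
    for (k in ord) {
      if (n_cur - sizes[k] < target_n &&
          abs(n_cur - target_n) <= abs(n_cur - sizes[k] - target_n)) break
      keep[pr[[k]]] <- FALSE
      n_cur <- n_cur - sizes[k]
      n_remove <- n_remove + 1
      if (n_cur <= target_n) break
    }
  }
  out <- apps[keep, , drop = FALSE]
  out$pair <- NULL
  out
}

#' Observed bouton densities per presynaptic m-type
#' @param syn synapse table.
#' @param axon_length named per-cell axon length.
#' @return named vector, synapses per um of axon.
#' @export
bouton_density <- function(syn, axon_length) {
  vapply(split(syn, syn$pre_mtype), function(s) {
    pres <- unique(s$pre)
    nrow(s) / sum(axon_length[as.character(pres)])
  }, numeric(1))
}

#' Predict gap junctions from dendrodendritic appositions
#'
#' Retains a random fraction of Rt_RC dendrodendritic appositions as gap
#' junctions (default 30%, the fraction that matched experimental
#' divergence) with a fixed unitary conductance.
#'
#' @param dendro_apps dendrodendritic apposition table.
#' @param retention fraction of appositions kept (default 0.3).
#' @param conductance_nS per-junction conductance (default 0.2).
#' @param seed integer seed.
#' @return gap-junction table.
#' @export
predict_gap_junctions <- function(dendro_apps, retention = 0.3,
                                  conductance_nS = 0.2, seed = 1,
                                  divergence_target = NULL) {
  set.seed(seed)
  n <- nrow(dendro_apps)
  if (!is.null(divergence_target) && n > 0) {
    # tune the retention so the expected number of coupled partners per
    # cell matches the target: a pair stays coupled when at least one of
    # its k candidate junctions is kept
    pair <- paste(pmin(dendro_apps$pre, dendro_apps$post),
                  pmax(dendro_apps$pre, dendro_apps$post))
    k <- table(pair)
    cells <- unique(c(dendro_apps$pre, dendro_apps$post))
    mean_partners <- function(r)
      2 * sum(1 - (1 - r)^as.numeric(k)) / length(cells)
    if (mean_partners(1) <= divergence_target) retention <- 1
    else retention <- stats::uniroot(function(r)
      mean_partners(r) - divergence_target, c(1e-4, 1))$root
  }
  keep <- stats::runif(n) < retention
  gj <- dendro_apps[keep, , drop = FALSE]
  gj$conductance_nS <- rep(conductance_nS, nrow(gj))
  attr(gj, "retention") <- retention
  gj
}

#' In-silico dye injection
#'
#' Reproduces the experimental protocol: sample Rt cells within a
#' central vertical slice and report the number of gap-junction-coupled
#' partners and their soma distances.
#'
#' @param gj gap-junction table.
#' @param nodes cell table (for soma positions).
#' @param n_cells sample size (default 33).
#' @param slice_thickness slab width in x around the center (um, default
#'   90).
#' @param seed integer seed.
#' @return list with per-sampled-cell partner counts (`divergence`) and
#'   pooled partner soma distances (`distances`).
#' @export
in_silico_dye_injection <- function(gj, nodes, n_cells = 33,
                                    slice_thickness = 90, seed = 1) {
  set.seed(seed)
  rt <- nodes[nodes$region == "Rt", ]
  slab <- rt[abs(rt$x) <= slice_thickness / 2, ]
  if (nrow(slab) < n_cells) {
    warning(sprintf("only %d Rt cells in the slice; using all", nrow(slab)))
    samp <- slab$id
  } else samp <- sample(slab$id, n_cells)
  partners <- lapply(samp, function(cid) {
    unique(c(gj$post[gj$pre == cid], gj$pre[gj$post == cid]))
  })
  dists <- unlist(lapply(seq_along(samp), function(k) {
    i <- match(samp[k], nodes$id)
    j <- match(partners[[k]], nodes$id)
    if (!length(j)) return(numeric(0))
    sqrt((nodes$x[j] - nodes$x[i])^2 + (nodes$y[j] - nodes$y[i])^2 +
         (nodes$z[j] - nodes$z[i])^2)
  }))
  list(cells = samp, divergence = lengths(partners), distances = dists)
}

#' Build afferent (ML or CT) synapses with fiber mapping
#'
#' Synapse count = volumetric bouton density x target region volume.
#' Synapses are placed on postsynaptic dendrite segments proportionally
#' to segment length, then each synapse is assigned to a virtual fiber
#' with probability proportional to exp(-|f_i - T|^2 / (2 sigma^2))
#' where |f_i - T| is the lateral (x, z) distance between fiber and
#' synapse. Fibers sit on a jittered hexagonal lattice over the circuit
#' cross-section (ML fibers enter from the bottom face, CT from the top).
#'
#' @param circ circuit segments.
#' @param nodes cell table.
#' @param geom geometry.
#' @param pathway "ML" (targets VPL only) or "CT" (targets VPL and Rt).
#' @param volumetric_density boutons/um^3 (order-of-magnitude placeholder
#'   defaults; field values are configuration, not printed constants).
#' @param n_fibers number of virtual fibers (full scale: ML 2601, CT
#'   75325; scale with density_scale).
#' @param sigma spatial-mapping parameter (um, default 25).
#' @param kernel_exponent "two_sigma_sq" (Gaussian, default) or
#'   "sigma_sq" (the alternative reading of the mapping formula).
#' @param seed integer seed.
#' @return list: `synapses` (data.frame with post cell/node, xyz, fiber)
#'   and `fibers` (fiber lattice positions).
#' @export
build_afferent_synapses <- function(circ, nodes, geom,
                                    pathway = c("ML", "CT"),
                                    volumetric_density = NULL,
                                    n_fibers = NULL, sigma = 25,
                                    kernel_exponent = c("two_sigma_sq",
                                                        "sigma_sq"),
                                    seed = 1) {
  pathway <- match.arg(pathway)
  kernel_exponent <- match.arg(kernel_exponent)
  set.seed(seed)
  if (is.null(volumetric_density))
    volumetric_density <- if (pathway == "ML") 1.2e-4 else 2.8e-4
  if (is.null(n_fibers)) n_fibers <- if (pathway == "ML") 2601 else 75325
  if (n_fibers < 1) stop("n_fibers must be >= 1")

  s <- circ$segments
  tgt_region <- if (pathway == "ML") "VPL" else c("VPL", "Rt")
  cellreg <- nodes$region[match(s$cell, nodes$id)]
  s <- s[s$type == SWC_DEND & cellreg %in% tgt_region, ]
  seglen <- sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2 + (s$z1 - s$z0)^2)
  vol <- if (pathway == "ML") geom$vpl_volume_mm3 else geom$volume_mm3
  n_syn <- round(volumetric_density * vol * 1e9)
  n_syn <- min(n_syn, 50 * nrow(s)) # generator sanity cap
  pick <- sample(nrow(s), n_syn, replace = TRUE, prob = seglen)
  u <- stats::runif(n_syn)
  sx <- s$x0[pick] + u * (s$x1[pick] - s$x0[pick])
  sy <- s$y0[pick] + u * (s$y1[pick] - s$y0[pick])
  sz <- s$z0[pick] + u * (s$z1[pick] - s$z0[pick])

  fib <- hex_fiber_lattice(geom$hex_side, n_fibers, jitter = TRUE)
  denom <- if (kernel_exponent == "two_sigma_sq") 2 * sigma^2 else sigma^2
  fiber_id <- integer(n_syn)
  # assign per synapse; restrict to fibers within 5 sigma for speed
  for (i in seq_len(n_syn)) {
    d2 <- (fib$x - sx[i])^2 + (fib$z - sz[i])^2
    near <- which(d2 < (5 * sigma)^2 * max(1, denom / (2 * sigma^2)))
    if (!length(near)) near <- which.min(d2)
    w <- exp(-d2[near] / denom)
    fiber_id[i] <- near[sample.int(length(near), 1, prob = w)]
  }
  syn <- data.frame(
    pre = -fiber_id, post = s$cell[pick], post_node = s$node[pick],
    x = sx, y = sy, z = sz, fiber = fiber_id,
    pre_mtype = pathway, post_mtype = nodes$mtype[match(s$cell[pick],
                                                        nodes$id)],
    kind = "afferent")
  list(synapses = syn, fibers = fib, pathway = pathway, sigma = sigma)
}

#' Hexagonal fiber lattice over the circuit cross-section
#' @param side hexagon side (um).
#' @param n number of fibers.
#' @param jitter add uniform jitter of half a lattice pitch?
#' @return data.frame x, z of fiber entry points.
#' @export
hex_fiber_lattice <- function(side, n, jitter = TRUE) {
  area <- hexagon_area(side)
  pitch <- sqrt(area / n / (sqrt(3) / 2))
  xs <- seq(-side, side, by = pitch)
  zs <- seq(-side * sqrt(3) / 2, side * sqrt(3) / 2, by = pitch * sqrt(3) / 2)
  g <- expand.grid(x = xs, z = zs)
  odd <- rep(seq_along(zs) %% 2 == 1, each = length(xs))
  g$x <- g$x + ifelse(odd, 0, pitch / 2)
  if (jitter) {
    g$x <- g$x + stats::runif(nrow(g), -pitch / 4, pitch / 4)
    g$z <- g$z + stats::runif(nrow(g), -pitch / 4, pitch / 4)
  }
  g <- g[as.logical(cpp_in_hexagon(g$x, g$z, side)), ]
  if (nrow(g) > n) g <- g[sample(nrow(g), n), ]
  while (nrow(g) < n) {
    extra <- data.frame(x = stats::runif(n - nrow(g), -side, side),
                        z = stats::runif(n - nrow(g), -side, side))
    extra <- extra[as.logical(cpp_in_hexagon(extra$x, extra$z, side)), ]
    g <- rbind(g, extra)
  }
  rownames(g) <- NULL
  g
}
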