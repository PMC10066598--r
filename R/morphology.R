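#' @useDynLib thalamosim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# SWC type codes: 1 soma, 2 axon, 3 dendrite (thalamic neurons are
# multipolar; no apical/basal split)
SWC_SOMA <- 1L
SWC_AXON <- 2L
SWC_DEND <- 3L

new_morphology <- function(nodes, annotations = list(), mtype = NA_character_) {
  structure(list(nodes = nodes, annotations = annotations, mtype = mtype),
            class = "morphology")
}

#' @export
print.morphology <- function(x, ...) {
  n <- x$nodes
  cat(sprintf("morphology (%s): %d nodes, %.0f um axon, %.0f um dendrite\n",
              x$mtype, nrow(n),
              total_length(x, SWC_AXON), total_length(x, SWC_DEND)))
  if (length(x$annotations))
    cat("  annotations:", paste(names(x$annotations), collapse = ", "), "\n")
  invisible(x)
}

#' Validate morphology tree structure
#'
#' Checks: a single soma root, all parents precede their children, no
#' cycles, strictly positive radii.
#' @param m morphology.
#' @return TRUE invisibly; stops on violation.
#' @export
validate_morphology <- function(m) {
  n <- m$nodes
  roots <- which(n$parent == -1)
  if (length(roots) != 1 || n$type[roots] != SWC_SOMA)
    stop("morphology must have exactly one soma root")
  if (any(n$radius <= 0)) stop("all radii must be positive")
  idx <- match(n$parent, n$id)
  if (any(is.na(idx[-roots]))) stop("dangling parent reference")
  if (any(idx[-roots] >= seq_len(nrow(n))[-roots]))
    stop("parents must precede children")
  invisible(TRUE)
}

.children_map <- function(nodes) {
  split(seq_len(nrow(nodes))[nodes$parent != -1],
        factor(match(nodes$parent, nodes$id)[nodes$parent != -1],
               levels = seq_len(nrow(nodes))))
}

#' Decompose a morphology into unbranched sections
#'
#' A section is a maximal chain of nodes between branch points (or soma /
#' terminals). The returned chains start at the parent node of the first
#' section node, so consecutive sections share their junction node.
#' @param m morphology.
#' @return list of integer vectors of row indices into `m$nodes`.
#' @export
morphology_sections <- function(m) {
  n <- m$nodes
  nr <- nrow(n)
  nchild <- tabulate(match(n$parent, n$id), nbins = nr)
  pidx <- match(n$parent, n$id)
  sections <- list()
  # section starts: children of soma, or children of branch points
  starts <- which(!is.na(pidx) &
                  (n$type[pidx] == SWC_SOMA | nchild[pidx] != 1 |
                   n$type[pidx] != n$type))
  for (s in starts) {
    chain <- c(pidx[s], s)
    cur <- s
    while (nchild[cur] == 1) {
      nxt <- which(pidx == cur)
      if (n$type[nxt] != n$type[cur]) break
      chain <- c(chain, nxt)
      cur <- nxt
    }
    sections[[length(sections) + 1]] <- chain
  }
  sections
}

.seg_lengths <- function(nodes, idx) {
  p <- as.matrix(nodes[idx, c("x", "y", "z")])
  sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
}

#' Total neurite length by SWC type
#' @param m morphology.
#' @param type SWC type code (2 axon, 3 dendrite).
#' @return length in micrometers.
#' @export
total_length <- function(m, type) {
  n <- m$nodes
  pidx <- match(n$parent, n$id)
  sel <- which(n$type == type & !is.na(pidx) & n$type[pidx] == type)
  if (!length(sel)) return(0)
  dx <- n$x[sel] - n$x[pidx[sel]]
  dy <- n$y[sel] - n$y[pidx[sel]]
  dz <- n$z[sel] - n$z[pidx[sel]]
  sum(sqrt(dx^2 + dy^2 + dz^2))
}

#' Vertical spans of a morphology and its annotations
#'
#' @param m morphology.
#' @return list with `full` = range of y over all nodes (relative to the
#'   soma) and one y-range per annotation.
#' @export
morphology_spans <- function(m) {
  y0 <- m$nodes$y[m$nodes$parent == -1][1]
  out <- list(full = range(m$nodes$y) - y0)
  for (a in names(m$annotations)) {
    idx <- match(m$annotations[[a]], m$nodes$id)
    out[[a]] <- range(m$nodes$y[idx]) - y0
  }
  out
}

# ---------------------------------------------------------------------------
# synthetic morphology generation

#' Generator parameters per m-type
#'
#' Synthetic stand-ins for reconstructed morphologies. Shape profiles:
#' Rt_RC dendrites are elongated laterally (discoid arbor in the plane of
#' the nucleus) and the axon descends into the VPL where its densest
#' arborization lies; VPL_TC dendrites form a compact bush and the axon
#' ascends, giving off a collateral arbor in the Rt on its way to cortex;
#' VPL_IN arbors are local and confined to the VPL.
#'
#' @param mtype one of "Rt_RC", "VPL_TC", "VPL_IN".
#' @return list of generator parameters (lengths in um).
#' @export
morphgen_params <- function(mtype) {
  switch(mtype,
    Rt_RC = list(
      n_stems = 5, seg_len = 12, branch_prob = 0.010, tortuosity = 0.25,
      dend_reach = 190, lateral_bias = 0.75, dend_len = 10500,
      axon_trunk = 280, axon_arbor_span = 380, axon_len = 4000,
      axon_local_len = 900, axon_lateral = 160, soma_radius = 7,
      dend_radius = 1.5, axon_radius = 0.7, taper = 0.15),
    VPL_TC = list(
      n_stems = 7, seg_len = 10, branch_prob = 0.016, tortuosity = 0.3,
      dend_reach = 150, lateral_bias = 0, dend_len = 6500,
      axon_trunk = 620, axon_arbor_span = 160, axon_len = 2800,
      axon_lateral = 130, soma_radius = 8, dend_radius = 1.7,
      axon_radius = 0.7, taper = 0.2),
    VPL_IN = list(
      n_stems = 4, seg_len = 10, branch_prob = 0.012, tortuosity = 0.35,
      dend_reach = 120, lateral_bias = 0, dend_len = 2400,
      axon_trunk = 30, axon_arbor_span = 160, axon_len = 700,
      axon_lateral = 90, soma_radius = 5, dend_radius = 1.0,
      axon_radius = 0.4, taper = 0.15),
    stop("unknown m-type: ", mtype))
}

.rnorm3 <- function(sd) stats::rnorm(3, 0, sd)
.normalize <- function(v) v / sqrt(sum(v^2))

# random arbor growth from a start node; returns node rows
.grow_arbor <- function(env, start_id, start_pos, start_dir, type, radius,
                        seg_len, branch_prob, tortuosity, len_budget,
                        keep_fun, bias_dir = NULL, bias_w = 0) {
  tips <- list(list(id = start_id, pos = start_pos, dir = start_dir,
                    r = radius))
  used <- 0
  while (length(tips) > 0 && used < len_budget) {
    tip <- tips[[1]]
    tips <- tips[-1]
    d <- .normalize(tip$dir + .rnorm3(tortuosity))
    if (!is.null(bias_dir)) d <- .normalize(d + bias_w * bias_dir)
    L <- seg_len * stats::runif(1, 0.7, 1.3)
    pos <- tip$pos + d * L
    if (!keep_fun(pos)) {
      # redirect rather than terminate, so arbors fill their allowed
      # extent and realized lengths track the budget
      ok <- FALSE
      for (k in 1:6) {
        d <- .normalize(.rnorm3(1))
        pos <- tip$pos + d * L
        if (keep_fun(pos)) { ok <- TRUE; break }
      }
      if (!ok) next
    }
    used <- used + L
    id <- env$next_id
    env$next_id <- id + 1L
    r <- max(0.3, tip$r)
    env$rows[[length(env$rows) + 1]] <-
      list(id = id, type = type, x = pos[1], y = pos[2], z = pos[3],
           radius = r, parent = tip$id)
    if (stats::runif(1) < branch_prob * L) {
      ax <- .normalize(.rnorm3(1))
      perp <- .normalize(pracma_cross(d, ax))
      ang <- stats::runif(1, 0.3, 0.8)
      d1 <- .normalize(cos(ang) * d + sin(ang) * perp)
      d2 <- .normalize(cos(ang) * d - sin(ang) * perp)
      rc <- max(0.35, r * 0.92)
      tips <- c(tips, list(list(id = id, pos = pos, dir = d1, r = rc),
                           list(id = id, pos = pos, dir = d2, r = rc)))
    } else {
      tips <- c(tips, list(list(id = id, pos = pos, dir = d, r = r * 0.995)))
    }
    # rotate the tip queue to grow breadth-first
    if (length(tips) > 1) tips <- c(tips[-1], tips[1])
  }
  invisible(NULL)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a synthetic morphology
#'
#' Grows a random tree according to the m-type's shape profile (see
#' [morphgen_params()]). Axonal target-region annotations are derived
#' automatically: for VPL_TC the collateral arbor nodes are annotated
#' "rt_collaterals"; for Rt_RC the descending arbor nodes are annotated
#' "dense_axon_arbor".
#'
#' @param mtype m-type name.
#' @param params generator parameters; default [morphgen_params()].
#' @param seed integer seed (same seed, same morphology).
#' @return a `morphology` object in local coordinates (soma at origin).
#' @export
generate_morphology <- function(mtype, params = morphgen_params(mtype),
                                seed = 1) {
  if (params$n_stems < 1) stop("degenerate parameters: zero stems")
  set.seed(seed)
  env <- new.env()
  env$rows <- list(list(id = 1L, type = SWC_SOMA, x = 0, y = 0, z = 0,
                        radius = params$soma_radius, parent = -1L))
  env$next_id <- 2L

  # dendrites
  for (s in seq_len(params$n_stems)) {
    d0 <- .normalize(.rnorm3(1))
    if (params$lateral_bias > 0)
      d0 <- .normalize(d0 * c(1, 1 - params$lateral_bias, 1))
    reach <- params$dend_reach
    bias <- params$lateral_bias
    keep <- function(pos) {
      r2 <- if (bias > 0)
        sum((pos * c(1, 1 / (1 - 0.6 * bias), 1))^2) else sum(pos^2)
      r2 < reach^2
    }
    .grow_arbor(env, 1L, c(0, 0, 0), d0, SWC_DEND, params$dend_radius,
                params$seg_len, params$branch_prob, params$tortuosity,
                params$dend_len / params$n_stems, keep)
  }

  # axon: trunk then arbor; direction depends on m-type. Rt_RC axons
  # additionally give off local collaterals within the Rt before
  # descending (the substrate of intra-reticular inhibition).
  trunk_dir <- switch(mtype, Rt_RC = c(0, -1, 0), VPL_TC = c(0, 1, 0),
                      VPL_IN = .normalize(.rnorm3(1)))
  if (mtype == "Rt_RC" && !is.null(params$axon_local_len) &&
      params$axon_local_len > 0) {
    keep_local <- function(p) {
      p[1]^2 + p[3]^2 < 200^2 && p[2] > -60 && p[2] < 60
    }
    .grow_arbor(env, 1L, c(0, 0, 0), .normalize(.rnorm3(1)), SWC_AXON,
                params$axon_radius, params$seg_len, 0.02, 0.45,
                params$axon_local_len, keep_local)
  }
  trunk_n <- max(2, round(params$axon_trunk / 12))
  prev <- 1L
  pos <- c(0, 0, 0)
  first_axon <- env$next_id
  for (k in seq_len(trunk_n)) {
    pos <- pos + .normalize(trunk_dir + .rnorm3(0.05)) * params$axon_trunk / trunk_n
    id <- env$next_id
    env$next_id <- id + 1L
    env$rows[[length(env$rows) + 1]] <-
      list(id = id, type = SWC_AXON, x = pos[1], y = pos[2], z = pos[3],
           radius = params$axon_radius, parent = prev)
    prev <- id
  }
  arbor_first <- env$next_id
  y_c <- pos[2] + sign(trunk_dir[2] + 1e-9) * params$axon_arbor_span / 2
  span <- params$axon_arbor_span
  lat <- params$axon_lateral
  keep_ax <- function(p) {
    abs(p[2] - y_c) < span / 2 && p[1]^2 + p[3]^2 < lat^2
  }
  .grow_arbor(env, prev, pos, .normalize(trunk_dir + .rnorm3(0.3)), SWC_AXON,
              params$axon_radius, params$seg_len, 0.03, 0.5,
              params$axon_len - params$axon_trunk, keep_ax)

  nodes <- do.call(rbind.data.frame, env$rows)
  ann <- list()
  arbor_ids <- nodes$id[nodes$id >= arbor_first & nodes$type == SWC_AXON]
  if (!length(arbor_ids)) arbor_ids <- nodes$id[nodes$type == SWC_AXON]
  if (mtype == "VPL_TC") ann$rt_collaterals <- arbor_ids
  if (mtype == "Rt_RC") ann$dense_axon_arbor <- arbor_ids
  m <- new_morphology(nodes, ann, mtype)
  validate_morphology(m)
  m
}

#' Generate a pool of morphologies for one m-type
#'
#' VPL_TC axon trunk lengths are spread over a range so that every soma
#' depth in the VPL finds a morphology whose Rt collateral band lands in
#' the Rt slab.
#'
#' @param mtype m-type.
#' @param n pool size.
#' @param geom geometry (used to spread VPL_TC trunk lengths).
#' @param seed integer seed.
#' @return list of morphologies.
#' @export
morphology_pool <- function(mtype, n = 12, geom = build_geometry(), seed = 1) {
  lapply(seq_len(n), function(k) {
    p <- morphgen_params(mtype)
    if (mtype == "VPL_TC") {
      # trunk must carry the collateral band center from soma depth y0 into
      # the Rt slab; spread trunks to cover all soma depths
      depth <- (k - 0.5) / n * geom$vpl_height
      p$axon_trunk <- geom$vpl_height - depth +
        stats::runif(1, 0.1, 0.3) * geom$rt_height
    }
    if (mtype == "Rt_RC") {
      depth <- (k - 0.5) / n * geom$rt_height
      p$axon_trunk <- depth + 20
      p$axon_arbor_span <- min(380, geom$vpl_height - 50)
    }
    generate_morphology(mtype, p, seed = seed * 1000 + k)
  })
}

# ---------------------------------------------------------------------------
# morphology processing pipeline

#' Unravel a morphology
#'
#' Straightens tortuosity introduced by tissue shrinkage. Per section, a
#' sliding window of `window` points is moved along the section; the
#' segment at the middle of each window is re-aligned along the window's
#' principal direction (first principal component of the windowed points,
#' sign chosen to preserve forward progression) while retaining its
#' original length. Section path lengths are preserved exactly; the reach
#' of tortuous branches increases.
#'
#' @param m morphology.
#' @param window number of points in the sliding window (default 5).
#' @return unraveled morphology.
#' @export
unravel <- function(m, window = 5) {
  if (window < 2) stop("window must be >= 2")
  nodes <- m$nodes
  secs <- morphology_sections(m)
  # process root-to-leaf so parents move before children
  for (sec in secs) {
    P <- as.matrix(nodes[sec, c("x", "y", "z")])
    k <- nrow(P) - 1  # segments
    if (k < 1) next
    lens <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-(k + 1), , drop = FALSE])^2))
    Q <- P
    for (i in seq_len(k)) {
      lo <- max(1, i - floor((window - 1) / 2))
      hi <- min(k + 1, lo + window - 1)
      lo <- max(1, hi - window + 1)
      W <- P[lo:hi, , drop = FALSE]
      u <- if (nrow(W) >= 2) {
        pc <- prcomp(W, center = TRUE, scale. = FALSE)
        v <- pc$rotation[, 1]
        fwd <- P[hi, ] - P[lo, ]
        if (sum(v * fwd) < 0) v <- -v
        v
      } else .normalize(P[i + 1, ] - P[i, ])
      seg <- P[i + 1, ] - P[i, ]
      if (sum(seg^2) > 0 && sum(u^2) > 0)
        Q[i + 1, ] <- Q[i, ] + u * lens[i]
      else Q[i + 1, ] <- Q[i, ] + seg
    }
    nodes[sec[-1], c("x", "y", "z")] <- Q[-1, , drop = FALSE]
    # shift subtrees hanging off this section's nodes (reached through a
    # child that is itself outside the section) by their anchor's
    # displacement
    delta <- Q[-1, , drop = FALSE] - P[-1, , drop = FALSE]
    pidx <- match(nodes$parent, nodes$id)
    for (j in seq_along(sec[-1])) {
      if (all(abs(delta[j, ]) < 1e-12)) next
      anchor <- sec[-1][j]
      kids <- which(pidx == anchor)
      kids <- setdiff(kids, sec)
      for (c in kids) {
        sub <- c(c, .subtree(nodes, c))
        nodes[sub, c("x", "y", "z")] <-
          sweep(as.matrix(nodes[sub, c("x", "y", "z")]), 2, delta[j, ], "+")
      }
    }
  }
  out <- m
  out$nodes <- nodes
  out
}

# row indices of the subtree rooted at row `root` (excluded)
.subtree <- function(nodes, root) {
  pidx <- match(nodes$parent, nodes$id)
  keep <- logical(nrow(nodes))
  keep[root] <- TRUE
  for (i in seq_len(nrow(nodes))) {
    if (!is.na(pidx[i]) && keep[pidx[i]]) keep[i] <- TRUE
  }
  which(keep & seq_len(nrow(nodes)) != root)
}

#' Detect cut points at the top slice plane
#'
#' Terminal dendrite points within `tolerance` of the maximal z extent are
#' flagged as cut by the slicing procedure (slices are cut along z; only
#' the top plane is searched).
#'
#' @param m morphology in slice coordinates (z = slice-thickness axis).
#' @param tolerance distance from the maximal z extent (um, default 15).
#' @return node ids of flagged terminals.
#' @export
detect_cut_points <- function(m, tolerance = 15) {
  n <- m$nodes
  nchild <- tabulate(match(n$parent, n$id), nbins = nrow(n))
  term <- which(nchild == 0 & n$type == SWC_DEND)
  if (!length(term)) return(integer(0))
  zmax <- max(n$z)
  n$id[term][n$z[term] >= zmax - tolerance]
}

#' Reference statistics for dendrite repair
#'
#' Tallies branch continuation / bifurcation / termination events of
#' intact dendrites, binned by branch order and concentric 20-um radial
#' shells around the soma, and records segment-length statistics used to
#' grow repaired branches.
#'
#' @param pool list of morphologies with intact dendrites.
#' @param shell_width radial shell width in um (default 20).
#' @return a `repair_stats` list.
#' @export
build_repair_stats <- function(pool, shell_width = 20) {
  max_order <- 6L
  max_shell <- 30L
  counts <- array(0L, dim = c(max_order + 1, max_shell, 3),
                  dimnames = list(NULL, NULL, c("continue", "bifurcate",
                                                "terminate")))
  seg_lens <- c()
  for (m in pool) {
    n <- m$nodes
    pidx <- match(n$parent, n$id)
    nchild <- tabulate(pidx, nbins = nrow(n))
    soma <- which(n$parent == -1)
    # branch order: number of bifurcations on the path from the soma
    ord <- integer(nrow(n))
    for (i in seq_len(nrow(n))) {
      if (is.na(pidx[i])) next
      ord[i] <- ord[pidx[i]] + as.integer(nchild[pidx[i]] >= 2)
    }
    dend <- which(n$type == SWC_DEND)
    r <- sqrt((n$x - n$x[soma])^2 + (n$y - n$y[soma])^2 +
              (n$z - n$z[soma])^2)
    for (i in dend) {
      o <- min(ord[i], max_order) + 1L
      s <- min(max(1L, ceiling(r[i] / shell_width)), max_shell)
      ev <- if (nchild[i] == 0) 3L else if (nchild[i] >= 2) 2L else 1L
      counts[o, s, ev] <- counts[o, s, ev] + 1L
    }
    sel <- dend[!is.na(pidx[dend])]
    seg_lens <- c(seg_lens, sqrt((n$x[sel] - n$x[pidx[sel]])^2 +
                                 (n$y[sel] - n$y[pidx[sel]])^2 +
                                 (n$z[sel] - n$z[pidx[sel]])^2))
  }
  structure(list(counts = counts, shell_width = shell_width,
                 mean_seg_len = mean(seg_lens), sd_seg_len = stats::sd(seg_lens)),
            class = "repair_stats")
}

#' Repair cut dendrites
#'
#' Grows new dendritic sections from each cut point by sampling
#' continue / bifurcate / terminate per (branch order, radial shell) bin
#' of the reference statistics. Empty bins fall back to the nearest
#' populated shell of the same order (with a warning). Regrown node
#' diameters are set to the mean diameter of the last intact section.
#'
#' @param m morphology.
#' @param cut_ids node ids from [detect_cut_points()].
#' @param stats reference from [build_repair_stats()].
#' @param seed integer seed.
#' @param max_steps growth-step cap per cut point.
#' @return repaired morphology.
#' @export
repair_dendrites <- function(m, cut_ids, stats, seed = 1, max_steps = 300) {
  set.seed(seed)
  nodes <- m$nodes
  pidx0 <- match(nodes$parent, nodes$id)
  soma <- which(nodes$parent == -1)
  warned <- FALSE
  next_id <- max(nodes$id) + 1L
  rows <- list()
  secs <- morphology_sections(m)
  for (cid in cut_ids) {
    ci <- match(cid, nodes$id)
    # mean diameter of the last intact section containing the cut point
    sec <- NULL
    for (s in secs) if (ci %in% s[-1]) { sec <- s; break }
    r_new <- if (is.null(sec)) nodes$radius[ci] else mean(nodes$radius[sec[-1]])
    dir <- if (!is.na(pidx0[ci])) {
      .normalize(c(nodes$x[ci] - nodes$x[pidx0[ci]],
                   nodes$y[ci] - nodes$y[pidx0[ci]],
                   nodes$z[ci] - nodes$z[pidx0[ci]]))
    } else c(0, 0, 1)
    # branch order at the cut point
    nchild <- tabulate(pidx0, nbins = nrow(nodes))
    ord <- 0L
    j <- ci
    while (!is.na(pidx0[j])) {
      if (nchild[pidx0[j]] >= 2) ord <- ord + 1L
      j <- pidx0[j]
    }
    tips <- list(list(id = cid, pos = c(nodes$x[ci], nodes$y[ci], nodes$z[ci]),
                      dir = dir, ord = min(ord, dim(stats$counts)[1] - 1L)))
    steps <- 0
    while (length(tips) > 0 && steps < max_steps) {
      steps <- steps + 1
      tip <- tips[[1]]
      tips <- tips[-1]
      r_shell <- sqrt(sum((tip$pos - c(nodes$x[soma], nodes$y[soma],
                                       nodes$z[soma]))^2))
      s <- min(max(1L, ceiling(r_shell / stats$shell_width)),
               dim(stats$counts)[2])
      cnt <- stats$counts[tip$ord + 1L, s, ]
      if (sum(cnt) == 0) {
        # nearest populated shell of this order
        avail <- which(apply(stats$counts[tip$ord + 1L, , , drop = FALSE], 2,
                             sum) > 0)
        if (!length(avail)) { next }
        s2 <- avail[which.min(abs(avail - s))]
        cnt <- stats$counts[tip$ord + 1L, s2, ]
        if (!warned) {
          warning("empty repair-reference bin; falling back to nearest populated shell")
          warned <- TRUE
        }
      }
      ev <- sample(3, 1, prob = cnt)
      if (ev == 3) next # terminate
      L <- max(1, stats::rnorm(1, stats$mean_seg_len, stats$sd_seg_len))
      d <- .normalize(tip$dir + .rnorm3(0.3))
      pos <- tip$pos + d * L
      id <- next_id
      next_id <- next_id + 1L
      rows[[length(rows) + 1]] <-
        list(id = id, type = SWC_DEND, x = pos[1], y = pos[2], z = pos[3],
             radius = r_new, parent = tip$id)
      if (ev == 2) { # bifurcate
        ax <- .normalize(.rnorm3(1))
        perp <- .normalize(pracma_cross(d, ax))
        ang <- stats::runif(1, 0.3, 0.8)
        tips <- c(tips,
                  list(list(id = id, pos = pos,
                            dir = .normalize(cos(ang) * d + sin(ang) * perp),
                            ord = min(tip$ord + 1L, dim(stats$counts)[1] - 1L)),
                       list(id = id, pos = pos,
                            dir = .normalize(cos(ang) * d - sin(ang) * perp),
                            ord = min(tip$ord + 1L, dim(stats$counts)[1] - 1L))))
      } else {
        tips <- c(tips, list(list(id = id, pos = pos, dir = d, ord = tip$ord)))
      }
    }
  }
  if (length(rows))
    nodes <- rbind(nodes, do.call(rbind.data.frame, rows))
  out <- m
  out$nodes <- nodes
  validate_morphology(out)
  out
}

#' Diversify a morphology
#'
#' Produces a structural variant: every section length is scaled by
#' 1 + N(0, length_sd) (clamped positive) and each branch at a
#' bifurcation is rotated about its parent direction by N(0, angle_sd)
#' degrees. Topology (node count, parent relations, types) is unchanged.
#'
#' @param m morphology.
#' @param seed integer seed.
#' @param length_sd standard deviation of relative length change
#'   (default 0.20).
#' @param angle_sd_deg standard deviation of branch rotations in degrees
#'   (default 20).
#' @return diversified morphology.
#' @export
diversify <- function(m, seed = 1, length_sd = 0.20, angle_sd_deg = 20) {
  set.seed(seed)
  nodes <- m$nodes
  secs <- morphology_sections(m)
  if (!length(secs)) return(m)
  # map: section index by its first (non-anchor) node
  sec_start <- vapply(secs, function(s) s[2], integer(1))
  sec_anchor <- vapply(secs, function(s) s[1], integer(1))
  new_xyz <- as.matrix(nodes[, c("x", "y", "z")])
  pidx <- match(nodes$parent, nodes$id)
  nchild <- tabulate(pidx, nbins = nrow(nodes))

  # process sections in root-to-leaf order, carrying an accumulated
  # rotation per section
  R_acc <- replicate(length(secs), diag(3), simplify = FALSE)
  ord <- order(sec_anchor)
  for (si in ord) {
    sec <- secs[[si]]
    P <- as.matrix(nodes[sec, c("x", "y", "z")])
    v <- P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE]
    f <- max(0.05, 1 + stats::rnorm(1, 0, length_sd))
    R <- R_acc[[si]]
    start <- new_xyz[sec[1], ]
    for (i in seq_len(nrow(v))) {
      w <- as.numeric(R %*% v[i, ]) * f
      start <- start + w
      new_xyz[sec[i + 1], ] <- start
    }
    # children sections attach at nodes of this section
    end_dir <- .normalize(as.numeric(R %*% v[nrow(v), ]))
    for (sj in which(sec_anchor %in% sec[-1])) {
      Rj <- R
      if (nchild[sec_anchor[sj]] >= 2) {
        ang <- stats::rnorm(1, 0, angle_sd_deg) * pi / 180
        Rj <- R %*% .rotation_about(end_dir, ang)
      }
      R_acc[[sj]] <- Rj
    }
  }
  out <- m
  out$nodes[, c("x", "y", "z")] <- new_xyz
  out
}

.rotation_about <- function(axis, theta) {
  a <- .normalize(axis)
  c <- cos(theta); s <- sin(theta); C <- 1 - c
  matrix(c(
    a[1]^2 * C + c, a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
    a[2] * a[1] * C + a[3] * s, a[2]^2 * C + c, a[2] * a[3] * C - a[1] * s,
    a[3] * a[1] * C - a[2] * s, a[3] * a[2] * C + a[1] * s, a[3]^2 * C + c),
    3, 3, byrow = TRUE)
}

#' Scale a morphology along the vertical axis
#'
#' @param m morphology.
#' @param factor vertical scale factor (the pipeline uses 0.975 and
#'   1.025, i.e. +/- 2.5%).
#' @return morphology with y-coordinates scaled about the soma.
#' @export
scale_vertical <- function(m, factor) {
  soma <- which(m$nodes$parent == -1)
  y0 <- m$nodes$y[soma]
  m$nodes$y <- y0 + (m$nodes$y - y0) * factor
  m
}

#' Topology fingerprint (parent relations and types)
#' @param m morphology.
#' @return a character string invariant under geometric changes.
#' @export
topology_hash <- function(m) {
  paste(c(m$nodes$parent, m$nodes$type), collapse = ",")
}

#' Tortuosity of a section polyline
#' @param m morphology.
#' @return per-section path/Euclidean length ratios.
#' @export
section_tortuosity <- function(m) {
  vapply(morphology_sections(m), function(sec) {
    P <- as.matrix(m$nodes[sec, c("x", "y", "z")])
    path <- sum(sqrt(rowSums((P[-1, , drop = FALSE] -
                              P[-nrow(P), , drop = FALSE])^2)))
    eucl <- sqrt(sum((P[nrow(P), ] - P[1, ])^2))
    if (eucl < 1e-9) NA_real_ else path / eucl
  }, numeric(1))
}

#' Section path lengths
#' @param m morphology.
#' @return numeric vector of per-section path lengths (um).
#' @export
section_lengths <- function(m) {
  vapply(morphology_sections(m), function(sec) sum(.seg_lengths(m$nodes, sec)),
         numeric(1))
}

#' Rigidly transform a morphology to a soma position with a y-rotation
#' @param m morphology (soma at origin).
#' @param position numeric xyz of the soma (um).
#' @param rotation angle about the vertical axis (radians).
#' @return transformed morphology.
#' @export
transform_morphology <- function(m, position, rotation = 0) {
  cs <- cos(rotation); sn <- sin(rotation)
  x <- m$nodes$x; z <- m$nodes$z
  m$nodes$x <- cs * x + sn * z + position[1]
  m$nodes$z <- -sn * x + cs * z + position[3]
  m$nodes$y <- m$nodes$y + position[2]
  m
}

#' Segment table of a morphology
#'
#' One row per (parent, node) segment with endpoint coordinates and the
#' mean of the endpoint radii; used by touch detection.
#' @param m morphology.
#' @return data.frame x0..z1, radius, node, type.
#' @export
morphology_segments <- function(m) {
  n <- m$nodes
  pidx <- match(n$parent, n$id)
  sel <- which(!is.na(pidx))
  data.frame(
    x0 = n$x[pidx[sel]], y0 = n$y[pidx[sel]], z0 = n$z[pidx[sel]],
    x1 = n$x[sel], y1 = n$y[sel], z1 = n$z[sel],
    radius = (n$radius[sel] + pmin(n$radius[pidx[sel]], 2)) / 2,
    node = n$id[sel], type = n$type[sel])
}
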