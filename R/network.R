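#' Assemble an executable network
#'
#' Groups the synapse table into connections (one engine edge per
#' connected pair; the number of release sites equals the number of
#' synapses of the connection), draws per-connection Tsodyks-Markram
#' parameters from the pathway physiology table (truncated Gaussians),
#' assigns receptor classes and conduction delays, maps afferent
#' synapses to virtual-fiber edges, and compensates leak conductances
#' for the gap-junction load so input resistances are preserved.
#'
#' Delays: 0.5 ms synaptic latency plus conduction at 300 um/ms over the
#' soma-to-soma distance; gap junctions have no delay. `g_compensation`
#' asks that per-cell synaptic input be preserved in subsampled
#' desk-scale circuits; because the bouton-density constraint fixes
#' synapses per axon and afferent counts scale with the cell count, the
#' required conductance factor is unity for constraint-based builds.
#'
#' @param nodes cell table (id, position, mtype, etype).
#' @param syn chemical synapse table from [prune_to_constraints()].
#' @param gj gap-junction table from [predict_gap_junctions()] (may be
#'   NULL).
#' @param afferents named list of results from
#'   [build_afferent_synapses()] (may be empty).
#' @param emodels named list from [default_emodels()].
#' @param pathways pathway table from [pathway_physiology()].
#' @param density_scale the circuit's density scale (1 = full).
#' @param g_compensation compensate conductances by 1/density_scale?
#' @param seed integer seed for parameter draws.
#' @return a `thalamic_network` object consumed by [run_simulation()].
#' @export
build_network <- function(nodes, syn, gj = NULL, afferents = list(),
                          emodels = default_emodels(),
                          pathways = pathway_physiology(),
                          density_scale = 1, g_compensation = TRUE,
                          seed = 1) {
  set.seed(seed)
  n <- nrow(nodes)
  idx <- stats::setNames(seq_len(n) - 1L, nodes$id) # 0-based engine index
  par <- emodel_matrix(emodels[emodel_key(nodes$mtype, nodes$etype)])

  # Per-cell synaptic input is preserved under density subsampling by
  # construction: intrathalamic convergence is fixed by the per-axon
  # bouton-density constraint, and afferent synapse counts scale with the
  # same density factor as the cell count. The conductance-compensation
  # factor that restores full-scale per-cell input is therefore unity;
  # the flag is kept for builds that bypass those constraints.
  gcomp_aff <- 1
  classes <- synapse_classes()
  cls_id <- stats::setNames(seq_len(nrow(classes)) - 1L, classes$name)

  edge_rows <- list()
  add_edges <- function(tab, pre_kind, pre_idx, pre_name, post_name,
                        dist_um) {
    key <- paste(pre_name, post_name)
    prow_all <- paste(pathways$pre, pathways$post)
    out <- vector("list", length(unique(key)))
    k <- 0
    for (pw in unique(key)) {
      sel <- which(key == pw)
      pi <- match(pw, prow_all)
      if (is.na(pi)) next # unparameterized pathway: skip with no synapse
      p <- pathways[pi, ]
      # group into connections
      conn <- paste(pre_idx[sel], tab$post[sel])
      grp <- split(sel, conn)
      ns <- lengths(grp)
      first <- vapply(grp, `[`, integer(1), 1)
      pars <- draw_synapse_params(length(grp), p,
                                  seed = sample.int(1e9, 1))
      is_inh <- !is.na(p$gaba_class)
      k <- k + 1
      out[[k]] <- data.frame(
        pre_kind = pre_kind,
        pre = pre_idx[first],
        post = idx[as.character(tab$post[first])],
        comp = 1L, # synapses placed on the lumped dendrite
        class1 = cls_id[[if (is_inh) p$gaba_class else p$ampa_class]],
        class2 = if (is_inh) -1L else cls_id[["NMDA"]],
        g = pars$g_nS * (if (pre_kind == 1L) gcomp_aff else 1),
        nmda_ratio = if (is_inh) 0 else p$nmda_ratio,
        U = pars$U, D = pars$D, F = pars$F,
        n_sites = as.integer(ns),
        delay = 0.5 + dist_um[first] / 300,
        pathway = pw)
    }
    do.call(rbind, out[seq_len(k)])
  }

  if (!is.null(syn) && nrow(syn) > 0) {
    pre_i <- idx[as.character(syn$pre)]
    post_i <- idx[as.character(syn$post)]
    d <- sqrt((nodes$x[pre_i + 1] - nodes$x[post_i + 1])^2 +
              (nodes$y[pre_i + 1] - nodes$y[post_i + 1])^2 +
              (nodes$z[pre_i + 1] - nodes$z[post_i + 1])^2)
    edge_rows$chem <- add_edges(syn, 0L, pre_i, syn$pre_mtype,
                                syn$post_mtype, d)
  }

  fiber_offset <- c(ML = 0L, CT = 0L)
  n_fibers <- c(ML = 0L, CT = 0L)
  off <- 0L
  for (nm in names(afferents)) {
    af <- afferents[[nm]]
    fiber_offset[[af$pathway]] <- off
    n_fibers[[af$pathway]] <- nrow(af$fibers)
    sa <- af$synapses
    d <- abs(if (af$pathway == "ML") sa$y else
             max(nodes$y) - sa$y) # conduction from the entry face
    edge_rows[[nm]] <- add_edges(sa, 1L, off + sa$fiber - 1L,
                                 sa$pre_mtype, sa$post_mtype, d)
    off <- off + nrow(af$fibers)
  }
  edges <- do.call(rbind, edge_rows)
  rownames(edges) <- NULL

  # gap junctions (dendritic compartments) + leak compensation
  gj_mat <- matrix(0, 0, 5)
  if (!is.null(gj) && nrow(gj) > 0) {
    gj_mat <- cbind(idx[as.character(gj$pre)], 1,
                    idx[as.character(gj$post)], 1, gj$conductance_nS)
    g_cell <- (par[, "g_leak_s"] * par[, "area_s"] +
               par[, "g_leak_d"] * par[, "area_d"]) * 1e6
    comp <- compensate_input_resistance(
      g_cell, cbind(gj_mat[, 1] + 1, gj_mat[, 3] + 1), gj_mat[, 5] * 1e-3)
    f <- comp / g_cell
    par[, "g_leak_s"] <- par[, "g_leak_s"] * f
    par[, "g_leak_d"] <- par[, "g_leak_d"] * f
  }

  structure(list(
    nodes = nodes, par = par, edges = edges, gj = gj_mat,
    classes = classes, n_fibers = n_fibers, fiber_offset = fiber_offset,
    fibers = lapply(afferents, function(a) a$fibers),
    density_scale = density_scale, seed = seed),
    class = "thalamic_network")
}

#' @export
print.thalamic_network <- function(x, ...) {
  cat(sprintf(
    "thalamic network: %d cells, %d connections (%d synapses), %d GJs, fibers ML %d / CT %d\n",
    nrow(x$nodes), if (is.null(x$edges)) 0 else nrow(x$edges),
    if (is.null(x$edges)) 0 else sum(x$edges$n_sites), nrow(x$gj),
    x$n_fibers[["ML"]], x$n_fibers[["CT"]]))
  invisible(x)
}

#' Simulation configuration
#'
#' Background afferent drive is delivered as Poisson spike trains on the
#' ML and CT virtual fibers; rate timelines are piecewise-constant
#' blocks. The extracellular calcium concentration scales release
#' probabilities through [calcium_scale()].
#'
#' @param duration ms.
#' @param dt integration step (ms; must be <= 0.025).
#' @param ca_mM extracellular calcium.
#' @param ml_rate,ct_rate baseline fiber rates (Hz).
#' @param minis_on spontaneous release at `mini_rate`?
#' @param mini_rate per-synapse rate (Hz, default 0.01).
#' @param record_cells engine indices (0-based) of cells whose somatic
#'   voltage is recorded.
#' @param record_dt trace sampling interval (ms; default 0.1 = 10 kHz).
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(duration = 1000, dt = 0.025, ca_mM = 2.0,
                       ml_rate = 0, ct_rate = 0, minis_on = FALSE,
                       mini_rate = 0.01, record_cells = integer(0),
                       record_dt = 0.1, seed = 1) {
  if (dt > 0.025) stop("dt must be <= 0.025 ms for network runs")
  structure(list(
    duration = duration, dt = dt, ca_mM = ca_mM,
    ml_blocks = data.frame(t0 = 0, t1 = duration, rate = ml_rate),
    ct_blocks = data.frame(t0 = 0, t1 = duration, rate = ct_rate),
    minis_on = minis_on, mini_rate = mini_rate,
    fiber_events = data.frame(fiber = integer(0), time = numeric(0)),
    pulses = matrix(0, 0, 4), holding = NULL,
    record_cells = record_cells, record_dt = record_dt, seed = seed),
    class = "sim_config")
}

#' Wakefulness-like in vivo protocol
#'
#' ML fibers at 25 Hz, CT fibers at 4 Hz, extracellular calcium lowered
#' to 1.2 mM. The anesthetized variant reduces ML drive to 10 Hz.
#'
#' @param cfg a [sim_config()].
#' @param anesthetized lightly-anesthetized variant?
#' @return modified config.
#' @export
protocol_wakefulness <- function(cfg, anesthetized = FALSE) {
  ml <- if (anesthetized) 10 else 25
  cfg$ml_blocks <- data.frame(t0 = 0, t1 = cfg$duration, rate = ml)
  cfg$ct_blocks <- data.frame(t0 = 0, t1 = cfg$duration, rate = 4)
  cfg$ca_mM <- 1.2
  cfg$minis_on <- TRUE
  cfg
}

#' In-vitro (slice-like) protocol
#'
#' No afferent background; spontaneous synaptic release only; calcium at
#' the in-vitro reference of 2 mM.
#' @param cfg a [sim_config()].
#' @return modified config.
#' @export
protocol_in_vitro <- function(cfg) {
  cfg$ml_blocks <- data.frame(t0 = 0, t1 = cfg$duration, rate = 0)
  cfg$ct_blocks <- data.frame(t0 = 0, t1 = cfg$duration, rate = 0)
  cfg$ca_mM <- 2.0
  cfg$minis_on <- TRUE
  cfg
}

#' Cortical up/down-state protocol
#'
#' After an initial wakefulness epoch, the CT background alternates
#' between 0 (down state) and its baseline rate (up state) in blocks of
#' `down_ms` / `up_ms`.
#'
#' @param cfg a [sim_config()] (typically after
#'   [protocol_wakefulness()]).
#' @param down_ms,up_ms block durations (default 500/500).
#' @param start_ms start of the alternation.
#' @return modified config.
#' @export
protocol_updown <- function(cfg, down_ms = 500, up_ms = 500,
                            start_ms = 1000) {
  base <- cfg$ct_blocks$rate[1]
  if (down_ms <= 0) return(cfg)
  blocks <- list(data.frame(t0 = 0, t1 = start_ms, rate = base))
  t <- start_ms
  while (t < cfg$duration) {
    blocks[[length(blocks) + 1]] <- data.frame(t0 = t,
                                               t1 = min(t + down_ms,
                                                        cfg$duration),
                                               rate = 0)
    t <- t + down_ms
    if (t >= cfg$duration) break
    blocks[[length(blocks) + 1]] <- data.frame(t0 = t,
                                               t1 = min(t + up_ms,
                                                        cfg$duration),
                                               rate = base)
    t <- t + up_ms
  }
  cfg$ct_blocks <- do.call(rbind, blocks)
  cfg
}

#' Sensory stimulus: pulse train on central ML fibers
#'
#' The `n_fibers` ML fibers closest to the circuit axis each emit one
#' spike per pulse (with optional jitter).
#'
#' @param cfg a [sim_config()].
#' @param net the network (for fiber positions).
#' @param n_fibers number of activated fibers (default 160, scaled by
#'   the circuit density scale by the caller if desired).
#' @param n_pulses number of pulses.
#' @param freq_hz pulse frequency.
#' @param t0 first pulse time (ms).
#' @param jitter_ms uniform spike-time jitter (default 1).
#' @return modified config.
#' @export
stimulus_sensory_train <- function(cfg, net, n_fibers = 160, n_pulses = 8,
                                   freq_hz = 8, t0 = 500, jitter_ms = 1) {
  fib <- net$fibers[["ML"]]
  if (is.null(fib)) stop("network has no ML fibers")
  ord <- order(fib$x^2 + fib$z^2)
  chosen <- ord[seq_len(min(n_fibers, nrow(fib)))]
  times <- t0 + (seq_len(n_pulses) - 1) * 1000 / freq_hz
  ev <- expand.grid(fiber = net$fiber_offset[["ML"]] + chosen - 1L,
                    time = times)
  if (jitter_ms > 0)
    ev$time <- ev$time + stats::runif(nrow(ev), -jitter_ms, jitter_ms)
  cfg$fiber_events <- rbind(cfg$fiber_events, ev)
  attr(cfg, "stim_times") <- times
  cfg
}

#' Current-pulse stimulus to a central Rt subset
#'
#' Injects a current pulse into the spatially contiguous subset of Rt_RC
#' cells closest to the circuit axis, simulating brief optogenetic
#' activation of the reticular nucleus.
#'
#' @param cfg a [sim_config()].
#' @param net the network.
#' @param fraction fraction of Rt_RC cells stimulated (default 0.1), or
#'   use `n_cells`.
#' @param n_cells absolute number (overrides `fraction`).
#' @param amplitude_nA pulse amplitude (not printed in the source
#'   protocol; default 0.3 nA evokes bursts).
#' @param t0 pulse onset (ms).
#' @param duration_ms pulse length (default 20).
#' @return modified config.
#' @export
stimulus_rt_pulse <- function(cfg, net, fraction = 0.1, n_cells = NULL,
                              amplitude_nA = 0.3, t0 = 1000,
                              duration_ms = 20) {
  rt <- which(net$nodes$mtype == "Rt_RC")
  if (is.null(n_cells)) n_cells <- max(1, round(fraction * length(rt)))
  ord <- rt[order(net$nodes$x[rt]^2 + net$nodes$z[rt]^2)]
  chosen <- ord[seq_len(min(n_cells, length(ord)))]
  cfg$pulses <- rbind(cfg$pulses,
                      cbind(chosen - 1L, t0, t0 + duration_ms, amplitude_nA))
  attr(cfg, "rt_pulse") <- list(cells = chosen, t0 = t0,
                                amplitude = amplitude_nA)
  cfg
}

#' Polarize a population to a target membrane potential
#'
#' Adds per-cell constant soma currents so the baseline membrane
#' potential of the population approximates `target_mV`. The holding
#' current is solved per e-model by binary search (cells sharing an
#' e-model receive the same current; morphology-specific input
#' resistance differences are not modeled at desk scale).
#'
#' @param cfg a [sim_config()].
#' @param net the network.
#' @param population "Rt" or "VPL" (region) or an m-type name.
#' @param target_mV target baseline potential.
#' @param emodels e-model list used for the solve.
#' @return modified config.
#' @export
set_population_polarization <- function(cfg, net, population, target_mV,
                                        emodels = default_emodels()) {
  nodes <- net$nodes
  sel <- if (population %in% c("Rt", "VPL")) nodes$region == population
         else nodes$mtype == population
  if (is.null(cfg$holding)) cfg$holding <- numeric(nrow(nodes))
  keys <- emodel_key(nodes$mtype, nodes$etype)
  for (k in unique(keys[sel])) {
    ht <- find_holding_threshold(emodels[[k]], v_target = target_mV)
    cfg$holding[sel & keys == k] <- ht$holding_nA
  }
  cfg
}

#' Run a network simulation
#'
#' Deterministic given (network, config, seed): Poisson fiber
#' backgrounds, minis, and stochastic release all derive from the config
#' seed. Release probabilities are scaled by the calcium dependence of
#' the configured extracellular calcium.
#'
#' @param net network from [build_network()].
#' @param cfg config from [sim_config()].
#' @return a `simulation_result`: spikes (data.frame gid, time, mtype),
#'   traces, config.
#' @export
run_simulation <- function(net, cfg) {
  set.seed(cfg$seed)
  e <- net$edges
  if (is.null(e) || nrow(e) == 0)
    e <- data.frame(pre_kind = integer(0), pre = integer(0),
                    post = integer(0), comp = integer(0),
                    class1 = integer(0), class2 = integer(0),
                    g = numeric(0), nmda_ratio = numeric(0),
                    U = numeric(0), D = numeric(0), F = numeric(0),
                    n_sites = integer(0), delay = numeric(0))
  ca_f <- calcium_scale(cfg$ca_mM)
  U_eff <- pmin(e$U * ca_f, 1)

  # fiber background spikes from the piecewise-constant rate blocks
  gen_fiber_spikes <- function(n_fib, offset, blocks) {
    out <- list()
    for (b in seq_len(nrow(blocks))) {
      r <- blocks$rate[b]
      if (r <= 0 || n_fib == 0) next
      len <- (blocks$t1[b] - blocks$t0[b]) / 1000
      n_ev <- stats::rpois(1, n_fib * r * len)
      if (n_ev == 0) next
      out[[length(out) + 1]] <- data.frame(
        fiber = offset + sample.int(n_fib, n_ev, replace = TRUE) - 1L,
        time = stats::runif(n_ev, blocks$t0[b], blocks$t1[b]))
    }
    if (!length(out)) data.frame(fiber = integer(0), time = numeric(0))
    else do.call(rbind, out)
  }
  fs <- rbind(
    gen_fiber_spikes(net$n_fibers[["ML"]], net$fiber_offset[["ML"]],
                     cfg$ml_blocks),
    gen_fiber_spikes(net$n_fibers[["CT"]], net$fiber_offset[["CT"]],
                     cfg$ct_blocks),
    cfg$fiber_events)
  fs <- fs[order(fs$time), , drop = FALSE]

  # minis: Poisson per synapse; edges sampled proportionally to n_sites
  minis <- data.frame(edge = integer(0), time = numeric(0))
  if (cfg$minis_on && nrow(e) > 0 && cfg$mini_rate > 0) {
    tot <- sum(e$n_sites)
    n_ev <- stats::rpois(1, tot * cfg$mini_rate * cfg$duration / 1000)
    if (n_ev > 0) {
      minis <- data.frame(
        edge = sample.int(nrow(e), n_ev, replace = TRUE,
                          prob = e$n_sites) - 1L,
        time = stats::runif(n_ev, 0, cfg$duration))
      minis <- minis[order(minis$time), ]
    }
  }

  hold <- if (is.null(cfg$holding)) numeric(nrow(net$nodes)) else cfg$holding
  res <- cpp_run_network(
    net$par, as.matrix(net$classes[, c("tau_r", "tau_d", "e_rev",
                                       "is_nmda")]),
    as.integer(e$pre_kind), as.integer(e$pre), as.integer(e$post),
    as.integer(e$comp), as.integer(e$class1), as.integer(e$class2),
    e$g, e$nmda_ratio, U_eff, e$D, e$F, as.integer(e$n_sites), e$delay,
    net$gj, fs$time, as.integer(fs$fiber), minis$time,
    as.integer(minis$edge), cfg$pulses, hold,
    cfg$dt, cfg$duration, sample.int(.Machine$integer.max, 1),
    as.integer(cfg$record_cells), cfg$record_dt, -20, -999)

  spikes <- data.frame(gid = res$spike_cell + 1L, time = res$spike_time)
  spikes$mtype <- net$nodes$mtype[spikes$gid]
  structure(list(spikes = spikes,
                 traces = if (length(res$trace_time))
                   list(time = res$trace_time, v = res$traces,
                        cells = cfg$record_cells + 1L) else NULL,
                 fiber_spikes = fs, config = cfg,
                 n_cells = nrow(net$nodes),
                 mtype_counts = as.list(table(net$nodes$mtype))),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation: %d cells, %.0f ms, %d spikes\n",
              x$n_cells, x$config$duration, nrow(x$spikes)))
  for (mt in unique(x$spikes$mtype))
    cat(sprintf("  %s: %.2f Hz mean rate\n", mt,
                population_rate(x, mt)))
  invisible(x)
}

#' Population mean firing rate
#' @param sim simulation result.
#' @param mtype m-type (NULL = all cells).
#' @param from,to analysis window (ms; defaults to the whole run).
#' @param n_cells number of cells of that m-type (taken from the spike
#'   table's gid range when not supplied via the result).
#' @return rate in Hz.
#' @export
population_rate <- function(sim, mtype = NULL, from = 0, to = NULL,
                            n_cells = NULL) {
  if (is.null(to)) to <- sim$config$duration
  sp <- sim$spikes
  if (!is.null(mtype)) sp <- sp[sp$mtype == mtype, ]
  if (is.null(n_cells)) {
    n_cells <- if (!is.null(mtype) && !is.null(sim$mtype_counts[[mtype]]))
      sim$mtype_counts[[mtype]] else sim$n_cells
  }
  sum(sp$time >= from & sp$time <= to) / n_cells / ((to - from) / 1000)
}
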