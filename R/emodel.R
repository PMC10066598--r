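# column order of the engine parameter matrix; must match PCol in
# src/engine.cpp
EMODEL_COLS <- c("area_s", "area_d", "cm", "g_na", "g_kd", "g_nap", "g_ka",
                 "g_kv3", "g_cat_s", "g_cat_d", "g_cah", "g_sk_s", "g_sk_d",
                 "g_ih_s", "g_ih_d", "g_leak_s", "g_leak_d", "e_leak",
                 "g_couple", "tau_ca", "gamma", "cat_variant", "v_init")

#' Construct an electrical model (e-model)
#'
#' Reduced two-compartment (soma + lumped dendrite) conductance-based
#' model. Conductances are densities in S/cm2, areas in cm2, membrane
#' capacitance 1 uF/cm2, coupling conductance in uS. The low-threshold
#' calcium current has a thalamocortical variant (cat_variant = 0) and a
#' reticular variant (1) with more depolarized activation and slower
#' inactivation recovery. Reversals: E_Na = 50 mV, E_K = -90 mV,
#' E_h = -43 mV; temperature-corrected kinetics at 34 C.
#'
#' @param ... named parameter overrides (see `EMODEL_COLS`).
#' @param etype e-type label.
#' @return an `emodel` object.
#' @export
emodel <- function(..., etype = NA_character_) {
  p <- list(
    area_s = 2.0e-5, area_d = 1.0e-4, cm = 1,
    g_na = 0.05, g_kd = 0.005, g_nap = 0, g_ka = 0.002, g_kv3 = 0,
    g_cat_s = 0.002, g_cat_d = 0.003, g_cah = 0,
    g_sk_s = 2e-4, g_sk_d = 0,
    g_ih_s = 2e-5, g_ih_d = 2e-5,
    g_leak_s = 3e-5, g_leak_d = 3e-5, e_leak = -70,
    g_couple = 0.03, tau_ca = 10, gamma = 0.05,
    cat_variant = 0, v_init = -70)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown e-model parameters: ",
                        paste(bad, collapse = ", "))
  p[names(over)] <- over
  if (any(unlist(p[grep("^g_", names(p))]) < 0))
    stop("conductances must be non-negative")
  p$etype <- etype
  structure(p, class = "emodel")
}

#' @export
print.emodel <- function(x, ...) {
  cat(sprintf("e-model (%s): soma %.0f um2, dend %.0f um2, R_in ~%.0f MOhm\n",
              x$etype, x$area_s * 1e8, x$area_d * 1e8,
              1 / ((x$g_leak_s * x$area_s + x$g_leak_d * x$area_d) * 1e6)))
  invisible(x)
}

#' Parameter matrix for the engine
#' @param ems a single emodel or list of emodels.
#' @return numeric matrix, one row per cell, columns `EMODEL_COLS`.
#' @export
emodel_matrix <- function(ems) {
  if (inherits(ems, "emodel")) ems <- list(ems)
  mat <- t(vapply(ems, function(e) unlist(e[EMODEL_COLS]),
                  numeric(length(EMODEL_COLS))))
  colnames(mat) <- EMODEL_COLS
  mat
}

#' Reference e-models for the five me-types
#'
#' Hand-tuned surrogate models reproducing the qualitative physiology of
#' the thalamic e-types: tonic spiking from a depolarized holding
#' (-64 mV) and stereotypical low-threshold bursts from a hyperpolarized
#' holding (-84 mV) for both VPL_TC and Rt_RC; adapting (cAD_ltb) versus
#' non-adapting (cNAD_ltb) tonic responses; deeper post-burst
#' afterhyperpolarization in Rt_RC (SK-mediated); fast non-bursting
#' interneuron (bAC). Quantitative targets are surrogates, not measured
#' thalamic values (experimental feature tables are not printed).
#'
#' @return named list of emodels: Rt_RC_cAD, Rt_RC_cNAD, VPL_TC_cAD,
#'   VPL_TC_cNAD, VPL_IN_bAC.
#' @export
default_emodels <- function() {
  list(
    VPL_TC_cAD = emodel(
      etype = "cAD_ltb", cat_variant = 0,
      g_na = 0.06, g_kd = 0.008, g_ka = 0.002,
      g_cat_s = 2e-4, g_cat_d = 5.8e-4, g_cah = 5e-5,
      g_sk_s = 5e-4, g_sk_d = 2.5e-4,
      g_ih_s = 2.2e-5, g_ih_d = 2.2e-5, tau_ca = 20, gamma = 0.05,
      g_leak_s = 3e-5, g_leak_d = 3e-5, e_leak = -76, v_init = -70),
    VPL_TC_cNAD = emodel(
      etype = "cNAD_ltb", cat_variant = 0,
      g_na = 0.06, g_kd = 0.008, g_ka = 0.002,
      g_cat_s = 2e-4, g_cat_d = 5.8e-4, g_cah = 0,
      g_sk_s = 4e-4, g_sk_d = 2e-4,
      g_ih_s = 2.2e-5, g_ih_d = 2.2e-5, tau_ca = 40, gamma = 0.03,
      g_leak_s = 3e-5, g_leak_d = 3e-5, e_leak = -76, v_init = -70),
    Rt_RC_cAD = emodel(
      etype = "cAD_ltb", cat_variant = 1,
      g_na = 0.06, g_kd = 0.006, g_ka = 0.001,
      g_cat_s = 2e-4, g_cat_d = 2e-3, g_cah = 5e-5,
      g_sk_s = 1.6e-3, g_sk_d = 8e-4,
      g_ih_s = 1e-5, g_ih_d = 1e-5, tau_ca = 100, gamma = 0.075,
      g_leak_s = 3.2e-5, g_leak_d = 3.2e-5, e_leak = -78, v_init = -72),
    Rt_RC_cNAD = emodel(
      etype = "cNAD_ltb", cat_variant = 1,
      g_na = 0.06, g_kd = 0.007, g_ka = 0.001,
      g_cat_s = 2e-4, g_cat_d = 2e-3, g_cah = 0,
      g_sk_s = 1.5e-3, g_sk_d = 7.5e-4,
      g_ih_s = 1e-5, g_ih_d = 1e-5, tau_ca = 100, gamma = 0.07,
      g_leak_s = 3.2e-5, g_leak_d = 3.2e-5, e_leak = -78, v_init = -72),
    VPL_IN_bAC = emodel(
      etype = "bAC", cat_variant = 0, area_s = 1.2e-5, area_d = 5e-5,
      g_na = 0.07, g_kd = 0.004, g_kv3 = 0.01, g_ka = 0.002,
      g_cat_s = 5e-5, g_cat_d = 5e-5, g_sk_s = 1e-4, g_sk_d = 0,
      g_ih_s = 1e-5, g_ih_d = 1e-5, tau_ca = 10, gamma = 0.02,
      g_leak_s = 5e-5, g_leak_d = 5e-5, e_leak = -62, v_init = -70)
  )
}

#' Map me-type labels to reference e-models
#' @param mtype,etype character vectors.
#' @return character vector of names into [default_emodels()].
#' @export
emodel_key <- function(mtype, etype) {
  ifelse(mtype == "VPL_IN", "VPL_IN_bAC",
         paste0(ifelse(mtype == "Rt_RC", "Rt_RC", "VPL_TC"), "_",
                ifelse(etype == "cNAD_ltb", "cNAD", "cAD")))
}

#' Step/ramp/noise stimulation protocol
#'
#' @param duration total simulated time (ms).
#' @param holding_nA constant holding current.
#' @param step_nA,step_t0,step_t1 current step (nA) and window (ms).
#' @param ramp_nA peak of a 0-to-peak ramp over the step window.
#' @param noise_sd white-noise current sd (nA) over the step window.
#' @param v_init initial voltage (mV); NA = model default.
#' @return a `protocol` list.
#' @export
protocol_spec <- function(duration = 1200, holding_nA = 0, step_nA = 0,
                          step_t0 = 300, step_t1 = 900, ramp_nA = 0,
                          noise_sd = 0, v_init = NA) {
  structure(list(duration = duration, holding_nA = holding_nA,
                 step_nA = step_nA, step_t0 = step_t0, step_t1 = step_t1,
                 ramp_nA = ramp_nA, noise_sd = noise_sd, v_init = v_init),
            class = "protocol")
}

#' Simulate a single neuron under a stimulation protocol
#'
#' @param em e-model.
#' @param proto protocol from [protocol_spec()].
#' @param dt integration step (ms, default 0.025; must be <= 0.025 for
#'   production runs).
#' @param seed seed for the noise component.
#' @return a `trace` list: time (ms), v (soma mV), v_dend, spikes (ms),
#'   protocol.
#' @export
simulate_neuron <- function(em, proto = protocol_spec(), dt = 0.025,
                            seed = 1) {
  n <- round(proto$duration / dt)
  inj <- rep(proto$holding_nA, n)
  i0 <- max(1, round(proto$step_t0 / dt))
  i1 <- min(n, round(proto$step_t1 / dt))
  if (i1 >= i0) {
    win <- i0:i1
    inj[win] <- inj[win] + proto$step_nA
    if (proto$ramp_nA != 0)
      inj[win] <- inj[win] + proto$ramp_nA * seq(0, 1, length.out = length(win))
    if (proto$noise_sd > 0) {
      set.seed(seed)
      inj[win] <- inj[win] + stats::rnorm(length(win), 0, proto$noise_sd)
    }
  }
  v_init <- if (is.na(proto$v_init)) em$v_init else proto$v_init
  res <- cpp_simulate_cell(emodel_matrix(em)[1, ], dt, inj, v_init)
  time <- seq_len(n) * dt
  structure(list(time = time, v = res$v_soma, v_dend = res$v_dend,
                 spikes = detect_spikes(res$v_soma, time),
                 protocol = proto, dt = dt),
            class = "trace")
}

#' Detect spikes as upward threshold crossings
#' @param v voltage trace (mV).
#' @param time time vector (ms).
#' @param threshold detection threshold (default -20 mV).
#' @param refractory minimum inter-detection interval (default 1 ms).
#' @return spike times (ms).
#' @export
detect_spikes <- function(v, time, threshold = -20, refractory = 1) {
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1
  if (!length(up)) return(numeric(0))
  t <- time[up]
  keep <- c(TRUE, diff(t) >= refractory)
  # enforce refractory sequentially
  out <- t[1]
  for (k in seq_along(t)[-1]) if (t[k] - out[length(out)] >= refractory)
    out <- c(out, t[k])
  out
}

#' Extract electrical features from a trace
#'
#' Feature definitions (eFEL-equivalent, re-implemented):
#' \itemize{
#' \item spike_count: spikes during the step window.
#' \item mean_frequency: spike_count / step duration (Hz).
#' \item AP_amplitude: mean spike peak minus threshold crossing (mV).
#' \item AHP_depth: mean post-spike minimum relative to threshold (mV).
#' \item adaptation_index: (1/ISI_last) / (1/ISI_first) = ISI_first /
#'   ISI_last; < 1 for adapting trains.
#' \item sag_amplitude: steady-state minus minimum voltage during a
#'   hyperpolarizing step (mV).
#' \item input_resistance: deflection / current (MOhm) for subthreshold
#'   steps.
#' \item resting_potential: mean voltage over the pre-step window (mV).
#' \item time_to_first_spike (ms from step onset).
#' \item initburst_sahp: minimum voltage in the 5-150 ms after the last
#'   spike of the initial burst (mV); quantifies the post-burst
#'   afterhyperpolarization.
#' \item burst_spike_count: spikes with ISI <= 15 ms at step onset.
#' }
#' Features undefined for the trace (e.g. ISI features without spikes)
#' are returned as NA.
#'
#' @param trace from [simulate_neuron()].
#' @param features character vector of feature names (default all).
#' @return named numeric vector.
#' @export
extract_features <- function(trace, features = NULL) {
  p <- trace$protocol
  v <- trace$v; tm <- trace$time
  instep <- tm >= p$step_t0 & tm <= p$step_t1
  prestep <- tm < p$step_t0
  sp <- trace$spikes[trace$spikes >= p$step_t0 & trace$spikes <= p$step_t1]
  isi <- diff(sp)
  vss_win <- tm >= p$step_t1 - 100 & tm <= p$step_t1
  out <- c()
  out["spike_count"] <- length(sp)
  out["mean_frequency"] <- length(sp) / (p$step_t1 - p$step_t0) * 1000
  out["resting_potential"] <- mean(v[prestep & tm > p$step_t0 - 200])
  out["time_to_first_spike"] <- if (length(sp)) sp[1] - p$step_t0 else NA
  out["adaptation_index"] <- if (length(isi) >= 2) isi[1] / isi[length(isi)]
                             else NA
  # spike shape
  if (length(sp)) {
    pk <- vapply(sp, function(s) max(v[tm >= s & tm <= s + 3]), numeric(1))
    ahp <- vapply(sp, function(s) min(v[tm >= s & tm <= s + 15]), numeric(1))
    out["AP_amplitude"] <- mean(pk) + 20
    out["AHP_depth"] <- -20 - mean(ahp)
  } else {
    out["AP_amplitude"] <- NA
    out["AHP_depth"] <- NA
  }
  # subthreshold features
  amp <- p$step_nA
  if (length(sp) == 0 && amp != 0) {
    vss <- mean(v[vss_win])
    out["input_resistance"] <- (vss - out[["resting_potential"]]) / amp
    vmin <- min(v[instep])
    out["sag_amplitude"] <- if (amp < 0) vss - vmin else NA
  } else {
    out["input_resistance"] <- NA
    out["sag_amplitude"] <- NA
  }
  # initial burst and its afterhyperpolarization
  burst <- if (length(sp)) {
    b <- sp[1]
    k <- 1
    while (k < length(sp) && sp[k + 1] - sp[k] <= 15) {
      k <- k + 1; b <- c(b, sp[k])
    }
    b
  } else numeric(0)
  out["burst_spike_count"] <- length(burst)
  if (length(burst) >= 2) {
    t_end <- burst[length(burst)]
    sel <- tm >= t_end + 5 & tm <= min(t_end + 150, p$step_t1)
    out["initburst_sahp"] <- if (any(sel)) min(v[sel]) else NA
  } else out["initburst_sahp"] <- NA
  if (!is.null(features)) out <- out[features]
  out
}

#' Feature z-score
#' @param value observed feature value (NA = missing).
#' @param mean,sd target mean and positive sd.
#' @return |value - mean| / sd; missing features map to +Inf (reject).
#' @export
zscore <- function(value, mean, sd) {
  if (any(sd <= 0)) stop("target sd must be positive")
  ifelse(is.na(value), Inf, abs(value - mean) / sd)
}

#' Find holding and threshold currents by binary search
#'
#' Holding: the constant current bringing the late membrane potential
#' within `v_tol` of `v_target`. Threshold: the minimal step (on top of
#' holding) evoking at least one spike, bracketed to 1% relative width.
#'
#' @param em e-model.
#' @param v_target holding target (mV), e.g. -84 or -64.
#' @param v_tol holding tolerance (default 1 mV).
#' @param i_max search bound (nA).
#' @param dt integration step.
#' @return list(holding_nA, threshold_nA).
#' @export
find_holding_threshold <- function(em, v_target = -84, v_tol = 1,
                                   i_max = 0.6, dt = 0.05) {
  v_at <- function(i) {
    tr <- tryCatch(
      simulate_neuron(em, protocol_spec(duration = 700, holding_nA = i,
                                        step_nA = 0), dt = dt),
      error = function(e) NULL)
    # over-strong currents drive V out of the integrator's range; treat as
    # saturation on the corresponding side
    if (is.null(tr)) return(if (i < 0) -Inf else Inf)
    mean(tr$v[tr$time > 600])
  }
  lo <- -i_max; hi <- i_max
  if (v_at(lo) > v_target || v_at(hi) < v_target)
    stop("holding target outside the searchable current range")
  for (k in 1:30) {
    mid <- (lo + hi) / 2
    vm <- v_at(mid)
    if (abs(vm - v_target) < v_tol * 0.5) { lo <- hi <- mid; break }
    if (vm < v_target) lo <- mid else hi <- mid
  }
  hold <- (lo + hi) / 2
  spikes_at <- function(step) {
    tr <- tryCatch(
      simulate_neuron(em, protocol_spec(duration = 900, holding_nA = hold,
                                        step_nA = step, step_t0 = 300,
                                        step_t1 = 800), dt = dt),
      error = function(e) NULL)
    if (is.null(tr)) return(Inf) # far above threshold
    length(tr$spikes[tr$spikes >= 300])
  }
  lo <- 0; hi <- 0.05
  while (spikes_at(hi) == 0) {
    hi <- hi * 2
    if (hi > i_max * 4) stop("no spiking up to the current bound")
  }
  while ((hi - lo) / hi > 0.01) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid) >= 1) hi <- mid else lo <- mid
  }
  list(holding_nA = hold, threshold_nA = hi)
}

#' Standard fitting protocols for an e-model
#'
#' Two hyperpolarizing steps (-40% and -140% of threshold) from the
#' hyperpolarized holding constrain passive properties and sag; three
#' depolarizing steps (150%, 200%, 250% of threshold) from the
#' depolarized holding (-64 mV) constrain the tonic firing pattern; one
#' 200% step from the hyperpolarized holding (-84 mV) constrains the
#' low-threshold burst.
#'
#' @param em e-model used to determine holding/threshold currents.
#' @param dt integration step.
#' @return named list of protocols plus the holding/threshold record.
#' @export
standard_protocols <- function(em, dt = 0.05) {
  hyp <- find_holding_threshold(em, -84, dt = dt)
  dep <- find_holding_threshold(em, -64, dt = dt)
  th_d <- dep$threshold_nA
  th_h <- hyp$threshold_nA
  list(
    hyp_step_small = protocol_spec(holding_nA = hyp$holding_nA,
                                   step_nA = -0.4 * th_d),
    hyp_step_large = protocol_spec(holding_nA = hyp$holding_nA,
                                   step_nA = -1.4 * th_d),
    tonic_150 = protocol_spec(holding_nA = dep$holding_nA,
                              step_nA = 1.5 * th_d),
    tonic_200 = protocol_spec(holding_nA = dep$holding_nA,
                              step_nA = 2.0 * th_d),
    tonic_250 = protocol_spec(holding_nA = dep$holding_nA,
                              step_nA = 2.5 * th_d),
    burst_200 = protocol_spec(holding_nA = hyp$holding_nA,
                              step_nA = 2.0 * th_h),
    rest = protocol_spec(holding_nA = 0, step_nA = 0),
    hold_only = protocol_spec(holding_nA = hyp$holding_nA, step_nA = 0),
    currents = list(hyp = hyp, dep = dep))
}

#' Surrogate feature targets generated from a reference model
#'
#' Runs the standard protocols on `em` and wraps the extracted feature
#' values as targets with a relative sd (documented surrogate for
#' unpublished experimental feature tables).
#'
#' @param em reference e-model.
#' @param rel_sd relative sd assigned to each feature (default 0.1, with
#'   a floor of 0.5 in feature units).
#' @param dt integration step.
#' @param protocols optionally reuse a [standard_protocols()] result.
#' @return data.frame: protocol, feature, mean, sd.
#' @export
feature_targets_from_model <- function(em, rel_sd = 0.1, dt = 0.05,
                                       protocols = NULL) {
  if (is.null(protocols)) protocols <- standard_protocols(em, dt = dt)
  protos <- protocols[setdiff(names(protocols), "currents")]
  rows <- list()
  for (pn in names(protos)) {
    f <- extract_features(simulate_neuron(em, protos[[pn]], dt = dt))
    f <- f[!is.na(f)]
    for (fn in names(f)) {
      rows[[length(rows) + 1]] <- data.frame(
        protocol = pn, feature = fn, mean = f[[fn]],
        sd = max(abs(f[[fn]]) * rel_sd, 0.5))
    }
  }
  do.call(rbind, rows)
}

#' Evaluate an e-model against feature targets
#' @param em e-model.
#' @param targets data.frame from [feature_targets_from_model()].
#' @param protocols named protocol list.
#' @param dt integration step.
#' @return targets with observed values and z-scores.
#' @export
evaluate_emodel <- function(em, targets, protocols, dt = 0.05) {
  protos <- protocols[setdiff(names(protocols), "currents")]
  targets$value <- NA_real_
  for (pn in unique(targets$protocol)) {
    f <- extract_features(simulate_neuron(em, protos[[pn]], dt = dt))
    sel <- targets$protocol == pn
    targets$value[sel] <- f[targets$feature[sel]]
  }
  targets$z <- zscore(targets$value, targets$mean, targets$sd)
  targets
}

#' Fit an e-model to feature targets
#'
#' Evolutionary multi-objective search (a compact (mu + lambda) strategy
#' minimizing the maximum feature z-score, ties broken by the sum of
#' z-scores) over the named conductance bounds. Returns the best model
#' and its z-table; if the best max-z is >= 3 the fit is flagged as
#' failed (best-effort model still returned).
#'
#' @param targets feature targets.
#' @param bounds named list of c(lo, hi) per free e-model parameter.
#' @param base e-model providing all non-fitted parameters.
#' @param protocols protocol list evaluated against the targets.
#' @param seed integer seed.
#' @param mu,lambda,generations search sizes.
#' @param dt integration step.
#' @return list(model, report, max_z, converged).
#' @export
fit_emodel <- function(targets, bounds, base = default_emodels()$VPL_TC_cAD,
                       protocols = NULL, seed = 1, mu = 4, lambda = 8,
                       generations = 10, dt = 0.05) {
  set.seed(seed)
  if (is.null(protocols)) protocols <- standard_protocols(base, dt = dt)
  pn <- names(bounds)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  make_model <- function(x) do.call(emodel, c(stats::setNames(as.list(x), pn),
                                              base[setdiff(names(base),
                                                           c(pn, "etype"))],
                                              list(etype = base$etype)))
  score <- function(x) {
    em <- make_model(x)
    rep <- tryCatch(evaluate_emodel(em, targets, protocols, dt = dt),
                    error = function(e) NULL)
    if (is.null(rep)) return(c(Inf, Inf))
    c(max(rep$z), sum(pmin(rep$z, 50)))
  }
  if (all(hi - lo < 1e-12)) {
    x <- lo
    em <- make_model(x)
    rep <- evaluate_emodel(em, targets, protocols, dt = dt)
    return(list(model = em, report = rep, max_z = max(rep$z),
                converged = max(rep$z) < 3))
  }
  pop <- lapply(seq_len(mu), function(k)
    lo + stats::runif(length(pn)) * (hi - lo))
  fit <- lapply(pop, score)
  for (g in seq_len(generations)) {
    offspring <- lapply(seq_len(lambda), function(k) {
      parent <- pop[[sample.int(mu, 1)]]
      child <- parent + stats::rnorm(length(pn), 0, 0.15 * (hi - lo))
      pmin(pmax(child, lo), hi)
    })
    ofit <- lapply(offspring, score)
    all_pop <- c(pop, offspring)
    all_fit <- c(fit, ofit)
    ord <- order(vapply(all_fit, `[`, numeric(1), 1),
                 vapply(all_fit, `[`, numeric(1), 2))
    pop <- all_pop[ord[seq_len(mu)]]
    fit <- all_fit[ord[seq_len(mu)]]
    if (fit[[1]][1] < 1) break
  }
  em <- make_model(pop[[1]])
  rep <- evaluate_emodel(em, targets, protocols, dt = dt)
  list(model = em, report = rep, max_z = max(rep$z),
       converged = max(rep$z) < 3)
}

#' Acceptance test of a morpho-electrical model
#'
#' A me-model variant passes if all feature z-scores against the exemplar
#' targets are below 5 and the model does not fire spontaneously at rest
#' (no stimulus, no holding).
#'
#' @param em candidate e-model (e.g. the exemplar with a perturbed
#'   morphology-dependent load).
#' @param targets exemplar feature targets.
#' @param protocols protocol list.
#' @param z_max acceptance bound (default 5).
#' @param dt integration step.
#' @return list(pass, max_z, spontaneous, report).
#' @export
accept_memodel <- function(em, targets, protocols, z_max = 5, dt = 0.05) {
  rep <- evaluate_emodel(em, targets, protocols, dt = dt)
  rest <- simulate_neuron(em, protocol_spec(duration = 1000, holding_nA = 0,
                                            step_nA = 0), dt = dt)
  spont <- length(rest$spikes) > 0
  list(pass = max(rep$z) < z_max && !spont, max_z = max(rep$z),
       spontaneous = spont, report = rep)
}
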