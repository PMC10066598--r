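# Receptor kinetic classes shared by the R-level model and the engine.
# AMPA rise/decay 0.2/1.74 ms (TC->Rt 1.58, CT->Rt 2.74), NMDA 0.29/43,
# GABA_A 0.2/8.3; E_AMPA = E_NMDA = 0 mV; E_GABAA = -82 mV except onto TC
# somata where the chloride reversal is lower (-94 mV).
synapse_classes <- function() {
  data.frame(
    name = c("AMPA", "AMPA_TC_Rt", "AMPA_CT_Rt", "NMDA", "GABAA",
             "GABAA_TC"),
    tau_r = c(0.2, 0.2, 0.2, 0.29, 0.2, 0.2),
    tau_d = c(1.74, 1.58, 2.74, 43, 8.3, 8.3),
    e_rev = c(0, 0, 0, 0, -82, -94),
    is_nmda = c(0, 0, 0, 1, 0, 0)
  )
}

#' Pathway physiology table
#'
#' One row per (pre, post) pathway with short-term plasticity class,
#' Tsodyks-Markram parameters (U release probability, D / F recovery time
#' constants from depression / facilitation, ms), per-site conductance
#' (nS) and receptor composition. All intrathalamic and lemniscal
#' pathways are depressing (E2 / I2); corticothalamic ones are
#' facilitating (E1). Uncharacterized pathways follow generalization
#' rules: TC->Rt from the strongest depressing excitatory template,
#' Rt->Rt and Rt->IN from IN->IN, CT->* from the facilitating E1
#' template, ML->TC from ML->IN. U/D/F means marked `surrogate` are
#' stand-ins calibrated at the class level, not measured thalamic values.
#'
#' @return data.frame of pathway parameters.
#' @export
pathway_physiology <- function() {
  rows <- list(
    #        pre       post      class  U     D    F   g_nS  nmda  ampa_class   gaba_class  surrogate
    list("Rt_RC",  "VPL_TC", "I2", 0.45, 700,  21, 2.8,  0,   NA,          "GABAA_TC",  TRUE),
    list("Rt_RC",  "Rt_RC",  "I2", 0.25, 700,  21, 2.0,  0,   NA,          "GABAA",     TRUE),
    list("VPL_IN", "VPL_TC", "I2", 0.35, 600,  20, 0.9,  0,   NA,          "GABAA_TC",  TRUE),
    list("VPL_IN", "VPL_IN", "I2", 0.25, 700,  21, 0.9,  0,   NA,          "GABAA",     TRUE),
    list("VPL_TC", "Rt_RC",  "E2", 0.86, 671,  17, 2.2,  0.6, "AMPA_TC_Rt", NA,         FALSE),
    list("ML",     "VPL_TC", "E2", 0.70, 750,  20, 2.6,  0.6, "AMPA",      NA,          TRUE),
    list("ML",     "VPL_IN", "E2", 0.70, 750,  20, 6.0,  0.6, "AMPA",      NA,          TRUE),
    list("CT",     "VPL_TC", "E1", 0.09, 138, 670, 0.4,  1.0, "AMPA",      NA,          FALSE),
    list("CT",     "VPL_IN", "E1", 0.09, 138, 670, 0.4,  1.0, "AMPA",      NA,          FALSE),
    list("CT",     "Rt_RC",  "E1", 0.09, 138, 670, 0.4,  1.0, "AMPA_CT_Rt", NA,         FALSE)
  )
  out <- do.call(rbind.data.frame, rows)
  names(out) <- c("pre", "post", "class", "U", "D", "F", "g_nS",
                  "nmda_ratio", "ampa_class", "gaba_class", "surrogate")
  # parameter spread for per-synapse truncated-Gaussian draws
  out$U_sd <- out$U * 0.25
  out$D_sd <- out$D * 0.25
  out$F_sd <- out$F * 0.25
  out$g_sd <- out$g_nS * 0.25
  out
}

#' Deterministic Tsodyks-Markram recursion
#'
#' Mean-field amplitudes for a spike train: u tracks facilitation
#' (increment U, recovery time F), R the recovered resource fraction
#' (recovery time D); the response to spike n is proportional to
#' R_n * u_n.
#'
#' @param U,D,F TM parameters (D, F in ms).
#' @param spike_times sorted spike times (ms).
#' @return data.frame with u, R and relative amplitude per spike.
#' @export
tm_deterministic <- function(U, D, F, spike_times) {
  n <- length(spike_times)
  u <- numeric(n); R <- numeric(n)
  u[1] <- U; R[1] <- 1
  if (n > 1) for (k in 2:n) {
    dt <- spike_times[k] - spike_times[k - 1]
    u[k] <- U + u[k - 1] * (1 - U) * exp(-dt / max(F, 1e-9))
    R[k] <- 1 - (1 - R[k - 1] * (1 - u[k - 1])) * exp(-dt / max(D, 1e-9))
  }
  data.frame(t = spike_times, u = u, R = R, amplitude = u * R)
}

#' Stochastic Tsodyks-Markram release
#'
#' Each of `n_sites` release sites is a 2-state Markov process (recovered
#' / unrecovered). At a presynaptic spike a recovered site releases with
#' probability u (the facilitation variable, incremented by U and
#' decaying with time constant F); a released site becomes unrecovered
#' and recovers exponentially with time constant D. The ensemble mean
#' release per site equals the deterministic recursion.
#'
#' @param U,D,F TM parameters.
#' @param spike_times sorted spike times (ms).
#' @param n_sites number of independent release sites.
#' @param seed integer seed.
#' @return integer vector: quanta released per spike.
#' @export
tm_release <- function(U, D, F, spike_times, n_sites = 1, seed = 1) {
  set.seed(seed)
  n <- length(spike_times)
  rel <- integer(n)
  rec <- rep(TRUE, n_sites)
  trel <- rep(-Inf, n_sites)
  u <- U
  tlast <- -Inf
  for (k in seq_len(n)) {
    t <- spike_times[k]
    u <- if (is.finite(tlast))
      U + u * (1 - U) * exp(-(t - tlast) / max(F, 1e-9)) else U
    tlast <- t
    for (s in seq_len(n_sites)) {
      if (!rec[s]) {
        if (stats::runif(1) < 1 - exp(-(t - trel[s]) / max(D, 1e-9)))
          rec[s] <- TRUE
        else trel[s] <- t # exponential recovery is memoryless
      }
      if (rec[s] && stats::runif(1) < u) {
        rec[s] <- FALSE
        trel[s] <- t
        rel[k] <- rel[k] + 1L
      }
    }
  }
  rel
}

#' Double-exponential conductance waveform
#'
#' g(t) = g_peak * (exp(-t/tau_d) - exp(-t/tau_r)) normalized so that the
#' peak equals g_peak.
#'
#' @param t time since release (ms; values < 0 give 0).
#' @param g_peak peak conductance.
#' @param tau_r,tau_d rise and decay time constants (ms, tau_r < tau_d).
#' @return conductance at `t`.
#' @export
syn_conductance <- function(t, g_peak, tau_r, tau_d) {
  stopifnot(tau_r < tau_d)
  tp <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  norm <- 1 / (exp(-tp / tau_d) - exp(-tp / tau_r))
  ifelse(t < 0, 0, g_peak * norm * (exp(-t / tau_d) - exp(-t / tau_r)))
}

#' Voltage-dependent magnesium block of NMDA receptors
#'
#' Jahr-Stevens sigmoidal block; approaches 1 at depolarized potentials.
#' @param V membrane potential (mV).
#' @param mg_mM extracellular magnesium (default 1 mM).
#' @return block factor in (0, 1).
#' @export
nmda_block <- function(V, mg_mM = 1) {
  1 / (1 + exp(-0.062 * V) * mg_mM / 3.57)
}

#' Fit Tsodyks-Markram parameters to a peak-amplitude train
#'
#' Multi-start Nelder-Mead minimizing the squared deviation between the
#' deterministic TM prediction and the observed peaks (both normalized to
#' the first peak). The standard protocol is 8 pulses at 40 Hz followed
#' by a recovery pulse.
#'
#' @param peaks amplitude train (>= 9 peaks for the standard protocol).
#' @param spike_times pulse times (ms); default 8 at 40 Hz + recovery at
#'   550 ms.
#' @param seed integer seed for start points.
#' @param n_starts number of random restarts.
#' @return list with U, D, F, class ("E1" facilitating / "E2/I2"
#'   depressing), sse, and `degenerate` flag for flat trains.
#' @export
fit_udf <- function(peaks, spike_times = c(seq(0, by = 25, length.out = 8),
                                           550),
                    seed = 1, n_starts = 12) {
  if (length(peaks) != length(spike_times))
    stop("peaks and spike_times must have equal length")
  set.seed(seed)
  y <- peaks / peaks[1]
  obj <- function(p) {
    U <- 1 / (1 + exp(-p[1]))
    D <- exp(p[2]); F <- exp(p[3])
    a <- tm_deterministic(U, D, F, spike_times)$amplitude
    sum((a / a[1] - y)^2)
  }
  best <- NULL
  for (k in seq_len(n_starts)) {
    p0 <- c(stats::rnorm(1, 0, 1.5), log(stats::runif(1, 50, 1500)),
            log(stats::runif(1, 5, 1500)))
    fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  U <- 1 / (1 + exp(-best$par[1]))
  D <- exp(best$par[2]); F <- exp(best$par[3])
  degenerate <- stats::sd(y) < 1e-6
  if (degenerate)
    warning("flat amplitude train: D and F are not identifiable")
  cls <- if (y[length(spike_times) - 1] > 1.05) "E1" else "E2/I2"
  list(U = U, D = D, F = F, sse = best$value, class = cls,
       degenerate = degenerate)
}

#' Calcium dependence of release probability
#'
#' Hill-type scaling of U with the extracellular calcium concentration,
#' anchored at the in-vitro reference of 2 mM (scale(2) = 1) and
#' monotonically increasing in calcium. The coefficients follow the
#' intermediate calcium dependence of uncharacterized cortical pathways
#' (configuration values imported from the neocortical model, not
#' measured in thalamus).
#'
#' @param ca_mM extracellular calcium (mM).
#' @param hill_n Hill coefficient (default 2.5).
#' @param hill_k half-activation (default 1.6 mM).
#' @return multiplicative factor on U (1 at 2 mM).
#' @export
calcium_scale <- function(ca_mM, hill_n = 2.5, hill_k = 1.6) {
  h <- function(ca) ca^hill_n / (ca^hill_n + hill_k^hill_n)
  h(ca_mM) / h(2.0)
}

#' Spontaneous miniature release events
#'
#' Independent Poisson process per synapse at the given rate; minis
#' engage the same release machinery as spikes (a mini can depress its
#' site).
#'
#' @param n_synapses number of synapses.
#' @param duration simulated time (ms).
#' @param rate_hz per-synapse rate (default 0.01 Hz).
#' @param seed integer seed.
#' @return data.frame with synapse index and event time (ms), sorted.
#' @export
apply_minis <- function(n_synapses, duration, rate_hz = 0.01, seed = 1) {
  set.seed(seed)
  if (rate_hz <= 0 || n_synapses == 0)
    return(data.frame(synapse = integer(0), time = numeric(0)))
  n_ev <- stats::rpois(1, n_synapses * rate_hz * duration / 1000)
  out <- data.frame(synapse = sample.int(n_synapses, n_ev, replace = TRUE),
                    time = stats::runif(n_ev, 0, duration))
  out[order(out$time), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# passive gap-junction network algebra
#
# Cells are reduced to their somatic input conductance for the purpose of
# steady-state coupling: node conductance matrix G with diagonal
# g_cell_i + sum(g_gj) and off-diagonal -g_gj. Input resistance of cell i
# with neighbors free is [G^-1]_ii.

.gj_conductance_matrix <- function(g_cell, gj_pairs, gj_g) {
  n <- length(g_cell)
  G <- diag(g_cell, n)
  if (length(gj_g)) for (k in seq_along(gj_g)) {
    i <- gj_pairs[k, 1]; j <- gj_pairs[k, 2]; g <- gj_g[k]
    G[i, i] <- G[i, i] + g
    G[j, j] <- G[j, j] + g
    G[i, j] <- G[i, j] - g
    G[j, i] <- G[j, i] - g
  }
  G
}

#' Measure steady-state input resistance in a gap-junction network
#' @param g_cell per-cell intrinsic (leak) conductance (uS).
#' @param gj_pairs 2-column matrix of coupled cell indices.
#' @param gj_g per-junction conductance (uS).
#' @return per-cell input resistance (MOhm), neighbors unclamped.
#' @export
gj_input_resistance <- function(g_cell, gj_pairs, gj_g) {
  G <- .gj_conductance_matrix(g_cell, gj_pairs, gj_g)
  diag(solve(G))
}

#' Compensate leak conductance for gap-junction load
#'
#' Solves per-cell leak conductances so that each cell's input resistance
#' in the coupled network returns to its pre-gap-junction value within
#' `tol` (relative). Uses a damped fixed-point iteration on the inverse
#' of the network conductance matrix; conductances that would become
#' negative are clamped at a small positive value with a warning.
#'
#' @param g_cell per-cell intrinsic conductance before adding gap
#'   junctions (uS).
#' @param gj_pairs,gj_g junction topology and conductances (uS).
#' @param tol relative input-resistance tolerance (default 0.01).
#' @param max_iter iteration cap.
#' @param clamp_frac lower bound on the compensated conductance as a
#'   fraction of the original (cells with a heavy junction load cannot
#'   be fully compensated without a negative leak).
#' @return adjusted per-cell leak conductance vector (uS).
#' @export
compensate_input_resistance <- function(g_cell, gj_pairs, gj_g, tol = 0.01,
                                        max_iter = 50, clamp_frac = 0.8) {
  if (!length(gj_g)) return(g_cell)
  r_target <- 1 / g_cell
  g <- g_cell
  lo <- clamp_frac * g_cell
  clamped <- FALSE
  for (it in seq_len(max_iter)) {
    r <- gj_input_resistance(g, gj_pairs, gj_g)
    err <- r_target / r - 1
    if (max(abs(err)) < tol) break
    g_new <- g + (1 / r_target - 1 / r)
    if (any(g_new < lo)) {
      g_new[g_new < lo] <- lo[g_new < lo]
      clamped <- TRUE
    }
    g <- g_new
  }
  if (clamped)
    warning("compensated leak conductance clamped at a small positive value for some cells")
  g
}

#' Steady-state coupling coefficient between two coupled cells
#'
#' CC = dV_post / dV_pre for a steady current step into the pre cell in
#' the full coupled network. For an isolated symmetric pair with cell
#' resistance R and junction conductance G, CC = GR / (1 + GR).
#'
#' @param g_cell per-cell conductance (uS).
#' @param gj_pairs,gj_g junction topology and conductances (uS).
#' @param pre,post cell indices.
#' @return the coupling coefficient (dimensionless).
#' @export
coupling_coefficient <- function(g_cell, gj_pairs, gj_g, pre, post) {
  G <- .gj_conductance_matrix(g_cell, gj_pairs, gj_g)
  Ginv <- solve(G)
  Ginv[post, pre] / Ginv[pre, pre]
}

#' Calibrate synaptic conductance to a target PSP amplitude
#'
#' In-silico paired recordings: for `n_pairs` model pairs the presynaptic
#' neuron is driven once per trial and the somatic postsynaptic-potential
#' amplitude is averaged over `n_trials` stochastic trials; the per-site
#' conductance is scaled iteratively until the mean amplitude matches the
#' target within `tol` (relative). Also reports the coefficient of
#' variation of first-PSP amplitudes across trials.
#'
#' @param psp_fun function(g_nS, seed) returning a vector of single-trial
#'   PSP amplitudes (mV) at conductance `g_nS`; the package supplies this
#'   from the network engine (see [measure_psp()]).
#' @param target_mV target mean PSP amplitude (mV, absolute value).
#' @param g_init starting conductance (nS).
#' @param n_pairs,n_trials protocol sizes (defaults 50 pairs x 30
#'   trials).
#' @param tol relative tolerance (default 0.05).
#' @param max_iter iteration cap.
#' @param seed integer seed.
#' @return list with calibrated g (nS), achieved mean PSP, first-PSP CV.
#' @export
calibrate_conductance <- function(psp_fun, target_mV, g_init = 1,
                                  n_pairs = 50, n_trials = 30, tol = 0.05,
                                  max_iter = 8, seed = 1) {
  g <- g_init
  amp <- NA
  cv <- NA
  for (it in seq_len(max_iter)) {
    amps <- psp_fun(g, seed + it)
    amp <- mean(abs(amps))
    cv <- stats::sd(abs(amps)) / amp
    if (!is.finite(amp) || amp <= 0)
      stop("unreachable target: no measurable PSP at g = ", g)
    if (abs(amp - target_mV) / target_mV < tol) break
    g_new <- g * target_mV / amp
    if (it == max_iter && abs(amp - target_mV) / target_mV >= tol)
      warning("PSP calibration did not converge (possible saturation)")
    g <- g_new
  }
  list(g_nS = g, psp_mV = amp, cv_first = cv)
}

#' Draw per-synapse parameters from truncated Gaussians
#'
#' U is truncated to (0.01, 1], D and F to > 1 ms, g to > 0.
#' @param n number of synapses.
#' @param p one row of [pathway_physiology()].
#' @param seed integer seed.
#' @return data.frame of per-synapse U, D, F, g_nS.
#' @export
draw_synapse_params <- function(n, p, seed = 1) {
  set.seed(seed)
  rtrunc <- function(n, mean, sd, lo, hi = Inf) {
    x <- stats::rnorm(n, mean, sd)
    bad <- x < lo | x > hi
    while (any(bad)) {
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
      bad <- x < lo | x > hi
    }
    x
  }
  data.frame(
    U = rtrunc(n, p$U, p$U_sd, 0.01, 1),
    D = rtrunc(n, p$D, p$D_sd, 1),
    F = rtrunc(n, p$F, p$F_sd, 1),
    g_nS = rtrunc(n, p$g_nS, p$g_sd, 0.01))
}
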