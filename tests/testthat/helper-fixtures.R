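# Shared fixtures, built once per test run and cached.
.fx_cache <- new.env(parent = emptyenv())

# small end-to-end circuit for connectome / engine tests
small_fixture <- function() {
  if (is.null(.fx_cache$small))
    .fx_cache$small <- suppressWarnings(
      make_fixture_circuit(density_scale = 0.04, seed = 1, pool_size = 6))
  .fx_cache$small
}

# the desk-scale operating point used by the acceptance criteria
desk_fixture <- function() {
  if (is.null(.fx_cache$desk))
    .fx_cache$desk <- suppressWarnings(
      make_fixture_circuit(density_scale = 0.1, seed = 1, pool_size = 8))
  .fx_cache$desk
}

# independent O(n^2) segment-pair touch oracle (mirrors the spec rule,
# not the engine implementation)
brute_force_touches <- function(seg, cell, pre_ok, post_ok, touch_distance) {
  # vectorized over the second segment: clamped closed-form distance
  # between segment i and all segments
  P2 <- seg[, 1:3, drop = FALSE]; Q2 <- seg[, 4:6, drop = FALSE]
  D2 <- Q2 - P2
  e <- rowSums(D2 * D2)
  out <- list()
  n <- nrow(seg)
  for (i in which(pre_ok)) {
    p1 <- seg[i, 1:3]; q1 <- seg[i, 4:6]
    d1 <- q1 - p1
    a <- sum(d1 * d1)
    r <- sweep(-P2, 2, p1, "+")           # p1 - P2
    f <- rowSums(D2 * r)
    cvec <- as.numeric(r %*% d1) * -1     # c = d1 . (P2 - p1) ... sign below
    cvec <- -cvec                          # d1 . (p1 - P2)
    b <- as.numeric(D2 %*% d1)
    den <- a * e - b * b
    s_ <- ifelse(den > 1e-12, pmin(1, pmax(0, (b * f - cvec * e) / den)), 0)
    t_ <- ifelse(e > 1e-12, (b * s_ + f) / e, 0)
    lo <- t_ < 0; hi <- t_ > 1
    t_[lo] <- 0; t_[hi] <- 1
    s_[lo] <- pmin(1, pmax(0, -cvec[lo] / a))
    s_[hi] <- pmin(1, pmax(0, (b[hi] - cvec[hi]) / a))
    if (a <= 1e-12) { s_[] <- 0; t_ <- pmin(1, pmax(0, f / pmax(e, 1e-12))) }
    cx <- p1[1] + d1[1] * s_ - (P2[, 1] + D2[, 1] * t_)
    cy <- p1[2] + d1[2] * s_ - (P2[, 2] + D2[, 2] * t_)
    cz <- p1[3] + d1[3] * s_ - (P2[, 3] + D2[, 3] * t_)
    gap <- pmax(0, sqrt(cx^2 + cy^2 + cz^2) - seg[i, 7] - seg[, 7])
    hit <- which(gap <= touch_distance & post_ok & cell != cell[i])
    if (length(hit))
      out[[length(out) + 1]] <- cbind(i, hit)
  }
  if (!length(out)) matrix(0, 0, 2) else do.call(rbind, out)
}

# brute-force burst labeling oracle (literal rule application)
brute_force_bursts <- function(st, isi_max = 15, pause_min = 50) {
  n <- length(st)
  lab <- integer(n)
  if (n == 0) return(lab)
  bid <- 0L
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && st[j + 1] - st[j] <= isi_max) j <- j + 1
    pause <- if (i == 1) Inf else st[i] - st[i - 1]
    if (j > i && pause >= pause_min) {
      bid <- bid + 1
      lab[i:j] <- bid
    }
    i <- j + 1
  }
  lab
}
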