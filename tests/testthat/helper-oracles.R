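# Shared fixtures and independent oracles used across the suite.

small_cfg <- function(seed = 1, n0_events = 150, growth_factor = 10, ...) {
  synthetic_config(seed = seed, n0_events = n0_events,
                   growth_factor = growth_factor, ...)
}

# Winding-angle point-in-polygon oracle, algorithmically unrelated to the
# package's even-odd ray casting.
oracle_in_polygon <- function(px, py, vx, vy) {
  vapply(seq_along(px), function(i) {
    dx <- vx - px[i]; dy <- vy - py[i]
    if (any(dx == 0 & dy == 0)) return(TRUE)
    on <- FALSE
    n <- length(vx); j <- n
    for (k in seq_len(n)) {
      cr <- (vx[k] - vx[j]) * (py[i] - vy[j]) - (vy[k] - vy[j]) * (px[i] - vx[j])
      if (abs(cr) < 1e-12 &&
          px[i] >= min(vx[j], vx[k]) - 1e-12 &&
          px[i] <= max(vx[j], vx[k]) + 1e-12 &&
          py[i] >= min(vy[j], vy[k]) - 1e-12 &&
          py[i] <= max(vy[j], vy[k]) + 1e-12) on <- TRUE
      j <- k
    }
    if (on) return(TRUE)
    ang <- atan2(dy, dx)
    d <- diff(c(ang, ang[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi
  }, logical(1))
}

# Mann-Whitney U oracle for the AUC under the "positive when score < t"
# orientation: P(score_pos < score_neg) + 0.5 * P(tie).
auc_oracle <- function(pos, neg) {
  mean(outer(pos, neg, function(a, b) (a < b) + 0.5 * (a == b)))
}

# Strict-policy MBC scan oracle: the lowest concentration c such that every
# concentration >= c is labelled above_or_MBC (NA if none).
mbc_scan_oracle <- function(conc, labels) {
  ok <- vapply(seq_along(conc),
               function(i) all(labels[1:i] == "above_or_MBC"), logical(1))
  if (!any(ok)) NA_real_ else conc[max(which(ok))]
}

# Shoelace polygon area (for gate-monotonicity checks).
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
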