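# Independent oracles used across the test files.

# Steady state of the 4-state photocycle at constant flux, by direct linear
# solve of the rate matrix (replacing one balance row with conservation).
pc_steady_oracle <- function(op, phi) {
  r <- light_rates(phi, op)
  A <- rbind(
    c(-r$Ga1, op$Gd1, 0, op$Gr),
    c(r$Ga1, -(op$Gd1 + r$Gf), r$Gb, 0),
    c(0, r$Gf, -(op$Gd2 + r$Gb), r$Ga2),
    c(1, 1, 1, 1))
  b <- c(0, 0, 0, 1)
  x <- solve(A, b)
  names(x) <- c("C1", "O1", "O2", "C2")
  x
}

# Peak-finding spike oracle: local maxima above `thresh` with prominence
# above `prom` relative to the lowest point between successive peaks.
peak_spike_oracle <- function(time, v, thresh = 0, prom = 20) {
  n <- length(v)
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1
  idx <- idx[v[idx] > thresh]
  if (length(idx) < 2) return(time[idx])
  keep <- idx[1]
  for (i in idx[-1]) {
    trough <- min(v[keep[length(keep)]:i])
    if (v[i] - trough >= prom && min(v[keep[length(keep)]:i]) < thresh)
      keep <- c(keep, i)
  }
  time[keep]
}

# Copy of an opsin parameter set with fields overridden (for analytic-limit
# checks with simplified kinetics).
opsin_variant <- function(base, ...) {
  ov <- list(...)
  for (nm in names(ov)) base[[nm]] <- ov[[nm]]
  base
}

# Trapezoid quadrature (local copy so tests do not rely on internals).
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
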