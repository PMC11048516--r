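# Shared fixtures and independent oracles, all built in code.

# O(n^2) pair-enumeration oracle for Kendall's tau-b (tie-corrected).
taub_oracle <- function(x, y) {
  n <- length(x); C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
    if (a == 0 && b == 0) next
    if (a == 0) tx <- tx + 1 else if (b == 0) ty <- ty + 1
    else if (a == b) C <- C + 1 else D <- D + 1
  }
  (C - D) / sqrt((C + D + tx) * (C + D + ty))
}

# Step-up BH oracle, written out directly from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# 1-pixel rasterized half-circle arc of radius R.
half_circle_mask <- function(size = 200, R = 70) {
  m <- matrix(FALSE, size, size)
  th <- seq(0, pi, length.out = 30 * R)
  r <- round(size * 0.3 + R * sin(th)); c <- round(size / 2 + R * cos(th))
  keep <- r >= 1 & r <= size & c >= 1 & c <= size
  m[cbind(r[keep], c[keep])] <- TRUE
  m
}

# 1-pixel rasterized sine-wave vessel; returns mask plus the analytic
# arc/chord ratio from numerical quadrature.
sine_vessel_fixture <- function(A = 12, lam = 60, L = 180) {
  t <- seq(0, L, length.out = 20 * L)
  m <- matrix(FALSE, 100, L + 40)
  m[cbind(round(50 + A * sin(2 * pi * t / lam)), round(10 + t))] <- TRUE
  f <- function(x) sqrt(1 + (2 * pi * A / lam * cos(2 * pi * x / lam))^2)
  list(mask = m,
       ratio = stats::integrate(f, 0, L, subdivisions = 2000L)$value / L)
}

# Annulus region mask (inner <= d < outer, pixel distances from center).
annulus_mask <- function(size, inner, outer, center = rep((size + 1) / 2, 2)) {
  d <- sqrt(outer((seq_len(size) - center[1])^2,
                  (seq_len(size) - center[2])^2, `+`))
  d >= inner & d < outer
}

# A small extracted synthetic cohort, cached across tests in one run.
cached_cohort <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) {
      coh <<- suppressWarnings(
        generate_cohort(8, 8, seed = 77, size_px = 144))
    }
    coh
  }
})
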