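# Independent brute-force oracles used across the suite.  These are
# deliberately naive re-implementations (plain loops, closed forms),
# kept separate from the package code paths they check.

# O(N^2) minimum pairwise distance between two coordinate sets.
brute_min_distance <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
    }
  }
  best
}

# Mass-weighted radius of gyration by direct formula evaluation.
brute_rg <- function(xyz, m) {
  m <- m / sum(m)
  cm <- colSums(xyz * m)
  sqrt(sum(m * rowSums(sweep(xyz, 2L, cm)^2)))
}

# Two-point weighted variance RMSF (no superposition), one residue.
brute_rmsf <- function(coords_list, w) {
  mu <- Reduce(`+`, Map(`*`, coords_list, w))
  sqrt(sum(unlist(Map(function(c_, wi) wi * sum((c_ - mu)^2),
                      coords_list, w))))
}

# Dense-quadrature Shrake-Rupley at arbitrary point count: independent
# plain-loop implementation with its own (latitude-band) point grid.
brute_sasa <- function(xyz, radii, probe, n_points) {
  k <- seq_len(n_points)
  z <- (2 * k - 1) / n_points - 1
  theta <- sqrt(n_points * pi) * asin(z)
  pts <- cbind(sqrt(1 - z^2) * cos(theta), sqrt(1 - z^2) * sin(theta), z)
  out <- numeric(nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    ri <- radii[i] + probe
    acc <- 0L
    for (q in seq_len(n_points)) {
      p <- xyz[i, ] + ri * pts[q, ]
      buried <- FALSE
      for (j in seq_len(nrow(xyz))) {
        if (j == i) next
        if (sum((p - xyz[j, ])^2) < (radii[j] + probe)^2) {
          buried <- TRUE
          break
        }
      }
      if (!buried) acc <- acc + 1L
    }
    out[i] <- 4 * pi * ri^2 * acc / n_points
  }
  out
}

# Analytic accessible area of sphere 1 (expanded radius R1) partially
# occluded by sphere 2 (R2) at centre distance d.
analytic_two_sphere <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h
}

# Exhaustive confusion-count metrics for tiny binary matrices.
brute_metrics <- function(y, p) {
  tp <- sum(y == 1 & p == 1); tn <- sum(y == 0 & p == 0)
  fp <- sum(y == 0 & p == 1); fn <- sum(y == 1 & p == 0)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(mcc = if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den),
       hamming = (fp + fn) / length(y),
       zero_one = mean(apply(y != p, 1L, any)))
}

# Small helper: conformation from bare CA coordinates.
ca_conf <- function(xyz, resid = seq_len(nrow(xyz)), ...) {
  conformation(xyz, resid = resid, element = "C", atom_name = "CA", ...)
}

# Small fixture spec used by fast tests.
small_spec <- function(seed = 7L) {
  fixture_spec(n_residues = 40L, n_frames = 10L, n_compounds = 300L,
               n_sites = 8L, n_planted = 10L, screen_size = 60L,
               screen_planted = 10L, rigid_block = c(15L, 28L),
               seed = seed)
}
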