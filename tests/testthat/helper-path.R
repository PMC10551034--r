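# Fixtures and independent oracles for the path model.

# Straight-line CV series between two 6-D points.
lineSeries <- function(a, b, n) {
  t(vapply(seq(0, 1, length.out = n), function(f) a + f * (b - a), numeric(length(a))))
}

# Identity-metric Euclidean projection oracle: independent of the package's
# softmin construction. Returns (s, z) from the closest clamped segment.
euclidProjectOracle <- function(x, nodes) {
  nSeg <- nrow(nodes) - 1
  best <- c(Inf, 0)
  for (i in seq_len(nSeg)) {
    v <- nodes[i + 1, ] - nodes[i, ]
    t <- sum((x - nodes[i, ]) * v) / sum(v * v)
    t <- min(max(t, 0), 1)
    p <- nodes[i, ] + t * v
    d <- sqrt(sum((x - p)^2))
    if (d < best[1]) best <- c(d, (i - 1 + t) / nSeg)
  }
  c(s = best[2], z = best[1])
}

# Dense-discretization brute-force oracle for the off-path distance with a
# constant metric M (distance^2 = Delta^T M^-1 Delta).
denseDistOracle <- function(x, nodes, Minv, nDense = 1e4) {
  nSeg <- nrow(nodes) - 1
  perSeg <- ceiling(nDense / nSeg)
  best <- Inf
  for (i in seq_len(nSeg)) {
    for (f in seq(0, 1, length.out = perSeg)) {
      p <- nodes[i, ] + f * (nodes[i + 1, ] - nodes[i, ])
      d <- x - p
      best <- min(best, sum(d * (Minv %*% d)))
    }
  }
  sqrt(best)
}

# A gently curving 6-D path for reparameterization tests.
smoothCurveNodes <- function(n, seed = 1) {
  set.seed(seed)
  tt <- sort(c(0, 1, runif(n - 2))) # non-uniform parameterization
  cbind(3 + 2 * tt, sin(1.5 * tt), cos(1.5 * tt), 0.5 * tt^2, 0.3 * tt, -0.4 * tt)
}

# Central finite differences of (s, z) in CV space.
fdPathGrad <- function(x, path, h = 1e-6, metric = NULL) {
  D <- length(x)
  ds <- numeric(D); dz <- numeric(D)
  for (k in seq_len(D)) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    ep <- evaluatePathCV(xp, path, metric)
    em <- evaluatePathCV(xm, path, metric)
    ds[k] <- (ep$s - em$s) / (2 * h)
    dz[k] <- (ep$z - em$z) / (2 * h)
  }
  list(ds = ds, dz = dz)
}
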