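## Path model: build a path in CV space from a guess trajectory and
## evaluate the metric-corrected path collective variable (s, z).
##
## The pathCV adopted here projects a CV point onto every path segment
## (clamped metric-orthogonal projection), then blends the per-segment
## progress values with softmin weights over the squared metric segment
## distances. It is exact at the nodes, smooth between segments, and
## reduces to plain Euclidean path projection in the identity-metric
## limit. Distances use the quadratic form with the inverse metric,
## Delta^T M^{-1} Delta, with periodic wrapping of dihedral components.

## squared metric distance between CV points
metricDist2 <- function(a, b, Ginv, periodic) {
  d <- maskedDiff(as.numeric(a), as.numeric(b), periodic)
  sum(d * (Ginv %*% d))
}

#' Project a trajectory into CV space
#'
#' Computes one CV vector per snapshot, preserving order. The periodic
#' (dihedral) components of the returned series are unwrapped for
#' continuity: consecutive jumps larger than pi are corrected by +/- 2 pi,
#' so the series is suitable for path construction. The plainly wrapped
#' values are retained in the `wrapped` attribute.
#'
#' @param trajectory List of n x 3 coordinate matrices (Angstrom).
#' @param frame An [AnchorFrame-class].
#' @return nFrames x 6 matrix of CVs (continuous scale), with attributes
#'   `wrapped` (the per-frame wrapped values) and `periodic`.
#' @export
projectTrajectory <- function(trajectory, frame) {
  stopifnot2(length(trajectory) >= 1, "trajectory must contain at least one snapshot")
  cvs <- matrix(0, length(trajectory), 6)
  for (i in seq_along(trajectory)) {
    cvs[i, ] <- tryCatch(as.numeric(computeCVs(trajectory[[i]], frame)),
                         error = function(e)
                           stop(sprintf("frame %d: %s", i, conditionMessage(e)),
                                call. = FALSE))
  }
  colnames(cvs) <- c("d", "thetaA", "thetaB", "phiA", "phiB", "phiC")
  wrapped <- cvs
  mask <- unname(cvPeriodicMask())
  for (j in which(mask)) {
    if (nrow(cvs) > 1) {
      steps <- wrapAngle(diff(cvs[, j]))
      cvs[, j] <- cvs[1, j] + c(0, cumsum(steps))
    }
  }
  attr(cvs, "wrapped") <- wrapped
  attr(cvs, "periodic") <- mask
  cvs
}

## Assemble a Path from node coordinates + per-node metrics, computing the
## frozen per-segment inverse metrics and cumulative metric arc lengths.
newPathFromNodes <- function(nodes, nodeMetrics, lambda, periodic,
                             provenance = list()) {
  n <- nrow(nodes)
  segGinv <- vector("list", n - 1)
  arcs <- numeric(n)
  for (i in seq_len(n - 1)) {
    segGinv[[i]] <- psdPinv((nodeMetrics[[i]] + nodeMetrics[[i + 1]]) / 2)
    d2 <- metricDist2(nodes[i + 1, ], nodes[i, ], segGinv[[i]], periodic)
    if (d2 <= 1e-16)
      stop(sprintf("degenerate path: nodes %d and %d coincide (metric distance <= 1e-8)",
                   i, i + 1), call. = FALSE)
    arcs[i + 1] <- arcs[i] + sqrt(d2)
  }
  new("Path", nodes = nodes, nodeMetrics = nodeMetrics, segGinv = segGinv,
      lambda = lambda, arcLengths = arcs, periodic = periodic,
      provenance = provenance)
}

## Normalize the metric argument into a list of per-frame matrices.
frameMetrics <- function(metric, nFrames, dim) {
  if (is.null(metric)) metric <- diag(dim)
  if (is.matrix(metric)) return(rep(list(metric), nFrames))
  stopifnot2(is.list(metric) && length(metric) == nFrames,
             "metric must be NULL, one matrix, or one matrix per frame")
  metric
}

#' Build a path from a CV series
#'
#' Three stages: (1) a backtracking filter greedily keeps frames whose
#' metric distance from the last kept frame exceeds a threshold (total
#' metric length / (4 n_nodes)) and additionally drops frames that
#' revisit the neighbourhood of an earlier kept frame, which removes the
#' pauses and retraces typical of interactively steered guess trajectories;
#' (2) each CV component is smoothed with a cubic smoothing spline
#' against cumulative metric arc length; (3) the smooth curve is
#' resampled to `nNodes` nodes equally spaced in metric arc length. The
#' series endpoints are preserved as the first and last nodes (the last
#' only when the trailing frames do not backtrack).
#'
#' @param cvSeries nFrames x D matrix on the continuous scale (e.g. from
#'   [projectTrajectory()]).
#' @param nNodes Number of path nodes (>= 2).
#' @param metric NULL (identity), a single D x D metric tensor, or a list
#'   of per-frame tensors; frozen into the path at construction.
#' @param lambda Softmin smoothing scale (default 4.6: a segment one
#'   node-spacing farther than the best one gets weight 0.01).
#' @param smooth Apply the smoothing-spline stage (default TRUE).
#' @param periodic Logical mask of periodic components (default: the six
#'   CV components' mask when D = 6, otherwise all FALSE).
#' @return A [Path-class].
#' @export
buildPath <- function(cvSeries, nNodes, metric = NULL, lambda = 4.6,
                      smooth = TRUE, periodic = NULL) {
  cvSeries <- as.matrix(cvSeries)
  n <- nrow(cvSeries); D <- ncol(cvSeries)
  stopifnot2(nNodes >= 2, "nNodes must be >= 2")
  if (is.null(periodic))
    periodic <- if (D == 6) unname(cvPeriodicMask()) else rep(FALSE, D)
  metrics <- frameMetrics(metric, n, D)
  Ginvs <- lapply(metrics, psdPinv)
  if (n < 2) stop("degenerate path: need at least 2 frames", call. = FALSE)

  ## consecutive metric arc increments
  inc <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    G <- if (identical(metrics[[i]], metrics[[i + 1]])) Ginvs[[i]] else
      psdPinv((metrics[[i]] + metrics[[i + 1]]) / 2)
    inc[i] <- sqrt(max(metricDist2(cvSeries[i + 1, ], cvSeries[i, ], G, periodic), 0))
  }
  total <- sum(inc)
  if (total <= 1e-12)
    stop("degenerate path: the CV series contains fewer than 2 distinct points",
         call. = FALSE)
  threshold <- total / (4 * nNodes)

  ## backtracking filter
  kept <- 1L
  for (i in 2:n) {
    last <- kept[length(kept)]
    dLast <- sqrt(metricDist2(cvSeries[i, ], cvSeries[last, ], Ginvs[[last]], periodic))
    if (dLast < threshold) next
    revisit <- FALSE
    if (length(kept) > 1) {
      for (k in kept[-length(kept)]) {
        if (sqrt(metricDist2(cvSeries[i, ], cvSeries[k, ], Ginvs[[k]], periodic)) <
            threshold) { revisit <- TRUE; break }
      }
    }
    if (!revisit) kept <- c(kept, i)
  }
  if (kept[length(kept)] != n) { # preserve the series end unless it backtracks
    dPrior <- if (length(kept) > 1) {
      min(vapply(kept[-length(kept)], function(k)
        sqrt(metricDist2(cvSeries[n, ], cvSeries[k, ], Ginvs[[k]], periodic)), 0))
    } else Inf
    if (dPrior >= threshold) { # the series end is new territory, keep it
      dLast <- sqrt(metricDist2(cvSeries[n, ], cvSeries[kept[length(kept)], ],
                                Ginvs[[kept[length(kept)]]], periodic))
      if (dLast >= threshold) kept <- c(kept, n)
      else kept[length(kept)] <- n # too close to the last kept frame: replace it
    }
  }
  if (length(kept) < 2) kept <- c(1L, n)
  pts <- cvSeries[kept, , drop = FALSE]

  ## cumulative arc length of the kept frames
  m <- nrow(pts)
  arc <- numeric(m)
  for (i in seq_len(m - 1)) {
    G <- psdPinv((metrics[[kept[i]]] + metrics[[kept[i + 1]]]) / 2)
    arc[i + 1] <- arc[i] + sqrt(metricDist2(pts[i + 1, ], pts[i, ], G, periodic))
  }

  ## cubic smoothing + dense resampling
  nDense <- max(40L * nNodes, 400L)
  denseArc <- seq(0, arc[m], length.out = nDense)
  dense <- matrix(0, nDense, D)
  for (j in seq_len(D)) {
    if (smooth && m >= 8) {
      fit <- stats::smooth.spline(arc, pts[, j], cv = FALSE)
      dense[, j] <- stats::predict(fit, denseArc)$y
    } else {
      dense[, j] <- stats::approx(arc, pts[, j], xout = denseArc, rule = 2)$y
    }
  }
  dense[1, ] <- cvSeries[1, ]
  if (kept[length(kept)] == n) dense[nDense, ] <- cvSeries[n, ]

  ## equal-arc resampling of the dense curve (metric arc length)
  denseMetricIdx <- pmin(pmax(round(stats::approx(
    x = seq(0, 1, length.out = m), y = kept, xout = denseArc / max(arc[m], 1e-300),
    rule = 2)$y), 1L), n)
  dinc <- numeric(nDense - 1)
  for (i in seq_len(nDense - 1)) {
    G <- Ginvs[[denseMetricIdx[i]]]
    dinc[i] <- sqrt(metricDist2(dense[i + 1, ], dense[i, ], G, periodic))
  }
  cum <- c(0, cumsum(dinc))
  targets <- seq(0, cum[nDense], length.out = nNodes)
  nodes <- matrix(0, nNodes, D, dimnames = list(NULL, colnames(cvSeries)))
  nodeMetricList <- vector("list", nNodes)
  for (k in seq_len(nNodes)) {
    i <- findInterval(targets[k], cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), nDense - 1L)
    f <- if (cum[i + 1] > cum[i]) (targets[k] - cum[i]) / (cum[i + 1] - cum[i]) else 0
    nodes[k, ] <- dense[i, ] + f * (dense[i + 1, ] - dense[i, ])
    nodeMetricList[[k]] <- metrics[[denseMetricIdx[i]]]
  }
  nodes[1, ] <- cvSeries[1, ]
  if (kept[length(kept)] == n) nodes[nNodes, ] <- cvSeries[n, ]

  newPathFromNodes(nodes, nodeMetricList, lambda, periodic,
                   provenance = list(keptFrames = kept, nFrames = n,
                                     threshold = threshold))
}

#' Redistribute path nodes to equal metric arc-length spacing
#'
#' Nodes are moved along the current piecewise-linear path so that they
#' sit at equal fractions of its total metric arc length; the endpoints
#' stay fixed. A path that is already uniform is returned unchanged.
#'
#' @param path A [Path-class].
#' @return A [Path-class] with uniformly spaced nodes.
#' @export
reparameterizePath <- function(path) {
  nodes <- path@nodes
  n <- nrow(nodes)
  periodic <- path@periodic
  seg <- numeric(n - 1)
  for (i in seq_len(n - 1))
    seg[i] <- sqrt(metricDist2(nodes[i + 1, ], nodes[i, ], path@segGinv[[i]], periodic))
  cum <- c(0, cumsum(seg))
  targets <- seq(0, cum[n], length.out = n)
  newNodes <- nodes
  for (k in 2:(n - 1)) {
    i <- findInterval(targets[k], cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), n - 1L)
    f <- if (cum[i + 1] > cum[i]) (targets[k] - cum[i]) / (cum[i + 1] - cum[i]) else 0
    newNodes[k, ] <- nodes[i, ] + f * (nodes[i + 1, ] - nodes[i, ])
  }
  ## metrics stay frozen per node index (string-method convention)
  newPathFromNodes(newNodes, path@nodeMetrics, path@lambda, periodic,
                   provenance = path@provenance)
}

## Resolve the per-segment inverse metrics, honoring an override metric.
segmentGinvs <- function(path, metric = NULL) {
  if (is.null(metric)) return(path@segGinv)
  G <- psdPinv(metric)
  rep(list(G), nrow(path@nodes) - 1)
}

## Per-segment projection of x: returns matrices/vectors over segments.
## Each row: tRaw, t (clamped), D2, plus cached residual r and Ginv index.
segmentProjections <- function(x, path, Ginvs) {
  nodes <- path@nodes
  nSeg <- nrow(nodes) - 1
  periodic <- path@periodic
  out <- list(t = numeric(nSeg), tRaw = numeric(nSeg), D2 = numeric(nSeg),
              r = vector("list", nSeg), v = vector("list", nSeg),
              c = numeric(nSeg))
  for (i in seq_len(nSeg)) {
    G <- Ginvs[[i]]
    v <- as.numeric(nodes[i + 1, ] - nodes[i, ])
    delta <- maskedDiff(as.numeric(x), as.numeric(nodes[i, ]), periodic)
    cc <- sum(v * (G %*% v))
    tRaw <- if (cc > 0) sum(delta * (G %*% v)) / cc else 0
    t <- min(max(tRaw, 0), 1)
    r <- delta - t * v
    out$t[i] <- t; out$tRaw[i] <- tRaw
    out$D2[i] <- max(sum(r * (G %*% r)), 0)
    out$r[[i]] <- r; out$v[[i]] <- v; out$c[i] <- cc
  }
  out
}

## Segment projections vectorized across segments for the common case of
## one shared inverse metric. Returns the same fields as
## segmentProjections plus matrices used by the gradient.
segmentProjectionsShared <- function(x, nodes, G, periodic) {
  nSeg <- nrow(nodes) - 1
  V <- nodes[-1, , drop = FALSE] - nodes[-(nSeg + 1), , drop = FALSE]
  delta <- matrix(as.numeric(x), nSeg, ncol(nodes), byrow = TRUE) -
    nodes[-(nSeg + 1), , drop = FALSE]
  if (any(periodic)) delta[, periodic] <- wrapAngle(delta[, periodic])
  GV <- V %*% G
  cc <- rowSums(V * GV)
  tRaw <- ifelse(cc > 0, rowSums(delta * GV) / cc, 0)
  t <- pmin(pmax(tRaw, 0), 1)
  r <- delta - t * V
  Gr <- r %*% G
  list(t = t, tRaw = tRaw, D2 = pmax(rowSums(r * Gr), 0),
       Gr = Gr, GV = GV, c = cc)
}

## Core evaluation shared by evaluatePathCV and pathCVGradient.
## Returns s, z plus everything needed for the analytic gradient.
evalPathCVCore <- function(x, path, metric = NULL, wantGrad = FALSE) {
  Ginvs <- segmentGinvs(path, metric)
  nodes <- path@nodes
  nSeg <- nrow(nodes) - 1
  lambda <- path@lambda
  sameG <- TRUE
  if (is.null(metric) && nSeg > 1) {
    for (i in 2:nSeg) if (!identical(Ginvs[[i]], Ginvs[[1]])) { sameG <- FALSE; break }
  }
  pr <- if (sameG) segmentProjectionsShared(x, nodes, Ginvs[[1]], path@periodic)
        else segmentProjections(x, path, Ginvs)
  m <- which.min(pr$D2)

  ## exact endpoint saturation: beyond the first/last node
  saturated <- 0L
  if (m == 1L && pr$tRaw[1] <= 0) saturated <- -1L
  if (m == nSeg && pr$tRaw[nSeg] >= 1) saturated <- 1L
  if (saturated != 0L) {
    G <- if (saturated < 0) Ginvs[[1]] else Ginvs[[nSeg]]
    node <- if (saturated < 0) nodes[1, ] else nodes[nSeg + 1, ]
    delta <- maskedDiff(as.numeric(x), as.numeric(node), path@periodic)
    z2 <- max(sum(delta * (G %*% delta)), 0)
    z <- sqrt(z2)
    res <- list(s = if (saturated < 0) 0 else 1, z = z, segment = m, t = pr$t[m])
    if (wantGrad) {
      res$ds <- numeric(length(x))
      res$dz <- if (z > 1e-12) as.numeric(G %*% delta) / z else numeric(length(x))
    }
    return(res)
  }

  Dmin2 <- max(pr$D2[m], 1e-300)
  u <- pr$D2 / Dmin2
  a <- exp(-lambda * (u - 1)) # shared factor exp(-lambda) cancels in the weights
  w <- a / sum(a)
  sigma <- (seq_len(nSeg) - 1 + pr$t) / nSeg
  s <- sum(w * sigma)
  z2 <- sum(w * pr$D2)
  z <- sqrt(max(z2, 0))
  res <- list(s = s, z = z, segment = m, t = pr$t[m])

  if (wantGrad) {
    D <- length(x)
    if (sameG) {
      dD2 <- 2 * pr$Gr            # rows: dD_i^2/dx
      interior <- pr$tRaw > 0 & pr$tRaw < 1 & pr$c > 0
      dt <- (pr$GV / pmax(pr$c, 1e-300)) * interior
    } else {
      dD2 <- matrix(0, nSeg, D)
      dt <- matrix(0, nSeg, D)
      for (i in seq_len(nSeg)) {
        G <- Ginvs[[i]]
        dD2[i, ] <- 2 * as.numeric(G %*% pr$r[[i]])
        if (pr$tRaw[i] > 0 && pr$tRaw[i] < 1 && pr$c[i] > 0)
          dt[i, ] <- as.numeric(G %*% pr$v[[i]]) / pr$c[i]
      }
    }
    gq <- dD2[m, ]                                  # d Dmin^2 / dx
    du <- (dD2 - outer(u, gq)) / Dmin2              # d(D_i^2/Dmin^2)/dx
    du[w < 1e-14, ] <- 0 # negligible-weight segments cannot contribute
    wdu <- colSums(w * du)
    dw <- -lambda * w * sweep(du, 2, wdu)           # dw_i/dx
    ds <- colSums(dw * sigma) + colSums(w * dt) / nSeg
    dz2 <- colSums(dw * pr$D2) + colSums(w * dD2)
    res$ds <- ds
    res$dz <- if (z > 1e-12) dz2 / (2 * z) else numeric(D)
  }
  res
}

#' Evaluate the path collective variable (s, z)
#'
#' `s` is progress along the path in [0, 1]; `z` is the metric distance
#' from the path. Points metrically beyond the first/last node saturate
#' at s = 0 / s = 1 exactly.
#'
#' @param x CV vector (continuous scale for periodic components).
#' @param path A [Path-class].
#' @param metric Optional metric tensor overriding the path's frozen
#'   per-segment metrics (useful for identity-metric evaluation).
#' @return List with elements `s`, `z`, `segment` (nearest segment index)
#'   and `t` (clamped progress on that segment).
#' @export
evaluatePathCV <- function(x, path, metric = NULL) {
  evalPathCVCore(x, path, metric, wantGrad = FALSE)
}

#' Analytic gradients of the path collective variable
#'
#' @inheritParams evaluatePathCV
#' @return List with `s`, `z`, `ds` and `dz`: the values and their
#'   gradients with respect to the CV components. Composed with
#'   [cvJacobian()] through the chain rule these give Cartesian bias
#'   forces.
#' @export
pathCVGradient <- function(x, path, metric = NULL) {
  evalPathCVCore(x, path, metric, wantGrad = TRUE)
}

## Vectorized evaluation over the rows of X (no gradients); used by the
## brute-force oracles and reporting code.
pathCVBatch <- function(X, path, metric = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); D <- ncol(X)
  Ginvs <- segmentGinvs(path, metric)
  nodes <- path@nodes
  nSeg <- nrow(nodes) - 1
  periodic <- path@periodic
  lambda <- path@lambda
  Tm <- matrix(0, n, nSeg); TRawm <- matrix(0, n, nSeg); D2m <- matrix(0, n, nSeg)
  for (i in seq_len(nSeg)) {
    G <- Ginvs[[i]]
    v <- as.numeric(nodes[i + 1, ] - nodes[i, ])
    delta <- sweep(X, 2, as.numeric(nodes[i, ]))
    if (any(periodic)) delta[, periodic] <- wrapAngle(delta[, periodic])
    cc <- sum(v * (G %*% v))
    Gv <- as.numeric(G %*% v)
    tRaw <- if (cc > 0) as.numeric(delta %*% Gv) / cc else rep(0, n)
    t <- pmin(pmax(tRaw, 0), 1)
    r <- delta - outer(t, v)
    D2 <- rowSums((r %*% G) * r)
    Tm[, i] <- t; TRawm[, i] <- tRaw; D2m[, i] <- pmax(D2, 0)
  }
  mIdx <- max.col(-D2m, ties.method = "first")
  Dmin2 <- pmax(D2m[cbind(seq_len(n), mIdx)], 1e-300)
  A <- exp(-lambda * (D2m / Dmin2 - 1))
  W <- A / rowSums(A)
  sigma <- sweep(Tm, 2, seq_len(nSeg) - 1, "+") / nSeg
  s <- rowSums(W * sigma)
  z <- sqrt(pmax(rowSums(W * D2m), 0))
  satLo <- mIdx == 1L & TRawm[, 1] <= 0
  satHi <- mIdx == nSeg & TRawm[, nSeg] >= 1
  s[satLo] <- 0; s[satHi] <- 1
  if (any(satLo | satHi)) { # z to the terminal node for saturated points
    for (idx in which(satLo | satHi)) {
      G <- if (satLo[idx]) Ginvs[[1]] else Ginvs[[nSeg]]
      node <- if (satLo[idx]) nodes[1, ] else nodes[nSeg + 1, ]
      delta <- maskedDiff(X[idx, ], as.numeric(node), periodic)
      z[idx] <- sqrt(max(sum(delta * (G %*% delta)), 0))
    }
  }
  cbind(s = s, z = z)
}
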