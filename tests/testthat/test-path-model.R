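test_that("projectTrajectory preserves order and matches per-frame CVs", {
  frame <- singleAtomFrame()
  base <- randomAnchorConfig(21)
  traj <- list(base, base, base)
  cvs <- projectTrajectory(traj, frame)
  expect_equal(cvs[1, ], cvs[2, ])
  expect_equal(cvs[2, ], cvs[3, ])

  # guest translated along the P1 -> L1 axis: d grows by exactly 1 A/frame
  u <- (base[4, ] - base[1, ]) / sqrt(sum((base[4, ] - base[1, ])^2))
  traj2 <- lapply(0:4, function(k) {
    x <- base
    x[4:6, ] <- x[4:6, ] + matrix(k * u, 3, 3, byrow = TRUE)
    x
  })
  cvs2 <- projectTrajectory(traj2, frame)
  expect_equal(diff(cvs2[, "d"]), rep(1, 4), tolerance = 1e-9)
  expect_equal(apply(cvs2[, 2:6], 2, function(x) max(abs(diff(x)))),
               setNames(rep(0, 5), colnames(cvs2)[2:6]), tolerance = 1e-9)

  # frame-by-frame oracle: wrapped values equal independent computeCVs calls
  wrapped <- attr(cvs2, "wrapped")
  for (i in seq_along(traj2))
    expect_equal(wrapped[i, ], setNames(as.numeric(computeCVs(traj2[[i]], frame)),
                                        colnames(wrapped)), tolerance = 1e-12)
})

test_that("projectTrajectory unwraps dihedral series across the branch cut", {
  # rotate L2 about the P1-L1 axis so phiB sweeps continuously through pi
  P <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 2, 0))
  nF <- 40
  traj <- lapply(seq_len(nF), function(i) {
    alpha <- 2.5 + 0.25 * (i - 1) # crosses pi and -pi
    L1 <- c(0, 0, 4)
    L2 <- L1 + c(cos(alpha), sin(alpha), 0.2)
    L3 <- L1 + c(0.3, 0.1, 1.2)
    rbind(P, L1, L2, L3)
  })
  cvs <- projectTrajectory(traj, singleAtomFrame())
  expect_lt(max(abs(diff(cvs[, "phiB"]))), pi)       # continuous series
  expect_gt(max(cvs[, "phiB"]) - min(cvs[, "phiB"]), 2 * pi) # really unwrapped
  w <- attr(cvs, "wrapped")
  expect_true(all(w[, "phiB"] > -pi & w[, "phiB"] <= pi + 1e-12))
})

test_that("projectTrajectory names the frame of a degenerate snapshot", {
  good <- randomAnchorConfig(2)
  bad <- good
  bad[3, ] <- bad[1, ] + 2 * (bad[2, ] - bad[1, ]) # P1,P2,P3 collinear
  expect_error(projectTrajectory(list(good, bad), singleAtomFrame()), "frame 2")
})

test_that("buildPath resamples a straight line to evenly spaced nodes", {
  a <- c(3, 1.2, 1.4, 0.1, -0.2, 0.3)
  b <- c(8, 1.0, 1.8, 0.5, 0.4, -0.1)
  path <- buildPath(lineSeries(a, b, 100), nNodes = 11)
  nodes <- pathNodes(path)
  for (i in 0:10)
    expect_equal(unname(nodes[i + 1, ]), a + (i / 10) * (b - a), tolerance = 1e-6)
  gaps <- diff(pathArcLengths(path))
  expect_lt(max(abs(gaps - mean(gaps))) / mean(gaps), 0.01)
})

test_that("backtracking filter yields a monotone path from a retracing series", {
  a <- rep(0, 6); b <- c(1, 0, 0, 0, 0, 0)
  fwd <- lineSeries(a, b, 60)
  back <- lineSeries(b, a + 0.5 * (b - a), 30)
  series <- rbind(fwd, back[-1, ])
  path <- buildPath(series, nNodes = 8, smooth = FALSE)
  kept <- path@provenance$keptFrames
  sKept <- vapply(kept, function(i) evaluatePathCV(series[i, ], path)$s, 0)
  expect_true(all(diff(sKept) >= -1e-6))
  # the path ends at the farthest point, not at the retraced series end
  expect_gt(pathNodes(path)[nPathNodes(path), 1], 0.9)
})

test_that("smoothing suppresses Gaussian jitter on a straight series", {
  a <- c(3, 1.2, 1.4, 0.1, -0.2, 0.3)
  b <- c(9, 1.1, 1.7, 0.6, 0.5, -0.2)
  sigma <- 0.02
  set.seed(42)
  series <- lineSeries(a, b, 120) + matrix(rnorm(120 * 6, sd = sigma), 120, 6)
  series[1, ] <- a; series[120, ] <- b
  path <- buildPath(series, nNodes = 10)
  u <- (b - a) / sqrt(sum((b - a)^2))
  for (i in seq_len(10)) {
    w <- pathNodes(path)[i, ] - a
    perp <- w - sum(w * u) * u
    expect_lt(sqrt(sum(perp^2)), 3 * sigma)
  }
})

test_that("buildPath rejects degenerate series", {
  series <- matrix(rep(c(1, 1, 1, 0, 0, 0), 5), 5, 6, byrow = TRUE)
  expect_error(buildPath(series, nNodes = 5), "degenerate")
})

test_that("reparameterization is idempotent on uniform paths", {
  a <- rep(0, 6); b <- c(2, 1, 0, 0, 0, 0)
  path <- buildPath(lineSeries(a, b, 50), nNodes = 9)
  path2 <- reparameterizePath(path)
  expect_lt(max(abs(pathNodes(path2) - pathNodes(path))), 1e-10)
})

test_that("reparameterization centers the middle of 3 collinear nodes", {
  nodes <- rbind(rep(0, 6), c(0.9, rep(0, 5)), c(1, rep(0, 5)))
  path <- pathFE:::newPathFromNodes(nodes, rep(list(diag(6)), 3), 4.6, rep(FALSE, 6))
  path2 <- reparameterizePath(path)
  expect_equal(unname(pathNodes(path2)[2, 1]), 0.5, tolerance = 1e-12)
})

test_that("reparameterized nodes sit at equal fractions of the parent polyline", {
  nodes <- smoothCurveNodes(20, seed = 7)
  path <- pathFE:::newPathFromNodes(nodes, rep(list(diag(6)), 20), 4.6, rep(FALSE, 6))
  path2 <- reparameterizePath(path)
  # dense piecewise-linear integration oracle along the OLD polyline
  seg <- sqrt(rowSums((nodes[-1, ] - nodes[-20, ])^2))
  cum <- c(0, cumsum(seg))
  arcOf <- function(x) { # arc-length position of a point on the old polyline
    for (i in 1:19) {
      v <- nodes[i + 1, ] - nodes[i, ]
      t <- sum((x - nodes[i, ]) * v) / sum(v * v)
      if (t > -1e-9 && t < 1 + 1e-9) {
        p <- nodes[i, ] + min(max(t, 0), 1) * v
        if (sqrt(sum((x - p)^2)) < 1e-9) return(cum[i] + min(max(t, 0), 1) * seg[i])
      }
    }
    NA_real_
  }
  arcs <- apply(pathNodes(path2), 1, arcOf)
  expect_equal(arcs, seq(0, cum[20], length.out = 20), tolerance = 1e-9)
  # total length along the parent curve preserved; chord gaps near-uniform
  expect_equal(arcs[20], cum[20], tolerance = 1e-9)
  gaps <- diff(pathArcLengths(path2))
  expect_lt(max(abs(gaps - mean(gaps))) / mean(gaps), 0.01)
})

test_that("pathCV is exact at nodes and segment midpoints", {
  nodes <- smoothCurveNodes(12, seed = 3)
  path <- pathFE:::newPathFromNodes(nodes, rep(list(diag(6)), 12), 4.6, rep(FALSE, 6))
  for (i in seq_len(12)) {
    e <- evaluatePathCV(nodes[i, ], path)
    expect_equal(e$s, (i - 1) / 11, tolerance = 1e-6)
    expect_lt(e$z, 1e-6)
  }
  for (i in c(2, 6, 10)) {
    mid <- (nodes[i, ] + nodes[i + 1, ]) / 2
    e <- evaluatePathCV(mid, path)
    expect_equal(e$s, (i - 1 + 0.5) / 11, tolerance = 1e-3)
  }
})

test_that("off-path z matches the dense-discretization brute-force oracle", {
  path0 <- pathFE:::newPathFromNodes(smoothCurveNodes(12, seed = 9),
                                     rep(list(diag(6)), 12), 4.6, rep(FALSE, 6))
  path <- reparameterizePath(path0) # uniform spacing
  nodes <- pathNodes(path)
  spacing <- mean(diff(pathArcLengths(path)))
  set.seed(17)
  for (rep in 1:20) {
    # generic off-path points: segment interior, z a fraction of the spacing
    i <- sample(2:10, 1)
    v <- nodes[i + 1, ] - nodes[i, ]
    off <- rnorm(6); off <- off - sum(off * v) / sum(v * v) * v
    x <- nodes[i, ] + runif(1, 0.3, 0.7) * v +
      0.2 * spacing * off / sqrt(sum(off^2))
    e <- evaluatePathCV(x, path)
    zOracle <- denseDistOracle(x, nodes, diag(6))
    expect_equal(e$z, zOracle, tolerance = 1e-3)
  }
})

test_that("identity-metric pathCV equals plain Euclidean projection", {
  path0 <- pathFE:::newPathFromNodes(smoothCurveNodes(10, seed = 5),
                                     rep(list(diag(6)), 10), 4.6, rep(FALSE, 6))
  path <- reparameterizePath(path0)
  nodes <- pathNodes(path)
  spacing <- mean(diff(pathArcLengths(path)))
  set.seed(8)
  for (rep in 1:15) {
    i <- sample(2:8, 1)
    v <- nodes[i + 1, ] - nodes[i, ]
    off <- rnorm(6); off <- off - sum(off * v) / sum(v * v) * v
    x <- nodes[i, ] + runif(1, 0.3, 0.7) * v +
      0.15 * spacing * off / sqrt(sum(off^2))
    e <- evaluatePathCV(x, path)
    o <- euclidProjectOracle(x, nodes)
    expect_equal(e$s, unname(o["s"]), tolerance = 1e-3)
    expect_equal(e$z, unname(o["z"]), tolerance = 1e-3)
  }
})

test_that("s saturates exactly beyond the endpoints", {
  nodes <- lineSeries(rep(0, 6), c(3, 0, 0, 0, 0, 0), 7)
  path <- pathFE:::newPathFromNodes(nodes, rep(list(diag(6)), 7), 4.6, rep(FALSE, 6))
  before <- c(-0.8, 0.1, 0, 0, 0, 0)
  beyond <- c(4.2, -0.1, 0, 0, 0, 0)
  expect_identical(evaluatePathCV(before, path)$s, 0)
  expect_identical(evaluatePathCV(beyond, path)$s, 1)
  expect_equal(evaluatePathCV(before, path)$z, sqrt(0.8^2 + 0.1^2), tolerance = 1e-9)
})

test_that("s is monotone along the generating series and moves smoothly", {
  a <- c(3, 1.2, 1.4, 0.1, -0.2, 0.3)
  b <- c(8, 1.0, 1.8, 0.5, 0.4, -0.1)
  set.seed(31)
  series <- lineSeries(a, b, 80) + matrix(rnorm(480, sd = 0.005), 80, 6)
  series[1, ] <- a; series[80, ] <- b
  path <- buildPath(series, nNodes = 11)
  kept <- path@provenance$keptFrames
  sSeq <- vapply(kept, function(i) evaluatePathCV(series[i, ], path)$s, 0)
  expect_true(all(diff(sSeq) >= -1e-6))

  # smoothness: crossing curve with steps <= half the node spacing
  nodes <- pathNodes(path)
  spacing <- mean(diff(pathArcLengths(path)))
  from <- nodes[5, ] - c(0, 0.4, 0, 0, 0, 0)
  to <- nodes[7, ] + c(0, 0.4, 0, 0, 0, 0)
  nStep <- ceiling(2 * sqrt(sum((to - from)^2)) / spacing) + 1
  prev <- NULL
  for (f in seq(0, 1, length.out = nStep)) {
    s <- evaluatePathCV(from + f * (to - from), path)$s
    if (!is.null(prev)) expect_lt(abs(s - prev), 1 / (nPathNodes(path) - 1) + 1e-9)
    prev <- s
  }
})

test_that("pathCV gradients match finite differences", {
  nodes <- smoothCurveNodes(12, seed = 13)
  path <- pathFE:::newPathFromNodes(nodes, rep(list(diag(6)), 12), 4.6, rep(FALSE, 6))
  set.seed(19)
  worstS <- 0; worstZ <- 0
  for (rep in 1:20) {
    i <- sample(2:10, 1)
    x <- nodes[i, ] + rnorm(6, sd = 0.04) + 0.02
    g <- pathCVGradient(x, path)
    fd <- fdPathGrad(x, path)
    worstS <- max(worstS, max(abs(g$ds - fd$ds)) / max(abs(fd$ds), 1e-8))
    worstZ <- max(worstZ, max(abs(g$dz - fd$dz)) / max(abs(fd$dz), 1e-8))
  }
  expect_lt(worstS, 1e-5)
  expect_lt(worstZ, 1e-5)
})

test_that("straight-line ds/dcv is the path direction over the total length", {
  a <- rep(0, 6); b <- c(4, 3, 0, 0, 0, 0)
  nodes <- lineSeries(a, b, 9)
  path <- pathFE:::newPathFromNodes(nodes, rep(list(diag(6)), 9), 4.6, rep(FALSE, 6))
  L <- sqrt(sum((b - a)^2))
  expect_ds <- (b - a) / L / L
  for (f in c(0.21, 0.47, 0.68)) { # interior points just off the line
    x <- a + f * (b - a) + c(0, 0, 0.01, -0.01, 0, 0)
    g <- pathCVGradient(x, path)
    expect_equal(g$ds, expect_ds, tolerance = 1e-6)
  }
})

test_that("dz is metric-orthogonal to the path tangent near the path", {
  nodes <- smoothCurveNodes(12, seed = 23)
  path <- pathFE:::newPathFromNodes(nodes, rep(list(diag(6)), 12), 4.6, rep(FALSE, 6))
  i <- 6
  v <- nodes[i + 1, ] - nodes[i, ]
  # small offset orthogonal to the segment keeps the point near the path
  set.seed(3)
  off <- rnorm(6); off <- off - sum(off * v) / sum(v * v) * v
  x <- nodes[i, ] + 0.4 * v + 1e-4 * off / sqrt(sum(off^2))
  g <- pathCVGradient(x, path)
  cosang <- sum(g$dz * v) / sqrt(sum(g$dz^2) * sum(v^2))
  expect_lt(abs(cosang), 1e-6)
})
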