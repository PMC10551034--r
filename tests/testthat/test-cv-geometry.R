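test_that("anchor centers are unweighted geometric means", {
  coords <- rbind(c(0, 0, 0), c(2, 0, 0), c(1.5, -2, 3))
  expect_equal(anchorCenter(coords, anchorGroup(0:1)), c(1, 0, 0))
  expect_equal(anchorCenter(coords, anchorGroup(2)), c(1.5, -2, 3))

  set.seed(11)
  pts <- matrix(rnorm(15), 5, 3)
  # loop-based elementwise mean oracle
  m <- c(0, 0, 0)
  for (i in 1:5) m <- m + pts[i, ]
  expect_equal(anchorCenter(pts, anchorGroup(0:4)), m / 5, tolerance = 1e-12)

  expect_error(anchorCenter(pts, anchorGroup(c(0, 7))), "invalid selection")
})

test_that("anchor group validity and triangle checks work", {
  expect_error(anchorGroup(integer(0)), "non-empty")
  expect_error(anchorGroup(c(1, 1)), "unique")
  expect_error(anchorGroup(-1), "0-based")

  # collinear protein anchors must be rejected on the reference snapshot
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                  c(0, 0, 3), c(1, 1, 3), c(0, 1, 3))
  expect_error(
    anchorFrame(list(anchorGroup(0), anchorGroup(1), anchorGroup(2)),
                list(anchorGroup(3), anchorGroup(4), anchorGroup(5)),
                reference = coords),
    "collinear")

  # elongated triangle warns about equilateral-ness
  coords2 <- rbind(c(0, 0, 0), c(3, 0, 0), c(1.5, 0.95, 0),
                   c(0, 0, 3), c(1, 0, 3), c(0.5, 0.9, 3))
  expect_warning(
    anchorFrame(list(anchorGroup(0), anchorGroup(1), anchorGroup(2)),
                list(anchorGroup(3), anchorGroup(4), anchorGroup(5)),
                reference = coords2),
    "equilateral")
})

test_that("computeCVs reproduces simple constructions", {
  # right-angle construction: d = 2, thetaA = thetaB = pi/2, phiA = 0 (cis)
  coords <- rbind(c(0, 0, 0),   # P1
                  c(1, 0, 0),   # P2
                  c(1, 0, 1),   # P3
                  c(0, 0, 2),   # L1
                  c(0, 1, 2),   # L2
                  c(1, 1, 2))   # L3
  cv <- computeCVs(coords, singleAtomFrame())
  expect_equal(unname(cv["d"]), 2)
  expect_equal(unname(cv["thetaA"]), pi / 2)
  expect_equal(unname(cv["thetaB"]), pi / 2)
  expect_equal(unname(cv["phiA"]), 0)
})

test_that("computeCVs matches an independent geometry oracle", {
  for (seed in c(1, 7, 23, 91)) {
    pts <- randomAnchorConfig(seed)
    cv <- computeCVs(pts, singleAtomFrame())
    expect_equal(as.numeric(cv), as.numeric(oracleCVs(pts)), tolerance = 1e-10,
                 label = sprintf("seed %d", seed))
  }
})

test_that("degenerate dihedral geometry raises a named error", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 1e-9),
                  c(0, 0, 3), c(1, 0.5, 3), c(0, 1, 3.5))
  # P3, P2, P1 nearly collinear -> phiA degenerate
  expect_error(computeCVs(coords, singleAtomFrame()), "phiA")
})

test_that("CVs are invariant under rigid rotation + translation", {
  frame <- singleAtomFrame()
  for (seed in 1:12) {
    pts <- randomAnchorConfig(seed)
    cv0 <- computeCVs(pts, frame)
    R <- randomRotation(seed + 100)
    set.seed(seed + 200)
    tr <- rnorm(3, sd = 5)
    pts2 <- pts %*% t(R) + matrix(tr, 6, 3, byrow = TRUE)
    cv1 <- computeCVs(pts2, frame)
    dcv <- maskedDiffTest(cv1, cv0, unname(cvPeriodicMask()))
    expect_lt(max(abs(dcv)), 1e-9)
  }
})

test_that("multi-atom groups equal pseudo-atoms at the group centers", {
  set.seed(5)
  centers <- randomAnchorConfig(5)
  # expand each anchor into a 3-atom cloud with the prescribed center
  cloud <- NULL
  groups <- list()
  for (i in 1:6) {
    offs <- matrix(rnorm(9, sd = 0.3), 3, 3)
    offs <- sweep(offs, 2, colMeans(offs)) # zero-mean offsets
    cloud <- rbind(cloud, sweep(offs, 2, centers[i, ], "+"))
    groups[[i]] <- anchorGroup((3 * (i - 1)):(3 * i - 1))
  }
  multi <- anchorFrame(groups[1:3], groups[4:6])
  cvMulti <- computeCVs(cloud, multi)
  cvSingle <- computeCVs(centers, singleAtomFrame())
  expect_equal(unname(cvMulti), unname(cvSingle), tolerance = 1e-10)
})

test_that("analytic Jacobian matches central finite differences", {
  frame <- singleAtomFrame()
  seeds <- 1:50
  worst <- 0
  for (seed in seeds) {
    pts <- randomAnchorConfig(seed)
    J <- cvJacobian(pts, frame)
    Jfd <- fdJacobian(pts, frame)
    scale <- pmax(abs(Jfd), 1e-4) # relative error with a floor on tiny entries
    worst <- max(worst, max(abs(J - Jfd) / scale))
  }
  expect_lt(worst, 1e-6)
})

test_that("distance row of the Jacobian is the unit inter-anchor vector", {
  pts <- randomAnchorConfig(3)
  J <- cvJacobian(pts, singleAtomFrame())
  u <- (pts[4, ] - pts[1, ]) / sqrt(sum((pts[4, ] - pts[1, ])^2))
  expect_equal(unname(J[1, 10:12]), u, tolerance = 1e-12)   # dd/dL1
  expect_equal(unname(J[1, 1:3]), -u, tolerance = 1e-12)    # dd/dP1
})

test_that("global translations lie in the Jacobian null space", {
  for (seed in c(2, 9, 40)) {
    pts <- randomAnchorConfig(seed)
    J <- cvJacobian(pts, singleAtomFrame())
    for (k in 1:3) {
      tdir <- rep(0, 18); tdir[seq(k, 18, by = 3)] <- 1
      expect_lt(max(abs(J %*% tdir)), 1e-10)
    }
  }
})

test_that("Jacobian of multi-atom groups spreads 1/|group| per member", {
  set.seed(6)
  centers <- randomAnchorConfig(6)
  cloud <- NULL
  groups <- list()
  for (i in 1:6) {
    offs <- matrix(rnorm(6, sd = 0.2), 2, 3)
    offs <- sweep(offs, 2, colMeans(offs))
    cloud <- rbind(cloud, sweep(offs, 2, centers[i, ], "+"))
    groups[[i]] <- anchorGroup((2 * (i - 1)):(2 * i - 1))
  }
  frame <- anchorFrame(groups[1:3], groups[4:6])
  J <- cvJacobian(cloud, frame)
  Jfd <- fdJacobian(cloud, frame)
  expect_lt(max(abs(J - Jfd) / pmax(abs(Jfd), 1e-4)), 1e-6)
  # both atoms of a group share the same derivative block
  expect_equal(J[, 1:3], J[, 4:6], tolerance = 1e-12)
})

test_that("metric is J W J^T: hand-built check on a symmetric configuration", {
  # P1 and L1 far apart on the x axis, single-atom anchors; only d couples
  # to x motion of P1 and L1, with unit weights M[d,d] = 2.
  pts <- rbind(c(0, 0, 0), c(0, 2, 0), c(0, 2, 2),
               c(10, 0, 0), c(10, 2, 0), c(10, 2, 2))
  M <- cvMetric(pts, singleAtomFrame())
  J <- cvJacobian(pts, singleAtomFrame())
  expect_equal(M, (J %*% t(J) + t(J %*% t(J))) / 2, tolerance = 1e-12)
  expect_equal(unname(M["d", "d"]), 2, tolerance = 1e-12)
  # hand-derived couplings: grad_thetaA at P1 = (0.5, 0.2, 0) against
  # grad_d at P1 = (-1, 0, 0) gives -0.5; likewise for thetaB at L1
  expect_equal(unname(M["d", "thetaA"]), -0.5, tolerance = 1e-10)
  expect_equal(unname(M["d", "thetaB"]), -0.5, tolerance = 1e-10)
  # d decouples from the out-of-plane dihedral phiA by mirror symmetry
  expect_lt(abs(M["d", "phiA"]), 1e-10)
})

test_that("metric is symmetric PSD and linear in the weights", {
  frame <- singleAtomFrame()
  for (seed in 1:100) {
    pts <- randomAnchorConfig(seed)
    M <- cvMetric(pts, frame)
    expect_lt(max(abs(M - t(M))), 1e-10)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10 * max(ev))
  }
  pts <- randomAnchorConfig(17)
  M1 <- cvMetric(pts, frame, weights = rep(1, 6))
  M2 <- cvMetric(pts, frame, weights = rep(2, 6))
  expect_equal(M2, 2 * M1, tolerance = 1e-12)
  expect_error(cvMetric(pts, frame, weights = rep(-1, 6)), "invalid parameter")
})

test_that("cvDifference wraps dihedrals into (-pi, pi]", {
  a <- cvVector(1, 1, 1, 3.0, 0, 0)
  b <- cvVector(1, 1, 1, -3.0, 0, 0)
  d <- cvDifference(a, b)
  expect_equal(d[4], 3.0 - (-3.0) - 2 * pi, tolerance = 1e-12)
  expect_equal(cvDifference(a, a), rep(0, 6))

  set.seed(99)
  for (i in 1:1000) {
    x <- cvVector(runif(1, 0.5, 9), runif(1, 0.1, 3), runif(1, 0.1, 3),
                  runif(1, -pi, pi), runif(1, -pi, pi), runif(1, -pi, pi))
    y <- cvVector(runif(1, 0.5, 9), runif(1, 0.1, 3), runif(1, 0.1, 3),
                  runif(1, -pi, pi), runif(1, -pi, pi), runif(1, -pi, pi))
    d <- cvDifference(x, y)
    expect_true(all(abs(d[4:6]) <= pi + 1e-12))
    expect_equal(d, -cvDifference(y, x), tolerance = 1e-12)
  }
})
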