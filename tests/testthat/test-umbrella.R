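# A 1-D "path" spanning [0, 1] with identity metric: s is effectively the
# coordinate itself, which makes biased-sampling statistics analytic.
unitLinePath <- function() {
  pathFE:::newPathFromNodes(matrix(c(0, 1), 2, 1),
                            rep(list(matrix(1, 1, 1)), 2), 4.6, FALSE)
}

flatProvider <- function() {
  forceProvider(function(x) 0, function(x) 0 * x, 1L, checkAt = 0.5)
}

test_that("window centers are evenly spaced on [0, 1] with derived seeds", {
  path <- unitLinePath()
  w56 <- buildWindows(path, 56, productionSteps = 10)
  expect_length(w56, 56)
  centers <- vapply(w56, function(w) w@sCenter, 0)
  expect_equal(centers, seq(0, 1, length.out = 56), tolerance = 1e-12)
  expect_equal(diff(centers), rep(1 / 55, 55), tolerance = 1e-12)

  w2 <- buildWindows(path, 2, productionSteps = 10)
  expect_equal(vapply(w2, function(w) w@sCenter, 0), c(0, 1))
  w5 <- buildWindows(path, 5, productionSteps = 10)
  expect_equal(diff(vapply(w5, function(w) w@sCenter, 0)), rep(0.25, 4))

  expect_error(buildWindows(path, 1), "invalid parameter")

  seeds <- vapply(w56, function(w) w@seed, 0L)
  expect_false(anyDuplicated(seeds) > 0)
  # derived seeds are deterministic
  expect_identical(seeds, vapply(buildWindows(path, 56, productionSteps = 10),
                                 function(w) w@seed, 0L))
})

test_that("default kS makes window width match the spacing", {
  path <- unitLinePath()
  w <- buildWindows(path, 11, productionSteps = 10)
  spacing <- 0.1
  expect_equal(w[[1]]@kS, kT(300) / spacing^2, tolerance = 1e-12)
})

test_that("initial structures are the closest snapshots in s", {
  path <- unitLinePath()
  sVals <- seq(0, 1, length.out = 100)
  cvSeries <- matrix(sVals, ncol = 1)
  wins <- buildWindows(path, 5, productionSteps = 10)
  wins <- assignInitialStructures(wins, cvSeries, path)
  frames <- vapply(wins, function(w) w@initFrame, 0L)
  expect_equal(frames[1], 1L)          # center 0 -> first frame
  expect_equal(frames[5], 100L)        # center 1 -> last frame
  expect_equal(frames[3], which.min(abs(sVals - 0.5)))

  # tie-break: two frames equally close -> lower index
  cvTie <- matrix(c(0.4, 0.6, 0.4, 0.6), ncol = 1)
  winMid <- assignInitialStructures(wins[3], cvTie, path)
  expect_equal(winMid[[1]]@initFrame, 1L)
})

test_that("bias energy, ramp, and derivatives are consistent", {
  path <- unitLinePath()
  w <- buildWindows(path, 5, kS = 200, kZ = 0, rampSteps = 100,
                    productionSteps = 10)[[3]] # center 0.5
  b <- biasEnergyForce(0.5, 0, w)
  expect_equal(b$energy, 0); expect_equal(b$dEds, 0); expect_equal(b$dEdz, 0)
  expect_equal(biasEnergyForce(0.6, 0, w)$energy, 1.0) # 1/2*200*0.01

  expect_equal(rampFactor(0, 100), 0)
  expect_equal(rampFactor(100, 100), 1)
  expect_equal(rampFactor(50, 100), 0.5)
  expect_equal(rampFactor(5, 0), 1)

  # derivative check against finite differences (kZ > 0 too)
  w2 <- buildWindows(path, 5, kS = 120, kZ = 30, productionSteps = 10)[[2]]
  h <- 1e-6
  for (pt in list(c(0.3, 0.2), c(0.7, 0.05))) {
    b <- biasEnergyForce(pt[1], pt[2], w2)
    fdS <- (biasEnergyForce(pt[1] + h, pt[2], w2)$energy -
              biasEnergyForce(pt[1] - h, pt[2], w2)$energy) / (2 * h)
    fdZ <- (biasEnergyForce(pt[1], pt[2] + h, w2)$energy -
              biasEnergyForce(pt[1], pt[2] - h, w2)$energy) / (2 * h)
    expect_equal(b$dEds, fdS, tolerance = 1e-6)
    expect_equal(b$dEdz, fdZ, tolerance = 1e-6)
  }
})

test_that("biased sampling of a flat potential has variance kT/kS", {
  path <- unitLinePath()
  kS <- 100; kTval <- 0.59616
  w <- buildWindows(path, 3, kS = kS, kZ = 0, rampSteps = 200,
                    productionSteps = 20000, masterSeed = 11)[[2]]
  ss <- runWindow(flatProvider(), path, w, x0 = 0.5,
                  params = list(dt = 0.05, gamma = 1, kT = kTval, stride = 5))
  s <- sampleData(ss)$s
  v <- stats::var(s)
  # standard error of the variance from 10 block estimates
  blocks <- split(s, cut(seq_along(s), 10, labels = FALSE))
  se <- stats::sd(vapply(blocks, stats::var, 0)) / sqrt(10)
  expect_lt(abs(v - kTval / kS), 3 * se)
  expect_equal(mean(s), 0.5, tolerance = 0.02)
})

test_that("biased variance on a quadratic surface is kT/(kS + curvature)", {
  path <- unitLinePath()
  kappa <- 80; kS <- 100; kTval <- 0.59616
  quad <- forceProvider(function(x) 0.5 * kappa * (x - 0.5)^2,
                        function(x) -kappa * (x - 0.5), 1L, checkAt = 0.4)
  w <- buildWindows(path, 3, kS = kS, kZ = 0, rampSteps = 200,
                    productionSteps = 20000, masterSeed = 5)[[2]]
  ss <- runWindow(quad, path, w, x0 = 0.5,
                  params = list(dt = 0.05, gamma = 1, kT = kTval, stride = 5))
  s <- sampleData(ss)$s
  blocks <- split(s, cut(seq_along(s), 10, labels = FALSE))
  se <- stats::sd(vapply(blocks, stats::var, 0)) / sqrt(10)
  expect_lt(abs(stats::var(s) - kTval / (kS + kappa)), 3 * se)
})

test_that("zero-temperature sampling relaxes monotonically to the bias center", {
  path <- unitLinePath()
  w <- buildWindows(path, 3, kS = 150, kZ = 0, rampSteps = 0,
                    productionSteps = 400, masterSeed = 2)[[2]]
  ss <- runWindow(flatProvider(), path, w, x0 = 0.15,
                  params = list(dt = 0.02, gamma = 25, kT = 0, stride = 1))
  e <- sampleData(ss)$bias
  expect_lt(max(diff(e)), 1e-10)   # overdamped descent: energy non-increasing
  expect_lt(abs(utils::tail(sampleData(ss)$s, 1) - 0.5), 1e-3)
})

test_that("identical seeds give bitwise-identical sample series", {
  path <- unitLinePath()
  w <- buildWindows(path, 3, kS = 100, rampSteps = 50,
                    productionSteps = 500, masterSeed = 42)[[2]]
  p <- list(dt = 0.05, gamma = 1, kT = 0.59616, stride = 5)
  s1 <- runWindow(flatProvider(), path, w, 0.5, p)
  s2 <- runWindow(flatProvider(), path, w, 0.5, p)
  expect_identical(sampleData(s1), sampleData(s2))
})

test_that("velocity-Verlet limit conserves energy on the double well", {
  toy <- makeDoubleWell1D(deltaE = 5)
  energies <- numeric(0)
  res <- langevinDynamics(toy@provider, x0 = 0.3, nSteps = 1e4, dt = 0.001,
                          gamma = 0, kT = 0, seed = 1,
                          record = function(step, x, v, bE)
                            toy@potential(x) + 0.5 * v^2,
                          stride = 10)
  e <- unlist(res$records)
  # seed the motion with initial potential energy only: drift, not scale
  expect_lt(max(e) - min(e), 1e-4)
})

test_that("pathCV bias forces are conservative (closed-loop work ~ 0)", {
  nodes <- lineSeries(c(0, 0, 0, 0, 0, 0), c(3, 1, 0, 0, 0, 0), 7)
  path <- pathFE:::newPathFromNodes(nodes, rep(list(diag(6)), 7), 4.6, rep(FALSE, 6))
  w <- buildWindows(path, 5, kS = 80, kZ = 25, productionSteps = 10)[[3]]
  biasForceAt <- function(x) {
    g <- pathCVGradient(x, path)
    b <- biasEnergyForce(g$s, g$z, w)
    -(b$dEds * g$ds + b$dEdz * g$dz)
  }
  # closed hexagonal loop around a point near the path, midpoint rule
  center <- nodes[4, ] + c(0.02, 0.05, 0.01, 0, 0, 0)
  radius <- 0.05
  nPts <- 2000
  ang <- seq(0, 2 * pi, length.out = nPts + 1)
  loop <- t(vapply(ang, function(a)
    center + radius * (cos(a) * c(1, 0, 0, 0, 0, 0) + sin(a) * c(0, 1, 0, 0, 0, 0)),
    numeric(6)))
  work <- 0
  for (i in seq_len(nPts)) {
    mid <- (loop[i, ] + loop[i + 1, ]) / 2
    work <- work + sum(biasForceAt(mid) * (loop[i + 1, ] - loop[i, ]))
  }
  expect_lt(abs(work), 1e-6)
})

test_that("campaigns are order-independent and resumable", {
  path <- unitLinePath()
  wins <- buildWindows(path, 3, kS = 100, rampSteps = 20,
                       productionSteps = 200, masterSeed = 9)
  wins <- assignInitialStructures(wins, matrix(seq(0, 1, length.out = 11), ncol = 1), path)
  prov <- flatProvider()
  p <- list(dt = 0.05, gamma = 1, kT = 0.59616, stride = 5)
  x0Fn <- function(w) c(w@sCenter)
  full <- runCampaign(prov, path, wins, x0Fn, p)
  rev1 <- runCampaign(prov, path, rev(wins), x0Fn, p)
  expect_identical(sampleData(full[[1]]), sampleData(rev1[[3]]))
  expect_identical(sampleData(full[[3]]), sampleData(rev1[[1]]))

  # resume: pre-run one window into outDir, then run the rest
  dir <- withr::local_tempdir()
  partial <- runCampaign(prov, path, wins[1], x0Fn, p, outDir = dir)
  expect_true(file.exists(file.path(dir, "window_001.csv")))
  resumed <- runCampaign(prov, path, wins, x0Fn, p, outDir = dir)
  for (i in 1:3)
    expect_equal(sampleData(resumed[[i]]), sampleData(full[[i]]), tolerance = 1e-12)
})

test_that("per-window failures do not abort sibling windows", {
  path <- unitLinePath()
  wins <- buildWindows(path, 2, kS = 100, productionSteps = 100, masterSeed = 3)
  bad <- forceProvider(function(x) 0, function(x) 0 * x, 1L, checkAt = 0.5)
  # a provider that blows up only for the second window's start
  bad@force <- function(x) if (abs(x - 1) < 0.2) NaN else 0 * x
  p <- list(dt = 0.05, gamma = 1, kT = 0.59616, stride = 5)
  res <- runCampaign(bad, path, wins, function(w) c(w@sCenter), p)
  expect_s4_class(res[[1]], "SampleSeries")
  expect_null(res[[2]])
  expect_match(attr(res, "errors")[["2"]], "blow-up")
})
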