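## Synthetic toy systems with analytic potentials and brute-force
## free-energy oracles. They stand in for a real receptor-ligand complex
## at desk scale: a 1-D double well, a four-Gaussian 2-D benchmark with
## multiple basins, and a Cartesian host-guest complex whose interaction
## is a function of the six anchor CVs, so its profile along a path has a
## quadrature oracle.

## ---- generic CV-space toy provider ----

cvToyProvider <- function(potential, gradient, dim, checkAt = NULL) {
  forceProvider(energy = potential,
                force = function(x) -gradient(x),
                nDof = dim, masses = 1,
                checkAt = checkAt %||% rep(0.3, dim))
}

#' 1-D double-well toy system
#'
#' V(x) = deltaE ((x/h)^2 - 1)^2 with h = separation/2: minima at +-h of
#' energy 0 and a barrier of height deltaE at x = 0. In one dimension the
#' free-energy profile equals the potential.
#'
#' @param deltaE Barrier height in kcal/mol (> 0).
#' @param separation Distance between the two minima (default 2).
#' @param kT Thermal-energy convention for sampling (default 0.59616).
#' @return A [ToySystem-class].
#' @export
makeDoubleWell1D <- function(deltaE = 5, separation = 2, kT = 0.59616) {
  stopifnot2(deltaE > 0, "deltaE must be > 0")
  h <- separation / 2
  pot <- function(x) deltaE * ((x[1] / h)^2 - 1)^2
  grad <- function(x) 4 * deltaE * x[1] * ((x[1] / h)^2 - 1) / h^2
  new("ToySystem", kind = "cv", dimension = 1L,
      potential = pot, gradient = grad,
      provider = cvToyProvider(pot, grad, 1L, checkAt = 0.4 * h),
      knownFeatures = list(minima = c(-h, h), saddle = 0, barrier = deltaE),
      kT = kT, extras = list(deltaE = deltaE, separation = separation))
}

## four-Gaussian benchmark surface parameters (standard published form)
.mbA <- c(-200, -100, -170, 15)
.mba <- c(-1, -1, -6.5, 0.7)
.mbb <- c(0, 0, 11, 0.6)
.mbc <- c(-10, -10, -6.5, 0.7)
.mbx0 <- c(1, 0, -0.5, -1)
.mby0 <- c(0, 0.5, 1.5, 1)

mbPotential <- function(x) {
  dx <- x[1] - .mbx0; dy <- x[2] - .mby0
  sum(.mbA * exp(.mba * dx^2 + .mbb * dx * dy + .mbc * dy^2))
}

mbGradient <- function(x) {
  dx <- x[1] - .mbx0; dy <- x[2] - .mby0
  e <- .mbA * exp(.mba * dx^2 + .mbb * dx * dy + .mbc * dy^2)
  c(sum(e * (2 * .mba * dx + .mbb * dy)),
    sum(e * (.mbb * dx + 2 * .mbc * dy)))
}

mbHessian <- function(x) {
  dx <- x[1] - .mbx0; dy <- x[2] - .mby0
  e <- .mbA * exp(.mba * dx^2 + .mbb * dx * dy + .mbc * dy^2)
  gx <- 2 * .mba * dx + .mbb * dy
  gy <- .mbb * dx + 2 * .mbc * dy
  h11 <- sum(e * (gx^2 + 2 * .mba))
  h22 <- sum(e * (gy^2 + 2 * .mbc))
  h12 <- sum(e * (gx * gy + .mbb))
  matrix(c(h11, h12, h12, h22), 2, 2)
}

#' 2-D multi-basin benchmark surface
#'
#' The classic four-Gaussian benchmark surface (three minima, two
#' saddles) used throughout the string-method literature. Its stationary
#' points are located at construction time by independent numerical
#' optimization (BFGS on V for minima, BFGS on |grad V|^2 with Hessian
#' classification for saddles) and stored in `knownFeatures`.
#'
#' @param kT Thermal-energy convention for sampling (default 10; the
#'   surface's wells are hundreds of energy units deep).
#' @return A [ToySystem-class].
#' @export
makeBenchmark2D <- function(kT = 10) {
  newtonPolish <- function(x, n = 8) {
    for (i in seq_len(n)) x <- x - solve(mbHessian(x), mbGradient(x))
    x
  }
  minima <- NULL
  for (start in list(c(0.6, 0), c(-0.55, 1.45), c(-0.1, 0.5))) {
    opt <- stats::optim(start, mbPotential, mbGradient, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    par <- newtonPolish(opt$par)
    minima <- rbind(minima, c(par, mbPotential(par)))
  }
  gnorm2 <- function(x) sum(mbGradient(x)^2)
  gnorm2Grad <- function(x) as.numeric(2 * mbHessian(x) %*% mbGradient(x))
  saddles <- NULL
  for (start in list(c(0.2, 0.3), c(-0.8, 0.6))) {
    opt <- stats::optim(start, gnorm2, gnorm2Grad, method = "BFGS",
                        control = list(reltol = 1e-16, maxit = 1000))
    par <- newtonPolish(opt$par)
    ev <- eigen(mbHessian(par), symmetric = TRUE, only.values = TRUE)$values
    if (gnorm2(par) < 1e-12 && sum(ev < 0) == 1)
      saddles <- rbind(saddles, c(par, mbPotential(par)))
  }
  colnames(minima) <- c("x", "y", "V")
  if (!is.null(saddles)) colnames(saddles) <- c("x", "y", "V")
  new("ToySystem", kind = "cv", dimension = 2L,
      potential = mbPotential, gradient = mbGradient,
      provider = cvToyProvider(mbPotential, mbGradient, 2L, checkAt = c(0.5, 0.2)),
      knownFeatures = list(minima = minima[order(minima[, "V"]), , drop = FALSE],
                           saddles = saddles,
                           hessian = mbHessian),
      kT = kT, extras = list())
}

## ---- host-guest Cartesian toy ----

## NeRF-style placement: the point D at distance r from C, angle theta at
## C in the triangle (B, C, D), and dihedral phi for (A, B, C, D) in the
## package's sign convention.
nerfPlace <- function(A, B, C, r, theta, phi) {
  e1 <- C - B; e1 <- e1 / vnorm(e1)
  p <- A - B
  pPerp <- p - sum(p * e1) * e1
  e2 <- pPerp / vnorm(pPerp)
  e3 <- cross3(e1, e2)
  C + r * (-cos(theta) * e1 + sin(theta) * (cos(phi) * e2 + sin(phi) * e3))
}

## rigid superposition (Kabsch) of template points onto target points
kabschTransform <- function(from, to) {
  cf <- colMeans(from); ct <- colMeans(to)
  H <- t(sweep(from, 2, cf)) %*% sweep(to, 2, ct)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, shift = ct - as.numeric(R %*% cf))
}

## hexagonal rigid guest template (6 atoms, xy-plane, circumradius rad)
guestTemplate <- function(rad = 1.4) {
  ang <- (0:5) * pi / 3
  atoms <- cbind(rad * cos(ang), rad * sin(ang), 0)
  centers <- rbind(colMeans(atoms[1:2, ]), colMeans(atoms[3:4, ]),
                   colMeans(atoms[5:6, ]))
  list(atoms = atoms, centers = centers,
       r12 = vnorm(centers[2, ] - centers[1, ]),
       r23 = vnorm(centers[3, ] - centers[2, ]),
       angle123 = angleBetween(centers[1, ], centers[2, ], centers[3, ]))
}

## Place the rigid guest so its anchor centers realize the given CVs
## relative to the host anchor points (rows P1, P2, P3).
placeGuestAtCV <- function(cv, hostPts, template) {
  cv <- as.numeric(cv)
  L1 <- nerfPlace(hostPts[3, ], hostPts[2, ], hostPts[1, ],
                  r = cv[1], theta = cv[2], phi = cv[4])
  L2 <- nerfPlace(hostPts[2, ], hostPts[1, ], L1,
                  r = template$r12, theta = cv[3], phi = cv[5])
  L3 <- nerfPlace(hostPts[1, ], L1, L2,
                  r = template$r23, theta = template$angle123, phi = cv[6])
  tr <- kabschTransform(template$centers, rbind(L1, L2, L3))
  sweep(template$atoms %*% t(tr$R), 2, tr$shift, "+")
}

#' Cartesian host-guest toy system
#'
#' A rigid triangular host (three frozen anchor atoms, equilateral, side
#' 2 A) binds a rigid hexagonal six-atom guest (stiff harmonic bond
#' network). The interaction is a function of the six anchor CVs:
#' a Morse well in d (depth `De`, minimum `d0`, width `aMorse`) plus a
#' Gaussian exit bump in d, and harmonic terms in thetaA and phiB, so
#' the system has a bound basin, an exit barrier, and
#' orientation-dependent energetics that make all six CVs meaningful.
#' Because the interaction is separable in the CVs and the guest is
#' rigid, the free-energy profile along any path has a brute-force
#' Boltzmann-integration oracle ([bruteForceProfile()]).
#'
#' @param De Morse depth, kcal/mol.
#' @param d0 Morse minimum, Angstrom.
#' @param aMorse Morse width parameter, 1/Angstrom.
#' @param kTheta,kPhi Angular force constants, kcal/mol/rad^2.
#' @param bumpHeight,bumpCenter,bumpWidth Gaussian exit-barrier term in d.
#' @param kBond Guest bond-network force constant, kcal/mol/A^2.
#' @param thetaA0,phiB0 Preferred approach angle and orientation.
#' @param kT Thermal energy, kcal/mol (default 0.59616, i.e. 300 K).
#' @param restrainHost Keep the host atoms mobile under harmonic
#'   positional restraints (10 kcal/mol/A^2) instead of frozen.
#' @return A [ToySystem-class]; `extras` carries the [AnchorFrame-class]
#'   (`anchors`), the guest template, the CV-space interaction
#'   (`cvPotential`, `cvPotentialGrad`) and `initFn(cv)` returning flat
#'   coordinates with the guest placed at a CV vector.
#' @export
makeHostGuestToy <- function(De = 8, d0 = 3, aMorse = 1.5, kTheta = 5,
                             kPhi = 5, bumpHeight = 3, bumpCenter = 5,
                             bumpWidth = 0.4, kBond = 300, thetaA0 = pi / 2,
                             phiB0 = 0, kT = 0.59616, restrainHost = FALSE) {
  hostPts <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0))
  template <- guestTemplate()
  anchors <- anchorFrame(
    protein = list(anchorGroup(0, "P1"), anchorGroup(1, "P2"), anchorGroup(2, "P3")),
    ligand = list(anchorGroup(c(3, 4), "L1"), anchorGroup(c(5, 6), "L2"),
                  anchorGroup(c(7, 8), "L3")))
  nAtoms <- 9L

  ## CV-space interaction and its gradient
  cvPotential <- function(cv) {
    cv <- if (is.matrix(cv)) cv else matrix(cv, 1)
    e <- exp(-aMorse * (cv[, 1] - d0))
    morse <- De * (1 - e)^2 - De
    bump <- bumpHeight * exp(-(cv[, 1] - bumpCenter)^2 / (2 * bumpWidth^2))
    ang <- 0.5 * kTheta * (cv[, 2] - thetaA0)^2
    ori <- 0.5 * kPhi * wrapAngle(cv[, 5] - phiB0)^2
    morse + bump + ang + ori
  }
  cvPotentialGrad <- function(cv) {
    cv <- as.numeric(cv)
    e <- exp(-aMorse * (cv[1] - d0))
    g <- numeric(6)
    g[1] <- 2 * De * (1 - e) * aMorse * e -
      bumpHeight * (cv[1] - bumpCenter) / bumpWidth^2 *
        exp(-(cv[1] - bumpCenter)^2 / (2 * bumpWidth^2))
    g[2] <- kTheta * (cv[2] - thetaA0)
    g[5] <- kPhi * wrapAngle(cv[5] - phiB0)
    g
  }

  ## stiff bond network holding the guest rigid (all 15 pairs)
  pairs <- t(utils::combn(4:9, 2))
  r0 <- apply(pairs, 1, function(p)
    vnorm(template$atoms[p[1] - 3, ] - template$atoms[p[2] - 3, ]))
  ## signed incidence matrix: bond force accumulation as one matrix product
  inc <- matrix(0, nAtoms, nrow(pairs))
  for (b in seq_len(nrow(pairs))) {
    inc[pairs[b, 1], b] <- -1
    inc[pairs[b, 2], b] <- 1
  }
  bondEnergy <- function(coords) {
    r <- sqrt(rowSums((coords[pairs[, 1], ] - coords[pairs[, 2], ])^2))
    0.5 * kBond * sum((r - r0)^2)
  }
  bondForce <- function(coords) {
    dvec <- coords[pairs[, 1], ] - coords[pairs[, 2], ]
    r <- sqrt(rowSums(dvec^2))
    inc %*% (kBond * (r - r0) / r * dvec)
  }

  ## shared CV/Jacobian cache: force, cvMap and the bias all need the
  ## same geometry within one integration step
  cache <- new.env()
  cvjOf <- function(x) {
    if (!is.null(cache$x) && identical(cache$x, x)) return(cache$res)
    coords <- unflattenCoords(x)
    res <- computeCVsAndJacobian(coords, anchors)
    res$coords <- coords
    cache$x <- x; cache$res <- res
    res
  }
  energy <- function(x) {
    cvj <- cvjOf(x)
    cvPotential(cvj$cv) + bondEnergy(cvj$coords)
  }
  force <- function(x) {
    cvj <- cvjOf(x)
    fCV <- -as.numeric(crossprod(cvj$jac, cvPotentialGrad(cvj$cv)))
    fCV + flattenCoords(bondForce(cvj$coords))
  }

  initFn <- function(cv) {
    guest <- placeGuestAtCV(cv, hostPts, template)
    flattenCoords(rbind(hostPts, guest))
  }
  boundCV <- c(d0, thetaA0, 1.2, 0.4, phiB0, 0.7)
  x0 <- initFn(boundCV)

  mobile <- if (restrainHost) seq_len(3 * nAtoms) else 10:(3 * nAtoms)
  ## compiled-kernel descriptor (frozen host only; the restrained-host
  ## variant runs through the reference R engine)
  kernel <- if (restrainHost) NULL else list(
    groups = lapply(anchorGroups(anchors), function(g) g@indices),
    params = list(De = De, d0 = d0, aMorse = aMorse, kTheta = kTheta,
                  kPhi = kPhi, bumpHeight = bumpHeight,
                  bumpCenter = bumpCenter, bumpWidth = bumpWidth,
                  kBond = kBond, thetaA0 = thetaA0, phiB0 = phiB0,
                  pairs = pairs - 1L, r0 = r0),
    mobileAtoms = 3:8)
  provider <- forceProvider(energy, force, 3L * nAtoms, masses = 1,
                            cvMap = function(x) cvjOf(x)[c("cv", "jac")],
                            mobile = mobile,
                            checkAt = x0 + seq_len(27) * 1e-4,
                            meta = list(reference = x0, kernel = kernel))
  if (restrainHost)
    provider <- addPositionalRestraints(provider, atoms = 0:2, k = 10,
                                        reference = x0)

  ## exit-barrier location and height along d (other CVs at their minima)
  dPot <- function(d) cvPotential(matrix(c(d, thetaA0, 1.2, 0.4, phiB0, 0.7), 1))
  opt <- stats::optimize(function(d) -dPot(d), c(d0, bumpCenter + 3 * bumpWidth))
  new("ToySystem", kind = "cartesian", dimension = 27L,
      potential = energy, gradient = function(x) -force(x),
      provider = provider,
      knownFeatures = list(boundCV = boundCV, boundEnergy = -De,
                           barrierD = opt$minimum, barrierHeight = -opt$objective + De),
      kT = kT,
      extras = list(anchors = anchors, hostPts = hostPts, template = template,
                    cvPotential = cvPotential, cvPotentialGrad = cvPotentialGrad,
                    initFn = initFn,
                    params = list(De = De, d0 = d0, aMorse = aMorse,
                                  kTheta = kTheta, kPhi = kPhi,
                                  bumpHeight = bumpHeight, bumpCenter = bumpCenter,
                                  bumpWidth = bumpWidth, kBond = kBond,
                                  thetaA0 = thetaA0, phiB0 = phiB0)))
}

#' Generate a synthetic guess unbinding trajectory
#'
#' Emulates interactively steered guess pathways on the host-guest toy:
#' `"direct"` pulls the guest straight out along d with the favourable
#' orientation; `"detour"` takes an angular excursion on the way out but
#' shares both endpoints with `"direct"`; `"bad_orientation"` forces an
#' unfavourable phiB rotation during the exit (by design its umbrella
#' barrier exceeds the direct path's). Seeded Gaussian jitter in CV space
#' mimics human pauses and wobble.
#'
#' @param toy A host-guest [ToySystem-class] from [makeHostGuestToy()].
#' @param style One of "direct", "detour", "bad_orientation".
#' @param sigma CV-space jitter standard deviation (>= 0).
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @param nFrames Number of snapshots.
#' @param dEnd Final separation in Angstrom.
#' @return List of 9 x 3 coordinate matrices with attributes `cvTargets`
#'   (the scripted CV waypoints) and `style`.
#' @export
generateGuessPath <- function(toy, style = c("direct", "detour", "bad_orientation"),
                              sigma = 0, seed = 1, nFrames = 60, dEnd = 9) {
  stopifnot2(identical(toy@kind, "cartesian"), "guess paths require the host-guest toy")
  stopifnot2(sigma >= 0, "sigma must be >= 0")
  style <- match.arg(style)
  p <- toy@extras$params
  base <- toy@knownFeatures$boundCV
  u <- seq(0, 1, length.out = nFrames)
  cvT <- matrix(rep(base, each = nFrames), nFrames, 6)
  cvT[, 1] <- p$d0 + (dEnd - p$d0) * u
  if (style == "detour") {
    cvT[, 2] <- base[2] + 0.5 * sin(pi * u)
    cvT[, 4] <- base[4] + 0.8 * sin(pi * u)
  } else if (style == "bad_orientation") {
    cvT[, 5] <- base[5] + 1.6 * sin(pi * u)^2
  }
  set.seed(seed)
  if (sigma > 0) {
    jit <- matrix(stats::rnorm(nFrames * 6, sd = sigma), nFrames, 6)
    jit[1, ] <- 0; jit[nFrames, ] <- 0
    cvT <- cvT + jit
    cvT[, 2] <- pmin(pmax(cvT[, 2], 0.15), pi - 0.15)
    cvT[, 3] <- pmin(pmax(cvT[, 3], 0.15), pi - 0.15)
    cvT[, 1] <- pmax(cvT[, 1], 1.5)
  }
  traj <- lapply(seq_len(nFrames), function(i)
    rbind(toy@extras$hostPts,
          placeGuestAtCV(cvT[i, ], toy@extras$hostPts, toy@extras$template)))
  attr(traj, "cvTargets") <- cvT
  attr(traj, "style") <- style
  attr(traj, "seed") <- seed
  traj
}

#' Brute-force free-energy profile along a path
#'
#' Direct Boltzmann integration of the toy's configuration space,
#' resolved in the path progress coordinate s -- the independent oracle
#' against which umbrella-sampling + WHAM results are validated.
#'
#' For 1-D and 2-D CV-space toys the integration is a dense grid
#' quadrature. For the Cartesian host-guest toy the guest is treated as a
#' rigid body, whose configuration measure in the six anchor CVs is the
#' exact rigid-rotor result d^2 sin(thetaA) sin(thetaB); the six-
#' dimensional integral is evaluated by seeded importance sampling with a
#' Gaussian tube proposal around the path (deterministic for a fixed
#' seed). The same harmonic z-confinement used by the umbrella windows
#' (`kZ`) is included as part of the system, matching what WHAM recovers.
#'
#' @param toy A [ToySystem-class].
#' @param path A [Path-class] over the toy's CV space.
#' @param nBins Number of s bins over [0, 1].
#' @param kZ Harmonic z-confinement constant (must match the campaign).
#' @param resolution Grid points per dimension (grid quadrature; default
#'   2000 in 1-D, 350 in 2-D).
#' @param nSamples Importance samples for the host-guest integration.
#' @param seed Seed for the importance sampler.
#' @param margin Grid margin beyond the path bounding box (CV units).
#' @return A [FreeEnergyProfile-class] (min over defined bins = 0).
#' @export
bruteForceProfile <- function(toy, path, nBins = 100, kZ = 0,
                              resolution = NULL, nSamples = 40000,
                              seed = 1, margin = NULL) {
  kTval <- toy@kT
  edges <- seq(0, 1, length.out = nBins + 1)
  centers <- (edges[-1] + edges[-(nBins + 1)]) / 2
  if (toy@kind == "cv" && toy@dimension == 1L) {
    resolution <- resolution %||% 2000L
    margin <- margin %||% 0.5
    rng <- range(path@nodes[, 1])
    xs <- seq(rng[1] - margin, rng[2] + margin, length.out = resolution)
    X <- matrix(xs, ncol = 1)
    sz <- pathCVBatch(X, path)
    V <- vapply(xs, function(x) toy@potential(x), 0)
    w <- exp(-(V + 0.5 * kZ * sz[, "z"]^2) / kTval)
    return(binWeightedProfile(sz[, "s"], w, edges, centers, kTval,
                              list(method = "quadrature-1d", kZ = kZ)))
  }
  if (toy@kind == "cv" && toy@dimension == 2L) {
    resolution <- resolution %||% 350L
    margin <- margin %||% if (kZ > 0) 4 * sqrt(kTval / kZ) else 0.75
    rngX <- range(path@nodes[, 1]) + c(-margin, margin)
    rngY <- range(path@nodes[, 2]) + c(-margin, margin)
    xs <- seq(rngX[1], rngX[2], length.out = resolution)
    ys <- seq(rngY[1], rngY[2], length.out = resolution)
    X <- cbind(rep(xs, times = resolution), rep(ys, each = resolution))
    V <- apply(X, 1, toy@potential)
    keep <- V < min(V) + 60 * kTval # discard negligible-weight grid points
    X <- X[keep, , drop = FALSE]
    sz <- pathCVBatch(X, path)
    w <- exp(-(V[keep] + 0.5 * kZ * sz[, "z"]^2) / kTval)
    return(binWeightedProfile(sz[, "s"], w, edges, centers, kTval,
                              list(method = "quadrature-2d", kZ = kZ)))
  }
  if (toy@kind == "cartesian") {
    return(hostGuestOracleProfile(toy, path, edges, centers, kZ, nSamples, seed))
  }
  stop("not tractable: no brute-force oracle for this toy", call. = FALSE)
}

## weighted histogram on s -> normalized free-energy profile
binWeightedProfile <- function(s, w, edges, centers, kTval, meta) {
  nBins <- length(centers)
  idx <- pmin(pmax(findInterval(s, edges, rightmost.closed = TRUE), 1L), nBins)
  mass <- vapply(seq_len(nBins), function(j) sum(w[idx == j]), 0)
  F <- ifelse(mass > 0, -kTval * log(mass), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  counts <- vapply(seq_len(nBins), function(j) sum(idx == j & w > 0), 0)
  new("FreeEnergyProfile", s = centers, F = F, sigma = NULL,
      counts = counts, meta = c(meta, list(kT = kTval)))
}

## Importance-sampled Boltzmann integration over the six rigid-body CVs
## of the host-guest toy. Proposal: uniform mixture over a dense path
## discretization x Gaussian per-CV widths (a "tube" around the path).
hostGuestOracleProfile <- function(toy, path, edges, centers, kZ, nSamples, seed) {
  kTval <- toy@kT
  stopifnot2(kZ > 0,
             "the host-guest oracle needs kZ > 0: without z-confinement the transverse angles are unbounded")
  ## proposal widths matched to the target per-CV precision: potential
  ## curvature plus z-confinement through the (inverse) metric
  p <- toy@extras$params
  Gd <- diag(Reduce(`+`, path@segGinv) / length(path@segGinv))
  prec <- kZ * Gd + c(2 * p$De * p$aMorse^2, p$kTheta, 0, 0, p$kPhi, 0)
  widths <- 1.4 * sqrt(kTval / prec)
  ## dense path discretization (mixture centers)
  nodes <- path@nodes
  K <- 25L * (nrow(nodes) - 1L)
  fr <- seq(0, 1, length.out = K)
  segIdx <- pmin(floor(fr * (nrow(nodes) - 1)) + 1, nrow(nodes) - 1)
  segF <- fr * (nrow(nodes) - 1) - (segIdx - 1)
  mix <- nodes[segIdx, , drop = FALSE] +
    (nodes[segIdx + 1, , drop = FALSE] - nodes[segIdx, , drop = FALSE]) * segF
  set.seed(seed)
  pick <- sample.int(K, nSamples, replace = TRUE)
  X <- mix[pick, , drop = FALSE] +
    matrix(stats::rnorm(nSamples * 6), nSamples, 6) %*% diag(widths)
  ## proposal density of the mixture (log-sum-exp over centers)
  logq <- matrix(0, nSamples, K)
  for (k in seq_len(K)) {
    zsc <- sweep(X, 2, mix[k, ]) %*% diag(1 / widths)
    logq[, k] <- -0.5 * rowSums(zsc^2)
  }
  mrow <- apply(logq, 1, max)
  qdens <- exp(mrow) * rowSums(exp(logq - mrow)) / (K * prod(widths) * (2 * pi)^3)
  ## target: Boltzmann weight x rigid-rotor measure x z-confinement
  ok <- X[, 1] > 0.5 & X[, 2] > 0 & X[, 2] < pi & X[, 3] > 0 & X[, 3] < pi
  w <- numeric(nSamples)
  sAll <- rep(NA_real_, nSamples)
  if (any(ok)) {
    V <- toy@extras$cvPotential(X[ok, , drop = FALSE])
    sz <- pathCVBatch(X[ok, , drop = FALSE], path)
    meas <- X[ok, 1]^2 * sin(X[ok, 2]) * sin(X[ok, 3])
    w[ok] <- meas * exp(-(V + 0.5 * kZ * sz[, "z"]^2) / kTval) / qdens[ok]
    sAll[ok] <- sz[, "s"]
  }
  keep <- ok & w > 0
  binWeightedProfile(sAll[keep], w[keep], edges, centers, kTval,
                     list(method = "mc-importance", kZ = kZ,
                          nSamples = nSamples, seed = seed))
}
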