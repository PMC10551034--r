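## Adaptive string method: refine a path toward the minimum free energy
## path using restrained mean-force estimates at the nodes, metric-
## preconditioned perpendicular node moves, and reparameterization.

#' Estimate the mean force on the CVs at a node
#'
#' Runs Langevin sampling with harmonic restraints holding the CVs at the
#' node (1/2 kNode |cv - node|^2 per component, dihedrals wrapped). By
#' linear response the restrained ensemble satisfies
#' kNode (<cv> - node) ~ -grad F(node), so the returned estimate points
#' downhill in free energy. The standard error comes from ten block
#' averages of the CV deviations.
#'
#' @param provider A [ForceProvider-class].
#' @param node CV vector at which the mean force is estimated.
#' @param kNode Restraint force constant (> 0), kcal/mol per CV-unit^2.
#' @param nSteps Sampling steps.
#' @param seed Integer seed.
#' @param params List: `dt`, `gamma`, `kT`, `stride`, `burnin` (steps
#'   discarded), `x0` (initial coordinates; default the node itself,
#'   valid for CV-space providers), `periodic` mask.
#' @return Numeric mean-force vector with attribute `se` (standard
#'   errors) and `meanCV` (the restrained ensemble CV mean).
#' @export
estimateMeanForce <- function(provider, node, kNode = 50, nSteps = 500,
                              seed = 1, params = list()) {
  stopifnot2(kNode > 0, "kNode must be > 0")
  node <- as.numeric(node)
  D <- length(node)
  periodic <- params$periodic %||%
    (if (D == 6) unname(cvPeriodicMask()) else rep(FALSE, D))
  dt <- params$dt %||% 0.01
  gamma <- params$gamma %||% 1
  kTval <- params$kT %||% 0.59616
  stride <- as.integer(params$stride %||% 2L)
  burnin <- as.integer(params$burnin %||% ceiling(nSteps / 5))
  x0 <- params$x0 %||% node
  cvMap <- provider@cvMap

  kernel <- provider@meta$kernel
  if (!is.null(kernel) && !identical(params$engine, "R")) {
    set.seed(seed)
    res <- .cppHostGuestRun(
      as.numeric(x0), kernel$groups, kernel$params, list(), mode = 1L,
      sCenter = 0, kS = 0, kZ = 0, rampSteps = 0L,
      node = node, kNode = kNode, nSteps = as.integer(nSteps), dt = dt,
      gamma = gamma, kT = kTval, stride = stride, burnin = burnin,
      mobileAtoms = kernel$mobileAtoms)
    dev <- res$dev
    stopifnot2(nrow(dev) >= 10, "too few samples for a mean-force estimate")
    est <- kNode * colMeans(dev)
    nb <- 10L
    blocks <- split(seq_len(nrow(dev)), cut(seq_len(nrow(dev)), nb, labels = FALSE))
    bm <- t(vapply(blocks, function(ii) colMeans(dev[ii, , drop = FALSE]),
                   numeric(D)))
    se <- kNode * apply(bm, 2, stats::sd) / sqrt(nb)
    attr(est, "se") <- se
    attr(est, "meanCV") <- node + colMeans(dev)
    return(est)
  }

  biasForce <- function(x, step) {
    cvj <- cvMap(x)
    delta <- maskedDiff(cvj$cv, node, periodic)
    list(energy = 0.5 * kNode * sum(delta^2),
         force = -as.numeric(crossprod(cvj$jac, kNode * delta)))
  }
  recEnv <- new.env(); recEnv$rows <- list(); recEnv$n <- 0L
  record <- function(step, x, v, biasE) {
    if (step > burnin) {
      recEnv$n <- recEnv$n + 1L
      recEnv$rows[[recEnv$n]] <- maskedDiff(cvMap(x)$cv, node, periodic)
    }
    NULL
  }
  langevinDynamics(provider, x0, nSteps, dt, gamma, kTval, seed = seed,
                   biasForce = biasForce, record = record, stride = stride)
  dev <- do.call(rbind, recEnv$rows)
  stopifnot2(!is.null(dev) && nrow(dev) >= 10, "too few samples for a mean-force estimate")
  est <- kNode * colMeans(dev)
  nb <- 10L
  blocks <- split(seq_len(nrow(dev)), cut(seq_len(nrow(dev)), nb, labels = FALSE))
  bm <- t(vapply(blocks, function(ii) colMeans(dev[ii, , drop = FALSE]),
                 numeric(D)))
  se <- kNode * apply(bm, 2, stats::sd) / sqrt(nb)
  attr(est, "se") <- se
  attr(est, "meanCV") <- node + colMeans(dev)
  est
}

#' One adaptive-string iteration
#'
#' Estimates the mean force at every node, preconditions it with the
#' frozen per-node inverse metric, moves interior nodes by
#' `stepSize x M^-1 f` projected perpendicular to the local path tangent
#' (in the metric inner product), lets the endpoints relax along the
#' full preconditioned force (so they find the free-energy minima), and
#' reparameterizes to uniform arc spacing.
#'
#' @param state A [StringState-class].
#' @param provider A [ForceProvider-class].
#' @param stepSize Step size (> 0) multiplying the preconditioned force.
#' @param params List: mean-force options as in [estimateMeanForce()]
#'   plus `kNode`, `nSteps`, `masterSeed`, and `x0Fn(node)` mapping a
#'   node to initial sampling coordinates (default: the node itself).
#' @return The advanced [StringState-class].
#' @export
evolveString <- function(state, provider, stepSize, params = list()) {
  stopifnot2(stepSize > 0, "stepSize must be > 0")
  path <- state@path
  nodes <- path@nodes
  n <- nrow(nodes); D <- ncol(nodes)
  masterSeed <- params$masterSeed %||% 1L
  x0Fn <- params$x0Fn %||% function(node) node
  kNode <- params$kNode %||% 50
  nSteps <- params$nSteps %||% 500
  mf <- matrix(0, n, D); seMat <- matrix(0, n, D)
  newNodes <- nodes
  for (i in seq_len(n)) {
    p <- params; p$x0 <- x0Fn(nodes[i, ])
    f <- estimateMeanForce(provider, nodes[i, ], kNode = kNode,
                           nSteps = nSteps,
                           seed = deriveSeed(masterSeed, state@iteration * 1009L + i),
                           params = p)
    mf[i, ] <- f; seMat[i, ] <- attr(f, "se")
    Minv <- psdPinv(path@nodeMetrics[[i]], floor = 1e-8)
    u <- as.numeric(Minv %*% f)
    if (i > 1 && i < n) {
      tau <- maskedDiff(nodes[min(i + 1, n), ], nodes[max(i - 1, 1), ],
                        path@periodic)
      denom <- sum(tau * (Minv %*% tau))
      if (denom > 0) u <- u - tau * sum(tau * (Minv %*% u)) / denom
    }
    newNodes[i, ] <- nodes[i, ] + stepSize * u
  }
  newPath <- reparameterizePath(
    newPathFromNodes(newNodes, path@nodeMetrics, path@lambda, path@periodic,
                     provenance = path@provenance))
  disp <- vapply(seq_len(n), function(i)
    sqrt(metricDist2(newPath@nodes[i, ], nodes[i, ],
                     psdPinv(path@nodeMetrics[[i]], floor = 1e-8),
                     path@periodic)), 0)
  rms <- sqrt(mean(disp^2))
  new("StringState", path = newPath, iteration = state@iteration + 1L,
      meanForces = mf, forceErrors = seMat,
      displacementHistory = c(state@displacementHistory, rms),
      converged = FALSE,
      diagnostics = c(state@diagnostics,
                      list(list(iteration = state@iteration + 1L,
                                rmsDisplacement = rms,
                                forceNorms = sqrt(rowSums(mf^2))))))
}

#' String convergence check
#'
#' @param state A [StringState-class].
#' @param m Window: number of trailing iterations averaged (>= 1).
#' @param tol Threshold on the mean RMS node displacement.
#' @return TRUE when the mean RMS displacement over the last `m`
#'   iterations is below `tol` (and at least `m` iterations exist).
#' @export
checkConvergence <- function(state, m = 5, tol = 1e-3) {
  stopifnot2(m >= 1, "m must be >= 1")
  h <- state@displacementHistory
  length(h) >= m && mean(utils::tail(h, m)) < tol
}

#' Refine a path toward the minimum free energy path
#'
#' Drives [evolveString()] until [checkConvergence()] or `maxIter`; the
#' refined path is ready for a fresh umbrella-sampling + WHAM campaign.
#'
#' @param path Initial [Path-class] (e.g. from a guess trajectory).
#' @param provider A [ForceProvider-class].
#' @param params List: `stepSize`, `maxIter`, `tol`, `convWindow`, plus
#'   everything [evolveString()] accepts.
#' @return A [StringState-class]; `stringPath(state)` is the refined
#'   path, `state@converged` reports whether the tolerance was met.
#' @export
refinePath <- function(path, provider, params = list()) {
  stepSize <- params$stepSize %||% 1e-3
  maxIter <- params$maxIter %||% 50L
  tol <- params$tol %||% 1e-3
  m <- params$convWindow %||% 5L
  state <- new("StringState", path = path, iteration = 0L,
               meanForces = matrix(0, nrow(path@nodes), ncol(path@nodes)),
               forceErrors = matrix(0, nrow(path@nodes), ncol(path@nodes)),
               displacementHistory = numeric(0), converged = FALSE,
               diagnostics = list())
  for (it in seq_len(maxIter)) {
    state <- evolveString(state, provider, stepSize, params)
    if (checkConvergence(state, m, tol)) {
      state@converged <- TRUE
      break
    }
  }
  state
}
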