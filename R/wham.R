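## Weighted histogram analysis method: combine biased umbrella samples
## into one free-energy profile along s.
##
## Convention: the harmonic z-confinement is identical in every window
## and is therefore treated as part of the system -- only the s-bias
## enters the per-window bias energies c_ij. The recovered F(s) is the
## profile of the z-confined ensemble, which is exactly what the
## brute-force oracles integrate.

#' Bin umbrella samples for WHAM
#'
#' @param series List of [SampleSeries-class] (burn-in already removed:
#'   windows record only post-ramp production samples).
#' @param nBins Number of uniform bins over s in [0, 1] (>= 10).
#' @return A [BinnedData-class].
#' @export
binSamples <- function(series, nBins = 100) {
  stopifnot2(nBins >= 10, "nBins must be >= 10")
  edges <- seq(0, 1, length.out = nBins + 1)
  centers <- (edges[-1] + edges[-(nBins + 1)]) / 2
  nW <- length(series)
  counts <- matrix(0, nW, nBins)
  bias <- matrix(0, nW, nBins)
  for (i in seq_len(nW)) {
    d <- series[[i]]@data
    if (nrow(d) == 0)
      stop(sprintf("window %d has no samples", series[[i]]@window@index),
           call. = FALSE)
    idx <- pmin(pmax(findInterval(d$s, edges, rightmost.closed = TRUE), 1L), nBins)
    counts[i, ] <- tabulate(idx, nBins)
    w <- series[[i]]@window
    bias[i, ] <- 0.5 * w@kS * (centers - w@sCenter)^2
  }
  new("BinnedData", counts = counts, edges = edges, centers = centers,
      bias = bias, totals = rowSums(counts))
}

## overlap-connectivity check: windows form one component of the graph
## whose edges join windows sharing at least one occupied bin
checkWindowConnectivity <- function(counts) {
  nW <- nrow(counts)
  occ <- counts > 0
  seen <- rep(FALSE, nW)
  queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    shared <- which(!seen & (occ %*% occ[i, ]) > 0)
    seen[shared] <- TRUE
    queue <- c(queue, shared)
  }
  if (!all(seen))
    stop(sprintf("windows are disconnected: no histogram overlap between windows {%s} and {%s}",
                 paste(which(seen), collapse = ","),
                 paste(which(!seen), collapse = ",")), call. = FALSE)
  invisible(TRUE)
}

#' Solve the WHAM equations
#'
#' Standard self-consistent iteration:
#' p_j proportional to (sum_i n_ij) / (sum_i N_i exp[(f_i - c_ij)/kT]),
#' f_i = -kT log sum_j p_j exp(-c_ij/kT),
#' iterated until the largest change in any window offset f_i falls below
#' `tol`. Bins never visited by any window are reported as NA, not
#' interpolated (poor overlap should be visible, not hidden).
#'
#' @param data A [BinnedData-class].
#' @param kT Thermal energy in kcal/mol.
#' @param tol Convergence tolerance on the window offsets (kcal/mol).
#' @param maxIter Maximum number of iterations.
#' @param f0 Optional warm-start window offsets.
#' @return List with `f` (window offsets, first window gauged to 0) and
#'   `profile` (a [FreeEnergyProfile-class]).
#' @export
solveWham <- function(data, kT = 0.59616, tol = 1e-8, maxIter = 1e5,
                      f0 = NULL) {
  counts <- data@counts
  stopifnot2(all(is.finite(data@bias)), "bias energies must be finite")
  checkWindowConnectivity(counts)
  nW <- nrow(counts); nBins <- ncol(counts)
  Ni <- data@totals
  nTot <- colSums(counts)
  expB <- exp(-data@bias / kT)   # nW x nBins
  f <- if (is.null(f0)) numeric(nW) else as.numeric(f0)
  occupied <- nTot > 0
  for (iter in seq_len(maxIter)) {
    denom <- colSums(Ni * exp(f / kT) * expB) # length nBins
    p <- ifelse(occupied, nTot / denom, 0)
    fNew <- -kT * log(as.numeric(expB %*% p))
    fNew <- fNew - fNew[1]
    delta <- max(abs(fNew - f))
    f <- fNew
    if (delta < tol) break
  }
  if (delta >= tol)
    stop(sprintf("WHAM failed to converge: max |delta f| = %.3g kcal/mol after %d iterations",
                 delta, maxIter), call. = FALSE)
  F <- ifelse(occupied, -kT * log(p), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  profile <- new("FreeEnergyProfile", s = data@centers, F = F, sigma = NULL,
                 counts = nTot,
                 meta = list(kT = kT, tol = tol, iterations = iter,
                             windows = nW))
  list(f = f, profile = profile)
}

#' Summary statistics of a free-energy profile
#'
#' @param profile A [FreeEnergyProfile-class].
#' @param boundRegion s-interval of the bound state (default c(0, 0.2)).
#' @param unboundRegion s-interval of the unbound state (default
#'   c(0.8, 1)).
#' @param flatTol Flatness tolerance for the local-minimum scan
#'   (kcal/mol).
#' @return List with `deltaF` (mean F over the unbound region minus the
#'   minimum over the bound region), `barrier` (max F between the two
#'   regions' representative minima, relative to the bound minimum),
#'   `barrierS` (its position), and `minima` (data.frame of local
#'   minima).
#' @export
profileStatistics <- function(profile, boundRegion = c(0, 0.2),
                              unboundRegion = c(0.8, 1), flatTol = 1e-3) {
  s <- profile@s; F <- profile@F
  inB <- s >= boundRegion[1] & s <= boundRegion[2]
  inU <- s >= unboundRegion[1] & s <= unboundRegion[2]
  stopifnot2(any(inB) && any(inU), "regions must contain at least one bin")
  if (any(!is.finite(F[inB])) || any(!is.finite(F[inU])))
    stop("undefined (never-visited) bins inside a requested region", call. = FALSE)
  bMinIdx <- which(inB)[which.min(F[inB])]
  uMinIdx <- which(inU)[which.min(F[inU])]
  deltaF <- mean(F[inU]) - F[bMinIdx]
  between <- seq(min(bMinIdx, uMinIdx), max(bMinIdx, uMinIdx))
  okBetween <- between[is.finite(F[between])]
  barrierIdx <- okBetween[which.max(F[okBetween])]
  barrier <- F[barrierIdx] - F[bMinIdx]
  ## discrete local minima with a flatness tolerance; runs of adjacent
  ## qualifying bins (flat basin bottoms) collapse to their lowest bin
  isMin <- logical(length(F))
  for (j in which(is.finite(F))) {
    lo <- max(1, j - 1); hi <- min(length(F), j + 1)
    neigh <- setdiff(seq(lo, hi), j)
    neigh <- neigh[is.finite(F[neigh])]
    isMin[j] <- length(neigh) > 0 && all(F[j] <= F[neigh] + flatTol) &&
      any(F[neigh] > F[j] + flatTol)
  }
  minima <- data.frame(s = numeric(0), F = numeric(0))
  j <- 1L
  while (j <= length(F)) {
    if (isMin[j]) {
      k <- j
      while (k < length(F) && isMin[k + 1]) k <- k + 1
      best <- (j:k)[which.min(F[j:k])]
      minima <- rbind(minima, data.frame(s = s[best], F = F[best]))
      j <- k + 1L
    } else j <- j + 1L
  }
  list(deltaF = deltaF, barrier = barrier, barrierS = s[barrierIdx],
       minima = minima)
}

#' Bootstrap uncertainty of profile summary statistics
#'
#' Convenience wrapper around [bootstrapUncertainty()]: evaluates
#' [profileStatistics()] on every bootstrap replicate and returns the
#' replicate spread of the unbinding free energy and barrier height.
#'
#' @inheritParams bootstrapUncertainty
#' @inheritParams profileStatistics
#' @return List with `deltaF` and `barrier`, each `c(value, sigma)` (the
#'   full-data value and the bootstrap standard deviation), plus
#'   `sigmaBins` (the per-bin sigma).
#' @export
bootstrapProfileStats <- function(series, nBoot = 30, blockLength = 50,
                                  seed = 1, nBins = 50, kT = 0.59616,
                                  boundRegion = c(0, 0.2),
                                  unboundRegion = c(0.8, 1)) {
  full <- solveWham(binSamples(series, nBins), kT = kT)
  st <- profileStatistics(full$profile, boundRegion, unboundRegion)
  sigma <- bootstrapUncertainty(series, nBoot, blockLength, seed, nBins, kT)
  reps <- attr(sigma, "replicates")
  centers <- profileGrid(full$profile)
  repStats <- apply(reps, 1, function(F) {
    if (all(is.na(F))) return(c(NA_real_, NA_real_))
    prof <- new("FreeEnergyProfile", s = centers, F = F - min(F, na.rm = TRUE),
                sigma = NULL, counts = full$profile@counts, meta = list())
    r <- tryCatch(profileStatistics(prof, boundRegion, unboundRegion),
                  error = function(e) NULL)
    if (is.null(r)) c(NA_real_, NA_real_) else c(r$deltaF, r$barrier)
  })
  list(deltaF = c(st$deltaF, stats::sd(repStats[1, ], na.rm = TRUE)),
       barrier = c(st$barrier, stats::sd(repStats[2, ], na.rm = TRUE)),
       sigmaBins = sigma, profile = full$profile)
}

#' Moving-block bootstrap uncertainty of the WHAM profile
#'
#' Resamples each window's time series in contiguous blocks (preserving
#' autocorrelation), re-solves WHAM per replicate, and reports the
#' per-bin standard deviation. The full-data solution warm-starts each
#' replicate.
#'
#' @param series List of [SampleSeries-class].
#' @param nBoot Number of bootstrap replicates (>= 20).
#' @param blockLength Block length in samples (must be shorter than every
#'   series).
#' @param seed Integer seed (replicate draws are deterministic).
#' @param nBins,kT,tol,maxIter Passed to [binSamples()]/[solveWham()].
#' @return Numeric vector of per-bin sigma (NA where any replicate is
#'   undefined), with attribute `replicates` (nBoot x nBins matrix of
#'   replicate profiles) for downstream statistics.
#' @export
bootstrapUncertainty <- function(series, nBoot = 50, blockLength = 50,
                                 seed = 1, nBins = 100, kT = 0.59616,
                                 tol = 1e-8, maxIter = 1e5) {
  stopifnot2(nBoot >= 20, "nBoot must be >= 20")
  lens <- vapply(series, function(ss) nrow(ss@data), 0L)
  if (any(blockLength >= lens))
    stop(sprintf("block length %d must be shorter than every series (min length %d)",
                 blockLength, min(lens)), call. = FALSE)
  full <- solveWham(binSamples(series, nBins), kT, tol, maxIter)
  reps <- matrix(NA_real_, nBoot, nBins)
  set.seed(seed)
  for (b in seq_len(nBoot)) {
    resampled <- lapply(series, function(ss) {
      d <- ss@data
      L <- nrow(d)
      nBlocks <- ceiling(L / blockLength)
      starts <- sample.int(L - blockLength + 1L, nBlocks, replace = TRUE)
      idx <- as.vector(vapply(starts, function(s0) s0:(s0 + blockLength - 1L),
                              integer(blockLength)))[seq_len(L)]
      new("SampleSeries", data = d[idx, , drop = FALSE], window = ss@window,
          stride = ss@stride, meta = ss@meta)
    })
    sol <- tryCatch(solveWham(binSamples(resampled, nBins), kT, tol, maxIter,
                              f0 = full$f),
                    error = function(e) NULL)
    if (!is.null(sol)) reps[b, ] <- sol$profile@F
  }
  sigma <- apply(reps, 2, stats::sd, na.rm = TRUE)
  sigma[colSums(is.finite(reps)) < nBoot / 2] <- NA_real_
  attr(sigma, "replicates") <- reps
  sigma
}
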