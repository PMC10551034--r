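## Umbrella sampling along the path collective variable: harmonic bias on
## s with harmonic confinement on z, a linear equilibration ramp of the
## force constants, and deterministic per-window seeding.

#' Build umbrella windows along a path
#'
#' Window centers are evenly spaced on s in [0, 1] inclusive (spacing
#' 1/(nWindows - 1)). The default force constant on s keeps neighbouring
#' window distributions overlapping: kS = kT / spacing^2, so the
#' unbiased-width sigma_s of a window roughly equals the spacing.
#'
#' @param path A [Path-class] (kept for provenance; window geometry only
#'   depends on the normalized s axis).
#' @param nWindows Number of windows (>= 2).
#' @param kS Force constant on s (kcal/mol per unit s^2); default
#'   kT / spacing^2.
#' @param kZ Confinement constant on z (kcal/mol per metric-unit^2).
#' @param rampSteps Equilibration steps ramping the bias from zero.
#' @param productionSteps Recorded production steps per window.
#' @param masterSeed Master seed; each window gets a deterministic
#'   derived seed.
#' @param temperature Temperature in K used for the kS default.
#' @return List of [UmbrellaWindow-class] objects.
#' @export
buildWindows <- function(path, nWindows, kS = NULL, kZ = 0, rampSteps = 0L,
                         productionSteps = 1000L, masterSeed = 1L,
                         temperature = 300) {
  if (nWindows < 2)
    stop("invalid parameter: nWindows must be >= 2", call. = FALSE)
  centers <- seq(0, 1, length.out = nWindows)
  spacing <- 1 / (nWindows - 1)
  if (is.null(kS)) kS <- kT(temperature) / spacing^2
  lapply(seq_len(nWindows), function(i) {
    new("UmbrellaWindow", index = as.integer(i), sCenter = centers[i],
        kS = kS, kZ = kZ, initFrame = NA_integer_,
        rampSteps = as.integer(rampSteps),
        productionSteps = as.integer(productionSteps),
        seed = deriveSeed(masterSeed, i))
  })
}

#' Assign initial structures to windows from the guess trajectory
#'
#' Each window is initialized from the trajectory snapshot whose path
#' progress s is closest to the window center (ties resolved to the lower
#' frame index) -- the closest-snapshot rule for seeding umbrella windows
#' from a guess pathway.
#'
#' @param windows List of [UmbrellaWindow-class].
#' @param cvSeries nFrames x D CV matrix of the guess trajectory (e.g.
#'   from [projectTrajectory()]).
#' @param path The [Path-class] the windows sample.
#' @param metric Optional metric override for the s evaluation.
#' @return The windows with `initFrame` set (1-based frame indices).
#' @export
assignInitialStructures <- function(windows, cvSeries, path, metric = NULL) {
  stopifnot2(nrow(as.matrix(cvSeries)) >= 1, "cvSeries must be non-empty")
  sz <- pathCVBatch(as.matrix(cvSeries), path, metric)
  s <- sz[, "s"]
  lapply(windows, function(w) {
    w@initFrame <- as.integer(which.min(abs(s - w@sCenter))) # which.min: lowest on ties
    w
  })
}

#' Linear equilibration ramp factor
#'
#' The bias force constant grows linearly from zero to its target over
#' `rampSteps` steps; with `rampSteps = 0` the bias is at full strength
#' immediately.
#'
#' @param step Current step (>= 0).
#' @param rampSteps Ramp duration in steps.
#' @return Scalar in [0, 1].
#' @export
rampFactor <- function(step, rampSteps) {
  stopifnot2(all(step >= 0), "step must be >= 0")
  if (rampSteps <= 0) return(rep(1, length(step)))
  pmin(step / rampSteps, 1)
}

#' Harmonic bias energy and derivatives
#'
#' E = 1/2 kS_eff (s - s0)^2 + 1/2 kZ_eff z^2, with both constants scaled
#' by the equilibration [rampFactor()] while `step < rampSteps`.
#'
#' @param s,z Current pathCV values.
#' @param window An [UmbrellaWindow-class].
#' @param step Integration step (default Inf: full-strength bias).
#' @return List with `energy`, `dEds`, `dEdz`.
#' @export
biasEnergyForce <- function(s, z, window, step = Inf) {
  f <- if (is.finite(step)) rampFactor(step, window@rampSteps) else 1
  kS <- f * window@kS
  kZ <- f * window@kZ
  ds <- s - window@sCenter
  list(energy = 0.5 * kS * ds^2 + 0.5 * kZ * z^2,
       dEds = kS * ds, dEdz = kZ * z)
}

#' Run one umbrella window
#'
#' BAOAB Langevin dynamics with the umbrella bias applied through the
#' chain rule: the bias force on the coordinates is
#' -J^T (dE/ds ds/dcv + dE/dz dz/dcv), with J the CV Jacobian from the
#' provider's `cvMap`. Samples of (s, z, bias energy) are recorded every
#' `stride` steps after the equilibration ramp (the ramp period is the
#' burn-in and is discarded). Runs are bitwise reproducible from the
#' window seed.
#'
#' @param provider A [ForceProvider-class].
#' @param path A [Path-class].
#' @param window An [UmbrellaWindow-class].
#' @param x0 Initial flat coordinates (e.g. the window's `initFrame`
#'   snapshot).
#' @param params List of integrator parameters: `dt`, `gamma`, `kT`,
#'   `stride` (defaults 0.01, 1, 0.59616, 10).
#' @return A [SampleSeries-class].
#' @export
runWindow <- function(provider, path, window, x0, params = list()) {
  dt <- params$dt %||% 0.01
  gamma <- params$gamma %||% 1
  kTval <- params$kT %||% 0.59616
  stride <- as.integer(params$stride %||% 10L)
  nSteps <- window@rampSteps + window@productionSteps
  cvMap <- provider@cvMap

  kernel <- provider@meta$kernel
  if (!is.null(kernel) && !identical(params$engine, "R")) {
    set.seed(window@seed)
    res <- .cppHostGuestRun(
      as.numeric(x0), kernel$groups, kernel$params,
      list(nodes = unname(path@nodes), Ginv = path@segGinv,
           lambda = path@lambda, periodic = path@periodic),
      mode = 0L, sCenter = window@sCenter, kS = window@kS, kZ = window@kZ,
      rampSteps = window@rampSteps, node = numeric(6), kNode = 0,
      nSteps = nSteps, dt = dt, gamma = gamma, kT = kTval,
      stride = stride, burnin = 0L, mobileAtoms = kernel$mobileAtoms)
    d <- as.data.frame(res$records)
    names(d) <- c("step", "s", "z", "bias")
    d$s <- pmin(pmax(d$s, 0), 1)
    d$z <- pmax(d$z, 0)
    return(new("SampleSeries", data = d, window = window, stride = stride,
               meta = list(dt = dt, gamma = gamma, kT = kTval,
                           seed = window@seed, engine = "compiled")))
  }

  biasForce <- function(x, step) {
    cvj <- cvMap(x)
    pc <- evalPathCVCore(cvj$cv, path, wantGrad = TRUE)
    b <- biasEnergyForce(pc$s, pc$z, window, step)
    g <- b$dEds * pc$ds + b$dEdz * pc$dz
    list(energy = b$energy, force = -as.numeric(crossprod(cvj$jac, g)),
         s = pc$s, z = pc$z)
  }
  recEnv <- new.env()
  recEnv$rows <- vector("list", window@productionSteps %/% max(stride, 1L) + 1L)
  recEnv$n <- 0L
  record <- function(step, x, v, biasE) {
    if (step > window@rampSteps) {
      cvj <- cvMap(x)
      pc <- evalPathCVCore(cvj$cv, path, wantGrad = FALSE)
      recEnv$n <- recEnv$n + 1L
      recEnv$rows[[recEnv$n]] <- c(step, pc$s, pc$z,
                                   biasEnergyForce(pc$s, pc$z, window)$energy)
    }
    NULL
  }
  langevinDynamics(provider, x0, nSteps, dt, gamma, kTval,
                   seed = window@seed, biasForce = biasForce,
                   record = record, stride = stride)
  rows <- recEnv$rows[seq_len(recEnv$n)]
  d <- as.data.frame(do.call(rbind, rows))
  names(d) <- c("step", "s", "z", "bias")
  d$s <- pmin(pmax(d$s, 0), 1)
  d$z <- pmax(d$z, 0)
  new("SampleSeries", data = d, window = window, stride = stride,
      meta = list(dt = dt, gamma = gamma, kT = kTval, seed = window@seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an umbrella-sampling campaign
#'
#' Runs every window independently (results do not depend on execution
#' order). When `outDir` is given, each window's samples are persisted as
#' CSV immediately after it finishes, and windows whose file already
#' exists are loaded instead of re-run -- an interrupted campaign resumes
#' where it stopped. Per-window failures are collected and reported at
#' the end without aborting sibling windows.
#'
#' @param provider A [ForceProvider-class].
#' @param path A [Path-class].
#' @param windows List of [UmbrellaWindow-class] with `initFrame` set.
#' @param trajectory List of snapshots (coordinate matrices) indexed by
#'   `initFrame`, or a function(window) -> flat initial coordinates.
#' @param params Integrator parameter list as in [runWindow()].
#' @param outDir Optional output directory for persistence/resume.
#' @return List of [SampleSeries-class]; windows that failed carry the
#'   condition message in attribute `errors`.
#' @export
runCampaign <- function(provider, path, windows, trajectory, params = list(),
                        outDir = NULL) {
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  out <- vector("list", length(windows))
  errors <- list()
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    file <- if (!is.null(outDir))
      file.path(outDir, sprintf("window_%03d.csv", w@index)) else NULL
    if (!is.null(file) && file.exists(file)) {
      out[[i]] <- readSamplesCSV(file)
      next
    }
    x0 <- if (is.function(trajectory)) {
      trajectory(w)
    } else {
      stopifnot2(!is.na(w@initFrame), "window has no initial frame; run assignInitialStructures first")
      flattenCoords(trajectory[[w@initFrame]])
    }
    res <- tryCatch(runWindow(provider, path, w, x0, params),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors[[as.character(w@index)]] <- conditionMessage(res)
      next
    }
    out[[i]] <- res
    if (!is.null(file)) writeSamplesCSV(res, file)
  }
  if (length(errors)) attr(out, "errors") <- errors
  out
}
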