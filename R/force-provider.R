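## Force-provider contract and the BAOAB Langevin engine.
##
## A ForceProvider is the only thing the sampling layers know about a
## physical system: energy and force over a flat coordinate vector, plus
## the map from coordinates to CV space. Real MD engines could implement
## the same contract; here it is fulfilled by analytic toy systems.

#' Create a force provider
#'
#' The force is checked against central finite differences of the energy
#' at `checkAt` on registration (relative tolerance 1e-4); providers whose
#' force is not the negative energy gradient are rejected.
#'
#' @param energy function(x) -> potential energy in kcal/mol.
#' @param force function(x) -> force vector (-dE/dx), same length as x.
#' @param nDof Number of degrees of freedom (3 x nAtoms for Cartesian
#'   systems).
#' @param masses Per-DOF masses (recycled; amu for Cartesian systems,
#'   1 for natural-unit toys).
#' @param cvMap function(x) -> list(cv, jac) mapping coordinates to CV
#'   space; defaults to the identity map (CV-space toys).
#' @param mobile Integer DOF indices the integrator moves (default all);
#'   frozen DOFs model the rigid receptor scaffold.
#' @param checkAt Coordinates at which the gradient self-check runs
#'   (default: a small deterministic perturbation around zero; pass a
#'   typical configuration for systems undefined at the origin).
#' @param meta Free-form metadata list.
#' @return A [ForceProvider-class].
#' @export
forceProvider <- function(energy, force, nDof, masses = 1, cvMap = NULL,
                          mobile = seq_len(nDof), checkAt = NULL,
                          meta = list()) {
  nDof <- as.integer(nDof)
  masses <- rep_len(masses, nDof)
  stopifnot2(all(masses > 0), "masses must be positive")
  if (is.null(cvMap))
    cvMap <- function(x) list(cv = x, jac = diag(length(x)))
  if (is.null(checkAt)) checkAt <- seq_len(nDof) * 1e-2
  p <- new("ForceProvider", energy = energy, force = force, nDof = nDof,
           masses = masses, cvMap = cvMap, mobile = as.integer(mobile),
           meta = meta)
  checkProviderGradient(p, checkAt)
  p
}

## finite-difference self-check of the registered force
checkProviderGradient <- function(provider, x0, h = 1e-5, tol = 1e-4) {
  f <- provider@force(x0)
  scale <- max(abs(f), 1)
  for (k in provider@mobile) {
    xp <- x0; xp[k] <- xp[k] + h
    xm <- x0; xm[k] <- xm[k] - h
    fd <- -(provider@energy(xp) - provider@energy(xm)) / (2 * h)
    if (abs(fd - f[k]) / scale > tol)
      stop(sprintf("force provider failed its gradient self-check at DOF %d (analytic %.6g vs finite-difference %.6g)",
                   k, f[k], fd), call. = FALSE)
  }
  invisible(TRUE)
}

#' Add harmonic positional restraints to a provider
#'
#' Adds 1/2 k |x_i - x_i,ref|^2 for each restrained atom, mirroring the
#' backbone/ion restraints used when a receptor must keep its frame while
#' a ligand is pulled out.
#'
#' @param provider A [ForceProvider-class] over Cartesian coordinates.
#' @param atoms Integer vector of 0-based atom indices to restrain.
#' @param k Force constant in kcal/mol/A^2 (recycled per atom).
#' @param reference Flat reference coordinates (defaults to provider
#'   `meta$reference`).
#' @return A new [ForceProvider-class] including the restraint term.
#' @export
addPositionalRestraints <- function(provider, atoms, k, reference = NULL) {
  if (is.null(reference)) reference <- provider@meta$reference
  stopifnot2(!is.null(reference), "reference coordinates required")
  k <- rep_len(k, length(atoms))
  dofs <- unlist(lapply(atoms, function(a) (3 * a + 1):(3 * a + 3)))
  kDof <- rep(k, each = 3)
  ref <- reference[dofs]
  baseE <- provider@energy; baseF <- provider@force
  energy <- function(x) baseE(x) + 0.5 * sum(kDof * (x[dofs] - ref)^2)
  force <- function(x) {
    f <- baseF(x)
    f[dofs] <- f[dofs] - kDof * (x[dofs] - ref)
    f
  }
  forceProvider(energy, force, provider@nDof, provider@masses,
                provider@cvMap, provider@mobile,
                checkAt = reference + stats::runif(provider@nDof, -0.01, 0.01),
                meta = c(provider@meta, list(restraints = list(atoms = atoms, k = k))))
}

#' BAOAB Langevin dynamics
#'
#' Integrates the provider's mobile degrees of freedom with the BAOAB
#' splitting. With `gamma = 0` the O-step is the identity and the scheme
#' reduces to velocity Verlet. An optional `biasForce` term (e.g. an
#' umbrella bias) is added to the physical force each step; `record` is
#' called every `stride` steps.
#'
#' @param provider A [ForceProvider-class].
#' @param x0 Initial flat coordinates.
#' @param nSteps Number of integration steps.
#' @param dt Time step (natural units for the built-in toys).
#' @param gamma Friction in inverse time units.
#' @param kT Thermal energy in kcal/mol.
#' @param seed Integer RNG seed; runs are bitwise reproducible.
#' @param biasForce NULL or function(x, step) -> list(energy, force).
#' @param record NULL or function(step, x, v, biasEnergy); its returns are
#'   collected in a list.
#' @param stride Recording stride in steps.
#' @return List with final `x`, `v`, and `records` (the collected record
#'   returns).
#' @export
langevinDynamics <- function(provider, x0, nSteps, dt, gamma = 1,
                             kT = 0.59616, seed = 1, biasForce = NULL,
                             record = NULL, stride = 10L) {
  mob <- provider@mobile
  m <- provider@masses[mob]
  c1 <- exp(-gamma * dt)
  c2 <- sqrt(max(0, 1 - c1 * c1))
  sdv <- sqrt(kT / m)
  x <- as.numeric(x0)
  v <- numeric(provider@nDof)
  set.seed(seed)
  getForce <- function(x, step) {
    f <- provider@force(x)
    bE <- 0
    if (!is.null(biasForce)) {
      b <- biasForce(x, step)
      f <- f + b$force
      bE <- b$energy
    }
    if (any(!is.finite(f)))
      stop(sprintf("integration blow-up: non-finite force at step %d", step),
           call. = FALSE)
    list(f = f, bE = bE)
  }
  fb <- getForce(x, 0L)
  records <- vector("list", if (is.null(record)) 0 else nSteps %/% stride + 1)
  nRec <- 0L
  for (step in seq_len(nSteps)) {
    v[mob] <- v[mob] + 0.5 * dt * fb$f[mob] / m
    x[mob] <- x[mob] + 0.5 * dt * v[mob]
    if (c2 > 0) {
      v[mob] <- c1 * v[mob] + c2 * sdv * stats::rnorm(length(mob))
    } else if (c1 < 1) {
      v[mob] <- c1 * v[mob]
    }
    x[mob] <- x[mob] + 0.5 * dt * v[mob]
    fb <- getForce(x, step)
    v[mob] <- v[mob] + 0.5 * dt * fb$f[mob] / m
    if (!is.null(record) && step %% stride == 0L) {
      nRec <- nRec + 1L
      records[[nRec]] <- record(step, x, v, fb$bE)
    }
  }
  list(x = x, v = v, records = if (nRec) records[seq_len(nRec)] else list())
}
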