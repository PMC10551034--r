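## S4 classes for the pathFE pipeline. CV vectors are plain named numerics
## (see cvVector()) for inner-loop speed; everything that travels between
## pipeline stages is a validated S4 container.

#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("functionOrNULL", c("function", "NULL"))

#' AnchorGroup: one atom group whose geometric center is an anchor point
#'
#' Atom indices are 0-based, matching all on-disk artifact files (PDB
#' serials are mapped on read). They are converted to R's 1-based indexing
#' only at the moment coordinates are subset.
#'
#' @slot indices Integer vector of unique 0-based atom indices.
#' @slot label Free-text label.
#' @export
setClass("AnchorGroup",
         representation(indices = "integer", label = "character"))

setValidity("AnchorGroup", function(object) {
  if (length(object@indices) == 0) return("anchor group must be non-empty")
  if (anyDuplicated(object@indices)) return("anchor group indices must be unique")
  if (any(object@indices < 0)) return("anchor group indices are 0-based and must be >= 0")
  TRUE
})

#' AnchorFrame: three anchor groups on each species
#'
#' @slot protein List of three AnchorGroup objects (P1, P2, P3).
#' @slot ligand List of three AnchorGroup objects (L1, L2, L3).
#' @export
setClass("AnchorFrame",
         representation(protein = "list", ligand = "list"))

setValidity("AnchorFrame", function(object) {
  ok <- function(l) length(l) == 3 && all(vapply(l, is, TRUE, "AnchorGroup"))
  if (!ok(object@protein)) return("protein anchors must be a list of 3 AnchorGroup")
  if (!ok(object@ligand)) return("ligand anchors must be a list of 3 AnchorGroup")
  TRUE
})

#' Path: ordered nodes in CV space with frozen metrics
#'
#' Nodes are stored on the continuous (unwrapped) scale for periodic
#' components; wrapping happens in every difference through
#' \code{cvDifference}. Per-segment inverse metrics (pseudo-inverse of the
#' mean of the two endpoint metrics) are frozen at construction so the
#' path collective variable is a fixed, conservative function of the CVs.
#'
#' @slot nodes N x D numeric matrix of node coordinates in CV space.
#' @slot nodeMetrics List of N D x D metric tensors (J W J^T at the nodes).
#' @slot segGinv List of N-1 frozen per-segment inverse metrics.
#' @slot lambda Softmin smoothing scale (dimensionless, > 0).
#' @slot arcLengths Cumulative metric arc length at each node.
#' @slot periodic Logical mask of periodic CV components.
#' @slot provenance List of free-form provenance metadata.
#' @export
setClass("Path",
         representation(nodes = "matrix", nodeMetrics = "list",
                        segGinv = "list", lambda = "numeric",
                        arcLengths = "numeric", periodic = "logical",
                        provenance = "list"))

setValidity("Path", function(object) {
  n <- nrow(object@nodes)
  if (n < 2) return("a path needs at least 2 nodes")
  if (length(object@nodeMetrics) != n) return("one metric per node required")
  if (length(object@segGinv) != n - 1) return("one inverse metric per segment required")
  if (length(object@periodic) != ncol(object@nodes))
    return("periodic mask length must match CV dimension")
  if (object@lambda <= 0) return("lambda must be > 0")
  if (length(object@arcLengths) != n) return("one arc length per node required")
  if (any(diff(object@arcLengths) <= 0)) return("arc lengths must be strictly increasing")
  TRUE
})

#' UmbrellaWindow: one biased simulation along the path coordinate
#'
#' @slot index Window index (1-based).
#' @slot sCenter Bias center on s in [0, 1].
#' @slot kS Force constant on s (kcal/mol per unit s^2).
#' @slot kZ Confinement constant on z (kcal/mol per metric-unit^2).
#' @slot initFrame Index into the guess trajectory used to initialize.
#' @slot rampSteps Equilibration steps over which the bias ramps 0 -> k.
#' @slot productionSteps Production steps recorded after the ramp.
#' @slot seed Integer RNG seed for this window.
#' @export
setClass("UmbrellaWindow",
         representation(index = "integer", sCenter = "numeric", kS = "numeric",
                        kZ = "numeric", initFrame = "integer",
                        rampSteps = "integer", productionSteps = "integer",
                        seed = "integer"))

setValidity("UmbrellaWindow", function(object) {
  if (object@sCenter < 0 || object@sCenter > 1) return("sCenter must lie in [0, 1]")
  if (object@kS <= 0) return("kS must be > 0")
  if (object@kZ < 0) return("kZ must be >= 0")
  if (object@rampSteps < 0 || object@productionSteps < 0)
    return("step counts must be >= 0")
  TRUE
})

#' SampleSeries: thinned biased samples from one umbrella window
#'
#' @slot data data.frame with columns step, s, z, bias (kcal/mol).
#' @slot window The UmbrellaWindow that produced the samples.
#' @slot stride Thinning stride in integrator steps.
#' @slot meta List of metadata (seed, integrator parameters, ...).
#' @export
setClass("SampleSeries",
         representation(data = "data.frame", window = "UmbrellaWindow",
                        stride = "integer", meta = "list"))

setValidity("SampleSeries", function(object) {
  d <- object@data
  need <- c("step", "s", "z", "bias")
  if (!all(need %in% names(d))) return("data needs columns step, s, z, bias")
  if (nrow(d) > 0) {
    if (any(!is.finite(d$s)) || any(d$s < -1e-9) || any(d$s > 1 + 1e-9))
      return("s samples must be finite and in [0, 1]")
    if (any(!is.finite(d$z)) || any(d$z < -1e-12)) return("z samples must be finite and >= 0")
    if (any(!is.finite(d$bias))) return("bias energies must be finite")
  }
  TRUE
})

#' BinnedData: histogrammed umbrella samples ready for WHAM
#'
#' @slot counts nWindows x nBins matrix of per-window bin counts.
#' @slot edges Bin edges on s (uniform over [0, 1]).
#' @slot centers Bin centers.
#' @slot bias nWindows x nBins matrix of window bias energies at bin centers.
#' @slot totals Per-window sample totals.
#' @export
setClass("BinnedData",
         representation(counts = "matrix", edges = "numeric",
                        centers = "numeric", bias = "matrix",
                        totals = "numeric"))

setValidity("BinnedData", function(object) {
  if (any(object@counts < 0)) return("counts must be >= 0")
  if (!isTRUE(all.equal(unname(rowSums(object@counts)), unname(object@totals))))
    return("row sums of counts must equal per-window totals")
  if (length(object@centers) != ncol(object@counts))
    return("one center per bin required")
  TRUE
})

#' FreeEnergyProfile: F(s) on a uniform grid
#'
#' Normalization convention: the minimum over defined bins is zero. Bins
#' never visited by any window are NA (reported, not interpolated).
#'
#' @slot s Bin centers.
#' @slot F Free energy in kcal/mol (NA on empty bins).
#' @slot sigma Optional per-bin bootstrap standard deviation.
#' @slot counts Total samples per bin.
#' @slot meta List of metadata (kT, iterations, tolerance, seeds, ...).
#' @export
setClass("FreeEnergyProfile",
         representation(s = "numeric", F = "numeric", sigma = "numericOrNULL",
                        counts = "numeric", meta = "list"))

setValidity("FreeEnergyProfile", function(object) {
  if (length(object@F) != length(object@s)) return("F and s lengths differ")
  ok <- is.finite(object@F)
  if (any(ok) && abs(min(object@F[ok])) > 1e-9)
    return("profile must be shifted so the minimum over defined bins is 0")
  TRUE
})

#' ForceProvider: the energy/force contract for sampling engines
#'
#' A provider maps a flat coordinate vector (x1, y1, z1, x2, ...; or plain
#' coordinates for CV-space toys) to a potential energy (kcal/mol) and the
#' force vector (-gradient). Providers are checked against finite
#' differences at construction. \code{cvMap} maps coordinates to the CV
#' vector and its Jacobian; the identity map is used for CV-space toys.
#'
#' @slot energy function(x) -> scalar energy.
#' @slot force function(x) -> force vector (same length as x).
#' @slot nDof Number of degrees of freedom.
#' @slot masses Per-DOF masses (amu, or 1 in natural units).
#' @slot cvMap function(x) -> list(cv = numeric, jac = nCV x nDof matrix).
#' @slot mobile Integer indices of DOFs that the integrator moves.
#' @slot meta List of metadata.
#' @export
setClass("ForceProvider",
         representation(energy = "function", force = "function",
                        nDof = "integer", masses = "numeric",
                        cvMap = "function", mobile = "integer",
                        meta = "list"))

#' ToySystem: analytic potential with known features and oracles
#'
#' @slot kind "cv" (coordinates are the CVs) or "cartesian".
#' @slot dimension Number of coordinates (CV dimension for kind "cv").
#' @slot potential function(x) -> energy.
#' @slot gradient function(x) -> gradient vector.
#' @slot provider ForceProvider for the sampling engine.
#' @slot knownFeatures List: minima, saddles, barriers (computed numerically).
#' @slot kT Thermal energy convention for the system (kcal/mol).
#' @slot extras List of system-specific pieces (anchors, templates, ...).
#' @export
setClass("ToySystem",
         representation(kind = "character", dimension = "integer",
                        potential = "function", gradient = "function",
                        provider = "ForceProvider", knownFeatures = "list",
                        kT = "numeric", extras = "list"))

setValidity("ToySystem", function(object) {
  if (!object@kind %in% c("cv", "cartesian")) return("kind must be 'cv' or 'cartesian'")
  TRUE
})

#' StringState: the evolving string of an adaptive string refinement
#'
#' @slot path Current Path.
#' @slot iteration Iteration counter.
#' @slot meanForces nNodes x D matrix of the latest mean-force estimates.
#' @slot forceErrors nNodes x D matrix of their standard errors.
#' @slot displacementHistory RMS metric node displacement per iteration.
#' @slot converged Logical convergence flag.
#' @slot diagnostics List of per-iteration diagnostics.
#' @export
setClass("StringState",
         representation(path = "Path", iteration = "integer",
                        meanForces = "matrix", forceErrors = "matrix",
                        displacementHistory = "numeric", converged = "logical",
                        diagnostics = "list"))

setValidity("StringState", function(object) {
  if (any(object@displacementHistory < 0))
    return("displacement history must be non-negative")
  TRUE
})
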