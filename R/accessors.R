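## Constructors, accessors and show methods.

#' Create an anchor atom group
#'
#' @param indices Integer vector of unique, 0-based atom indices.
#' @param label Optional free-text label.
#' @return An [AnchorGroup-class] object.
#' @export
anchorGroup <- function(indices, label = "") {
  new("AnchorGroup", indices = as.integer(indices), label = as.character(label))
}

#' Create an anchor frame from six atom groups
#'
#' Three anchor groups per species; each anchor point is the unweighted
#' geometric center of its group. On a reference snapshot the two anchor
#' triangles must be non-degenerate (smallest angle > `epsDeg`), and a
#' warning is emitted when a triangle is far from equilateral (side-length
#' ratio max/min > 1.5), since strongly anisotropic triangles make the
#' orientational CVs ill-conditioned.
#'
#' @param protein List of three AnchorGroup (P1, P2, P3).
#' @param ligand List of three AnchorGroup (L1, L2, L3).
#' @param reference Optional n x 3 coordinate matrix (Angstrom) on which
#'   the triangle checks are performed.
#' @param epsDeg Degeneracy tolerance in degrees (default 10).
#' @return An [AnchorFrame-class] object.
#' @export
anchorFrame <- function(protein, ligand, reference = NULL, epsDeg = 10) {
  fr <- new("AnchorFrame", protein = protein, ligand = ligand)
  if (!is.null(reference)) checkAnchorTriangles(fr, reference, epsDeg)
  fr
}

## Triangle sanity checks used by anchorFrame() and readAnchorsYAML().
checkAnchorTriangles <- function(frame, coords, epsDeg = 10) {
  for (species in c("protein", "ligand")) {
    grp <- slot(frame, species)
    pts <- t(vapply(grp, function(g) anchorCenter(coords, g), numeric(3)))
    sides <- c(vnorm(pts[1, ] - pts[2, ]), vnorm(pts[2, ] - pts[3, ]),
               vnorm(pts[1, ] - pts[3, ]))
    if (min(sides) < 1e-12)
      stop(sprintf("%s anchor triangle is degenerate (coincident points)", species),
           call. = FALSE)
    angs <- c(angleBetween(pts[2, ], pts[1, ], pts[3, ]),
              angleBetween(pts[1, ], pts[2, ], pts[3, ]),
              angleBetween(pts[1, ], pts[3, ], pts[2, ]))
    if (min(angs) * 180 / pi < epsDeg)
      stop(sprintf("%s anchor triangle is nearly collinear (min angle %.2f deg < %g deg)",
                   species, min(angs) * 180 / pi, epsDeg), call. = FALSE)
    if (max(sides) / min(sides) > 1.5)
      warning(sprintf("%s anchor triangle is far from equilateral (side ratio %.2f > 1.5)",
                      species, max(sides) / min(sides)), call. = FALSE)
  }
  invisible(TRUE)
}

#' @describeIn anchorFrame All six anchor groups as one list (P1..P3, L1..L3).
#' @param frame An AnchorFrame.
#' @export
anchorGroups <- function(frame) c(frame@protein, frame@ligand)

#' Path accessors
#'
#' @param path A [Path-class] object.
#' @return `pathNodes`: the N x D node matrix; `pathArcLengths`: cumulative
#'   metric arc lengths; `nodeMetrics`: the list of frozen per-node metric
#'   tensors; `nPathNodes`: the node count.
#' @export
pathNodes <- function(path) path@nodes

#' @rdname pathNodes
#' @export
pathArcLengths <- function(path) path@arcLengths

#' @rdname pathNodes
#' @export
nodeMetrics <- function(path) path@nodeMetrics

#' @rdname pathNodes
#' @export
nPathNodes <- function(path) nrow(path@nodes)

#' FreeEnergyProfile accessors
#'
#' @param profile A [FreeEnergyProfile-class] object.
#' @return `profileGrid`: bin centers on s; `profileF`: F(s) in kcal/mol
#'   (NA on unvisited bins); `profileSigma`: per-bin bootstrap sigma or
#'   NULL.
#' @export
profileGrid <- function(profile) profile@s

#' @rdname profileGrid
#' @export
profileF <- function(profile) profile@F

#' @rdname profileGrid
#' @export
profileSigma <- function(profile) profile@sigma

#' SampleSeries accessors
#'
#' @param series A [SampleSeries-class] object.
#' @return `sampleData`: the data.frame of (step, s, z, bias);
#'   `sampleWindow`: the generating UmbrellaWindow.
#' @export
sampleData <- function(series) series@data

#' @rdname sampleData
#' @export
sampleWindow <- function(series) series@window

#' @rdname sampleData
#' @param state A [StringState-class] object.
#' @export
stringPath <- function(state) state@path

setMethod("show", "AnchorGroup", function(object) {
  cat(sprintf("AnchorGroup '%s': %d atom(s), 0-based indices [%s]\n",
              object@label, length(object@indices),
              paste(utils::head(object@indices, 8), collapse = ", ")))
})

setMethod("show", "AnchorFrame", function(object) {
  cat("AnchorFrame with 3 + 3 anchor groups\n")
  cat(" protein:", paste(vapply(object@protein, function(g)
    sprintf("%s(%d)", g@label, length(g@indices)), ""), collapse = " "), "\n")
  cat(" ligand: ", paste(vapply(object@ligand, function(g)
    sprintf("%s(%d)", g@label, length(g@indices)), ""), collapse = " "), "\n")
})

setMethod("show", "Path", function(object) {
  n <- nrow(object@nodes)
  cat(sprintf("Path: %d nodes in %d-D CV space, metric length %.4g, lambda %.3g\n",
              n, ncol(object@nodes), object@arcLengths[n], object@lambda))
})

setMethod("show", "UmbrellaWindow", function(object) {
  cat(sprintf("UmbrellaWindow %d: s0=%.4f kS=%.3g kZ=%.3g ramp=%d prod=%d seed=%d init=%d\n",
              object@index, object@sCenter, object@kS, object@kZ,
              object@rampSteps, object@productionSteps, object@seed,
              object@initFrame))
})

setMethod("show", "SampleSeries", function(object) {
  cat(sprintf("SampleSeries: window %d, %d samples (stride %d), mean s=%.4f\n",
              object@window@index, nrow(object@data), object@stride,
              if (nrow(object@data)) mean(object@data$s) else NA_real_))
})

setMethod("show", "FreeEnergyProfile", function(object) {
  ok <- is.finite(object@F)
  cat(sprintf("FreeEnergyProfile: %d bins (%d defined), max F = %.3f kcal/mol\n",
              length(object@s), sum(ok), if (any(ok)) max(object@F[ok]) else NA_real_))
})

setMethod("show", "ToySystem", function(object) {
  cat(sprintf("ToySystem (%s, %d-D): kT=%.4g kcal/mol, features: %s\n",
              object@kind, object@dimension, object@kT,
              paste(names(object@knownFeatures), collapse = ", ")))
})

setMethod("show", "StringState", function(object) {
  cat(sprintf("StringState: iteration %d, %sconverged, last RMS displacement %.4g\n",
              object@iteration, if (object@converged) "" else "not ",
              if (length(object@displacementHistory))
                utils::tail(object@displacementHistory, 1) else NA_real_))
})

setMethod("show", "ForceProvider", function(object) {
  cat(sprintf("ForceProvider: %d DOF (%d mobile)\n",
              object@nDof, length(object@mobile)))
})
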