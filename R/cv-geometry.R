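## Anchor-based collective-variable geometry.
##
## Six CVs describe the relative position and orientation of a ligand with
## respect to a receptor through three anchor points on each species
## (geometric centers of user-chosen atom groups P1..P3, L1..L3):
##   d      = |P1 - L1|                       (Angstrom)
##   thetaA = angle(P2, P1, L1)               (rad, vertex P1)
##   thetaB = angle(P1, L1, L2)               (rad, vertex L1)
##   phiA   = dihedral(P3, P2, P1, L1)        (rad, IUPAC sign)
##   phiB   = dihedral(P2, P1, L1, L2)
##   phiC   = dihedral(P1, L1, L2, L3)
## This is the standard six-degree-of-freedom relative-orientation set
## built from 3+3 reference points. All gradients are analytic.

## Tolerance below which sin(angle) flags collinear dihedral geometry.
.dihedralSinTol <- 1e-6

#' Geometric center of an anchor group
#'
#' @param coords n x 3 coordinate matrix in Angstrom.
#' @param group An [AnchorGroup-class] (0-based indices).
#' @return Length-3 numeric vector: the unweighted mean of the member
#'   atom coordinates.
#' @export
anchorCenter <- function(coords, group) {
  idx <- group@indices + 1L
  if (any(idx > nrow(coords)))
    stop(sprintf("invalid selection: anchor group '%s' references atom index %d (0-based) but snapshot has %d atoms",
                 group@label, max(group@indices), nrow(coords)), call. = FALSE)
  colMeans(coords[idx, , drop = FALSE])
}

## angle at vertex B formed by points A-B-C
angleBetween <- function(A, B, C) {
  u <- A - B; v <- C - B
  cs <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cs)))
}

## IUPAC-signed dihedral of points A-B-C-D via the atan2 form
dihedralAngle <- function(A, B, C, D, what = "dihedral") {
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  nb2 <- vnorm(b2)
  s1 <- vnorm(n1) / (vnorm(b1) * nb2)
  s2 <- vnorm(n2) / (nb2 * vnorm(b3))
  if (s1 < .dihedralSinTol || s2 < .dihedralSinTol)
    stop(sprintf("degenerate geometry: three consecutive points of %s are collinear",
                 what), call. = FALSE)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / nb2
  phi <- atan2(y, x)
  if (phi <= -pi) phi <- phi + 2 * pi
  phi
}

## Anchor-point matrix (6 x 3): rows P1, P2, P3, L1, L2, L3.
anchorPoints <- function(coords, frame) {
  grp <- c(frame@protein, frame@ligand)
  pts <- t(vapply(grp, function(g) anchorCenter(coords, g), numeric(3)))
  rownames(pts) <- c("P1", "P2", "P3", "L1", "L2", "L3")
  pts
}

#' Construct a CV vector with range validation
#'
#' @param d Distance in Angstrom (> 0).
#' @param thetaA,thetaB Angles in radians, open interval (0, pi).
#' @param phiA,phiB,phiC Dihedrals in radians; wrapped into (-pi, pi].
#' @return Named numeric vector of length 6 carrying the periodicity mask
#'   (attribute `periodic`, from [cvPeriodicMask()]).
#' @export
cvVector <- function(d, thetaA, thetaB, phiA, phiB, phiC) {
  stopifnot2(d > 0, "d must be > 0")
  stopifnot2(thetaA > 0 && thetaA < pi, "thetaA must lie in (0, pi)")
  stopifnot2(thetaB > 0 && thetaB < pi, "thetaB must lie in (0, pi)")
  v <- c(d = d, thetaA = thetaA, thetaB = thetaB,
         phiA = wrapAngle(phiA), phiB = wrapAngle(phiB), phiC = wrapAngle(phiC))
  attr(v, "periodic") <- unname(cvPeriodicMask())
  v
}

#' Compute the six anchor-based CVs of a snapshot
#'
#' @param coords n x 3 coordinate matrix in Angstrom.
#' @param frame An [AnchorFrame-class].
#' @return A CV vector as from [cvVector()].
#' @export
computeCVs <- function(coords, frame) {
  p <- anchorPoints(coords, frame)
  cvVector(d = vnorm(p["P1", ] - p["L1", ]),
           thetaA = angleBetween(p["P2", ], p["P1", ], p["L1", ]),
           thetaB = angleBetween(p["P1", ], p["L1", ], p["L2", ]),
           phiA = dihedralAngle(p["P3", ], p["P2", ], p["P1", ], p["L1", ], "phiA"),
           phiB = dihedralAngle(p["P2", ], p["P1", ], p["L1", ], p["L2", ], "phiB"),
           phiC = dihedralAngle(p["P1", ], p["L1", ], p["L2", ], p["L3", ], "phiC"))
}

## ---- analytic gradients with respect to the defining points ----

## distance |A - B|: returns list(A=, B=) of 3-vectors
gradDistance <- function(A, B) {
  u <- A - B; d <- vnorm(u)
  list(A = u / d, B = -u / d)
}

## angle at vertex B: d theta / d {A, B, C}
gradAngle <- function(A, B, C) {
  u <- A - B; v <- C - B
  nu <- vnorm(u); nv <- vnorm(v)
  uh <- u / nu; vh <- v / nv
  cs <- max(-1, min(1, sum(uh * vh)))
  sn <- sqrt(max(1 - cs^2, 1e-24))
  gA <- (cs * uh - vh) / (nu * sn)
  gC <- (cs * vh - uh) / (nv * sn)
  list(A = gA, B = -gA - gC, C = gC)
}

## IUPAC dihedral A-B-C-D: d phi / d {A, B, C, D}
gradDihedral <- function(A, B, C, D) {
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  nb2 <- vnorm(b2)
  gA <- -nb2 / sum(n1 * n1) * n1
  gD <- nb2 / sum(n2 * n2) * n2
  f1 <- sum(b1 * b2) / (nb2 * nb2)
  f3 <- sum(b3 * b2) / (nb2 * nb2)
  gB <- -(1 + f1) * gA + f3 * gD
  gC <- f1 * gA - (1 + f3) * gD
  list(A = gA, B = gB, C = gC, D = gD)
}

#' Analytic Jacobian of the six CVs with respect to Cartesian coordinates
#'
#' Each anchor point is the unweighted mean of its group, so each member
#' atom receives 1/|group| of the anchor-point derivative; atoms outside
#' all anchor groups have identically zero columns.
#'
#' @inheritParams computeCVs
#' @return 6 x (3 n) matrix; columns ordered (x1, y1, z1, x2, ...).
#' @export
cvJacobian <- function(coords, frame) {
  cvJacobianAt(anchorPoints(coords, frame), coords, frame)
}

## Jacobian given precomputed anchor points (shared with the combined
## CV+Jacobian evaluation used in sampling inner loops).
cvJacobianAt <- function(p, coords, frame) {
  grp <- c(frame@protein, frame@ligand)
  n <- nrow(coords)
  J <- matrix(0, 6, 3 * n,
              dimnames = list(c("d", "thetaA", "thetaB", "phiA", "phiB", "phiC"), NULL))
  add <- function(row, anchor, g3) {
    g <- grp[[anchor]]
    idx <- g@indices + 1L
    w <- 1 / length(idx)
    for (i in idx) {
      cols <- (3 * (i - 1) + 1):(3 * i)
      J[row, cols] <<- J[row, cols] + w * g3
    }
  }
  ## anchor order: 1=P1, 2=P2, 3=P3, 4=L1, 5=L2, 6=L3
  gd <- gradDistance(p["P1", ], p["L1", ])
  add(1, 1, gd$A); add(1, 4, gd$B)
  ga <- gradAngle(p["P2", ], p["P1", ], p["L1", ])
  add(2, 2, ga$A); add(2, 1, ga$B); add(2, 4, ga$C)
  gb <- gradAngle(p["P1", ], p["L1", ], p["L2", ])
  add(3, 1, gb$A); add(3, 4, gb$B); add(3, 5, gb$C)
  g1 <- gradDihedral(p["P3", ], p["P2", ], p["P1", ], p["L1", ])
  add(4, 3, g1$A); add(4, 2, g1$B); add(4, 1, g1$C); add(4, 4, g1$D)
  g2 <- gradDihedral(p["P2", ], p["P1", ], p["L1", ], p["L2", ])
  add(5, 2, g2$A); add(5, 1, g2$B); add(5, 4, g2$C); add(5, 5, g2$D)
  g3 <- gradDihedral(p["P1", ], p["L1", ], p["L2", ], p["L3", ])
  add(6, 1, g3$A); add(6, 4, g3$B); add(6, 5, g3$C); add(6, 6, g3$D)
  J
}

## CVs and Jacobian in one pass (anchor points computed once).
computeCVsAndJacobian <- function(coords, frame) {
  p <- anchorPoints(coords, frame)
  cv <- cvVector(d = vnorm(p["P1", ] - p["L1", ]),
                 thetaA = angleBetween(p["P2", ], p["P1", ], p["L1", ]),
                 thetaB = angleBetween(p["P1", ], p["L1", ], p["L2", ]),
                 phiA = dihedralAngle(p["P3", ], p["P2", ], p["P1", ], p["L1", ], "phiA"),
                 phiB = dihedralAngle(p["P2", ], p["P1", ], p["L1", ], p["L2", ], "phiB"),
                 phiC = dihedralAngle(p["P1", ], p["L1", ], p["L2", ], p["L3", ], "phiC"))
  list(cv = as.numeric(cv), jac = cvJacobianAt(p, coords, frame))
}

#' CV-space metric tensor M = J W J^T
#'
#' The metric accounts for the different functional forms and couplings of
#' the CV components (a distance mixes with angles and dihedrals only
#' through the shared anchor atoms). W is diagonal; unit weights by
#' default, inverse-mass weights optionally.
#'
#' @inheritParams computeCVs
#' @param weights `"unit"` (default), `"invmass"` (requires `masses`), or a
#'   numeric vector of positive per-atom weights.
#' @param masses Per-atom masses in amu, used when `weights = "invmass"`.
#' @return 6 x 6 symmetric positive-semidefinite matrix.
#' @export
cvMetric <- function(coords, frame, weights = "unit", masses = NULL) {
  J <- cvJacobian(coords, frame)
  n <- nrow(coords)
  w <- if (identical(weights, "unit")) {
    rep(1, n)
  } else if (identical(weights, "invmass")) {
    stopifnot2(!is.null(masses) && length(masses) == n,
               "invmass weighting needs one mass per atom")
    stopifnot2(all(masses > 0), "invalid parameter: masses must be > 0")
    1 / masses
  } else {
    stopifnot2(is.numeric(weights) && length(weights) == n,
               "weights must be 'unit', 'invmass', or one value per atom")
    stopifnot2(all(weights > 0), "invalid parameter: weights must be > 0")
    weights
  }
  W <- rep(w, each = 3)
  M <- J %*% (W * t(J))
  (M + t(M)) / 2
}

#' Componentwise CV difference with periodic wrapping
#'
#' @param a,b CV vectors (named numeric, same length).
#' @param periodic Logical mask of periodic components; defaults to the
#'   mask carried by `a`, else [cvPeriodicMask()].
#' @return a - b with periodic components wrapped into (-pi, pi].
#'   Antisymmetric up to the wrap convention at the branch point.
#' @export
cvDifference <- function(a, b, periodic = NULL) {
  if (is.null(periodic)) {
    periodic <- attr(a, "periodic")
    if (is.null(periodic)) periodic <- unname(cvPeriodicMask())[seq_along(a)]
  }
  maskedDiff(as.numeric(a), as.numeric(b), periodic)
}
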