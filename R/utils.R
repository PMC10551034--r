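## Shared numerical helpers and physical constants.

#' Boltzmann constant in kcal/mol/K
#'
#' @return Numeric scalar, 0.0019872041 kcal/mol/K.
#' @export
kBoltzmann <- function() 0.0019872041

#' Thermal energy at a given temperature
#'
#' @param temperature Temperature in Kelvin (default 300).
#' @return k_B T in kcal/mol (0.59616 kcal/mol at 300 K).
#' @export
kT <- function(temperature = 300) kBoltzmann() * temperature

#' Periodicity mask of the six-dimensional CV vector
#'
#' The descriptor space is (d, thetaA, thetaB, phiA, phiB, phiC); only the
#' three dihedrals are periodic on (-pi, pi].
#'
#' @return Logical vector of length 6.
#' @export
cvPeriodicMask <- function() {
  c(d = FALSE, thetaA = FALSE, thetaB = FALSE,
    phiA = TRUE, phiB = TRUE, phiC = TRUE)
}

#' Wrap angles into (-pi, pi]
#'
#' @param x Numeric vector of angles in radians.
#' @return Wrapped angles; exactly -pi maps to +pi.
#' @export
wrapAngle <- function(x) {
  y <- x - 2 * pi * round(x / (2 * pi))
  y[y <= -pi] <- y[y <= -pi] + 2 * pi
  y
}

## Pseudo-inverse of a symmetric PSD matrix via eigendecomposition with an
## eigenvalue floor relative to the largest eigenvalue.
psdPinv <- function(M, floor = 1e-12) {
  if (!is.matrix(M)) M <- as.matrix(M)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lmax <- max(abs(e$values), .Machine$double.xmin)
  inv <- ifelse(e$values > floor * lmax, 1 / e$values, 0)
  e$vectors %*% (inv * t(e$vectors))
}

## Deterministic per-stream seed derived from a master seed and an index.
## Kept strictly below 2^31 so it is always a valid R integer seed.
deriveSeed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807 + 12345) %%
               2147483629)
}

vnorm <- function(v) sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## coords: n x 3 matrix -> flat c(x1,y1,z1,x2,...) and back
flattenCoords <- function(coords) as.vector(t(coords))

unflattenCoords <- function(x) matrix(x, ncol = 3, byrow = TRUE)

## Componentwise difference with periodic wrap on masked components.
maskedDiff <- function(a, b, mask) {
  d <- a - b
  if (any(mask)) d[mask] <- wrapAngle(d[mask])
  d
}

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
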