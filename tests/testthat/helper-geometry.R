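# Shared fixtures and independent oracles for the geometry layer.

# A frame where every anchor is its own single atom: atoms 1..6 are
# P1, P2, P3, L1, L2, L3 (0-based indices 0..5).
singleAtomFrame <- function() {
  anchorFrame(
    protein = list(anchorGroup(0, "P1"), anchorGroup(1, "P2"), anchorGroup(2, "P3")),
    ligand = list(anchorGroup(3, "L1"), anchorGroup(4, "L2"), anchorGroup(5, "L3"))
  )
}

# Random non-degenerate 6-point configuration (rows P1..P3, L1..L3).
randomAnchorConfig <- function(seed) {
  set.seed(seed)
  repeat {
    x <- matrix(stats::rnorm(18, sd = 2), 6, 3)
    x[4, ] <- x[4, ] + c(4, 0, 0) # keep the species apart so d > 0
    x[5, ] <- x[5, ] + c(4, 0, 0)
    x[6, ] <- x[6, ] + c(4, 0, 0)
    ok <- tryCatch({
      cv <- computeCVs(x, singleAtomFrame())
      all(is.finite(cv)) && cv["d"] > 0.5 &&
        min(cv["thetaA"], pi - cv["thetaA"]) > 0.15 &&
        min(cv["thetaB"], pi - cv["thetaB"]) > 0.15
    }, error = function(e) FALSE)
    if (ok) return(x)
  }
}

# Independent CV oracle: acos/cos formulas and a triple-product sign,
# deliberately different from the package's atan2 construction.
oracleCVs <- function(pts) {
  ang <- function(a, b, c) {
    u <- a - b; v <- c - b
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }
  dih <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
    phi <- acos(max(-1, min(1, cosphi)))
    if (sum(n1 * b3) < 0) phi <- -phi
    phi
  }
  c(d = sqrt(sum((pts[1, ] - pts[4, ])^2)),
    thetaA = ang(pts[2, ], pts[1, ], pts[4, ]),
    thetaB = ang(pts[1, ], pts[4, ], pts[5, ]),
    phiA = dih(pts[3, ], pts[2, ], pts[1, ], pts[4, ]),
    phiB = dih(pts[2, ], pts[1, ], pts[4, ], pts[5, ]),
    phiC = dih(pts[1, ], pts[4, ], pts[5, ], pts[6, ]))
}

# Central finite-difference Jacobian of the six CVs (dihedrals wrapped).
fdJacobian <- function(coords, frame, h = 1e-5) {
  mask <- unname(cvPeriodicMask())
  n <- nrow(coords)
  J <- matrix(0, 6, 3 * n)
  for (i in seq_len(n)) {
    for (k in 1:3) {
      cp <- coords; cp[i, k] <- cp[i, k] + h
      cm <- coords; cm[i, k] <- cm[i, k] - h
      dcv <- maskedDiffTest(computeCVs(cp, frame), computeCVs(cm, frame), mask)
      J[, 3 * (i - 1) + k] <- dcv / (2 * h)
    }
  }
  J
}

maskedDiffTest <- function(a, b, mask) {
  d <- as.numeric(a) - as.numeric(b)
  d[mask] <- d[mask] - 2 * pi * round(d[mask] / (2 * pi))
  d
}

# Random proper rotation matrix.
randomRotation <- function(seed) {
  set.seed(seed)
  qr <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
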