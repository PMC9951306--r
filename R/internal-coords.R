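# Analytic gradients of internal coordinates with respect to Cartesian
# positions. Angles are handled in degrees to match measure_cnnc; the
# radian-space formulas (Blondel & Karplus form for the dihedral) are
# scaled by 180/pi. Both are finite-difference checked in the test suite.

# gradient of the signed dihedral p1-p2-p3-p4 (degrees) wrt the four
# atom positions; returns a 4 x 3 matrix
.dihedral_grad <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  n1sq <- sum(n1^2); n2sq <- sum(n2^2)
  nb2 <- sqrt(sum(b2^2))
  if (n1sq < 1e-14 || n2sq < 1e-14)
    return(matrix(NaN, 4, 3))
  F1 <- -(nb2 / n1sq) * n1
  F4 <- (nb2 / n2sq) * n2
  t12 <- sum(b1 * b2) / nb2^2
  t32 <- sum(b3 * b2) / nb2^2
  F2 <- -(1 + t12) * F1 + t32 * F4
  F3 <- t12 * F1 - (1 + t32) * F4
  rbind(F1, F2, F3, F4) * (180 / pi)
}

# gradient of the bond angle p1-p2-p3 (degrees) wrt the three positions;
# returns a 3 x 3 matrix
.angle_grad <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  uh <- u / nu; vh <- v / nv
  cth <- max(-1, min(1, sum(uh * vh)))
  sth <- sqrt(max(1e-18, 1 - cth^2))
  d1 <- (cth * uh - vh) / (nu * sth)
  d3 <- (cth * vh - uh) / (nv * sth)
  rbind(d1, -(d1 + d3), d3) * (180 / pi)
}
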