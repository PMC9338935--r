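# Small 3D geometry kernel shared by all analysis modules.
# Angles are in degrees throughout, wrapped to (-180, 180].

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[!is.na(w) & w == -180] <- 180
  w
}

# Rotation matrix about an arbitrary unit axis (Rodrigues), angle in degrees.
rotation_about <- function(axis, angle) {
  u <- unitv(axis)
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

#' Angle subtended at b by a and c
#'
#' @param a,b,c 3-vectors (positions, Angstrom).
#' @return angle in degrees.
#' @export
bond_angle <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  cosang <- sum(v1 * v2) / (vnorm(v1) * vnorm(v2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Signed dihedral angle of four points
#'
#' Standard IUPAC convention: looking from `b` to `c`, the angle from the
#' plane (a,b,c) to the plane (b,c,d), positive clockwise.
#'
#' @param a,b,c,d 3-vectors (positions, Angstrom).
#' @return dihedral in degrees in (-180, 180], or `NA` if any point is missing.
#' @export
dihedral_angle <- function(a, b, c, d) {
  if (anyNA(c(a, b, c, d))) return(NA_real_)
  b1 <- c - b
  b1n <- b1 / vnorm(b1)
  v <- (a - b) - sum((a - b) * b1n) * b1n
  w <- (d - c) - sum((d - c) * b1n) * b1n
  x <- sum(v * w)
  y <- sum(cross3(b1n, v) * w)
  atan2(y, x) * 180 / pi
}

# Least-squares rigid superposition (Kabsch, SVD with chirality guard).
# Returns list(R, t, rmsd) with y ~ R %*% x + t for row-matrices X -> Y.
kabsch_fit <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y), ncol(X) == 3, ncol(Y) == 3)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- t(Xc) %*% Yc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cy - as.vector(R %*% cx)
  fit <- sweep(Xc %*% t(R), 2, cy, "+")
  rmsd <- sqrt(mean(rowSums((fit - Y)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

# --- CEHS / mid-frame helix parameter algebra -------------------------------
#
# A frame is a 3x3 orthonormal matrix whose columns are the x, y, z axes in
# global coordinates, plus an origin.  decompose() expresses frame 2 relative
# to frame 1 as (tilt, roll, twist | d1, d2, d3) using the symmetric
# mid-frame construction; compose()/halves() are its exact inverses, used by
# the fiber generator so that generated parameters are recovered bit-exactly.

cehs_decompose <- function(R1, o1, R2, o2) {
  z1 <- R1[, 3]; z2 <- R2[, 3]
  cr <- cross3(z1, z2)
  gamma <- atan2(vnorm(cr), sum(z1 * z2)) * 180 / pi
  if (vnorm(cr) < 1e-10) {
    h <- R1[, 1]  # arbitrary: no bend, hinge unused
    R1p <- R1; R2p <- R2
  } else {
    h <- unitv(cross3(z1, z2))
    R1p <- rotation_about(h, +gamma / 2) %*% R1
    R2p <- rotation_about(h, -gamma / 2) %*% R2
  }
  zm <- R1p[, 3]
  # twist: signed angle from x1' to x2' about the common z
  x1 <- R1p[, 1]; x2 <- R2p[, 1]
  twist <- atan2(sum(cross3(x1, x2) * zm), sum(x1 * x2)) * 180 / pi
  Rm <- rotation_about(zm, twist / 2) %*% R1p
  tilt <- gamma * sum(h * Rm[, 1])
  roll <- gamma * sum(h * Rm[, 2])
  d <- as.vector(t(Rm) %*% (o2 - o1))
  list(tilt = tilt, roll = roll, twist = twist,
       d1 = d[1], d2 = d[2], d3 = d[3],
       Rm = Rm, om = (o1 + o2) / 2)
}

# Split a mid-frame into the two flanking frames that decompose to `par`.
cehs_halves <- function(Rm, om, tilt, roll, twist, d1 = 0, d2 = 0, d3 = 0) {
  gamma <- sqrt(tilt^2 + roll^2)
  R1p <- rotation_about(Rm[, 3], -twist / 2) %*% Rm
  R2p <- rotation_about(Rm[, 3], +twist / 2) %*% Rm
  if (gamma < 1e-12) {
    R1 <- R1p; R2 <- R2p
  } else {
    h <- as.vector(Rm %*% c(tilt / gamma, roll / gamma, 0))
    R1 <- rotation_about(h, -gamma / 2) %*% R1p
    R2 <- rotation_about(h, +gamma / 2) %*% R2p
  }
  dv <- as.vector(Rm %*% c(d1, d2, d3))
  list(R1 = R1, o1 = om - dv / 2, R2 = R2, o2 = om + dv / 2)
}

# Given frame 1 and step parameters, construct frame 2 (exact inverse of
# cehs_decompose; solved by fixed-point iteration on the hinge axis).
cehs_compose <- function(R1, o1, tilt, roll, twist, d1 = 0, d2 = 0, d3 = 0) {
  gamma <- sqrt(tilt^2 + roll^2)
  if (gamma < 1e-12) {
    R1p <- R1
    zm <- R1p[, 3]
    Rm <- rotation_about(zm, twist / 2) %*% R1p
    R2 <- rotation_about(zm, twist) %*% R1p
  } else {
    hm <- c(tilt / gamma, roll / gamma, 0)
    h <- as.vector(R1 %*% hm)
    for (it in 1:25) {
      R1p <- rotation_about(h, +gamma / 2) %*% R1
      Rm <- rotation_about(R1p[, 3], twist / 2) %*% R1p
      hnew <- as.vector(Rm %*% hm)
      if (vnorm(hnew - h) < 1e-14) { h <- hnew; break }
      h <- hnew
    }
    R1p <- rotation_about(h, +gamma / 2) %*% R1
    Rm <- rotation_about(R1p[, 3], twist / 2) %*% R1p
    R2 <- rotation_about(h, +gamma / 2) %*%
      rotation_about(R1p[, 3], twist) %*% R1p
  }
  o2 <- o1 + as.vector(Rm %*% c(d1, d2, d3))
  list(R2 = R2, o2 = o2, Rm = Rm)
}

# y-z flip used to express the complementary strand in the pair frame
.pair_flip <- diag(c(1, -1, -1))
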