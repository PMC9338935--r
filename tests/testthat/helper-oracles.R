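# Independent oracles used to cross-check the package's geometry kernels.
# Each deliberately uses a different algorithm than the implementation.

# Dihedral by rotational search: rotate D about the B->C axis until it
# eclipses A (dihedral zero); the original dihedral is minus that rotation.
oracle_dihedral <- function(a, b, c, d) {
  axis <- c - b
  axis <- axis / sqrt(sum(axis^2))
  rot <- function(p, theta) {
    # Rodrigues rotation of p (relative to c) about axis
    v <- p - c
    th <- theta * pi / 180
    vr <- v * cos(th) + pracma_cross(axis, v) * sin(th) +
      axis * sum(axis * v) * (1 - cos(th))
    vr + c
  }
  # alignment score: cosine between the perpendicular components of A and
  # rotated D; maximized when eclipsed
  perp <- function(p, ref) {
    v <- p - ref
    v - sum(v * axis) * axis
  }
  score <- function(theta) {
    vD <- perp(rot(d, theta), c)
    vA <- perp(a, b)
    sum(vA * vD) / sqrt(sum(vA^2) * sum(vD^2))
  }
  # out-of-plane (sine-like) component: crosses zero steeply at eclipse
  oop <- function(theta) {
    vD <- perp(rot(d, theta), c)
    vA <- perp(a, b)
    sum(pracma_cross(vA, vD) * axis) / sqrt(sum(vA^2) * sum(vD^2))
  }
  grid <- seq(-180, 179, by = 1)
  s <- vapply(grid, score, numeric(1))
  t0 <- grid[which.max(s)]
  th <- stats::uniroot(oop, c(t0 - 1.5, t0 + 1.5), tol = 1e-14,
                       extendInt = "yes")$root
  w <- (-th + 180) %% 360 - 180
  if (w == -180) w <- 180
  w
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rigid superposition RMSD by the quaternion (Horn) eigen-decomposition,
# independent of the SVD route used in the package.
oracle_superpose_rmsd <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  S <- t(Xc) %*% Yc
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Xc^2) + sum(Yc^2) - 2 * lmax) / nrow(X)
  sqrt(max(0, msd))
}

# Brute-force all-pairs contact scan (double loop, no vectorization).
oracle_contacts <- function(modelA, modelB, cutoff, inclusive = FALSE) {
  A <- as.data.frame(modelA); B <- as.data.frame(modelB)
  A <- A[!(A$elem %in% c("H", "D")), ]; B <- B[!(B$elem %in% c("H", "D")), ]
  out <- NULL
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 + (A$z[i] - B$z[j])^2)
    ok <- if (inclusive) d <= cutoff else d < cutoff
    if (ok) out <- rbind(out, data.frame(i = i, j = j, d = d))
  }
  out
}

# Exhaustive groove minimum: all opposite-strand phosphates whose aligned
# offset (in the strand's own 5'->3' sense) falls inside the window.
oracle_groove_min <- function(model, numbering, window = c(-5, -2)) {
  dna <- select_component(model, "dna")
  a <- as.data.frame(dna)
  P <- a[a$elety == "P", ]
  kn <- paste(numbering$chain, numbering$resno, sep = "\r")
  m <- match(paste(P$chain, P$resno, sep = "\r"), kn)
  idx <- numbering$index[m]; strand <- numbering$strand[m]
  res <- NULL
  for (i in seq_len(nrow(P))) {
    sgn <- if (strand[i] == "c") 1 else -1
    best <- Inf
    for (j in seq_len(nrow(P))) {
      if (strand[j] == strand[i]) next
      off <- sgn * (idx[j] - idx[i])
      if (off < window[1] || off > window[2]) next
      d <- sqrt((P$x[i] - P$x[j])^2 + (P$y[i] - P$y[j])^2 + (P$z[i] - P$z[j])^2)
      best <- min(best, d)
    }
    res <- rbind(res, data.frame(index = idx[i], strand = strand[i],
                                 dmin = ifelse(is.finite(best), best, NA)))
  }
  res
}

# Random rigid transform applied to a structure model.
random_rigid_motion <- function(model, seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 10, 170) * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) * cos(th) + sin(th) * K + (1 - cos(th)) * (ax %o% ax)
  t <- runif(3, -30, 30)
  a <- as.data.frame(model)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + t[1]; a$y <- xyz[, 2] + t[2]; a$z <- xyz[, 3] + t[3]
  out <- structure_model(a, source = attr(model, "source"))
  attr(out, "fiber") <- attr(model, "fiber")
  out
}

random_sequence <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                            replace = TRUE), collapse = "")

revcomp <- function(s) {
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

hmpa1_seq <- "AACACGAATATCATCTACCAATT"

# Strip model class/metadata for whole-table identity comparisons.
plain_atoms <- function(m) {
  a <- as.data.frame(m)
  a <- data.frame(a, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(a) <- NULL
  a
}
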