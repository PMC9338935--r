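# Solvent-accessible surface area by Shrake-Rupley sphere sampling with a
# deterministic Fibonacci point lattice (no RNG; results are reproducible
# bit for bit), and buried surface areas between chain groups.

.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
                Fe = 1.40, H = 1.20, D = 1.20)

# Deterministic quasi-uniform unit-sphere points (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA by sampling `n_points` quasi-uniform points on each
#' solvent-expanded atom sphere and counting those not buried inside any
#' neighboring sphere.  Waters are excluded by default; hydrogens always.
#' An element without a tabulated van der Waals radius is an error naming
#' the atom -- no silent default radius.
#'
#' @param model a [structure_model()].
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points sample points per atom (default 960).
#' @param radii named vector of van der Waals radii (Angstrom) extending /
#'   overriding the built-in set (C 1.70, N 1.55, O 1.52, P 1.80, S 1.80,
#'   Fe 1.40).
#' @param include_waters include water molecules (default FALSE).
#' @return object of class `sasa_result`: list with `atom` (per-atom
#'   table including `area`), `total` (Angstrom^2), `per_residue`,
#'   `per_chain`, and the parameters used.
#' @export
shrake_rupley_sasa <- function(model, probe = 1.4, n_points = 960,
                               radii = NULL, include_waters = FALSE) {
  a <- as.data.frame(model)
  if (!include_waters) a <- a[classify_residue(a$resid) != "water", , drop = FALSE]
  a <- a[!(a$elem %in% c("H", "D")), , drop = FALSE]
  if (!nrow(a)) stop("no atoms to compute SASA for")
  rtab <- .vdw_radii
  if (!is.null(radii)) rtab[names(radii)] <- radii
  r <- rtab[a$elem]
  if (anyNA(r)) {
    bad <- which(is.na(r))[1]
    stop("no van der Waals radius for element '", a$elem[bad], "' (atom ",
         a$chain[bad], ":", a$resno[bad], " ", a$elety[bad], ")")
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  rs <- r + probe
  pts <- fibonacci_sphere(n_points)
  area <- numeric(n)
  maxr <- max(rs)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (rs[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (rs[i] + rs[nb])^2]
    if (!length(nb)) { area[i] <- 4 * pi * rs[i]^2; next }
    sp <- sweep(pts * rs[i], 2, xyz[i, ], "+")
    alive <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(alive)) break
      dj <- colSums((t(sp[alive, , drop = FALSE]) - xyz[j, ])^2)
      alive[alive] <- dj >= rs[j]^2
    }
    area[i] <- 4 * pi * rs[i]^2 * sum(alive) / n_points
  }
  at <- data.frame(a[, c("chain", "resno", "icode", "resid", "elety", "elem")],
                   area = area, stringsAsFactors = FALSE)
  per_res <- stats::aggregate(list(area = area),
                              by = list(chain = at$chain, resno = at$resno,
                                        resid = at$resid), FUN = sum)
  per_chain <- stats::aggregate(list(area = area),
                                by = list(chain = at$chain), FUN = sum)
  structure(list(atom = at, total = sum(area), per_residue = per_res,
                 per_chain = per_chain, probe = probe, n_points = n_points,
                 radii = rtab),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("sasa_result: total", round(x$total, 1), "A^2 over", nrow(x$atom),
      "atoms (probe", x$probe, "A,", x$n_points, "points/atom)\n")
  invisible(x)
}

#' Buried surface area between two groups
#'
#' BSA = SASA(A alone) + SASA(B alone) - SASA(A and B together).  The two
#' groups are isolated by selection: atoms belonging to neither group are
#' excluded from all three computations, they do not shadow the interface.
#'
#' @param model a [structure_model()] containing both groups.
#' @param groupA,groupB selectors understood by [select_component()], or
#'   [structure_model()]s taken as literal atom sets.
#' @param ... passed to [shrake_rupley_sasa()] (probe, n_points, radii).
#' @return numeric BSA in Angstrom^2, with attribute `sasa` carrying the
#'   three group totals.
#' @export
buried_surface_area <- function(model, groupA, groupB, ...) {
  gA <- if (inherits(groupA, "structure_model")) groupA
        else select_component(model, groupA)
  gB <- if (inherits(groupB, "structure_model")) groupB
        else select_component(model, groupB)
  kA <- with(as.data.frame(gA), paste(chain, resno, icode, elety))
  kB <- with(as.data.frame(gB), paste(chain, resno, icode, elety))
  if (length(intersect(kA, kB)))
    stop("groups overlap: ", length(intersect(kA, kB)), " shared atoms")
  both <- structure_model(rbind(as.data.frame(gA), as.data.frame(gB)),
                          source = attr(model, "source"))
  sA <- shrake_rupley_sasa(gA, ...)
  sB <- shrake_rupley_sasa(gB, ...)
  sAB <- shrake_rupley_sasa(both, ...)
  bsa <- sA$total + sB$total - sAB$total
  attr(bsa, "sasa") <- c(A = sA$total, B = sB$total, AB = sAB$total)
  bsa
}
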