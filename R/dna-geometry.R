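# Nucleic-acid geometry: backbone torsions, B_I/B_II substates, base-pair
# detection, base reference frames, and pair/step helical parameters by the
# mid-frame (CEHS-style) construction.

.purine <- c("DA", "DG")
.base_letter <- function(resid) {
  l <- sub("^D", "", toupper(resid))
  ifelse(l %in% c("A", "C", "G", "T"), l, NA_character_)
}

.base_ring <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  T = c("N1", "C2", "N3", "C4", "C5", "C6"))

#' Backbone and glycosidic torsion angles of a DNA duplex
#'
#' Computes alpha, beta, gamma, delta, epsilon, zeta and chi for every
#' nucleotide, using the standard signed-dihedral definitions.  A torsion
#' whose defining atoms are absent (chain termini, missing phosphates) is
#' `NA`, never zero.  The 5'-terminal nucleotide has no alpha/beta (no
#' phosphate), the 3'-terminal one no epsilon/zeta.
#'
#' @param model a [structure_model()]; only DNA residues are used.
#' @return data.frame, one row per nucleotide, with the seven torsions plus
#'   `eps_minus_zeta` (degrees, wrapped to (-180, 180]).
#' @export
backbone_torsions <- function(model) {
  dna <- select_component(model, "dna")
  res <- residue_table(dna)
  P   <- atom_coords(dna, "P");    O5 <- atom_coords(dna, "O5'")
  C5  <- atom_coords(dna, "C5'");  C4 <- atom_coords(dna, "C4'")
  C3  <- atom_coords(dna, "C3'");  O3 <- atom_coords(dna, "O3'")
  C1  <- atom_coords(dna, "C1'");  O4 <- atom_coords(dna, "O4'")
  n <- nrow(res)
  out <- data.frame(res[, c("chain", "resno", "icode", "resid")],
                    alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
                    delta = NA_real_, epsilon = NA_real_, zeta = NA_real_,
                    chi = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    prev <- if (i > 1 && res$chain[i - 1] == res$chain[i]) i - 1 else NA
    nxt  <- if (i < n && res$chain[i + 1] == res$chain[i]) i + 1 else NA
    if (!is.na(prev))
      out$alpha[i] <- dihedral_angle(O3[prev, ], P[i, ], O5[i, ], C5[i, ])
    out$beta[i]  <- dihedral_angle(P[i, ], O5[i, ], C5[i, ], C4[i, ])
    out$gamma[i] <- dihedral_angle(O5[i, ], C5[i, ], C4[i, ], C3[i, ])
    out$delta[i] <- dihedral_angle(C5[i, ], C4[i, ], C3[i, ], O3[i, ])
    if (!is.na(nxt)) {
      out$epsilon[i] <- dihedral_angle(C4[i, ], C3[i, ], O3[i, ], P[nxt, ])
      out$zeta[i]    <- dihedral_angle(C3[i, ], O3[i, ], P[nxt, ], O5[nxt, ])
    }
    # chi: O4'-C1'-N9-C4 (purines) / O4'-C1'-N1-C2 (pyrimidines)
    ra <- residue_atoms(dna, res$chain[i], res$resno[i], res$icode[i])
    pur <- toupper(res$resid[i]) %in% .purine
    nat <- if (pur) "N9" else "N1"
    cat2 <- if (pur) "C4" else "C2"
    gN <- ra[ra$elety == nat, c("x", "y", "z")]
    gC <- ra[ra$elety == cat2, c("x", "y", "z")]
    if (nrow(gN) == 1 && nrow(gC) == 1)
      out$chi[i] <- dihedral_angle(O4[i, ], C1[i, ],
                                   as.numeric(gN), as.numeric(gC))
  }
  out$eps_minus_zeta <- wrap_angle(out$epsilon - out$zeta)
  out
}

#' Classify backbone substates from epsilon - zeta
#'
#' B-DNA backbones populate two substates distinguished by the epsilon and
#' zeta torsions about the 3'-phosphodiester: B_I (epsilon - zeta around
#' -90 degrees) and B_II (around +90).  A symmetric dead zone of width
#' 2 * `band` around zero is reported as `intermediate`; missing torsions
#' give `undefined`.  Classification is monotone in epsilon - zeta.
#'
#' @param x numeric vector of epsilon - zeta values (degrees), or the
#'   data.frame returned by [backbone_torsions()].
#' @param band half-width of the intermediate zone (degrees, default 45).
#' @return factor with levels `BI`, `intermediate`, `BII`, `undefined`.
#' @export
classify_backbone_state <- function(x, band = 45) {
  if (is.data.frame(x)) x <- x$eps_minus_zeta
  x <- wrap_angle(x)
  out <- ifelse(is.na(x), "undefined",
                ifelse(x <= -band, "BI",
                       ifelse(x >= band, "BII", "intermediate")))
  factor(out, levels = c("BI", "intermediate", "BII", "undefined"))
}

#' Fit the reference frame of one base
#'
#' Least-squares superposition (Kabsch) of the idealized base geometry onto
#' the observed ring atoms.  The returned rotation columns are the x, y, z
#' axes of the fitted standard frame in global coordinates; the origin is
#' the fitted position of the standard-frame origin.
#'
#' @param atoms data.frame of one nucleotide's atoms (rows of a
#'   [structure_model()]).
#' @return list with `origin` (3-vector), `R` (3x3), `rmsd` (Angstrom) and
#'   `base` (letter), or `NULL` when fewer than 6 ring atoms are present.
#' @export
base_frame <- function(atoms) {
  b <- .base_letter(atoms$resid[1])
  if (is.na(b)) stop("not a standard nucleotide: ", atoms$resid[1])
  ring <- .base_ring[[b]]
  std <- .base_geom[[b]]
  common <- intersect(ring, atoms$elety)
  if (length(common) < 6) return(NULL)
  X <- std[common, , drop = FALSE]
  Y <- as.matrix(atoms[match(common, atoms$elety), c("x", "y", "z")])
  fit <- kabsch_fit(X, Y)
  list(origin = as.vector(fit$t), R = fit$R, rmsd = fit$rmsd, base = b)
}

#' Detect Watson-Crick base pairs geometrically
#'
#' Candidate pairs must have a C1'-C1' distance of 10.4 +/- 1.6 Angstrom,
#' at least two inter-base N/O atom pairs within 3.5 Angstrom, and base
#' planes inclined by at most 65 degrees.  Each nucleotide joins at most
#' one pair (best H-bond support wins); pairs are ordered 5' to 3' along
#' the reference strand.  Complementary base identities are typed `WC`,
#' anything else `other`.
#'
#' @param model a [structure_model()] with at least two DNA strands (or a
#'   self-folding chain; pairing within a chain requires a separation of
#'   more than 2 residues).
#' @param reference_chain chain id of the strand to order by (default:
#'   first DNA chain).
#' @return data.frame with strand-c and strand-d residue identifiers, base
#'   letters and pair `type`.  Zero rows (with a diagnostic attribute) when
#'   nothing pairs.
#' @export
detect_base_pairs <- function(model, reference_chain = NULL) {
  dna <- select_component(model, "dna")
  res <- residue_table(dna)
  if (is.null(reference_chain)) reference_chain <- res$chain[1]
  n <- nrow(res)
  C1 <- atom_coords(dna, "C1'")
  a <- as.data.frame(dna)
  akey <- paste(a$chain, a$resno, a$icode, sep = "\r")
  frames <- vector("list", n)
  basemats <- vector("list", n)
  for (i in seq_len(n)) {
    ra <- a[akey == res$key[i], , drop = FALSE]
    b <- .base_letter(res$resid[i])
    if (is.na(b)) next
    frames[[i]] <- base_frame(ra)
    sel <- ra$elety %in% setdiff(rownames(.base_geom[[b]]), "C1'") &
      ra$elem %in% c("N", "O")
    basemats[[i]] <- ra[sel, c("elety", "x", "y", "z")]
  }
  cand <- NULL
  for (i in seq_len(n)) {
    if (is.null(frames[[i]]) || anyNA(C1[i, ])) next
    for (j in seq_len(n)) {
      if (j <= i) next
      if (res$chain[i] == res$chain[j] && abs(j - i) <= 2) next
      if (is.null(frames[[j]]) || anyNA(C1[j, ])) next
      dc1 <- vnorm(C1[i, ] - C1[j, ])
      if (dc1 < 10.4 - 1.6 || dc1 > 10.4 + 1.6) next
      zi <- frames[[i]]$R[, 3]; zj <- frames[[j]]$R[, 3]
      ang <- acos(max(-1, min(1, abs(sum(zi * zj))))) * 180 / pi
      if (ang > 65) next
      # coplanarity: stacked neighbors sit ~one rise above/below, true
      # partners have near-zero vertical separation along the pair normal
      zj_al <- if (sum(zi * zj) < 0) -zj else zj
      nm <- unitv(zi + zj_al)
      vert <- abs(sum((frames[[i]]$origin - frames[[j]]$origin) * nm))
      if (vert > 2.0) next
      Bi <- basemats[[i]]; Bj <- basemats[[j]]
      if (!nrow(Bi) || !nrow(Bj)) next
      D <- sqrt(outer(rowSums(as.matrix(Bi[, 2:4])^2), rowSums(as.matrix(Bj[, 2:4])^2), "+") -
                  2 * as.matrix(Bi[, 2:4]) %*% t(as.matrix(Bj[, 2:4])))
      nhb <- sum(D <= 3.5)
      if (nhb < 2) next
      cand <- rbind(cand, data.frame(i = i, j = j, nhb = nhb,
                                     score = mean(D[D <= 3.5])))
    }
  }
  if (is.null(cand) || !nrow(cand)) {
    out <- data.frame(chain_c = character(), resno_c = integer(),
                      icode_c = character(), base_c = character(),
                      chain_d = character(), resno_d = integer(),
                      icode_d = character(), base_d = character(),
                      type = character(), stringsAsFactors = FALSE)
    attr(out, "diagnostic") <- "no base pairs found by the geometric criteria"
    return(out)
  }
  cand <- cand[order(-cand$nhb, cand$score), , drop = FALSE]
  used <- logical(n); keep <- integer(0)
  for (k in seq_len(nrow(cand))) {
    if (used[cand$i[k]] || used[cand$j[k]]) next
    used[cand$i[k]] <- used[cand$j[k]] <- TRUE
    keep <- c(keep, k)
  }
  cand <- cand[keep, , drop = FALSE]
  # orient: strand c on the reference chain where possible
  ci <- ifelse(res$chain[cand$i] == reference_chain, cand$i, cand$j)
  di <- ifelse(res$chain[cand$i] == reference_chain, cand$j, cand$i)
  ord <- order(match(ci, which(res$chain == reference_chain)))
  ci <- ci[ord]; di <- di[ord]
  bc <- .base_letter(res$resid[ci]); bd <- .base_letter(res$resid[di])
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  data.frame(chain_c = res$chain[ci], resno_c = res$resno[ci],
             icode_c = res$icode[ci], base_c = bc,
             chain_d = res$chain[di], resno_d = res$resno[di],
             icode_d = res$icode[di], base_d = bd,
             type = ifelse(!is.na(bc) & !is.na(bd) & comp[bc] == bd,
                           "WC", "other"),
             stringsAsFactors = FALSE)
}

#' Base-pair and step parameters
#'
#' Intra-pair parameters (buckle, propeller, opening and the shear /
#' stretch / stagger displacements) and inter-pair step parameters (tilt,
#' roll, twist, shift, slide, rise) by the symmetric mid-frame
#' construction.  The strand-d base frame is flipped about its x axis
#' before comparison, propeller is the roll-like component of the
#' intra-pair rotation (negative for the usual B-DNA propeller), and the
#' base-pair origin is the midpoint of the two fitted base origins.
#'
#' @param model a [structure_model()].
#' @param pairs base-pair table from [detect_base_pairs()] (detected when
#'   `NULL`); every nucleotide listed must resolve a base frame.
#' @return list with data.frames `pairs` (per base pair, including origin
#'   and frame columns) and `steps` (per consecutive pair step).
#' @export
bp_and_step_parameters <- function(model, pairs = NULL) {
  dna <- select_component(model, "dna")
  if (is.null(pairs)) pairs <- detect_base_pairs(dna)
  if (!nrow(pairs)) stop("no base pairs to parameterize")
  a <- as.data.frame(dna)
  akey <- paste(a$chain, a$resno, a$icode, sep = "\r")
  np <- nrow(pairs)
  Rbp <- vector("list", np); obp <- vector("list", np)
  out <- data.frame(pairs,
                    buckle = NA_real_, propeller = NA_real_, opening = NA_real_,
                    shear = NA_real_, stretch = NA_real_, stagger = NA_real_,
                    ox = NA_real_, oy = NA_real_, oz = NA_real_)
  for (k in seq_len(np)) {
    rc <- a[akey == paste(pairs$chain_c[k], pairs$resno_c[k], pairs$icode_c[k],
                          sep = "\r"), , drop = FALSE]
    rd <- a[akey == paste(pairs$chain_d[k], pairs$resno_d[k], pairs$icode_d[k],
                          sep = "\r"), , drop = FALSE]
    fc <- base_frame(rc); fd <- base_frame(rd)
    if (is.null(fc) || is.null(fd))
      stop("cannot resolve a base frame for pair ", k,
           " (", pairs$chain_c[k], pairs$resno_c[k], "/",
           pairs$chain_d[k], pairs$resno_d[k], ")")
    Rdf <- fd$R %*% .pair_flip
    dec <- cehs_decompose(Rdf, fd$origin, fc$R, fc$origin)
    out$buckle[k] <- dec$tilt; out$propeller[k] <- dec$roll
    out$opening[k] <- dec$twist
    out$shear[k] <- dec$d1; out$stretch[k] <- dec$d2; out$stagger[k] <- dec$d3
    Rbp[[k]] <- dec$Rm; obp[[k]] <- dec$om
    out[k, c("ox", "oy", "oz")] <- dec$om
  }
  steps <- NULL
  if (np >= 2) {
    steps <- data.frame(step = seq_len(np - 1),
                        tilt = NA_real_, roll = NA_real_, twist = NA_real_,
                        shift = NA_real_, slide = NA_real_, rise = NA_real_)
    for (k in seq_len(np - 1)) {
      dec <- cehs_decompose(Rbp[[k]], obp[[k]], Rbp[[k + 1]], obp[[k + 1]])
      steps$tilt[k] <- dec$tilt; steps$roll[k] <- dec$roll
      steps$twist[k] <- dec$twist
      steps$shift[k] <- dec$d1; steps$slide[k] <- dec$d2; steps$rise[k] <- dec$d3
    }
  }
  list(pairs = out, steps = steps,
       frames = Rbp, origins = obp)
}

#' Average roll over an operator region
#'
#' Arithmetic mean of the step roll over all steps lying fully inside the
#' region.  When `numbering` is given, `region` is an operator index range
#' (e.g. `c(-5, 5)` for the central 11 bp); otherwise it indexes steps
#' directly.
#'
#' @param params result of [bp_and_step_parameters()], or its `steps` table.
#' @param region length-2 numeric range (inclusive).
#' @param numbering optional operator numbering table
#'   ([assign_operator_numbering()]) used to translate the region into
#'   step positions via the strand-c indices of the flanking pairs.
#' @return mean roll in degrees.
#' @export
region_average_roll <- function(params, region, numbering = NULL) {
  steps <- if (is.data.frame(params)) params else params$steps
  if (is.null(steps) || !nrow(steps)) stop("no steps available")
  if (!is.null(numbering)) {
    if (is.data.frame(params)) stop("numbering requires the full parameter list")
    prs <- params$pairs
    kc <- paste(prs$chain_c, prs$resno_c, prs$icode_c, sep = "\r")
    kn <- paste(numbering$chain, numbering$resno, numbering$icode, sep = "\r")
    idx <- numbering$index[match(kc, kn)]
    inside <- idx >= region[1] & idx <= region[2]
    use <- which(inside[-length(inside)] & inside[-1])
  } else {
    use <- which(steps$step >= region[1] & steps$step <= region[2])
  }
  if (length(use) < 1) stop("region contains no complete step")
  mean(steps$roll[use])
}
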