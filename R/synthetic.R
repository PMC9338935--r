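# Synthetic structure generator: fiber-model B-DNA of arbitrary sequence,
# controlled step/backbone perturbations, and toy protein-like probe groups.
# The generator composes base-pair frames with the exact inverse of the
# analyzer's mid-frame decomposition, so that every builder parameter is
# recovered by the analysis stages (generator/analyzer closure).

.complement <- c(A = "T", T = "A", G = "C", C = "G")

.fiber_defaults <- list(twist = 36.0, rise = 3.38, roll = 0.0, tilt = 0.0,
                        shift = 0.0, slide = 0.0, propeller = 0.0,
                        buckle = 0.0, opening = 0.0)

#' Build an idealized fiber-model B-DNA duplex
#'
#' Constructs an all-heavy-atom double helix from idealized base and
#' B-form sugar-phosphate geometry.  Base-pair frames are chained with the
#' given helical step parameters (defaults: twist 36 degrees, rise 3.38
#' Angstrom, zero roll -- a straight duplex whose minimal cross-strand
#' phosphate P-P distance across the minor groove averages 11.7 Angstrom).
#' Strand c is chain `A`, running 5' to 3'; chain `B` is its reverse
#' complement.  5'-terminal nucleotides carry no phosphate group, as in
#' synthesized oligonucleotides.  Output is deterministic unless `jitter`
#' is positive.
#'
#' @param sequence string over A/C/G/T (strand c, 5' to 3', length >= 4).
#' @param twist,rise,roll,tilt,shift,slide per-step helical parameters;
#'   scalars or vectors of length `nchar(sequence) - 1` (degrees/Angstrom).
#' @param propeller,buckle,opening per-pair intra-pair parameters; scalars
#'   or vectors of length `nchar(sequence)` (degrees).
#' @param jitter standard deviation of optional Gaussian coordinate noise
#'   (Angstrom; default 0 = none).
#' @param seed integer seed used only when `jitter > 0`.
#' @return a [structure_model()] carrying the generator parameters in the
#'   `fiber` attribute.
#' @export
build_fiber_bdna <- function(sequence, twist = 36.0, rise = 3.38,
                             roll = 0.0, tilt = 0.0, shift = 0.0,
                             slide = 0.0, propeller = 0.0, buckle = 0.0,
                             opening = 0.0, jitter = 0.0, seed = NULL) {
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "")[[1]]
  bad <- which(!(bases %in% c("A", "C", "G", "T")))
  if (length(bad)) stop("invalid base '", bases[bad[1]], "' at position ", bad[1])
  n <- length(bases)
  if (n < 4) stop("sequence must have at least 4 bases")
  nst <- n - 1
  stepdf <- data.frame(twist = rep_len(twist, nst), rise = rep_len(rise, nst),
                       roll = rep_len(roll, nst), tilt = rep_len(tilt, nst),
                       shift = rep_len(shift, nst), slide = rep_len(slide, nst))
  pairdf <- data.frame(propeller = rep_len(propeller, n),
                       buckle = rep_len(buckle, n),
                       opening = rep_len(opening, n))
  # chain of bp frames
  Rbp <- vector("list", n); obp <- vector("list", n)
  Rbp[[1]] <- diag(3); obp[[1]] <- c(0, 0, 0)
  for (k in seq_len(nst)) {
    cmp <- cehs_compose(Rbp[[k]], obp[[k]], stepdf$tilt[k], stepdf$roll[k],
                        stepdf$twist[k], stepdf$shift[k], stepdf$slide[k],
                        stepdf$rise[k])
    Rbp[[k + 1]] <- cmp$R2; obp[[k + 1]] <- cmp$o2
  }
  place <- function(R, o, coords) sweep(coords %*% t(R), 2, o, "+")
  rows <- list(); ri <- 0
  add_res <- function(chain, resno, resid, R, o, with_phosphate) {
    b <- sub("^D", "", resid)
    coords <- rbind(.backbone_geom, .base_geom[[b]])
    if (!with_phosphate)
      coords <- coords[!(rownames(coords) %in% c("P", "OP1", "OP2")), , drop = FALSE]
    xyz <- place(R, o, coords)
    ri <<- ri + 1
    rows[[ri]] <<- data.frame(chain = chain, resno = resno, icode = "",
                              resid = resid, elety = rownames(coords),
                              elem = infer_element(rownames(coords)),
                              x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                              occ = 1, b = 0, alt = "",
                              stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    hv <- cehs_halves(Rbp[[i]], obp[[i]], pairdf$buckle[i], pairdf$propeller[i],
                      pairdf$opening[i])
    add_res("A", i, paste0("D", bases[i]), hv$R2, hv$o2, with_phosphate = i > 1)
  }
  for (j in seq_len(n)) {
    p <- n + 1 - j   # bp position of strand-d residue j
    hv <- cehs_halves(Rbp[[p]], obp[[p]], pairdf$buckle[p], pairdf$propeller[p],
                      pairdf$opening[p])
    Rd <- hv$R1 %*% .pair_flip
    add_res("B", j, paste0("D", .complement[bases[p]]), Rd, hv$o1,
            with_phosphate = j > 1)
  }
  atoms <- do.call(rbind, rows)
  if (jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, jitter)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, jitter)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, jitter)
  }
  m <- structure_model(atoms, source = "fiber-bdna",
                       title = paste0("fiber B-DNA duplex ", sequence))
  attr(m, "fiber") <- list(sequence = sequence, steps = stepdf, pairs = pairdf,
                           jitter = jitter, seed = seed)
  m
}

#' Perturb step parameters and backbone substates of a fiber duplex
#'
#' Rebuilds a fiber-generated duplex with selected step parameters
#' overridden, then optionally re-positions individual 3'-phosphates so
#' that epsilon - zeta takes a requested value (switching the classified
#' B_I/B_II substate).  The epsilon/zeta adjustment rotates the phosphate
#' group of the following nucleotide about the C3'-O3' bond of the target
#' nucleotide (sugar atoms fixed) and solves for the rotation angle; the
#' analyzed epsilon - zeta then matches the request to better than 1e-6
#' degrees at the cost of a strained P-O5' link.
#'
#' @param model a duplex built by [build_fiber_bdna()].
#' @param step_overrides data.frame with column `step` (1-based step index
#'   on strand c) plus any of `twist`, `roll`, `tilt`, `rise`, `shift`,
#'   `slide`.
#' @param eps_zeta_overrides data.frame with columns `chain`, `resno`
#'   (the nucleotide whose 3'-phosphate is adjusted) and `value` (target
#'   epsilon - zeta, degrees).
#' @return the rebuilt [structure_model()].
#' @export
apply_step_perturbations <- function(model, step_overrides = NULL,
                                     eps_zeta_overrides = NULL) {
  fib <- attr(model, "fiber")
  if (is.null(fib)) stop("model was not built by build_fiber_bdna()")
  no_steps <- is.null(step_overrides) || !nrow(step_overrides)
  no_ez <- is.null(eps_zeta_overrides) || !nrow(eps_zeta_overrides)
  if (no_steps && no_ez) return(model)
  steps <- fib$steps
  if (!no_steps) {
    if (any(step_overrides$step < 1 | step_overrides$step > nrow(steps)))
      stop("step override outside 1..", nrow(steps))
    for (col in intersect(names(step_overrides), names(steps)))
      steps[step_overrides$step, col] <- step_overrides[[col]]
  }
  out <- build_fiber_bdna(fib$sequence,
                          twist = steps$twist, rise = steps$rise,
                          roll = steps$roll, tilt = steps$tilt,
                          shift = steps$shift, slide = steps$slide,
                          propeller = fib$pairs$propeller,
                          buckle = fib$pairs$buckle,
                          opening = fib$pairs$opening)
  if (!no_ez) {
    for (k in seq_len(nrow(eps_zeta_overrides)))
      out <- .set_eps_zeta(out, eps_zeta_overrides$chain[k],
                           eps_zeta_overrides$resno[k],
                           eps_zeta_overrides$value[k])
  }
  out
}

# Rotate the 3'-phosphate group of (chain, resno) to a target eps - zeta.
.set_eps_zeta <- function(model, chain, resno, target) {
  a <- as.data.frame(model)
  res <- residue_table(model)
  i <- which(res$chain == chain & res$resno == resno)
  if (length(i) != 1) stop("no nucleotide ", chain, ":", resno)
  if (i == nrow(res) || res$chain[i + 1] != chain)
    stop("nucleotide ", chain, ":", resno, " has no 3'-phosphate")
  get <- function(ridx, name) {
    r <- a$chain == res$chain[ridx] & a$resno == res$resno[ridx] & a$elety == name
    if (!any(r)) stop("missing atom ", name)
    as.numeric(a[which(r)[1], c("x", "y", "z")])
  }
  C4 <- get(i, "C4'"); C3 <- get(i, "C3'"); O3 <- get(i, "O3'")
  O5n <- get(i + 1, "O5'")
  sel <- a$chain == chain & a$resno == res$resno[i + 1] &
    a$elety %in% c("P", "OP1", "OP2")
  grp <- as.matrix(a[sel, c("x", "y", "z")])
  Pidx <- which(a$elety[sel] == "P")
  axis <- O3 - C3
  ez <- function(alpha) {
    R <- rotation_about(axis, alpha)
    g <- sweep(sweep(grp, 2, O3) %*% t(R), 2, O3, "+")
    P <- g[Pidx, ]
    wrap_angle(dihedral_angle(C4, C3, O3, P) -
                 dihedral_angle(C3, O3, P, O5n))
  }
  f <- function(alpha) wrap_angle(ez(alpha) - target)
  grid <- seq(-180, 180, by = 2)
  vals <- vapply(grid, f, numeric(1))
  root <- NULL
  for (g in seq_len(length(grid) - 1)) {
    if (is.na(vals[g]) || is.na(vals[g + 1])) next
    if (abs(vals[g]) < 1e-9) { root <- grid[g]; break }
    if (vals[g] * vals[g + 1] < 0 && abs(vals[g] - vals[g + 1]) < 180) {
      root <- stats::uniroot(f, c(grid[g], grid[g + 1]), tol = 1e-12)$root
      break
    }
  }
  if (is.null(root)) stop("no phosphate rotation reaches eps - zeta = ", target)
  R <- rotation_about(axis, root)
  a[sel, c("x", "y", "z")] <- sweep(sweep(grp, 2, O3) %*% t(R), 2, O3, "+")
  out <- structure_model(a, source = attr(model, "source"),
                         title = attr(model, "title"))
  attr(out, "fiber") <- attr(model, "fiber")
  out
}

# Probe group templates: reference (approach) atom at the origin, group
# extending along +x (away from the DNA after placement).
.probe_geom <- function(type) {
  pent <- function(names) {
    s <- 1.34; R <- s / (2 * sin(pi / 5))
    ctr <- c(s / 2, sqrt(R^2 - (s / 2)^2))
    phi0 <- atan2(-ctr[2], -ctr[1])
    ang <- phi0 + (0:4) * 2 * pi / 5
    m <- cbind(ctr[1] + R * cos(ang), ctr[2] + R * sin(ang), 0)
    rownames(m) <- names
    m
  }
  switch(type,
         point = { m <- rbind(CA = c(0, 0, 0)); colnames(m) <- c("x","y","z")
                   list(resid = "GLY", coords = m) },
         LYS = { m <- rbind(NZ = c(0, 0, 0), CE = c(1.49, 0, 0))
                 list(resid = "LYS", coords = m) },
         ARG = { m <- rbind(NH1 = c(0, 0, 0), CZ = c(1.33, 0, 0),
                            NH2 = c(1.995, 1.152, 0), NE = c(1.995, -1.152, 0))
                 list(resid = "ARG", coords = m) },
         HIS = list(resid = "HIS",
                    coords = pent(c("NE2", "CD2", "CG", "ND1", "CE1"))),
         stop("unknown probe type: ", type))
}

#' Place protein-like probe groups near a DNA duplex
#'
#' Adds small amino-acid-like heavy-atom groups (chain `P`) approaching a
#' chosen nucleotide from the minor groove, major groove, or phosphate
#' backbone, positioned so that the closest probe-DNA atom distance equals
#' the request to within 0.05 Angstrom.  Used to exercise the contact and
#' clash analyses with constructed ground truth.
#'
#' @param duplex a DNA [structure_model()] (typically from
#'   [build_fiber_bdna()]).
#' @param probes data.frame with columns `type` (`"ARG"`, `"LYS"`, `"HIS"`,
#'   `"point"`), `index` (operator index), `strand` (`"c"`/`"d"`),
#'   `groove` (`"minor"`, `"major"`, `"backbone"`), `distance` (Angstrom),
#'   and optionally `atom` (explicit target atom name).
#' @param numbering operator numbering (default: centered on the middle of
#'   chain `A`).
#' @return a [structure_model()] of the duplex plus probe residues.
#' @export
make_probe_complex <- function(duplex, probes, numbering = NULL) {
  a <- as.data.frame(select_component(duplex, "dna"))
  if (is.null(numbering)) {
    resA <- sort(unique(a$resno[a$chain == "A"]))
    numbering <- assign_operator_numbering(duplex,
                                           center = list("A", resA[ceiling(length(resA) / 2)]))
  }
  dnaxyz <- as.matrix(a[, c("x", "y", "z")])
  rows <- list()
  for (k in seq_len(nrow(probes))) {
    pr <- probes[k, ]
    if (pr$distance <= 0) stop("probe distance must be positive")
    hit <- numbering$index == pr$index & numbering$strand == pr$strand
    if (!any(hit)) stop("no nucleotide at operator index ", pr$index,
                        " strand ", pr$strand)
    nres <- numbering[which(hit)[1], ]
    ra <- a[a$chain == nres$chain & a$resno == nres$resno, , drop = FALSE]
    base <- .base_letter(nres$resid)
    atom <- if (!is.null(pr$atom) && !is.na(pr$atom) && nzchar(pr$atom)) pr$atom
            else switch(pr$groove,
                        minor = if (base %in% c("A", "G")) "N3" else "O2",
                        major = if (base %in% c("A", "G")) "N7"
                                else if (base == "T") "O4" else "N4",
                        backbone = "OP1",
                        stop("unknown groove: ", pr$groove))
    trow <- ra[ra$elety == atom, , drop = FALSE]
    if (!nrow(trow)) stop("target atom ", atom, " absent in ",
                          nres$chain, ":", nres$resno)
    target <- as.numeric(trow[1, c("x", "y", "z")])
    # approach direction: among all unit directions, take the one that
    # keeps the rest of the DNA farthest away when the probe reference
    # atom sits at the requested distance from the target atom.  This
    # finds the open groove mouth automatically: directions through the
    # base or into the backbone score poorly.
    ti <- which(abs(dnaxyz[, 1] - target[1]) < 1e-9 &
                  abs(dnaxyz[, 2] - target[2]) < 1e-9 &
                  abs(dnaxyz[, 3] - target[3]) < 1e-9)[1]
    others <- dnaxyz[-ti, , drop = FALSE]
    dirs <- fibonacci_sphere(400)
    cand <- sweep(dirs * pr$distance, 2, target, "+")
    cd <- sqrt(outer(rowSums(cand^2), rowSums(others^2), "+") -
                 2 * cand %*% t(others))
    clear <- apply(cd, 1, min)
    u <- dirs[which.max(clear), ]
    if (max(clear) < pr$distance - 0.5)
      stop("infeasible probe placement at requested distance ", pr$distance,
           ": target atom is buried")
    gg <- .probe_geom(as.character(pr$type))
    # rotate template +x onto u
    ex <- c(1, 0, 0)
    axis <- cross3(ex, u)
    Rrot <- if (vnorm(axis) < 1e-9) {
      if (sum(ex * u) > 0) diag(3) else rotation_about(c(0, 0, 1), 180)
    } else rotation_about(axis, acos(max(-1, min(1, sum(ex * u)))) * 180 / pi)
    tmpl <- gg$coords %*% t(Rrot)
    if (nrow(tmpl) > 1) {
      # spin the group about the approach axis so that the non-reference
      # atoms stay as clear of the DNA as possible (the reference atom is
      # on the axis and unaffected)
      clearance <- function(ang) {
        tk <- sweep(tmpl %*% t(rotation_about(u, ang)), 2,
                    target + pr$distance * u, "+")
        tk <- tk[-1, , drop = FALSE]
        min(sqrt(outer(rowSums(tk^2), rowSums(dnaxyz^2), "+") -
                   2 * tk %*% t(dnaxyz)))
      }
      angs <- seq(0, 350, by = 10)
      best <- angs[which.max(vapply(angs, clearance, numeric(1)))]
      tmpl <- tmpl %*% t(rotation_about(u, best))
    }
    mind <- function(s) {
      pts <- sweep(tmpl, 2, target + s * u, "+")
      min(sqrt(outer(rowSums(pts^2), rowSums(dnaxyz^2), "+") -
                 2 * pts %*% t(dnaxyz)))
    }
    f <- function(s) mind(s) - pr$distance
    lo <- 0.05; hi <- pr$distance + 30
    if (f(lo) > 0 || f(hi) < 0)
      stop("infeasible probe placement at requested distance ", pr$distance)
    # take the first (innermost) crossing: the clearance profile along the
    # approach line need not be monotone, and the intended placement is
    # the one nearest the target atom
    sg <- seq(lo, hi, by = 0.1)
    fv <- vapply(sg, f, numeric(1))
    br <- which(fv[-length(fv)] < 0 & fv[-1] >= 0)[1]
    if (is.na(br))
      stop("infeasible probe placement at requested distance ", pr$distance)
    s <- stats::uniroot(f, c(sg[br], sg[br + 1]), tol = 1e-9)$root
    xyz <- sweep(tmpl, 2, target + s * u, "+")
    rows[[k]] <- data.frame(chain = "P", resno = k, icode = "",
                            resid = gg$resid, elety = rownames(gg$coords),
                            elem = infer_element(rownames(gg$coords)),
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            occ = 1, b = 0, alt = "", stringsAsFactors = FALSE)
  }
  out <- rbind(as.data.frame(duplex), do.call(rbind, rows))
  m <- structure_model(out, source = attr(duplex, "source"),
                       title = paste0(attr(duplex, "title"), " + probes"))
  attr(m, "fiber") <- attr(duplex, "fiber")
  m
}
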