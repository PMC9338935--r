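# Structure container and I/O.  Parsing and writing of the standard formats
# is delegated to bio3d; this file owns the flat atom-table representation
# used by every analysis stage, component selection and the signed operator
# numbering convention.

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "MSE", "PHE", "PRO", "SER", "THR",
          "TRP", "TYR", "VAL")
.dna_res <- c("DA", "DC", "DG", "DT", "DI", "DU")
.water_res <- c("HOH", "WAT", "DOD", "H2O")

.two_letter_elems <- c("FE", "ZN", "MG", "MN", "NA", "CL", "BR", "CA", "CU",
                       "NI", "CO", "SE", "CD", "HG", "MO", "AS", "AL")

#' Construct a structure model from an atom table
#'
#' A `structure_model` is a flat data frame of heavy-atom records (one row
#' per atom) with chain / residue / atom identification, coordinates in
#' Angstrom, occupancy and B-factor, plus `source` and `title` metadata
#' attributes.  Residue order within a chain follows the input order.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `icode`, `resid`,
#'   `elety` (atom name), `elem`, `x`, `y`, `z`, `occ`, `b`, `alt`.
#' @param source identifier of the originating file or generator.
#' @param title free-text description.
#' @return an object of class `structure_model`.
#' @export
structure_model <- function(atoms, source = "", title = "") {
  need <- c("chain", "resno", "icode", "resid", "elety", "elem",
            "x", "y", "z", "occ", "b", "alt")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms[, need], stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE))
    stop("occupancies must lie in [0, 1]")
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$elety, atoms$alt)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, icode, atom, altloc) records")
  rownames(atoms) <- NULL
  structure(atoms, class = c("structure_model", "data.frame"),
            source = source, title = title)
}

# Infer element symbols from PDB atom names where the element column is
# absent or blank ("OP1" -> O, "C1'" -> C, "FE1" -> Fe).
infer_element <- function(elety) {
  base <- gsub("[0-9'*\"]", "", toupper(elety))
  out <- character(length(base))
  two <- base %in% .two_letter_elems
  out[two] <- paste0(substr(base[two], 1, 1), tolower(substr(base[two], 2, 2)))
  out[!two] <- substr(base[!two], 1, 1)
  out
}

classify_residue <- function(resid) {
  resid <- toupper(resid)
  ifelse(resid %in% .aa3, "protein",
         ifelse(resid %in% .dna_res, "dna",
                ifelse(resid %in% .water_res, "water", "hetero")))
}

#' Parse a macromolecular structure file
#'
#' Reads PDB or mmCIF through bio3d and returns a [structure_model()].
#' All ATOM/HETATM records are represented.  Where several alternate
#' locations exist for one atom, the highest-occupancy conformer is kept
#' (ties broken by altloc letter ascending); the number of discarded
#' records is stored in the `altloc_dropped` attribute.  Elements missing
#' from the file are inferred from atom names.  Hydrogens are dropped:
#' every downstream analysis in this package is heavy-atom only.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"pdb"`, `"cif"`; `"auto"` decides from
#'   the file extension (`.cif`/`.mmcif` vs anything else).
#' @param keep_hydrogens keep H/D atoms (default drops them).
#' @return a [structure_model()].
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "cif"),
                            keep_hydrogens = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  raw <- tryCatch(
    suppressWarnings(
      if (format == "cif") bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
      else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  a <- raw$atom
  elem <- a$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(a))
  blank <- is.na(elem) | !nzchar(trimws(elem))
  elem <- ifelse(blank, infer_element(a$elety), trimws(elem))
  elem <- ifelse(nchar(elem) == 2,
                 paste0(toupper(substr(elem, 1, 1)), tolower(substr(elem, 2, 2))),
                 toupper(elem))
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), " ", a$chain),
    resno = a$resno,
    icode = ifelse(is.na(a$insert), "", a$insert),
    resid = a$resid,
    elety = a$elety,
    elem = elem,
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, pmin(1, pmax(0, a$o))),
    b = ifelse(is.na(a$b), 0, a$b),
    alt = ifelse(is.na(a$alt), "", a$alt),
    stringsAsFactors = FALSE)
  if (!keep_hydrogens) atoms <- atoms[!(atoms$elem %in% c("H", "D")), , drop = FALSE]
  # altloc policy: highest occupancy, tie-break altloc letter ascending
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$elety)
  ord <- order(key, -atoms$occ, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  dup <- duplicated(paste(atoms$chain, atoms$resno, atoms$icode, atoms$elety))
  dropped <- sum(dup)
  atoms <- atoms[!dup, , drop = FALSE]
  # restore file order
  atoms <- atoms[order(as.numeric(rownames(atoms))), , drop = FALSE]
  atoms$alt <- ""
  m <- structure_model(atoms, source = basename(path), title = format)
  attr(m, "altloc_dropped") <- dropped
  m
}

#' Write a structure model to a PDB file
#'
#' @param model a [structure_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- as.data.frame(model)
  het <- classify_residue(a$resid) %in% c("hetero", "water")
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   chain = a$chain, insert = ifelse(nzchar(a$icode), a$icode, NA),
                   o = a$occ, b = a$b, elesy = a$elem)
  invisible(path)
}

#' Select a component of a structure
#'
#' @param model a [structure_model()].
#' @param selector `"protein"`, `"dna"`, `"hetero"`, `"water"`, `"all"`, or a
#'   list with elements `chains` (chain ids) and/or `resno` (residue numbers)
#'   combined conjunctively.
#' @return the sub-model, preserving order and metadata.  Selecting nothing
#'   is an error, never a silently empty model.
#' @export
select_component <- function(model, selector) {
  stopifnot(inherits(model, "structure_model"))
  a <- as.data.frame(model)
  if (is.character(selector) && length(selector) == 1 &&
      selector %in% c("protein", "dna", "hetero", "water", "all")) {
    keep <- if (selector == "all") rep(TRUE, nrow(a))
            else classify_residue(a$resid) == selector
  } else if (is.list(selector)) {
    keep <- rep(TRUE, nrow(a))
    if (!is.null(selector$chains)) keep <- keep & a$chain %in% selector$chains
    if (!is.null(selector$resno)) keep <- keep & a$resno %in% selector$resno
    bad <- setdiff(selector$chains, unique(a$chain))
    if (length(bad)) stop("unknown chain id(s): ", paste(bad, collapse = ", "))
  } else {
    stop("selector must be a component keyword or list(chains=, resno=)")
  }
  if (!any(keep))
    stop("empty selection: no atoms match the selector")
  structure_model(a[keep, , drop = FALSE],
                  source = attr(model, "source"), title = attr(model, "title"))
}

#' @export
print.structure_model <- function(x, ...) {
  a <- as.data.frame(x)
  cls <- classify_residue(a$resid)
  nres <- function(m) length(unique(paste(a$chain[m], a$resno[m], a$icode[m])))
  cat("structure_model: ", nrow(a), " atoms, ",
      length(unique(a$chain)), " chain(s) [",
      paste(unique(a$chain), collapse = ","), "]\n", sep = "")
  for (k in c("protein", "dna", "hetero", "water")) {
    m <- cls == k
    if (any(m)) cat(sprintf("  %-8s %5d atoms  %4d residues\n", k, sum(m), nres(m)))
  }
  if (nzchar(attr(x, "source"))) cat("  source:", attr(x, "source"), "\n")
  invisible(x)
}

# Ordered residue table of a model (one row per residue, input order kept).
residue_table <- function(model) {
  a <- as.data.frame(model)
  key <- paste(a$chain, a$resno, a$icode, sep = "\r")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             icode = a$icode[first], resid = a$resid[first],
             key = key[first], stringsAsFactors = FALSE)
}

# Coordinates of one named atom per residue key; NA rows where absent.
atom_coords <- function(model, elety) {
  a <- as.data.frame(model)
  res <- residue_table(model)
  sel <- a$elety == elety
  key <- paste(a$chain, a$resno, a$icode, sep = "\r")
  idx <- match(res$key, key[sel])
  out <- matrix(NA_real_, nrow(res), 3, dimnames = list(res$key, c("x", "y", "z")))
  hit <- !is.na(idx)
  out[hit, ] <- as.matrix(a[sel, c("x", "y", "z")])[idx[hit], , drop = FALSE]
  out
}

residue_atoms <- function(model, chain, resno, icode = "") {
  a <- as.data.frame(model)
  a[a$chain == chain & a$resno == resno & a$icode == icode, , drop = FALSE]
}

#' Map author numbering onto operator coordinates
#'
#' Operators are numbered with a signed index relative to the central base
#' pair, which gets index 0; the reference strand is labeled `c` and its
#' partner `d`.  Strand `c` indices increase 5' to 3' along the reference
#' chain; strand `d` nucleotides inherit the index of their base-pair
#' partner, and unpaired overhangs are extrapolated along the chain.
#'
#' @param model a [structure_model()] containing a DNA duplex.
#' @param center list or vector `(chain, resno)` naming the strand-c
#'   nucleotide to be assigned index 0.
#' @param pairs base-pair table from [detect_base_pairs()]; detected
#'   automatically when `NULL`.
#' @return data.frame with columns `chain`, `resno`, `icode`, `resid`,
#'   `index`, `strand`.
#' @export
assign_operator_numbering <- function(model, center, pairs = NULL) {
  dna <- select_component(model, "dna")
  res <- residue_table(dna)
  cc <- as.character(center[[1]]); cr <- as.integer(center[[2]])
  ci <- which(res$chain == cc & res$resno == cr)
  if (length(ci) != 1)
    stop("center residue ", cc, ":", cr, " is not a nucleotide of the model")
  if (is.null(pairs)) pairs <- detect_base_pairs(dna, reference_chain = cc)
  onref <- res$chain == cc
  idx <- rep(NA_integer_, nrow(res))
  strand <- rep(NA_character_, nrow(res))
  refpos <- which(onref)
  idx[refpos] <- seq_along(refpos) - which(refpos == ci)
  strand[refpos] <- "c"
  # partner indices via pairing
  if (nrow(pairs)) {
    kc <- paste(pairs$chain_c, pairs$resno_c, pairs$icode_c, sep = "\r")
    kd <- paste(pairs$chain_d, pairs$resno_d, pairs$icode_d, sep = "\r")
    mc <- match(kc, res$key)
    md <- match(kd, res$key)
    ok <- !is.na(mc) & !is.na(md)
    idx[md[ok]] <- idx[mc[ok]]
    strand[md[ok]] <- "d"
  }
  # extrapolate unassigned nucleotides along their chain from paired anchors
  for (ch in setdiff(unique(res$chain), cc)) {
    pos <- which(res$chain == ch)
    known <- pos[!is.na(idx[pos])]
    if (!length(known)) next
    slope <- if (length(known) >= 2)
      sign(idx[known[2]] - idx[known[1]]) else -1L
    for (p in pos[is.na(idx[pos])]) {
      anchor <- known[which.min(abs(known - p))]
      idx[p] <- idx[anchor] + slope * (p - anchor)
      strand[p] <- "d"
    }
  }
  data.frame(chain = res$chain, resno = res$resno, icode = res$icode,
             resid = res$resid, index = idx, strand = strand,
             stringsAsFactors = FALSE)
}

#' Download a structure from the PDB archive
#'
#' Thin optional helper; every analysis in this package runs equally on
#' local files.  Requires network access.
#'
#' @param accession 4-character PDB accession.
#' @param path destination (default: temp file).
#' @param format `"pdb"` or `"cif"`.
#' @param timeout seconds before giving up.
#' @return the downloaded file path.
#' @export
fetch_structure <- function(accession, path = NULL,
                            format = c("pdb", "cif"), timeout = 30) {
  format <- match.arg(format)
  ext <- if (format == "cif") ".cif" else ".pdb"
  if (is.null(path)) path <- file.path(tempdir(), paste0(toupper(accession), ext))
  url <- paste0("https://files.rcsb.org/download/", toupper(accession), ext)
  old <- getOption("timeout"); on.exit(options(timeout = old))
  options(timeout = timeout)
  status <- tryCatch(utils::download.file(url, path, quiet = TRUE, mode = "wb"),
                     error = function(e) -1L, warning = function(w) -1L)
  if (!identical(status, 0L) || !file.exists(path) || file.size(path) < 100)
    stop("could not download ", accession, " from the PDB archive")
  path
}
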