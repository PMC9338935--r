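# Operator threading: model a different operator sequence onto a fixed DNA
# backbone using idealized base geometry, then scan the modeled bases
# against the bound protein for attractive and repulsive (steric-collision)
# contacts.  The backbone is never moved -- rigid threading by construction.

#' Idealized heavy-atom geometry of a base
#'
#' Standard base coordinates in the base reference frame, including the
#' glycosidic nitrogen (N9/N1) and, for thymine, the C7 methyl carbon.
#'
#' @param base one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @param with_c1 include the C1' anchor row (default FALSE).
#' @return numeric matrix (atoms x 3) with atom-name rownames.
#' @export
ideal_base_geometry <- function(base, with_c1 = FALSE) {
  base <- toupper(base)
  if (!base %in% c("A", "C", "G", "T")) stop("unknown base: ", base)
  m <- .base_geom[[base]]
  if (!with_c1) m <- m[rownames(m) != "C1'", , drop = FALSE]
  m
}

.is_purine_letter <- function(b) b %in% c("A", "G")

#' Thread a new operator sequence onto a template backbone
#'
#' Each substituted position keeps its sugar-phosphate backbone and C1'
#' atoms bit-identical to the template; only base atoms are rebuilt from
#' idealized geometry.  Like-for-like substitutions (purine to purine,
#' pyrimidine to pyrimidine) reuse the fitted frame of the old base;
#' purine/pyrimidine swaps place the new base in the standard pairing
#' frame derived from the template partner base, so the new glycosidic
#' bond follows standard Watson-Crick geometry.  Strand d is forced to
#' the complement of the threaded strand-c base.
#'
#' @param template a [structure_model()] holding the template complex
#'   (protein atoms, if any, are carried through untouched).
#' @param alignment data.frame with columns `index` (operator index) and
#'   `base` (new strand-c base letter).  Positions absent from the
#'   template are an error.
#' @param numbering operator numbering of the template DNA; computed
#'   (centered mid-chain) when `NULL`.
#' @param pairs base-pair table; detected when `NULL`.
#' @return object of class `threaded_model`: list with `model` (the new
#'   [structure_model()]), `changes` (per-position bookkeeping) and the
#'   template reference.
#' @export
thread_operator_sequence <- function(template, alignment, numbering = NULL,
                                     pairs = NULL) {
  dna <- select_component(template, "dna")
  res <- residue_table(dna)
  if (is.null(numbering)) {
    ch <- res$chain[1]; rs <- res$resno[res$chain == ch]
    numbering <- assign_operator_numbering(dna,
                                           center = list(ch, rs[ceiling(length(rs) / 2)]))
  }
  if (is.null(pairs)) pairs <- detect_base_pairs(dna)
  alignment$base <- toupper(alignment$base)
  if (!all(alignment$base %in% c("A", "C", "G", "T")))
    stop("alignment bases must be A/C/G/T")
  miss <- setdiff(alignment$index,
                  numbering$index[numbering$strand == "c"])
  if (length(miss))
    stop("alignment references operator positions absent from the template: ",
         paste(miss, collapse = ", "))
  a <- as.data.frame(template)
  akey <- paste(a$chain, a$resno, a$icode, sep = "\r")
  kc <- paste(pairs$chain_c, pairs$resno_c, pairs$icode_c, sep = "\r")
  kd <- paste(pairs$chain_d, pairs$resno_d, pairs$icode_d, sep = "\r")
  kn <- paste(numbering$chain, numbering$resno, numbering$icode, sep = "\r")
  changes <- NULL
  for (k in seq_len(nrow(alignment))) {
    opix <- alignment$index[k]
    new_c <- alignment$base[k]
    nrow_c <- which(numbering$index == opix & numbering$strand == "c")[1]
    key_c <- kn[nrow_c]
    pk <- which(kc == key_c)
    if (!length(pk))
      stop("operator position ", opix, " is unpaired; cannot thread both strands")
    key_d <- kd[pk[1]]
    for (side in c("c", "d")) {
      key <- if (side == "c") key_c else key_d
      newb <- if (side == "c") new_c else .complement[new_c]
      ratoms <- a[akey == key, , drop = FALSE]
      oldb <- .base_letter(ratoms$resid[1])
      replaced <- !identical(oldb, unname(newb))
      if (replaced) {
        if (.is_purine_letter(oldb) == .is_purine_letter(newb)) {
          fr <- base_frame(ratoms)
          if (is.null(fr)) stop("no resolvable base frame at position ", opix,
                                " strand ", side)
          R <- fr$R; o <- fr$origin
        } else {
          pkey <- if (side == "c") key_d else key_c
          pfr <- base_frame(a[akey == pkey, , drop = FALSE])
          if (is.null(pfr)) stop("no resolvable partner frame at position ",
                                 opix, " strand ", side)
          R <- pfr$R %*% .pair_flip; o <- pfr$origin
        }
        std <- ideal_base_geometry(newb)
        xyz <- sweep(std %*% t(R), 2, o, "+")
        keepnames <- c(rownames(.backbone_geom), "C1'")
        keep <- a[akey == key & a$elety %in% keepnames, , drop = FALSE]
        newrows <- data.frame(chain = keep$chain[1], resno = keep$resno[1],
                              icode = keep$icode[1],
                              resid = paste0("D", newb), elety = rownames(std),
                              elem = infer_element(rownames(std)),
                              x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                              occ = 1, b = 0, alt = "",
                              stringsAsFactors = FALSE)
        keep$resid <- paste0("D", newb)
        pos <- which(akey == key)
        before <- if (min(pos) > 1) a[seq_len(min(pos) - 1), , drop = FALSE]
                  else a[0, , drop = FALSE]
        after <- if (max(pos) < nrow(a)) a[(max(pos) + 1):nrow(a), , drop = FALSE]
                 else a[0, , drop = FALSE]
        a <- rbind(before, keep, newrows, after)
        akey <- paste(a$chain, a$resno, a$icode, sep = "\r")
      }
      changes <- rbind(changes,
                       data.frame(index = opix, strand = side,
                                  chain = ratoms$chain[1], resno = ratoms$resno[1],
                                  old_base = oldb, new_base = unname(newb),
                                  replaced = replaced, stringsAsFactors = FALSE))
    }
  }
  model <- structure_model(a, source = attr(template, "source"),
                           title = paste0(attr(template, "title"), " [threaded]"))
  structure(list(model = model, changes = changes, numbering = numbering,
                 template_source = attr(template, "source")),
            class = "threaded_model")
}

#' @export
print.threaded_model <- function(x, ...) {
  cat("threaded_model:", sum(x$changes$replaced), "of", nrow(x$changes),
      "strand positions rebuilt\n")
  invisible(x)
}

#' Scan threaded bases against the protein for clashes
#'
#' Reports, for every base atom of the (threaded or native) DNA, protein
#' heavy atoms within the attractive window; a record is `repulsive` when
#' the distance falls below the steric cutoff (default 2.85 Angstrom, all
#' heavy-atom pairs), otherwise `attractive`.  N/O-N/O pairs between 2.6
#' Angstrom and the cutoff are additionally flagged as possible hydrogen
#' bonds rather than genuine collisions.
#'
#' @param threaded a `threaded_model` or plain [structure_model()].
#' @param protein protein component ([structure_model()]); taken from
#'   `threaded` when `NULL`.
#' @param attractive outer distance window in Angstrom (default 4.0).
#' @param repulsive steric collision cutoff in Angstrom (default 2.85,
#'   strict `<`).
#' @return data.frame of class `clash_table`, one row per base-atom /
#'   protein-atom pair within the window, with `verdict` and
#'   `possible_hbond`; summary counts in attributes `n_repulsive` and
#'   `repulsive_by_residue`.
#' @export
clash_scan <- function(threaded, protein = NULL, attractive = 4.0,
                       repulsive = 2.85) {
  model <- if (inherits(threaded, "threaded_model")) threaded$model else threaded
  numbering <- if (inherits(threaded, "threaded_model")) threaded$numbering else NULL
  if (is.null(protein)) protein <- select_component(model, "protein")
  dna <- select_component(model, "dna")
  da <- as.data.frame(dna)
  da <- da[dna_moiety(da$elety) == "base" & da$elety != "C1'", , drop = FALSE]
  dsub <- structure_model(da)
  cts <- enumerate_contacts(protein, dsub, cutoff = attractive,
                            inclusive = TRUE, numbering = numbering)
  if (inherits(threaded, "threaded_model") && nrow(cts)) {
    ch <- threaded$changes
    kch <- paste(ch$chain, ch$resno, sep = "\r")
    m <- match(paste(cts$d_chain, cts$d_resno, sep = "\r"), kch)
    cts$modeled <- !is.na(m) & ch$replaced[ifelse(is.na(m), 1, m)]
  } else cts$modeled <- logical(nrow(cts))
  cts$verdict <- ifelse(cts$distance < repulsive, "repulsive", "attractive")
  cts$possible_hbond <- cts$verdict == "repulsive" &
    cts$p_elem %in% c("N", "O") & cts$d_elem %in% c("N", "O") &
    cts$distance >= 2.6
  rep_tab <- cts[cts$verdict == "repulsive", , drop = FALSE]
  byres <- if (nrow(rep_tab))
    stats::aggregate(list(n = rep(1L, nrow(rep_tab))),
                     by = list(resid = rep_tab$p_resid, resno = rep_tab$p_resno,
                               chain = rep_tab$p_chain), FUN = sum)
  else data.frame(resid = character(), resno = integer(), chain = character(),
                  n = integer())
  class(cts) <- c("clash_table", "data.frame")
  attr(cts, "n_repulsive") <- nrow(rep_tab)
  attr(cts, "repulsive_by_residue") <- byres
  attr(cts, "cutoffs") <- c(attractive = attractive, repulsive = repulsive)
  cts
}
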