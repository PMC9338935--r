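# Protein-DNA contact enumeration and distance-based classification.
# Thresholds follow the crystallographic convention for heavy-atom models
# without hydrogens: polar contacts at d <= 3.3 A (hydrogen bonds; salt
# bridges when a titratable side-chain N meets a phosphate oxygen) and
# remaining van der Waals contacts at d < 3.8 A.

.phosphate_atoms <- c("P", "OP1", "OP2", "OP3", "O5'", "O3'")
.sugar_atoms <- c("C1'", "C2'", "C3'", "C4'", "C5'", "O4'")
.mainchain_atoms <- c("N", "CA", "C", "O", "OXT")
.salt_bridge_atoms <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                           HIS = c("ND1", "NE2"))

# expected heavy side-chain atom counts for completeness annotation
.sidechain_n <- c(ALA = 1, ARG = 7, ASN = 4, ASP = 4, CYS = 2, GLN = 5,
                  GLU = 5, GLY = 0, HIS = 6, ILE = 4, LEU = 4, LYS = 5,
                  MET = 4, PHE = 7, PRO = 3, SER = 2, THR = 3, TRP = 10,
                  TYR = 8, VAL = 3)

dna_moiety <- function(elety) {
  ifelse(elety %in% .phosphate_atoms, "phosphate",
         ifelse(elety %in% .sugar_atoms, "sugar", "base"))
}

#' Enumerate protein-DNA atomic contacts
#'
#' All heavy-atom pairs between the two components with distance below
#' `cutoff` (strict `<` by default; the boundary convention is
#' configurable).  Waters and hydrogens are excluded unless requested.
#' Equivalent to a brute-force all-pairs scan.
#'
#' @param protein,dna the two components as [structure_model()]s.
#' @param cutoff distance cutoff in Angstrom (default 3.8).
#' @param inclusive include pairs at exactly the cutoff (default FALSE).
#' @param include_waters keep water molecules (default FALSE).
#' @param numbering optional operator numbering used to annotate DNA atoms
#'   with `index`/`strand`.
#' @return data.frame of contacts with protein atom, DNA atom (plus
#'   moiety: phosphate, sugar or base), and distance, sorted by distance.
#' @export
enumerate_contacts <- function(protein, dna, cutoff = 3.8,
                               inclusive = FALSE, include_waters = FALSE,
                               numbering = NULL) {
  pa <- as.data.frame(protein); da <- as.data.frame(dna)
  if (!include_waters) {
    pa <- pa[classify_residue(pa$resid) != "water", , drop = FALSE]
    da <- da[classify_residue(da$resid) != "water", , drop = FALSE]
  }
  pa <- pa[!(pa$elem %in% c("H", "D")), , drop = FALSE]
  da <- da[!(da$elem %in% c("H", "D")), , drop = FALSE]
  if (!nrow(pa) || !nrow(da)) stop("empty component in contact enumeration")
  P <- as.matrix(pa[, c("x", "y", "z")]); D <- as.matrix(da[, c("x", "y", "z")])
  d2 <- outer(rowSums(P^2), rowSums(D^2), "+") - 2 * P %*% t(D)
  d2[d2 < 0] <- 0
  dm <- sqrt(d2)
  hit <- if (inclusive) which(dm <= cutoff, arr.ind = TRUE)
         else which(dm < cutoff, arr.ind = TRUE)
  i <- hit[, 1]; j <- hit[, 2]
  out <- data.frame(
    p_chain = pa$chain[i], p_resno = pa$resno[i], p_resid = pa$resid[i],
    p_atom = pa$elety[i], p_elem = pa$elem[i],
    p_mainchain = pa$elety[i] %in% .mainchain_atoms &
      classify_residue(pa$resid[i]) == "protein",
    d_chain = da$chain[j], d_resno = da$resno[j], d_resid = da$resid[j],
    d_atom = da$elety[j], d_elem = da$elem[j],
    moiety = dna_moiety(da$elety[j]),
    distance = dm[hit],
    stringsAsFactors = FALSE)
  if (!is.null(numbering)) {
    kn <- paste(numbering$chain, numbering$resno, sep = "\r")
    m <- match(paste(out$d_chain, out$d_resno, sep = "\r"), kn)
    out$index <- numbering$index[m]
    out$strand <- numbering$strand[m]
  }
  out[order(out$distance), , drop = FALSE]
}

#' Classify contacts as H-bonds, salt bridges or van der Waals
#'
#' `hbond`: both atoms N or O and d <= `polar_cutoff`.  `salt_bridge`:
#' d <= `polar_cutoff`, DNA atom a phosphate oxygen (or P) and protein
#' atom a titratable side-chain nitrogen (Arg NH1/NH2/NE, Lys NZ, His
#' ND1/NE2); His-phosphate bridges are qualified `"possible"` since the
#' imidazole protonation state is unknown in a heavy-atom model.
#' Everything else below the enumeration cutoff is `vdw`.
#'
#' @param contacts table from [enumerate_contacts()].
#' @param polar_cutoff polar-contact threshold in Angstrom (default 3.3,
#'   inclusive).
#' @return the table with `class` and `qualifier` columns added.
#' @export
classify_contacts <- function(contacts, polar_cutoff = 3.3) {
  sb_atoms <- unlist(lapply(names(.salt_bridge_atoms), function(r)
    paste(r, .salt_bridge_atoms[[r]])))
  is_sb_protein <- paste(toupper(contacts$p_resid), contacts$p_atom) %in% sb_atoms
  is_phos_o <- contacts$moiety == "phosphate" & contacts$d_elem %in% c("O", "P")
  polar <- contacts$distance <= polar_cutoff
  both_no <- contacts$p_elem %in% c("N", "O") & contacts$d_elem %in% c("N", "O")
  cls <- ifelse(polar & is_sb_protein & is_phos_o, "salt_bridge",
                ifelse(polar & both_no, "hbond", "vdw"))
  contacts$class <- cls
  contacts$qualifier <- ifelse(cls == "salt_bridge" &
                                 toupper(contacts$p_resid) == "HIS",
                               "possible", "")
  contacts
}

#' Summarize classified contacts per residue and per nucleotide
#'
#' @param contacts classified contact table ([classify_contacts()]).
#' @param protein optional protein [structure_model()] used to flag
#'   residues with missing (disordered) side-chain atoms.
#' @return list with `per_residue` and `per_nucleotide` count tables
#'   (class and moiety breakdown).
#' @export
summarize_contacts <- function(contacts, protein = NULL) {
  if (!"class" %in% names(contacts)) contacts <- classify_contacts(contacts)
  tab <- function(keys) {
    agg <- stats::aggregate(list(n = rep(1L, nrow(contacts))),
                            by = keys, FUN = sum)
    for (cl in c("hbond", "salt_bridge", "vdw")) {
      sub <- contacts[contacts$class == cl, , drop = FALSE]
      if (nrow(sub)) {
        a2 <- stats::aggregate(list(x = rep(1L, nrow(sub))),
                               by = lapply(keys, function(k) k[contacts$class == cl]),
                               FUN = sum)
        names(a2)[ncol(a2)] <- cl
        agg <- merge(agg, a2, all.x = TRUE)
      } else agg[[cl]] <- 0L
    }
    for (cl in c("hbond", "salt_bridge", "vdw"))
      agg[[cl]][is.na(agg[[cl]])] <- 0L
    agg
  }
  per_res <- tab(list(chain = contacts$p_chain, resno = contacts$p_resno,
                      resid = contacts$p_resid))
  nuckey <- if ("index" %in% names(contacts) && !anyNA(contacts$index))
    list(index = contacts$index, strand = contacts$strand,
         resid = contacts$d_resid)
  else list(chain = contacts$d_chain, resno = contacts$d_resno,
            resid = contacts$d_resid)
  per_nuc <- tab(nuckey)
  if (!is.null(protein)) {
    pa <- as.data.frame(protein)
    cnt <- stats::aggregate(
      list(n_side = !(pa$elety %in% .mainchain_atoms)),
      by = list(chain = pa$chain, resno = pa$resno, resid = pa$resid), FUN = sum)
    expect <- .sidechain_n[toupper(cnt$resid)]
    cnt$incomplete_side_chain <- !is.na(expect) & cnt$n_side < expect
    per_res <- merge(per_res,
                     cnt[, c("chain", "resno", "incomplete_side_chain")],
                     by = c("chain", "resno"), all.x = TRUE)
  }
  list(per_residue = per_res[order(per_res$chain, per_res$resno), , drop = FALSE],
       per_nucleotide = per_nuc)
}
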