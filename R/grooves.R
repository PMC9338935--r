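# Groove width profiles from cross-strand phosphate P positions: for each
# phosphate, the minimal P-to-P distance to the opposite strand within a
# fixed offset window along the duplex alignment (minor groove: partner
# 2-5 bp back along the strand's own 5'->3' direction; major groove: 2-7
# ahead).  Distances are raw P-P values, no phosphate-radius subtraction.

#' Minor- and major-groove width profile of a duplex
#'
#' For each phosphate the minimal cross-strand P-to-P distance across the
#' minor groove (`dPP_MiG`) and the major groove (`dPP_MaG`) is reported
#' together with the partner phosphate identity.  Terminal phosphates
#' whose offset window is truncated report the restricted minimum and are
#' flagged `edge`.  5'-terminal nucleotides without phosphate are skipped.
#'
#' @param model a [structure_model()] containing the duplex.
#' @param numbering operator numbering ([assign_operator_numbering()]);
#'   computed automatically (centered mid-chain) when `NULL`.
#' @param minor_window,major_window integer offset ranges (in base pairs,
#'   along each strand's own 5'->3' sense) defining which opposite-strand
#'   phosphates bracket each groove.
#' @return data.frame of class `groove_profile`: one row per phosphate
#'   with `index`, `strand`, partner identities, `dPP_MiG`, `dPP_MaG`,
#'   `delta_PP_MiG` (vs. the 11.7 Angstrom regular-B-DNA reference) and
#'   `edge`.
#' @export
groove_profile <- function(model, numbering = NULL,
                           minor_window = c(-5, -2),
                           major_window = c(2, 7)) {
  dna <- select_component(model, "dna")
  res <- residue_table(dna)
  if (is.null(numbering)) {
    ch <- res$chain[1]
    rs <- res$resno[res$chain == ch]
    numbering <- assign_operator_numbering(dna,
                                           center = list(ch, rs[ceiling(length(rs) / 2)]))
  }
  P <- atom_coords(dna, "P")
  kn <- paste(numbering$chain, numbering$resno, numbering$icode, sep = "\r")
  m <- match(res$key, kn)
  if (anyNA(m)) stop("numbering does not cover every nucleotide")
  idx <- numbering$index[m]; strand <- numbering$strand[m]
  have <- !is.na(P[, 1])
  # lookup of phosphate coordinates by (strand, aligned index)
  pkey <- paste(strand, idx)
  rows <- list(); ri <- 0
  for (i in which(have)) {
    sgn <- if (strand[i] == "c") 1 else -1
    other <- if (strand[i] == "c") "d" else "c"
    find <- function(window) {
      offs <- seq(window[1], window[2])
      cand <- match(paste(other, idx[i] + sgn * offs), pkey)
      cand <- cand[!is.na(cand)]
      cand <- cand[have[cand]]
      if (!length(cand)) return(NULL)
      d <- sqrt(colSums((t(P[cand, , drop = FALSE]) - P[i, ])^2))
      j <- which.min(d)
      list(d = d[j], partner = cand[j], nfound = length(cand),
           nfull = length(offs))
    }
    mi <- find(minor_window); ma <- find(major_window)
    ri <- ri + 1
    rows[[ri]] <- data.frame(
      chain = res$chain[i], resno = res$resno[i], icode = res$icode[i],
      index = idx[i], strand = strand[i],
      dPP_MiG = if (is.null(mi)) NA_real_ else unname(mi$d),
      partner_index_MiG = if (is.null(mi)) NA_integer_ else idx[mi$partner],
      partner_strand_MiG = if (is.null(mi)) NA_character_ else strand[mi$partner],
      dPP_MaG = if (is.null(ma)) NA_real_ else unname(ma$d),
      partner_index_MaG = if (is.null(ma)) NA_integer_ else idx[ma$partner],
      partner_strand_MaG = if (is.null(ma)) NA_character_ else strand[ma$partner],
      edge = is.null(mi) || mi$nfound < mi$nfull,
      edge_MaG = is.null(ma) || ma$nfound < ma$nfull,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- delta_pp_profile(out)
  class(out) <- c("groove_profile", "data.frame")
  attr(out, "minor_window") <- minor_window
  attr(out, "major_window") <- major_window
  out
}

#' Deviation of the minor-groove profile from regular B-DNA
#'
#' Adds (or recomputes) `delta_PP_MiG = dPP_MiG - reference`, the deviation
#' of each minimal minor-groove P-P distance from its average value in
#' regular B-DNA.
#'
#' @param profile a [groove_profile()] table.
#' @param reference regular-B-DNA reference distance in Angstrom
#'   (default 11.7).
#' @return the profile with an updated `delta_PP_MiG` column and
#'   `reference` attribute.
#' @export
delta_pp_profile <- function(profile, reference = 11.7) {
  profile$delta_PP_MiG <- profile$dPP_MiG - reference
  attr(profile, "reference") <- reference
  profile
}
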