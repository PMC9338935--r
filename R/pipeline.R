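# Orchestration: run the full analysis on one complex, serialize reports,
# and build comparative tables across complexes aligned by operator index.

.default_config <- function() {
  list(center = NULL,              # list(chain, resno); default: mid reference chain
       reference_chain = NULL,     # strand-c chain id; default: first DNA chain
       contact_cutoff = 3.8,
       polar_cutoff = 3.3,
       repulsive_cutoff = 2.85,
       groove_reference = 11.7,
       bi_bii_band = 45,
       include_waters = FALSE,
       sasa_n_points = 960,
       stages = c("geometry", "grooves", "contacts", "sasa"))
}

#' Run the full protein-DNA analysis on one complex
#'
#' Parses (or takes) a structure, assigns operator numbering, and runs the
#' geometry, groove, contact and buried-surface stages in order.  A stage
#' that fails (for example, no protein present) is recorded as an
#' annotated gap in the report, not an abort; configuration errors are
#' raised before any stage runs.
#'
#' @param x file path or [structure_model()].
#' @param config list overriding entries of the default configuration:
#'   `center`, `reference_chain`, `contact_cutoff` (3.8), `polar_cutoff`
#'   (3.3), `repulsive_cutoff` (2.85), `groove_reference` (11.7),
#'   `bi_bii_band` (45), `include_waters`, `sasa_n_points`, `stages`.
#' @return object of class `dna_analysis_report`: list of data.frames
#'   (`nucleotides`, `pairs`, `steps`, `grooves`, `contacts`,
#'   `contact_summary`, `bsa`) plus metadata.
#' @export
analyze_complex <- function(x, config = list()) {
  cfg <- utils::modifyList(.default_config(), config)
  model <- if (inherits(x, "structure_model")) x else parse_structure(x)
  unknown <- setdiff(cfg$stages, c("geometry", "grooves", "contacts", "sasa"))
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  dna <- select_component(model, "dna")
  res <- residue_table(dna)
  refch <- if (is.null(cfg$reference_chain)) res$chain[1] else cfg$reference_chain
  if (!refch %in% res$chain) stop("reference chain ", refch, " has no DNA")
  if (is.null(cfg$center)) {
    rs <- res$resno[res$chain == refch]
    cfg$center <- list(refch, rs[ceiling(length(rs) / 2)])
  }
  has_protein <- any(classify_residue(as.data.frame(model)$resid) == "protein")
  pairs <- detect_base_pairs(dna, reference_chain = refch)
  numbering <- assign_operator_numbering(dna, center = cfg$center, pairs = pairs)
  report <- list(meta = list(source = attr(model, "source"),
                             title = attr(model, "title"),
                             n_atoms = nrow(model),
                             config = cfg[c("contact_cutoff", "polar_cutoff",
                                            "repulsive_cutoff", "groove_reference",
                                            "bi_bii_band", "sasa_n_points")]),
                 numbering = numbering)
  run <- function(expr) tryCatch(expr, error = function(e)
    list(error = conditionMessage(e)))
  if ("geometry" %in% cfg$stages) {
    report$nucleotides <- run({
      t <- backbone_torsions(dna)
      t$state <- as.character(classify_backbone_state(t, band = cfg$bi_bii_band))
      kn <- paste(numbering$chain, numbering$resno, numbering$icode, sep = "\r")
      m <- match(paste(t$chain, t$resno, t$icode, sep = "\r"), kn)
      t$index <- numbering$index[m]; t$strand <- numbering$strand[m]
      t
    })
    geo <- run(bp_and_step_parameters(dna, pairs = pairs))
    if (!is.null(geo$error)) {
      report$pairs <- geo; report$steps <- geo
    } else {
      report$pairs <- geo$pairs[, setdiff(names(geo$pairs), character(0))]
      report$steps <- geo$steps
    }
  }
  if ("grooves" %in% cfg$stages)
    report$grooves <- run({
      g <- groove_profile(dna, numbering = numbering)
      delta_pp_profile(g, reference = cfg$groove_reference)
    })
  if ("contacts" %in% cfg$stages)
    report$contacts <- run({
      if (!has_protein) stop("no protein component present")
      prot <- select_component(model, "protein")
      ct <- enumerate_contacts(prot, dna, cutoff = cfg$contact_cutoff,
                               include_waters = cfg$include_waters,
                               numbering = numbering)
      classify_contacts(ct, polar_cutoff = cfg$polar_cutoff)
    })
  if ("contacts" %in% cfg$stages)
    report$contact_summary <- run({
      if (is.null(report$contacts$error))
        summarize_contacts(report$contacts,
                           protein = select_component(model, "protein"))
      else stop(report$contacts$error)
    })
  if ("sasa" %in% cfg$stages)
    report$bsa <- run({
      if (!has_protein) stop("no protein component present")
      prot <- select_component(model, "protein")
      het <- tryCatch(select_component(model, "hetero"), error = function(e) NULL)
      if (!is.null(het))   # cofactors (e.g. FeS clusters) count with the protein
        prot <- structure_model(rbind(as.data.frame(prot), as.data.frame(het)))
      b <- buried_surface_area(model, prot, dna, n_points = cfg$sasa_n_points)
      data.frame(groupA = "protein", groupB = "dna", bsa = as.numeric(b),
                 sasa_A = attr(b, "sasa")[["A"]], sasa_B = attr(b, "sasa")[["B"]],
                 sasa_AB = attr(b, "sasa")[["AB"]])
    })
  structure(report, class = "dna_analysis_report")
}

#' @export
print.dna_analysis_report <- function(x, ...) {
  cat("dna_analysis_report:", x$meta$source, "\n")
  for (nm in setdiff(names(x), c("meta", "numbering"))) {
    el <- x[[nm]]
    if (is.list(el) && !is.null(el$error))
      cat(sprintf("  %-16s <failed: %s>\n", nm, el$error))
    else if (is.data.frame(el))
      cat(sprintf("  %-16s %d rows\n", nm, nrow(el)))
  }
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Deterministic, lossless round-trip: identical reports serialize to
#' byte-identical files.
#'
#' @param report a `dna_analysis_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", null = "null")
  invisible(path)
}

#' Read back a serialized analysis report
#'
#' @param path JSON file written by [write_report()].
#' @return `dna_analysis_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in setdiff(names(x), "meta")) {
    if (is.list(x[[nm]]) && !is.data.frame(x[[nm]]) && is.null(x[[nm]]$error) &&
        nm != "contact_summary")
      x[[nm]] <- as.data.frame(x[[nm]], stringsAsFactors = FALSE)
  }
  structure(x, class = "dna_analysis_report")
}

#' Compare analysis reports across complexes
#'
#' Aligns groove and step tables by operator index and summarizes each
#' complex side by side.
#'
#' @param reports named list of `dna_analysis_report`s.
#' @param alignment optional data.frame mapping a common `position` column
#'   to one operator-index column per report (columns named like the
#'   reports).  Defaults to identity on the operator indices.  Positions
#'   referencing absent indices are an error listing them.
#' @param roll_region operator index range for the average-roll summary
#'   (default c(-5, 5), the central 11 bp).
#' @return list with `grooves` (aligned dPP_MiG per position), `rolls`
#'   (aligned step roll) and `summary` (one row per complex).
#' @export
compare_complexes <- function(reports, alignment = NULL,
                              roll_region = c(-5, 5)) {
  if (length(reports) < 2) stop("need at least two reports")
  if (is.null(names(reports)))
    names(reports) <- paste0("complex", seq_along(reports))
  getg <- function(r) { g <- r$grooves; if (!is.null(g$error)) NULL else g }
  if (is.null(alignment)) {
    allidx <- sort(unique(unlist(lapply(reports, function(r) {
      g <- getg(r); if (is.null(g)) integer(0) else g$index
    }))))
    alignment <- data.frame(position = allidx)
    for (nm in names(reports)) alignment[[nm]] <- allidx
  } else {
    for (nm in names(reports)) {
      g <- getg(reports[[nm]])
      if (is.null(g)) next
      bad <- setdiff(stats::na.omit(alignment[[nm]]), g$index)
      if (length(bad))
        stop("alignment references positions absent from '", nm, "': ",
             paste(bad, collapse = ", "))
    }
  }
  gro <- data.frame(position = alignment$position)
  rol <- data.frame(position = alignment$position)
  summ <- NULL
  for (nm in names(reports)) {
    r <- reports[[nm]]
    g <- getg(r)
    if (!is.null(g)) {
      gc <- g[g$strand == "c", , drop = FALSE]
      gro[[nm]] <- gc$dPP_MiG[match(alignment[[nm]], gc$index)]
    }
    st <- r$steps; prs <- r$pairs
    if (is.data.frame(st) && is.data.frame(prs) && nrow(st)) {
      num <- r$numbering
      kn <- paste(num$chain, num$resno, sep = "\r")
      pidx <- num$index[match(paste(prs$chain_c, prs$resno_c, sep = "\r"), kn)]
      stidx <- pidx[-length(pidx)]           # step labeled by its 5' pair
      rol[[nm]] <- st$roll[match(alignment[[nm]], stidx)]
      inside <- pidx >= roll_region[1] & pidx <= roll_region[2]
      use <- inside[-length(inside)] & inside[-1]
      avg_roll <- mean(st$roll[use])
      mean_twist <- mean(st$twist)
    } else { avg_roll <- NA; mean_twist <- NA }
    nuc <- r$nucleotides
    states <- if (is.data.frame(nuc)) table(factor(nuc$state,
                                                  levels = c("BI", "intermediate", "BII", "undefined")))
              else rep(NA, 4)
    summ <- rbind(summ, data.frame(
      complex = nm,
      n_bp = if (is.data.frame(prs)) nrow(prs) else NA,
      mean_twist = mean_twist, avg_roll_region = avg_roll,
      n_BI = states[[1]], n_intermediate = states[[2]], n_BII = states[[3]],
      bsa = if (is.data.frame(r$bsa)) r$bsa$bsa[1] else NA,
      stringsAsFactors = FALSE))
  }
  list(grooves = gro, rolls = rol, summary = summ)
}
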