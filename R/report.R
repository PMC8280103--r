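## Report assembly: tabular outputs with the shapes of the conventional
## mitogenome-paper tables (gene organization, composition/skewness,
## codon usage, Ka/Ks, gene-order comparison).

## fixed rounding profile, applied only at serialization: percentages
## 2 dp, skews 3 dp, RSCU 2 dp (the precision such tables are printed at)
.fmtPct <- function(x) round(x, 2)
.fmtSkew <- function(x) round(x, 3)
.fmtRscu <- function(x) round(x, 2)

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.writeRunLog <- function(outDir, stage, params) {
  log <- file.path(outDir, paste0(stage, "_params.json"))
  jsonlite::write_json(params, log, auto_unbox = TRUE, pretty = TRUE)
  invisible(log)
}

#' Characterize an annotated mitogenome
#'
#' Writes the three core characterization reports to a directory: the
#' gene-organization table (\code{annotation.tsv}), the per-region
#' composition and skewness table (\code{composition.tsv}), and the
#' circular adjacency report (\code{adjacency.tsv} plus
#' \code{adjacency_summary.tsv}). When the annotation carries no
#' sequence, the composition table is skipped with a warning and the
#' coordinate-based reports are still produced. A JSON parameter log
#' accompanies the reports. Output is deterministic: rerunning
#' overwrites byte-identical files.
#'
#' @param ann a \code{\linkS4class{MitoAnnotation}}.
#' @param outDir output directory (created if needed).
#' @param codeId translation table (default 5).
#' @return invisibly, named vector of written paths.
#' @export
characterizeMitogenome <- function(ann, outDir, codeId = 5L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(annotation = file.path(outDir, "annotation.tsv"))
  writeAnnotationTable(ann, paths[["annotation"]], codeId = codeId)
  if (!is.null(genomeSequence(ann))) {
    comp <- compositionReport(ann)
    comp$A_pct <- .fmtPct(comp$A_pct); comp$T_pct <- .fmtPct(comp$T_pct)
    comp$G_pct <- .fmtPct(comp$G_pct); comp$C_pct <- .fmtPct(comp$C_pct)
    comp$AT_pct <- .fmtPct(comp$AT_pct)
    comp$AT_skew <- .fmtSkew(comp$AT_skew)
    comp$GC_skew <- .fmtSkew(comp$GC_skew)
    paths <- c(paths, composition = file.path(outDir, "composition.tsv"))
    .writeTsv(comp, paths[["composition"]])
  } else {
    warning("annotation carries no sequence; composition table skipped")
  }
  adj <- adjacencyReport(ann)
  paths <- c(paths, adjacency = file.path(outDir, "adjacency.tsv"),
             adjacency_summary = file.path(outDir,
                                           "adjacency_summary.tsv"))
  .writeTsv(adj$pairs, paths[["adjacency"]])
  .writeTsv(data.frame(
    n_pairs = nrow(adj$pairs), n_spacers = adj$n_spacers,
    n_overlaps = adj$n_overlaps, largest_spacer = adj$largest_spacer,
    largest_overlap = adj$largest_overlap,
    largest_overlap_between = paste(adj$largest_overlap_pair,
                                    collapse = "/")),
    paths[["adjacency_summary"]])
  .writeRunLog(outDir, "characterize",
               list(stage = "characterize", code_id = codeId,
                    genome_length = genomeLength(ann),
                    n_features = nrow(features(ann)),
                    sequence_attached = !is.null(genomeSequence(ann))))
  invisible(paths)
}

#' Write the codon-usage table of a mitogenome
#'
#' 64-row table of codon counts, RSCU, and usage per thousand codons
#' (CDspT), over all protein-coding genes of the annotation.
#'
#' @param ann a \code{\linkS4class{MitoAnnotation}} carrying a sequence,
#'   or a prebuilt \code{\linkS4class{CodonUsageTable}}.
#' @param path output TSV path.
#' @param codeId translation table (default 5).
#' @return invisibly, \code{path}.
#' @export
codonUsageReport <- function(ann, path, codeId = 5L) {
  tab <- if (methods::is(ann, "CodonUsageTable")) rscu(ann, codeId)
         else annotationCodonUsage(ann, codeId = codeId)
  code <- geneticCode(codeId)
  aa <- unname(code$aa[chartr("U", "T", names(codonCounts(tab)))])
  df <- data.frame(codon = names(codonCounts(tab)),
                   amino_acid = aa,
                   count = unname(codonCounts(tab)),
                   rscu = .fmtRscu(unname(rscuValues(tab))),
                   per_thousand = round(1000 * unname(codonCounts(tab)) /
                                          totalCodons(tab), 2),
                   stringsAsFactors = FALSE)
  .writeTsv(df, path)
}

#' Write a per-gene Ka/Ks report for an aligned CDS panel
#'
#' @param panel input of \code{\link{panelKaKs}} (or a directory/FASTA
#'   paths readable by \code{\link{readCdsPanel}}).
#' @param path output TSV path.
#' @param focal optional focal species (see \code{\link{panelKaKs}}).
#' @param codeId translation table (default 5).
#' @return invisibly, the report \code{data.frame}.
#' @export
kaksReport <- function(panel, path, focal = NULL, codeId = 5L) {
  if (is.character(panel)) {
    if (length(panel) == 1L && dir.exists(panel))
      panel <- list.files(panel, pattern = "\\.(fa|fasta|fna)$",
                          full.names = TRUE, ignore.case = TRUE)
    panel <- readCdsPanel(panel)
  }
  res <- panelKaKs(panel, focal = focal, codeId = codeId)
  out <- res
  for (col in c("mean_Ka", "mean_Ks", "mean_KaKs"))
    out[[col]] <- round(out[[col]], 4)
  .writeTsv(out, path)
  invisible(res)
}

#' Gene-order comparison report
#'
#' Compares a derived gene order (from an annotation, an order string,
#' or a \code{\linkS4class{GeneOrder}}) against a named built-in
#' reference or a user-supplied order: breakpoint count, detected
#' rearrangement events, single-TDRL reachability, and a text linear map
#' of both arrangements.
#'
#' @param derived a \code{MitoAnnotation}, \code{GeneOrder} or order
#'   string.
#' @param reference \code{"decapoda"}, \code{"caridea"}, a
#'   \code{GeneOrder}, or an order string.
#' @param outDir output directory.
#' @param maxMoved search bound of \code{\link{detectEvents}}.
#' @return invisibly, the \code{RearrangementReport} with the TDRL flag
#'   attached as \code{$tdrl_one_step}.
#' @export
geneOrderReport <- function(derived, reference = "decapoda", outDir,
                            maxMoved = 3L) {
  as_order <- function(x) {
    if (methods::is(x, "GeneOrder")) x
    else if (methods::is(x, "MitoAnnotation")) orderFromAnnotation(x)
    else if (is.character(x) && x[1] %in% c("decapoda", "caridea"))
      ancestralGeneOrder(x[1])
    else GeneOrder(x)
  }
  der <- as_order(derived)
  ref <- as_order(reference)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ev <- detectEvents(der, ref, maxMoved = maxMoved)
  tdrl <- tdrlOneStep(der, ref)
  ev$tdrl_one_step <- as.logical(tdrl)
  fmt <- function(v) if (length(v) == 0L) "none"
                     else if (all(is.na(v))) "NA"
                     else paste(v, collapse = ",")
  .writeTsv(data.frame(
    breakpoints = ev$breakpoints,
    translocated = fmt(ev$translocated),
    inverted = fmt(ev$inverted),
    duplicated = fmt(ev$duplicated),
    complex = ev$complex,
    tdrl_one_step = as.logical(tdrl),
    tdrl_reason = attr(tdrl, "reason") %||% ""),
    file.path(outDir, "gene_order_events.tsv"))
  map <- c("# linear maps (circular orders cut at their first token)",
           paste0("derived\t", gsub(",", " ", as.character(der))),
           paste0("reference\t", gsub(",", " ", as.character(ref))))
  writeLines(map, file.path(outDir, "gene_order_map.txt"))
  invisible(ev)
}
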