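## Published annotation data for the Exhippolysmata ensirostris
## mitogenome (GenBank accession MK681888), shipped as plain-text tables
## under inst/extdata so the coordinate-level analyses can run offline.
## The genome sequence itself is not bundled; composition analyses on
## the real record require downloading the accession.

#' Published gene organization of the E. ensirostris mitogenome
#'
#' The 38 annotated features (37 genes plus the control region) of
#' GenBank accession MK681888, with strands, 1-based coordinates,
#' anticodons and reported start/stop codons, loaded from the bundled
#' feature table.
#'
#' @return a \code{\linkS4class{MitoAnnotation}} of 16,350 bp without
#'   sequence.
#' @examples
#' ann <- mk681888Annotation()
#' sum(featureLengths(ann)[features(ann)$type == "PCG"])
#' @export
mk681888Annotation <- function() {
  path <- system.file("extdata", "MK681888_features.tsv",
                      package = "MitoCircle", mustWork = TRUE)
  parseFeatureTable(path, genomeLength = 16350L, circular = TRUE)
}

#' Published codon usage of the E. ensirostris mitogenome
#'
#' The 64 codon counts and RSCU values reported for the protein-coding
#' genes of accession MK681888 (invertebrate mitochondrial code), loaded
#' from the bundled table. The \code{rscu} column carries the published
#' values at their printed 2-decimal precision; recompute from the
#' counts with \code{\link{codonUsageTable}} / \code{\link{rscu}} to get
#' full precision.
#'
#' @return \code{data.frame} with columns \code{codon},
#'   \code{amino_acid}, \code{count}, \code{rscu}.
#' @examples
#' cc <- mk681888CodonCounts()
#' tab <- codonUsageTable(stats::setNames(cc$count, cc$codon))
#' round(rscuValues(tab)[["UUA"]], 2)
#' @export
mk681888CodonCounts <- function() {
  path <- system.file("extdata", "MK681888_codon_usage.tsv",
                      package = "MitoCircle", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
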