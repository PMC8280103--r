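## CDS extraction, start/stop identification, codon counting and RSCU.

#' Extract the reading-sense CDS of a protein-coding gene
#'
#' Returns the coding sequence of a PCG on its reading strand: the
#' heavy-strand slice for \code{"+"} genes, its reverse complement for
#' \code{"-"} genes, with circular-origin wrap handled. A CDS whose
#' length is not a multiple of 3 (common in mitogenomes, where truncated
#' stop codons are completed by polyadenylation) is flagged via the
#' \code{"incomplete_frame"} attribute.
#'
#' @param ann a \code{\linkS4class{MitoAnnotation}} carrying a sequence.
#' @param gene name of a protein-coding gene feature.
#' @return character CDS with attribute \code{incomplete_frame}.
#' @export
extractCDS <- function(ann, gene) {
  f <- features(ann)
  i <- which(f$name == gene)
  if (length(i) == 0L) stop("no feature named ", gene)
  i <- i[1]
  if (f$type[i] != "PCG")
    stop(gene, " is not a protein-coding gene")
  cds <- .extractRegion(ann, f$start[i], f$end[i], f$strand[i])
  attr(cds, "incomplete_frame") <- (nchar(cds) %% 3L) != 0L
  cds
}

#' Identify start and stop codons of a CDS
#'
#' The start codon is the first triplet. The stop is the last complete
#' in-frame triplet when that triplet is a stop under the genetic code;
#' otherwise the trailing 1-2 nucleotides beyond the last full codon are
#' reported as an incomplete stop (the mitochondrial \code{T}/\code{TA}
#' convention, completed to UAA by polyadenylation of the mRNA).
#'
#' @param cds character CDS (reading sense), length at least 6.
#' @param codeId translation table (default 5).
#' @return list with \code{start}, \code{stop} (codon, or the trailing
#'   nucleotides for an incomplete stop), \code{incomplete} (logical).
#' @examples
#' detectStartStop("ATGAAATAA")
#' @export
detectStartStop <- function(cds, codeId = 5L) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) < 6L) stop("CDS shorter than two codons")
  code <- geneticCode(codeId)
  startc <- substr(cds, 1L, 3L)
  r <- nchar(cds) %% 3L
  m <- nchar(cds) %/% 3L
  lastc <- substr(cds, 3L * m - 2L, 3L * m)
  if (r == 0L && lastc %in% code$stops) {
    list(start = startc, stop = lastc, incomplete = FALSE)
  } else if (r > 0L) {
    list(start = startc, stop = substr(cds, 3L * m + 1L, nchar(cds)),
         incomplete = TRUE)
  } else {
    ## full frame but no terminal stop: report the last codon, flagged
    list(start = startc, stop = lastc, incomplete = TRUE)
  }
}

#' Count in-frame codons across coding sequences
#'
#' Tallies complete in-frame triplets over a set of CDS (trailing partial
#' codons ignored), producing the counts of a conventional codon-usage
#' table. Triplets containing non-ACGT characters are skipped and their
#' number recorded. Stop codons are tallied by default, so internal and
#' terminal stop triplets appear in the stop family, as published
#' whole-PCG codon tables do.
#'
#' @param cds character vector (or list) of CDS strings, reading sense.
#' @param codeId translation table (default 5).
#' @param includeStop tally stop codons (default \code{TRUE}).
#' @return a \code{\linkS4class{CodonUsageTable}} (RSCU filled); the
#'   \code{"skipped"} attribute counts ambiguous triplets.
#' @export
countCodons <- function(cds, codeId = 5L, includeStop = TRUE) {
  cds <- toupper(unlist(cds, use.names = FALSE))
  stopifnot(all(nchar(cds) >= 3L))
  code <- geneticCode(codeId)
  trip <- unlist(lapply(cds, .splitCodons), use.names = FALSE)
  ok <- grepl("^[ACGT]{3}$", trip)
  skipped <- sum(!ok)
  trip <- trip[ok]
  if (!includeStop) trip <- trip[!(trip %in% code$stops)]
  cnt <- table(factor(trip, levels = .DNA_CODONS))
  counts <- stats::setNames(as.numeric(cnt), .RNA_CODONS)
  out <- codonUsageTable(counts, codeId = codeId)
  attr(out, "skipped") <- skipped
  out
}

#' Relative synonymous codon usage
#'
#' For codon \eqn{c} in synonymous family \eqn{F},
#' \eqn{RSCU(c) = n_c / (\sum_{f \in F} n_f / |F|)}: the observed count
#' divided by the count expected under uniform usage within the family.
#' Families are the amino-acid classes of the genetic code, with the stop
#' codons forming their own family (\{UAA, UAG\} under code 5). Families
#' with zero total get RSCU 0 for all members and are listed in the
#' \code{"zero_families"} attribute. The per-family RSCU values of any
#' nonzero family sum exactly to the family size, and the statistic is
#' invariant to scaling all counts.
#'
#' @param table a \code{\linkS4class{CodonUsageTable}} (counts used,
#'   RSCU recomputed).
#' @param codeId translation table; defaults to the table's own code.
#' @return the table with its \code{rscu} slot filled.
#' @examples
#' tab <- codonUsageTable(c(UUA = 106, UUG = 32, CUU = 95, CUC = 74,
#'                          CUA = 99, CUG = 29))
#' round(rscuValues(tab)[["UUA"]], 2)
#' @export
rscu <- function(table, codeId = NULL) {
  stopifnot(methods::is(table, "CodonUsageTable"))
  if (is.null(codeId)) codeId <- table@codeId
  code <- geneticCode(codeId)
  counts <- table@counts
  vals <- stats::setNames(rep(0, 64), .RNA_CODONS)
  zero <- character()
  for (famname in names(code$families)) {
    fam_dna <- code$families[[famname]]
    fam <- chartr("T", "U", fam_dna)
    tot <- sum(counts[fam])
    if (tot == 0) {
      zero <- c(zero, famname)
      next
    }
    vals[fam] <- counts[fam] / (tot / length(fam))
  }
  table@rscu <- vals
  table@codeId <- as.integer(codeId)
  attr(table, "zero_families") <- zero
  table
}

#' Codon usage of all protein-coding genes of an annotation
#'
#' Extracts every PCG CDS on its reading strand and tallies codons and
#' RSCU across them.
#'
#' @param ann a \code{\linkS4class{MitoAnnotation}} carrying a sequence.
#' @param codeId translation table (default 5).
#' @param includeStop see \code{\link{countCodons}}.
#' @return a \code{\linkS4class{CodonUsageTable}}.
#' @export
annotationCodonUsage <- function(ann, codeId = 5L, includeStop = TRUE) {
  f <- features(ann)
  pcgs <- f$name[f$type == "PCG"]
  if (length(pcgs) == 0L)
    stop("annotation contains no protein-coding genes")
  cds <- vapply(pcgs, function(g) as.character(extractCDS(ann, g)), "")
  countCodons(cds, codeId = codeId, includeStop = includeStop)
}
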