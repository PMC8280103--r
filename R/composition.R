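## Base composition, strand skews, and circular overlap/spacer accounting.

#' Strand skew statistic
#'
#' Computes the strand-asymmetry statistic \eqn{(x - y)/(x + y)} used for
#' AT skew (\code{skew(A, T)}) and GC skew (\code{skew(G, C)}). Because
#' the statistic is scale invariant it accepts raw counts or percentages
#' interchangeably.
#'
#' @param x,y nonnegative counts or percentages (vectorized).
#' @return dimensionless skew in \eqn{[-1, 1]}.
#' @examples
#' skew(32.51, 31.91)  # AT skew from whole-genome base percentages
#' skew(14.24, 21.33)  # GC skew, negative: C over-represented
#' @export
skew <- function(x, y) {
  if (any(x + y == 0))
    stop("skew undefined: x + y = 0")
  (x - y) / (x + y)
}

#' Nucleotide composition of a genome region class
#'
#' Tallies A/T/G/C, their percentages, A+T content and the AT/GC skews
#' for a region of an annotated mitogenome, reproducing the rows of a
#' conventional composition-and-skewness table. Single genes are counted
#' on their reading-sense strand (reverse complement for light-strand
#' genes); the whole-genome row is counted on the heavy strand; class
#' rows (\code{"PCG"}, \code{"tRNA"}, \code{"rRNA"}, \code{"CR"})
#' concatenate the reading-sense sequences of their member genes in
#' annotation order. Ambiguous bases are excluded from all numerators and
#' denominators and reported separately.
#'
#' @param ann a \code{\linkS4class{MitoAnnotation}} carrying a sequence.
#' @param region a gene name, a class among \code{"PCG"}, \code{"tRNA"},
#'   \code{"rRNA"}, \code{"CR"}, or \code{"mitogenome"} (alias
#'   \code{"all"}) for the whole genome.
#' @return one-row \code{data.frame} with columns \code{region},
#'   \code{size_bp}, \code{A}, \code{T}, \code{G}, \code{C},
#'   \code{A_pct}, \code{T_pct}, \code{G_pct}, \code{C_pct},
#'   \code{AT_pct}, \code{AT_skew}, \code{GC_skew}, \code{ambiguous}.
#'   Values are kept at full precision; rounding happens only in report
#'   writers.
#' @export
regionComposition <- function(ann, region) {
  if (is.null(genomeSequence(ann)))
    stop("annotation carries no sequence")
  f <- features(ann)
  region0 <- region
  if (tolower(region) %in% c("mitogenome", "all", "genome")) {
    seqs <- as.character(genomeSequence(ann))
    label <- "Mitogenome"
  } else if (region %in% c("PCG", "tRNA", "rRNA", "CR", "PCGs", "tRNAs",
                           "rRNAs")) {
    cls <- sub("s$", "", region)
    idx <- which(f$type == cls)
    if (length(idx) == 0L)
      stop("no features of class ", region0)
    seqs <- paste(vapply(idx, function(i)
      .extractRegion(ann, f$start[i], f$end[i], f$strand[i]), ""),
      collapse = "")
    label <- if (cls == "CR") "CR" else paste0(cls, "s")
  } else {
    idx <- which(f$name == region)
    if (length(idx) == 0L)
      stop("no feature named ", region0)
    i <- idx[1]
    seqs <- .extractRegion(ann, f$start[i], f$end[i], f$strand[i])
    label <- region0
  }
  .composition1(seqs, label)
}

.composition1 <- function(seqchar, label) {
  cnt <- Biostrings::letterFrequency(Biostrings::DNAString(seqchar),
                                     c("A", "T", "G", "C"))
  n <- sum(cnt)
  amb <- nchar(seqchar) - n
  pct <- 100 * cnt / n
  data.frame(region = label, size_bp = nchar(seqchar),
             A = unname(cnt["A"]), T = unname(cnt["T"]),
             G = unname(cnt["G"]), C = unname(cnt["C"]),
             A_pct = unname(pct["A"]), T_pct = unname(pct["T"]),
             G_pct = unname(pct["G"]), C_pct = unname(pct["C"]),
             AT_pct = unname(pct["A"] + pct["T"]),
             AT_skew = skew(cnt[["A"]], cnt[["T"]]),
             GC_skew = skew(cnt[["G"]], cnt[["C"]]),
             ambiguous = amb,
             stringsAsFactors = FALSE)
}

#' Composition table for a whole mitogenome
#'
#' Assembles the standard composition-and-skewness table: one row for the
#' whole mitogenome (heavy strand), one per protein-coding gene (reading
#' sense), and one per class (PCGs, tRNAs, rRNAs, CR).
#'
#' @param ann a \code{\linkS4class{MitoAnnotation}} carrying a sequence.
#' @return \code{data.frame}, one row per region, columns as in
#'   \code{\link{regionComposition}}.
#' @export
compositionReport <- function(ann) {
  f <- features(ann)
  pcgs <- f$name[f$type == "PCG"]
  regions <- c("mitogenome", pcgs,
               c("PCG", "tRNA", "rRNA", "CR")[
                 c("PCG", "tRNA", "rRNA", "CR") %in% f$type])
  do.call(rbind, lapply(regions, function(r) regionComposition(ann, r)))
}

#' Circular adjacency report: spacers, abutments and overlaps
#'
#' Scans consecutive features around the circle (ordered by start,
#' wrapping last back to first) and reports for each pair the signed gap
#' \code{start(next) - end(prev) - 1} under modular arithmetic: positive
#' gaps are intergenic spacers, negative gaps overlaps of
#' \code{|gap|} bp, zero abutting genes.
#'
#' @param ann a circular \code{\linkS4class{MitoAnnotation}} with at
#'   least two features.
#' @return list of class \code{"AdjacencyReport"} with elements
#'   \code{pairs} (data.frame \code{upstream}, \code{downstream},
#'   \code{gap_bp}), \code{n_spacers}, \code{n_overlaps},
#'   \code{largest_spacer}, \code{largest_overlap},
#'   \code{largest_overlap_pair}, \code{largest_spacer_pair}.
#' @export
adjacencyReport <- function(ann) {
  f <- features(ann)
  if (nrow(f) < 2L) stop("adjacency report needs at least 2 features")
  if (!isCircular(ann)) stop("adjacency report assumes a circular genome")
  L <- genomeLength(ann)
  n <- nrow(f)
  nxt <- c(seq_len(n)[-1], 1L)
  gap <- f$start[nxt] - f$end - 1L
  gap[n] <- gap[n] + L  # wrap last -> first
  pairs <- data.frame(upstream = f$name, downstream = f$name[nxt],
                      gap_bp = as.integer(gap), stringsAsFactors = FALSE)
  ov <- pairs$gap_bp < 0L
  sp <- pairs$gap_bp > 0L
  res <- list(
    pairs = pairs,
    n_spacers = sum(sp),
    n_overlaps = sum(ov),
    largest_spacer = if (any(sp)) max(pairs$gap_bp[sp]) else 0L,
    largest_overlap = if (any(ov)) max(abs(pairs$gap_bp[ov])) else 0L,
    largest_spacer_pair = if (any(sp))
      unlist(pairs[which.max(pairs$gap_bp), c("upstream", "downstream")])
      else character(),
    largest_overlap_pair = if (any(ov))
      unlist(pairs[which.min(pairs$gap_bp), c("upstream", "downstream")])
      else character())
  class(res) <- "AdjacencyReport"
  res
}

#' @export
print.AdjacencyReport <- function(x, ...) {
  cat(sprintf(
    "AdjacencyReport: %d pairs, %d spacers, %d overlaps\n",
    nrow(x$pairs), x$n_spacers, x$n_overlaps))
  if (x$n_overlaps > 0)
    cat(sprintf("  largest overlap: %d bp (%s/%s)\n", x$largest_overlap,
                x$largest_overlap_pair[1], x$largest_overlap_pair[2]))
  if (x$n_spacers > 0)
    cat(sprintf("  largest spacer:  %d bp (%s/%s)\n", x$largest_spacer,
                x$largest_spacer_pair[1], x$largest_spacer_pair[2]))
  invisible(x)
}
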