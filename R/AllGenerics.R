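## Generics, accessors and show methods.

#' @name MitoAnnotation-accessors
#' @title Accessors for MitoAnnotation objects
#' @description Accessors for the slots of a
#'   \code{\linkS4class{MitoAnnotation}}: the genome length, circularity,
#'   the feature table, the heavy-strand sequence, and wrap-aware feature
#'   lengths.
#' @param x,object a \code{MitoAnnotation}.
#' @return \code{genomeLength}: integer bp; \code{isCircular}: logical;
#'   \code{features}: the feature \code{data.frame}; \code{genomeSequence}:
#'   a \code{DNAString} or \code{NULL}; \code{featureLengths}: named
#'   integer vector of feature lengths in bp.
NULL

#' @rdname MitoAnnotation-accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname MitoAnnotation-accessors
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))
#' @rdname MitoAnnotation-accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname MitoAnnotation-accessors
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))
#' @rdname MitoAnnotation-accessors
#' @export
setGeneric("featureLengths", function(x) standardGeneric("featureLengths"))

#' @rdname MitoAnnotation-accessors
#' @export
setMethod("genomeLength", "MitoAnnotation", function(x) x@genomeLength)
#' @rdname MitoAnnotation-accessors
#' @export
setMethod("isCircular", "MitoAnnotation", function(x) x@circular)
#' @rdname MitoAnnotation-accessors
#' @export
setMethod("features", "MitoAnnotation", function(x) x@features)
#' @rdname MitoAnnotation-accessors
#' @export
setMethod("genomeSequence", "MitoAnnotation", function(x) x@sequence)

#' @rdname MitoAnnotation-accessors
#' @export
setMethod("featureLengths", "MitoAnnotation", function(x) {
  f <- x@features
  len <- ifelse(f$end >= f$start,
                f$end - f$start + 1L,
                x@genomeLength - f$start + 1L + f$end)
  stats::setNames(as.integer(len), f$name)
})

#' @rdname MitoAnnotation-accessors
#' @export
setMethod("length", "MitoAnnotation", function(x) nrow(x@features))

setMethod("show", "MitoAnnotation", function(object) {
  f <- object@features
  cat(sprintf("MitoAnnotation: %s genome of %d bp, %d features\n",
              if (object@circular) "circular" else "linear",
              object@genomeLength, nrow(f)))
  tab <- table(factor(f$type, levels = c("PCG", "tRNA", "rRNA", "CR",
                                         "other")))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  heavy strand: %d, light strand: %d\n",
              sum(f$strand == "+"), sum(f$strand == "-")))
  cat(sprintf("  sequence: %s\n",
              if (is.null(object@sequence)) "absent" else "attached"))
})

#' @name GeneOrder-accessors
#' @title Accessors for GeneOrder objects
#' @param x,object a \code{\linkS4class{GeneOrder}}.
#' @return \code{orderTokens}: character vector of tokens;
#'   \code{orientations}: parallel \code{"+"}/\code{"-"} vector;
#'   \code{length}: number of tokens.
NULL

#' @rdname GeneOrder-accessors
#' @export
setGeneric("orderTokens", function(x) standardGeneric("orderTokens"))
#' @rdname GeneOrder-accessors
#' @export
setGeneric("orientations", function(x) standardGeneric("orientations"))

#' @rdname GeneOrder-accessors
#' @export
setMethod("orderTokens", "GeneOrder", function(x) x@tokens)
#' @rdname GeneOrder-accessors
#' @export
setMethod("orientations", "GeneOrder", function(x) x@orientation)
#' @rdname GeneOrder-accessors
#' @export
setMethod("length", "GeneOrder", function(x) length(x@tokens))

#' @rdname GeneOrder-accessors
#' @export
setMethod("as.character", "GeneOrder", function(x) {
  paste(ifelse(x@orientation == "-", paste0("-", x@tokens), x@tokens),
        collapse = ",")
})

setMethod("show", "GeneOrder", function(object) {
  cat(sprintf("GeneOrder with %d tokens (circular):\n",
              length(object@tokens)))
  cat("  ", as.character(object), "\n", sep = "")
})

#' @name CodonUsageTable-accessors
#' @title Accessors for CodonUsageTable objects
#' @param x,object a \code{\linkS4class{CodonUsageTable}}.
#' @return \code{codonCounts}: named numeric(64) of counts;
#'   \code{rscuValues}: named numeric(64) of RSCU values;
#'   \code{totalCodons}: total tallied codons.
NULL

#' @rdname CodonUsageTable-accessors
#' @export
setGeneric("codonCounts", function(x) standardGeneric("codonCounts"))
#' @rdname CodonUsageTable-accessors
#' @export
setGeneric("rscuValues", function(x) standardGeneric("rscuValues"))
#' @rdname CodonUsageTable-accessors
#' @export
setGeneric("totalCodons", function(x) standardGeneric("totalCodons"))

#' @rdname CodonUsageTable-accessors
#' @export
setMethod("codonCounts", "CodonUsageTable", function(x) x@counts)
#' @rdname CodonUsageTable-accessors
#' @export
setMethod("rscuValues", "CodonUsageTable", function(x) x@rscu)
#' @rdname CodonUsageTable-accessors
#' @export
setMethod("totalCodons", "CodonUsageTable", function(x) sum(x@counts))

setMethod("show", "CodonUsageTable", function(object) {
  cat(sprintf(
    "CodonUsageTable: %d codons tallied, translation table %d\n",
    sum(object@counts), object@codeId))
  top <- sort(object@counts, decreasing = TRUE)[1:5]
  cat("  most used: ",
      paste(sprintf("%s (%g)", names(top), top), collapse = ", "),
      "\n", sep = "")
})
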