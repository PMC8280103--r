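## Core S4 containers.

setClassUnion("DNAStringOrNULL", c("DNAString", "NULL"))

#' MitoAnnotation: an annotated circular mitochondrial genome
#'
#' @description
#' The central container of the package: the length and (optional)
#' sequence of a mitochondrial genome together with its ordered gene
#' features. Coordinates are 1-based inclusive, as in GenBank flat files.
#' A feature may wrap the circular origin, in which case \code{end <
#' start} and its length is computed modulo the genome length.
#'
#' @slot genomeLength genome size in bp.
#' @slot circular logical; mitogenomes are circular molecules.
#' @slot features \code{data.frame} with columns \code{name} (canonical
#'   token, occurrence-suffixed for duplications), \code{type}
#'   (\code{PCG/tRNA/rRNA/CR/other}), \code{strand} (\code{"+"} heavy,
#'   \code{"-"} light), \code{start}, \code{end}, \code{anticodon}
#'   (\code{NA} except tRNAs), \code{flagged} (name not canonicalizable),
#'   ordered by ascending start.
#' @slot sequence \code{\link[Biostrings]{DNAString}} of exactly
#'   \code{genomeLength} bases (heavy strand), or \code{NULL}.
#'
#' @seealso \code{\link{parseFeatureTable}}, \code{\link{parseGenBank}},
#'   \code{\link{generateGenome}}
#' @export
setClass("MitoAnnotation",
  slots = c(genomeLength = "integer",
            circular = "logical",
            features = "data.frame",
            sequence = "DNAStringOrNULL"))

.FEATURE_COLS <- c("name", "type", "strand", "start", "end",
                   "anticodon", "flagged")

setValidity("MitoAnnotation", function(object) {
  msg <- character()
  L <- object@genomeLength
  f <- object@features
  if (length(L) != 1L || is.na(L) || L < 1L)
    msg <- c(msg, "genomeLength must be a single positive integer")
  if (!all(.FEATURE_COLS %in% names(f)))
    msg <- c(msg, paste("features must have columns:",
                        paste(.FEATURE_COLS, collapse = ", ")))
  if (nrow(f) > 0 && all(c("start", "end", "strand", "type") %in% names(f))) {
    if (any(f$start < 1L | f$start > L | f$end < 1L | f$end > L))
      msg <- c(msg, "feature coordinates must lie in [1, genomeLength]")
    if (!all(f$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
    if (any(f$end < f$start) && !isTRUE(object@circular))
      msg <- c(msg, "origin-wrapping features require a circular genome")
    if (is.unsorted(f$start))
      msg <- c(msg, "features must be ordered by ascending start")
    bad_ac <- !is.na(f$anticodon) & f$type != "tRNA"
    if (any(bad_ac))
      msg <- c(msg, "anticodon may only be set on tRNA features")
    dup <- duplicated(f$name)
    if (any(dup))
      msg <- c(msg, paste("duplicate feature names (use occurrence",
                          "suffixes like 'trnQ#2'):",
                          paste(unique(f$name[dup]), collapse = ", ")))
  }
  if (!is.null(object@sequence) && length(object@sequence) != L)
    msg <- c(msg, "sequence length must equal genomeLength")
  if (length(msg)) msg else TRUE
})

#' Construct a MitoAnnotation
#'
#' @param features data.frame with at least \code{name}, \code{strand},
#'   \code{start}, \code{end}; \code{type}, \code{anticodon} and
#'   \code{flagged} are filled in when absent. Gene names are
#'   canonicalized unless \code{canonicalize = FALSE}.
#' @param genomeLength genome size in bp.
#' @param circular logical, default \code{TRUE}.
#' @param sequence optional heavy-strand sequence
#'   (\code{DNAString} or character).
#' @param canonicalize canonicalize gene names (default \code{TRUE}).
#' @return a \code{\linkS4class{MitoAnnotation}}.
#' @examples
#' ft <- data.frame(name = c("cox1", "trnL2"), strand = c("+", "+"),
#'                  start = c(1L, 1540L), end = c(1536L, 1605L))
#' MitoAnnotation(ft, genomeLength = 2000L)
#' @export
MitoAnnotation <- function(features, genomeLength, circular = TRUE,
                           sequence = NULL, canonicalize = TRUE) {
  stopifnot(is.data.frame(features),
            all(c("name", "strand", "start", "end") %in% names(features)))
  f <- features
  f$start <- as.integer(f$start)
  f$end <- as.integer(f$end)
  f$name <- as.character(f$name)
  if (canonicalize) {
    cn <- canonicalizeGeneName(f$name)
    f$flagged <- attr(cn, "flagged")
    f$name <- as.character(cn)
  } else if (is.null(f$flagged)) {
    f$flagged <- FALSE
  }
  if (is.null(f$type)) f$type <- geneFeatureType(f$name)
  if (is.null(f$anticodon)) f$anticodon <- NA_character_
  f$anticodon <- as.character(f$anticodon)
  f$anticodon[f$type != "tRNA"] <- NA_character_
  ## disambiguate repeated names with occurrence suffixes
  if (anyDuplicated(f$name)) {
    occ <- stats::ave(seq_len(nrow(f)), f$name, FUN = seq_along)
    rep2 <- occ > 1L
    f$name[rep2] <- paste0(f$name[rep2], "#", occ[rep2])
  }
  f <- f[order(f$start), .FEATURE_COLS, drop = FALSE]
  rownames(f) <- NULL
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  methods::new("MitoAnnotation",
               genomeLength = as.integer(genomeLength),
               circular = as.logical(circular),
               features = f, sequence = sequence)
}

#' GeneOrder: a signed circular gene arrangement
#'
#' @description
#' The arrangement of genes around a mitochondrial chromosome, as a
#' circular sequence of (token, orientation) pairs. Orientation \code{"+"}
#' is the heavy strand. Duplicated genes carry occurrence suffixes
#' (\code{"trnQ#2"}). Two \code{GeneOrder}s describe the same arrangement
#' iff one is a rotation of the other; \code{\link{normalizeOrder}} fixes
#' a deterministic rotation.
#'
#' @slot tokens character vector of gene tokens (circular; first element
#'   arbitrary unless normalized).
#' @slot orientation character vector of \code{"+"}/\code{"-"}, parallel
#'   to \code{tokens}.
#' @export
setClass("GeneOrder",
  slots = c(tokens = "character", orientation = "character"))

setValidity("GeneOrder", function(object) {
  msg <- character()
  if (length(object@tokens) == 0L)
    msg <- c(msg, "a GeneOrder must contain at least one token")
  if (length(object@tokens) != length(object@orientation))
    msg <- c(msg, "tokens and orientation must have equal length")
  if (!all(object@orientation %in% c("+", "-")))
    msg <- c(msg, "orientation must be '+' or '-'")
  if (anyDuplicated(object@tokens))
    msg <- c(msg, "duplicated tokens must carry occurrence suffixes")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneOrder
#'
#' @param tokens character vector of gene tokens, or a single string of
#'   comma/semicolon-separated signed tokens (\code{"cox1,-nad1,trnV"}
#'   or \code{"cox1,+; nad1,-"}) in which a \code{-} denotes the light
#'   strand.
#' @param orientation optional \code{"+"}/\code{"-"} vector parallel to
#'   \code{tokens}; defaults to all \code{"+"} when \code{tokens} is a
#'   plain vector.
#' @return a \code{\linkS4class{GeneOrder}}.
#' @examples
#' GeneOrder("cox1, -nad1, trnV")
#' @export
GeneOrder <- function(tokens, orientation = NULL) {
  if (length(tokens) == 1L && is.null(orientation) &&
      grepl("[,;]", tokens)) {
    parts <- trimws(strsplit(tokens, "[,;]")[[1]])
    parts <- parts[nzchar(parts)]
    ## "tok,+" dialect: a bare +/- element applies to the previous token
    signs <- parts %in% c("+", "-")
    if (any(signs)) {
      tok <- parts[!signs]
      ori <- rep("+", length(tok))
      j <- 0L
      for (p in parts) {
        if (p %in% c("+", "-")) ori[j] <- p else j <- j + 1L
      }
    } else {
      ori <- ifelse(startsWith(parts, "-"), "-", "+")
      tok <- sub("^[+-]", "", parts)
    }
    tokens <- tok
    orientation <- ori
  }
  if (is.null(orientation)) orientation <- rep("+", length(tokens))
  methods::new("GeneOrder", tokens = as.character(tokens),
               orientation = as.character(orientation))
}

#' CodonUsageTable: codon counts and RSCU under a genetic code
#'
#' @description
#' Counts of the 64 codons (RNA alphabet, as conventionally printed) over
#' a set of coding sequences, and their relative synonymous codon usage
#' (RSCU). RSCU of a codon is its count divided by the mean count of its
#' synonymous family; within every family with nonzero total the RSCU
#' values sum to the family size. Under the invertebrate mitochondrial
#' code (translation table 5) AGA/AGG encode Ser (an eight-member Ser
#' family), UGA encodes Trp, and the stop family is \{UAA, UAG\}.
#'
#' @slot counts named numeric(64), codon counts keyed by RNA codon.
#' @slot rscu named numeric(64); \code{NA} until \code{\link{rscu}} is
#'   applied; 0 for members of all-zero families.
#' @slot codeId integer NCBI translation table identifier.
#' @export
setClass("CodonUsageTable",
  slots = c(counts = "numeric", rscu = "numeric", codeId = "integer"))

setValidity("CodonUsageTable", function(object) {
  msg <- character()
  if (length(object@counts) != 64L || is.null(names(object@counts)))
    msg <- c(msg, "counts must be a named vector over the 64 codons")
  if (any(object@counts < 0, na.rm = TRUE))
    msg <- c(msg, "codon counts must be nonnegative")
  if (length(object@rscu) != 64L)
    msg <- c(msg, "rscu must have 64 entries")
  if (length(msg)) msg else TRUE
})

#' Construct a CodonUsageTable from codon counts
#'
#' @param counts named numeric vector of codon counts (RNA or DNA
#'   alphabet; missing codons count 0).
#' @param codeId NCBI translation table (default 5, invertebrate
#'   mitochondrial).
#' @param compute.rscu also fill the RSCU slot (default \code{TRUE}).
#' @return a \code{\linkS4class{CodonUsageTable}}.
#' @examples
#' codonUsageTable(c(UUA = 106, UUG = 32, CUU = 95, CUC = 74,
#'                   CUA = 99, CUG = 29))
#' @export
codonUsageTable <- function(counts, codeId = 5L, compute.rscu = TRUE) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  key <- toupper(chartr("T", "U", names(counts)))
  full <- stats::setNames(numeric(64), .RNA_CODONS)
  bad <- !(key %in% .RNA_CODONS)
  if (any(bad))
    stop("not codons: ", paste(names(counts)[bad], collapse = ", "))
  for (i in seq_along(counts)) full[key[i]] <- full[key[i]] + counts[i]
  obj <- methods::new("CodonUsageTable", counts = full,
                      rscu = stats::setNames(rep(NA_real_, 64), .RNA_CODONS),
                      codeId = as.integer(codeId))
  if (compute.rscu) obj <- rscu(obj) else obj
}

.RNA_CODONS <- {
  b <- c("U", "C", "A", "G")
  g <- expand.grid(third = b, second = b, first = b,
                   stringsAsFactors = FALSE)
  paste0(g$first, g$second, g$third)
}

.DNA_CODONS <- chartr("U", "T", .RNA_CODONS)
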