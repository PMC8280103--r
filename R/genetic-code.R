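## Genetic-code utilities shared by the codon-usage and Ka/Ks modules.

.codeCache <- new.env(parent = emptyenv())

#' A genetic code with its synonymous codon families
#'
#' Wraps \code{\link[Biostrings]{getGeneticCode}} into the structure the
#' codon-level operations need: the codon-to-amino-acid map (DNA
#' alphabet), the partition of the 64 codons into synonymous families,
#' and the stop codons. The default is NCBI translation table 5, the
#' invertebrate mitochondrial code, under which AGA/AGG encode serine
#' (giving an 8-codon Ser family), UGA encodes tryptophan, and the stop
#' family is \{UAA, UAG\}.
#'
#' @param codeId NCBI translation table identifier (default 5).
#' @return list with elements \code{codeId}, \code{aa} (named character,
#'   DNA codon to amino-acid one-letter code, stops \code{"*"}),
#'   \code{families} (list of DNA codon vectors keyed by amino acid,
#'   stops keyed \code{"*"}), \code{stops} (DNA stop codons).
#' @examples
#' geneticCode(5)$families[["W"]]  # UGA is Trp under code 5
#' @export
geneticCode <- function(codeId = 5L) {
  key <- as.character(codeId)
  if (!is.null(.codeCache[[key]])) return(.codeCache[[key]])
  aa <- Biostrings::getGeneticCode(key)
  aa <- aa[.DNA_CODONS]  # fixed codon order
  code <- list(codeId = as.integer(codeId),
               aa = aa,
               families = split(names(aa), aa),
               stops = names(aa)[aa == "*"])
  .codeCache[[key]] <- code
  code
}

## translate a vector of DNA codons
.translateCodons <- function(codons, code) unname(code$aa[codons])

## reverse complement for plain character sequences
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## split an in-frame character sequence into complete DNA triplets
.splitCodons <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character())
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}
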