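## Canonical 37-gene mitochondrial vocabulary and synonym handling.

#' @name geneVocabulary
#' @title The canonical mitochondrial gene vocabulary
#'
#' @description
#' Animal mitogenomes carry a near-universal set of 37 genes: 13
#' protein-coding genes (PCGs), 22 tRNAs and 2 rRNAs, plus the large
#' non-coding control region (CR). \code{mitoGeneTokens()} returns the
#' canonical tokens used throughout the package, optionally restricted to
#' one feature class.
#'
#' @param type optional class filter, one of \code{"PCG"}, \code{"tRNA"},
#'   \code{"rRNA"}, \code{"CR"}.
#' @return character vector of canonical gene tokens.
#' @examples
#' mitoGeneTokens("rRNA")
#' @export
mitoGeneTokens <- function(type = NULL) {
  if (is.null(type)) return(names(.GENE_TYPES))
  type <- match.arg(type, c("PCG", "tRNA", "rRNA", "CR"))
  names(.GENE_TYPES)[.GENE_TYPES == type]
}

.PCGS  <- c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
            "nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6")
.TRNAS <- c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH",
            "trnI", "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP",
            "trnQ", "trnR", "trnS1", "trnS2", "trnT", "trnV", "trnW",
            "trnY")
.RRNAS <- c("rrnL", "rrnS")

.GENE_TYPES <- c(
  stats::setNames(rep("PCG", length(.PCGS)), .PCGS),
  stats::setNames(rep("tRNA", length(.TRNAS)), .TRNAS),
  stats::setNames(rep("rRNA", length(.RRNAS)), .RRNAS),
  CR = "CR"
)

## amino-acid three-letter -> one-letter, for tRNA name parsing
.AA3 <- c(ala = "A", arg = "R", asn = "N", asp = "D", cys = "C",
          gln = "Q", glu = "E", gly = "G", his = "H", ile = "I",
          lys = "K", leu = "L", met = "M", phe = "F", pro = "P",
          ser = "S", thr = "T", trp = "W", tyr = "Y", val = "V")

## normalized-key synonym table (keys are lowercase alphanumerics)
.SYNONYMS <- c(
  co1 = "cox1", coi = "cox1", cox1 = "cox1", coxi = "cox1",
  co2 = "cox2", coii = "cox2", cox2 = "cox2", coxii = "cox2",
  co3 = "cox3", coiii = "cox3", cox3 = "cox3", coxiii = "cox3",
  cytb = "cob", cyb = "cob", cob = "cob", cytochromeb = "cob",
  nd1 = "nad1", nad1 = "nad1", nd2 = "nad2", nad2 = "nad2",
  nd3 = "nad3", nad3 = "nad3", nd4 = "nad4", nad4 = "nad4",
  nd4l = "nad4l", nad4l = "nad4l", nd5 = "nad5", nad5 = "nad5",
  nd6 = "nad6", nad6 = "nad6",
  atp6 = "atp6", atpase6 = "atp6", atp8 = "atp8", atpase8 = "atp8",
  `16s` = "rrnL", `16srrna` = "rrnL", rrnl = "rrnL", lrrna = "rrnL",
  lsu = "rrnL", mtlsu = "rrnL",
  `12s` = "rrnS", `12srrna` = "rrnS", rrns = "rrnS", srrna = "rrnS",
  ssu = "rrnS", mtssu = "rrnS",
  cr = "CR", dloop = "CR", controlregion = "CR",
  putativecontrolregion = "CR", atrichregion = "CR", ncr = "CR"
)

## anticodon-family qualifiers disambiguating the two Leu/Ser tRNAs
.LS_FAMILY <- c(uur = "trnL2", uua = "trnL2", uag = "trnL2",
                cun = "trnL1", taa = "trnL2", tag = "trnL2",
                agn = "trnS1", agy = "trnS1", gcu = "trnS1", tcn = "trnS2",
                ucn = "trnS2", uga = "trnS2", tga = "trnS2")

#' Canonicalize raw mitochondrial gene names
#'
#' Maps the many spellings found in GenBank records and feature tables
#' (\code{"COI"}, \code{"COX1"}, \code{"cox1"}; \code{"16S"},
#' \code{"l-rRNA"}; \code{"tRNA-Leu2"}, \code{"trnL(UUR)"};
#' \code{"D-loop"}, \code{"control region"}) onto the canonical tokens of
#' \code{\link{mitoGeneTokens}}. Names that cannot be canonicalized are
#' returned unchanged and flagged, never dropped. Occurrence suffixes used
#' for duplicated genes (\code{"trnQ#2"}) survive canonicalization of the
#' base name. The mapping is idempotent.
#'
#' @param raw character vector of raw gene names.
#' @return character vector of the same length; attribute \code{"flagged"}
#'   holds a logical vector marking names that were not recognized.
#' @examples
#' canonicalizeGeneName(c("COIII", "tRNA-Ser2", "unknownORF"))
#' @export
canonicalizeGeneName <- function(raw) {
  stopifnot(is.character(raw))
  out <- character(length(raw))
  flagged <- logical(length(raw))
  for (i in seq_along(raw)) {
    res <- .canonicalize1(raw[i])
    out[i] <- res$name
    flagged[i] <- res$flagged
  }
  attr(out, "flagged") <- flagged
  out
}

.canonicalize1 <- function(x) {
  if (is.na(x) || !nzchar(trimws(x)))
    return(list(name = x, flagged = TRUE))
  s <- trimws(x)
  ## split off an occurrence suffix for duplicated genes
  suffix <- ""
  m <- regmatches(s, regexpr("#[0-9]+$", s))
  if (length(m) && nzchar(m)) {
    suffix <- m
    s <- sub("#[0-9]+$", "", s)
  }
  if (s %in% names(.GENE_TYPES))   # already canonical
    return(list(name = paste0(s, suffix), flagged = FALSE))
  low <- tolower(s)
  ## anticodon-family qualifier in parentheses, e.g. trnL(UUR)
  fam <- regmatches(low, regexpr("\\(([a-z]{3})\\)", low))
  famkey <- if (length(fam) && nzchar(fam)) gsub("[()]", "", fam) else ""
  key <- gsub("[^a-z0-9]", "", low)
  if (key %in% names(.SYNONYMS))
    return(list(name = paste0(.SYNONYMS[[key]], suffix), flagged = FALSE))
  ## tRNA forms: trn?/trna? prefix then aa letter/name, optional 1|2
  if (grepl("^trna?", key)) {
    rest <- sub("^trna?", "", key)
    if (nzchar(famkey)) rest <- sub(famkey, "", rest, fixed = TRUE)
    num <- regmatches(rest, regexpr("[12]$", rest))
    aa <- sub("[12]$", "", rest)
    letter <- if (aa %in% names(.AA3)) .AA3[[aa]]
              else if (nchar(aa) == 1) toupper(aa)
              else ""
    if (nzchar(letter)) {
      if (letter %in% c("L", "S")) {
        if (length(num) && nzchar(num))
          return(list(name = paste0("trn", letter, num, suffix),
                      flagged = FALSE))
        if (famkey %in% names(.LS_FAMILY))
          return(list(name = paste0(.LS_FAMILY[[famkey]], suffix),
                      flagged = FALSE))
        ## ambiguous Leu/Ser without qualifier: keep verbatim, flag
        return(list(name = x, flagged = TRUE))
      }
      cand <- paste0("trn", letter)
      if (cand %in% .TRNAS)
        return(list(name = paste0(cand, suffix), flagged = FALSE))
    }
  }
  list(name = x, flagged = TRUE)
}

#' Feature class of a canonical gene token
#'
#' @param name character vector of gene tokens (occurrence suffixes such as
#'   \code{"trnQ#2"} are ignored for classification).
#' @return character vector over \code{PCG, tRNA, rRNA, CR, other}.
#' @export
geneFeatureType <- function(name) {
  base <- sub("#[0-9]+$", "", name)
  typ <- .GENE_TYPES[base]
  typ[is.na(typ)] <- "other"
  unname(typ)
}
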