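## Pairwise Ka/Ks by the Nei-Gojobori (1986) counting method with
## Jukes-Cantor correction: fractional synonymous/nonsynonymous site
## counts per codon, pathway-averaged difference counting between codon
## pairs, and per-gene panel averaging.

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Each codon position contributes the fraction of its viable one-step
#' mutations that are synonymous; mutations creating a stop codon are
#' excluded from the denominator (they are not viable in a functional
#' protein-coding gene). The synonymous site count S is the sum of those
#' fractions over the three positions and N = 3 - S, so every codon
#' contributes exactly three sites.
#'
#' @param codon a 3-mer over A/C/G/T, not a stop codon.
#' @param codeId translation table (default 5).
#' @return named numeric \code{c(S = , N = )}.
#' @examples
#' codonSites("GGA")  # 4-fold degenerate third position: S = 1
#' @export
codonSites <- function(codon, codeId = 5L) {
  codon <- toupper(codon)
  code <- geneticCode(codeId)
  tab <- .ngSiteTable(code)
  if (!codon %in% rownames(tab))
    stop(codon, " is not a sense codon under code ", codeId)
  c(S = tab[codon, "S"], N = tab[codon, "N"])
}

.siteCache <- new.env(parent = emptyenv())

.ngSiteTable <- function(code) {
  key <- as.character(code$codeId)
  if (!is.null(.siteCache[[key]])) return(.siteCache[[key]])
  sense <- setdiff(.DNA_CODONS, code$stops)
  bases <- c("A", "C", "G", "T")
  tab <- matrix(0, nrow = length(sense), ncol = 2,
                dimnames = list(sense, c("S", "N")))
  for (cod in sense) {
    aa0 <- code$aa[[cod]]
    S <- 0
    for (pos in 1:3) {
      syn <- 0L
      viable <- 0L
      for (b in setdiff(bases, substr(cod, pos, pos))) {
        mut <- cod
        substr(mut, pos, pos) <- b
        if (code$aa[[mut]] == "*") next  # mutation to stop: not viable
        viable <- viable + 1L
        if (code$aa[[mut]] == aa0) syn <- syn + 1L
      }
      if (viable > 0L) S <- S + syn / viable
    }
    tab[cod, "S"] <- S
    tab[cod, "N"] <- 3 - S
  }
  .siteCache[[key]] <- tab
  tab
}

## all permutations of a short vector (mutation pathways per codon pair)
.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in .perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

#' Pathway-averaged synonymous/nonsynonymous differences between codons
#'
#' Enumerates all minimal mutational pathways between two codons (the
#' orderings of their differing positions), discards pathways passing
#' through a stop codon, classifies each single-nucleotide step as
#' synonymous or nonsynonymous, and averages the step counts over the
#' surviving pathways with equal weights. The averaged counts satisfy
#' \code{sd + nd = } Hamming distance. When every pathway passes through
#' a stop, the average is taken over all pathways instead and the result
#' carries attribute \code{stop_paths = TRUE}.
#'
#' @param codonA,codonB 3-mers over A/C/G/T, neither a stop codon.
#' @param codeId translation table (default 5).
#' @return named numeric \code{c(sd = , nd = )}.
#' @export
codonPathDifferences <- function(codonA, codonB, codeId = 5L) {
  codonA <- toupper(codonA); codonB <- toupper(codonB)
  code <- geneticCode(codeId)
  if (code$aa[[codonA]] == "*" || code$aa[[codonB]] == "*")
    stop("stop codons have no defined pathway differences")
  diffpos <- which(strsplit(codonA, "")[[1]] != strsplit(codonB, "")[[1]])
  if (length(diffpos) == 0L) return(c(sd = 0, nd = 0))
  paths <- .perms(diffpos)
  tally <- function(order, allow_stops) {
    cur <- codonA
    sd <- nd <- 0
    for (k in seq_along(order)) {
      pos <- order[k]
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codonB, pos, pos)
      if (!allow_stops && k < length(order) && code$aa[[nxt]] == "*")
        return(NULL)
      if (code$aa[[cur]] == code$aa[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(paths, tally, allow_stops = FALSE))
  flagged <- FALSE
  if (length(res) == 0L) {
    res <- lapply(paths, tally, allow_stops = TRUE)
    flagged <- TRUE
  }
  m <- Reduce(`+`, res) / length(res)
  out <- c(sd = m[1], nd = m[2])
  if (flagged) attr(out, "stop_paths") <- TRUE
  out
}

#' Pairwise Ka and Ks by the Nei-Gojobori method
#'
#' For two aligned, in-frame coding sequences: synonymous and
#' nonsynonymous site counts are summed over codons (averaged between the
#' two sequences), pathway-averaged differences are summed, the
#' proportions \eqn{pS = Sd/S} and \eqn{pN = Nd/N} are Jukes-Cantor
#' corrected as \eqn{K = -\frac{3}{4}\ln(1 - \frac{4}{3}p)}, and the
#' Ka/Ks ratio is formed. Codon pairs containing ambiguity characters or
#' a stop codon in either sequence are skipped pairwise. A proportion at
#' or beyond the Jukes-Cantor saturation point 3/4 yields \code{NA} for
#' that rate; \code{Ks = 0} leaves the ratio \code{NA}. Diagnostic notes
#' accumulate in the \code{"flags"} attribute. The statistic is
#' symmetric in its two arguments.
#'
#' @param cdsA,cdsB aligned CDS strings of equal length, reading sense,
#'   length a multiple of 3.
#' @param codeId translation table (default 5).
#' @param gene,pair optional labels stored in the result.
#' @return one-row \code{data.frame} with columns \code{gene},
#'   \code{pair}, \code{n_codons}, \code{S_sites}, \code{N_sites},
#'   \code{Sd}, \code{Nd}, \code{pS}, \code{pN}, \code{Ks}, \code{Ka},
#'   \code{KaKs}.
#' @examples
#' ng86("ATGAAACGA", "ATGAAGCGC")
#' @export
ng86 <- function(cdsA, cdsB, codeId = 5L, gene = NA_character_,
                 pair = NA_character_) {
  cdsA <- toupper(as.character(cdsA)); cdsB <- toupper(as.character(cdsB))
  if (nchar(cdsA) != nchar(cdsB))
    stop("sequences must be aligned to equal length")
  if (nchar(cdsA) %% 3L != 0L)
    stop("alignment length must be a multiple of 3")
  code <- geneticCode(codeId)
  tab <- .ngSiteTable(code)
  ca <- .splitCodons(cdsA)
  cb <- .splitCodons(cdsB)
  usable <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  usable <- usable & !(ca %in% code$stops) & !(cb %in% code$stops)
  flags <- character()
  if (any(!usable))
    flags <- c(flags, sprintf("skipped_codons=%d", sum(!usable)))
  ca <- ca[usable]; cb <- cb[usable]
  if (length(ca) == 0L) stop("no comparable codons")
  S <- sum((tab[ca, "S"] + tab[cb, "S"]) / 2)
  N <- sum((tab[ca, "N"] + tab[cb, "N"]) / 2)
  Sd <- Nd <- 0
  stop_paths <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    d <- codonPathDifferences(ca[i], cb[i], codeId)
    if (isTRUE(attr(d, "stop_paths"))) stop_paths <- stop_paths + 1L
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  if (stop_paths > 0L)
    flags <- c(flags, sprintf("stop_only_pathways=%d", stop_paths))
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- jc(pS)
  Ka <- jc(pN)
  if (is.na(Ks)) flags <- c(flags, "Ks_saturated")
  if (is.na(Ka)) flags <- c(flags, "Ka_saturated")
  ratio <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  if (!is.na(Ks) && Ks == 0) flags <- c(flags, "Ks_zero")
  out <- data.frame(gene = gene, pair = pair, n_codons = length(ca),
                    S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
                    pS = pS, pN = pN, Ks = Ks, Ka = Ka, KaKs = ratio,
                    stringsAsFactors = FALSE)
  attr(out, "flags") <- flags
  out
}

#' Per-gene average Ka/Ks across a species panel
#'
#' Runs \code{\link{ng86}} on every species pair (or on focal-vs-others
#' when \code{focal} is given) for each gene of an aligned CDS panel and
#' averages per gene. Undefined ratios (saturated or \code{Ks = 0}) are
#' excluded from the ratio mean and counted. A gene whose alignment is
#' unusable (e.g. mismatched lengths) yields an \code{NA} row with a
#' note; the rest of the panel is still processed.
#'
#' @param panel named list, one element per gene: a named character
#'   vector or \code{DNAStringSet} of aligned CDS, one per species.
#' @param focal optional focal species name: only pairs involving it are
#'   compared.
#' @param codeId translation table (default 5).
#' @return \code{data.frame} with one row per gene: \code{gene},
#'   \code{n_pairs}, \code{mean_Ka}, \code{mean_Ks}, \code{mean_KaKs},
#'   \code{n_undefined}, \code{note}.
#' @export
panelKaKs <- function(panel, focal = NULL, codeId = 5L) {
  stopifnot(is.list(panel), !is.null(names(panel)))
  rows <- lapply(names(panel), function(g) {
    seqs <- panel[[g]]
    if (methods::is(seqs, "DNAStringSet"))
      seqs <- stats::setNames(as.character(seqs), names(seqs))
    if (length(seqs) < 2L)
      return(data.frame(gene = g, n_pairs = 0L, mean_Ka = NA_real_,
                        mean_Ks = NA_real_, mean_KaKs = NA_real_,
                        n_undefined = 0L, note = "fewer than 2 species",
                        stringsAsFactors = FALSE))
    if (is.null(names(seqs)))
      names(seqs) <- paste0("sp", seq_along(seqs))
    cmb <- utils::combn(names(seqs), 2L)
    if (!is.null(focal)) {
      keep <- cmb[1, ] == focal | cmb[2, ] == focal
      cmb <- cmb[, keep, drop = FALSE]
    }
    res <- tryCatch({
      do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
        ng86(seqs[[cmb[1, j]]], seqs[[cmb[2, j]]], codeId = codeId,
             gene = g, pair = paste(cmb[, j], collapse = ":"))
      }))
    }, error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(gene = g, n_pairs = 0L, mean_Ka = NA_real_,
                        mean_Ks = NA_real_, mean_KaKs = NA_real_,
                        n_undefined = 0L, note = conditionMessage(res),
                        stringsAsFactors = FALSE))
    def <- !is.na(res$KaKs)
    data.frame(gene = g, n_pairs = nrow(res),
               mean_Ka = mean(res$Ka, na.rm = TRUE),
               mean_Ks = mean(res$Ks, na.rm = TRUE),
               mean_KaKs = if (any(def)) mean(res$KaKs[def]) else NA_real_,
               n_undefined = sum(!def),
               note = if (all(def)) "" else "undefined ratios excluded",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read an aligned CDS panel from FASTA files
#'
#' One FASTA file per gene, one record per species, all records aligned
#' to equal length. Gene names default to the file names without
#' extension.
#'
#' @param paths character vector of FASTA paths, optionally named by
#'   gene.
#' @return named list of named character vectors, the input shape of
#'   \code{\link{panelKaKs}}.
#' @export
readCdsPanel <- function(paths) {
  nm <- names(paths)
  if (is.null(nm))
    nm <- sub("\\.(fa|fasta|fna)$", "", basename(paths),
              ignore.case = TRUE)
  out <- lapply(paths, function(p) {
    set <- Biostrings::readDNAStringSet(p)
    stats::setNames(as.character(set), names(set))
  })
  names(out) <- nm
  out
}
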