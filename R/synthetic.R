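## Synthetic mitogenomes and codon-evolved CDS panels: inputs with the
## statistical structure the characterization pipeline assumes, so every
## stage can be exercised and checked without downloads.

## composition targets used as generator defaults: the heavy-strand base
## percentages observed for the E. ensirostris mitogenome (MK681888)
.DEFAULT_BASE_COMP <- c(A = 32.51, T = 31.91, G = 14.24, C = 21.33)

## default gene lengths (bp): the observed mitogenome gene sizes, with
## each PCG length a multiple of 3 so the generator can emit a clean ORF
.DEFAULT_PCG_LEN <- c(atp6 = 666, atp8 = 165, cob = 1137, cox1 = 1512,
                      cox2 = 687, cox3 = 783, nad1 = 870, nad2 = 981,
                      nad3 = 366, nad4 = 1227, nad4l = 255, nad5 = 1704,
                      nad6 = 498)
.DEFAULT_RRNA_LEN <- c(rrnL = 1368, rrnS = 818)

#' Codon weights calibrated to a base-composition target
#'
#' Returns a 64-long weight vector over DNA codons proportional to a
#' position-independent product of base frequencies, with stop codons
#' zeroed and the base frequencies iteratively recalibrated so that the
#' expected nucleotide composition of sampled sense codons matches the
#' target despite the stop-codon exclusion (AT-rich stop codons would
#' otherwise bias sampled coding sequence away from the target).
#'
#' @param baseComp named numeric \code{c(A=,T=,G=,C=)} of target base
#'   percentages (or proportions).
#' @param codeId translation table whose stop codons are excluded
#'   (default 5).
#' @return named numeric(64) of sampling weights (sum 1), DNA codons.
#' @export
calibratedCodonWeights <- function(baseComp = .DEFAULT_BASE_COMP,
                                   codeId = 5L) {
  p <- baseComp[c("A", "T", "G", "C")] / sum(baseComp)
  code <- geneticCode(codeId)
  bases <- c("A", "T", "G", "C")
  pos <- lapply(1:3, function(k) substr(.DNA_CODONS, k, k))
  sense <- !(.DNA_CODONS %in% code$stops)
  q <- p
  for (iter in 1:200) {
    w <- q[pos[[1]]] * q[pos[[2]]] * q[pos[[3]]]
    w[!sense] <- 0
    w <- w / sum(w)
    e <- vapply(bases, function(b)
      sum(w * ((pos[[1]] == b) + (pos[[2]] == b) + (pos[[3]] == b)) / 3),
      0)
    if (max(abs(e - p)) < 1e-12) break
    q <- q * p / pmax(e, 1e-12)
    q <- q / sum(q)
  }
  stats::setNames(as.numeric(w), .DNA_CODONS)
}

.sampleBases <- function(n, baseComp) {
  p <- baseComp[c("A", "T", "G", "C")] / sum(baseComp)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.sampleCodons <- function(n, weights) {
  sample(names(weights), n, replace = TRUE, prob = weights)
}

#' Apply rearrangement operations to a gene order
#'
#' Supported operations, each a list: \code{list(op = "translocate",
#' gene =, after =)} moves a gene to the position following
#' \code{after}; \code{list(op = "invert", gene =)} flips its
#' orientation; \code{list(op = "duplicate", gene =, after =)} inserts a
#' second, occurrence-suffixed copy (\code{after} defaults to the gene
#' itself, i.e. a tandem copy).
#'
#' @param order a \code{\linkS4class{GeneOrder}}.
#' @param ops list of operation lists, applied in sequence.
#' @return the rearranged \code{GeneOrder}.
#' @export
applyOrderOps <- function(order, ops) {
  tok <- orderTokens(order)
  ori <- orientations(order)
  for (o in ops) {
    stopifnot(!is.null(o$op), !is.null(o$gene))
    i <- match(o$gene, tok)
    if (is.na(i)) stop("gene ", o$gene, " absent from order")
    if (o$op == "translocate") {
      g <- tok[i]; s <- ori[i]
      tok <- tok[-i]; ori <- ori[-i]
      j <- match(o$after, tok)
      if (is.na(j)) stop("anchor ", o$after, " absent from order")
      tok <- append(tok, g, after = j)
      ori <- append(ori, if (is.null(o$orientation)) s else o$orientation,
                    after = j)
    } else if (o$op == "invert") {
      ori[i] <- if (ori[i] == "+") "-" else "+"
    } else if (o$op == "duplicate") {
      after <- if (is.null(o$after)) o$gene else o$after
      j <- match(after, tok)
      base <- sub("#[0-9]+$", "", o$gene)
      copy <- paste0(base, "#", sum(sub("#[0-9]+$", "", tok) == base) + 1L)
      tok <- append(tok, copy, after = j)
      ori <- append(ori, ori[i], after = j)
    } else {
      stop("unknown rearrangement op: ", o$op)
    }
  }
  GeneOrder(tok, ori)
}

#' Generate an annotated synthetic mitogenome
#'
#' Builds a circular genome with the full 37-gene complement plus
#' control region laid out along a template gene order (ancestral
#' decapod by default, optionally rearranged by \code{ops}). Each
#' protein-coding gene is a clean open reading frame on its reading
#' strand: an ATG start, interior codons drawn from a composition-
#' calibrated codon-usage distribution with stop codons excluded, and a
#' terminal TAA. tRNA, rRNA, control-region and spacer nucleotides are
#' drawn i.i.d. from the base-composition target. Light-strand genes are
#' generated on their reading sense and placed as the reverse complement,
#' so A+T content is preserved on the heavy strand by construction.
#' Output is fully deterministic under \code{seed}.
#'
#' @param order template \code{\linkS4class{GeneOrder}} (default
#'   \code{ancestralGeneOrder("decapoda")}).
#' @param ops optional rearrangement operations applied to the template
#'   (see \code{\link{applyOrderOps}}).
#' @param baseComp named \code{c(A=,T=,G=,C=)} base-composition target
#'   for the generated strands.
#' @param pcgLengths named bp lengths of the 13 PCGs (multiples of 3).
#' @param trnaLengthRange bp range tRNA lengths are drawn from
#'   (default 63-70).
#' @param rrnaLengths named bp lengths of \code{rrnL}, \code{rrnS}.
#' @param crLength control-region length in bp.
#' @param spacer intergenic spacer in bp inserted after every feature
#'   (default 1).
#' @param codonWeights optional 64-long codon sampling weights (DNA
#'   codons); default calibrated from \code{baseComp}.
#' @param codeId translation table (default 5).
#' @param seed integer seed fixing all randomness.
#' @return a \code{\linkS4class{MitoAnnotation}} with sequence attached.
#' @examples
#' ann <- generateGenome(seed = 1)
#' genomeLength(ann)
#' @export
generateGenome <- function(order = ancestralGeneOrder("decapoda"),
                           ops = NULL,
                           baseComp = .DEFAULT_BASE_COMP,
                           pcgLengths = .DEFAULT_PCG_LEN,
                           trnaLengthRange = c(63L, 70L),
                           rrnaLengths = .DEFAULT_RRNA_LEN,
                           crLength = 1249L,
                           spacer = 1L,
                           codonWeights = NULL,
                           codeId = 5L,
                           seed = 1L) {
  stopifnot(all(pcgLengths %% 3L == 0L), spacer >= 0L)
  set.seed(seed)
  if (is.null(codonWeights))
    codonWeights <- calibratedCodonWeights(baseComp, codeId)
  if (!is.null(ops)) order <- applyOrderOps(order, ops)
  tok <- orderTokens(order)
  ori <- orientations(order)
  base <- sub("#[0-9]+$", "", tok)
  typ <- geneFeatureType(tok)

  pieces <- character(length(tok))
  anticodons <- rep(NA_character_, length(tok))
  for (i in seq_along(tok)) {
    len <- switch(typ[i],
      PCG = {
        if (!base[i] %in% names(pcgLengths))
          stop("no length configured for PCG ", base[i])
        pcgLengths[[base[i]]]
      },
      tRNA = sample(trnaLengthRange[1]:trnaLengthRange[2], 1L),
      rRNA = rrnaLengths[[base[i]]],
      CR = crLength,
      stop("cannot place feature of unknown type: ", tok[i]))
    if (typ[i] == "PCG") {
      inner <- .sampleCodons(len / 3L - 2L, codonWeights)
      sense <- paste0("ATG", paste(inner, collapse = ""), "TAA")
    } else {
      sense <- .sampleBases(len, baseComp)
      if (typ[i] == "tRNA")
        anticodons[i] <- substr(sense, 32L, 34L)
    }
    pieces[i] <- if (ori[i] == "-") .revcomp(sense) else sense
  }
  lens <- nchar(pieces)
  starts <- cumsum(c(1L, (lens + spacer)[-length(lens)]))
  ends <- starts + lens - 1L
  spacers <- vapply(seq_along(tok), function(i)
    .sampleBases(spacer, baseComp), "")
  genome <- paste(paste0(pieces, spacers), collapse = "")
  f <- data.frame(name = tok, type = typ, strand = ori,
                  start = starts, end = ends, anticodon = anticodons,
                  flagged = FALSE, stringsAsFactors = FALSE)
  MitoAnnotation(f, genomeLength = nchar(genome), circular = TRUE,
                 sequence = genome, canonicalize = FALSE)
}

#' Evolve an aligned CDS pair with a controlled dN/dS
#'
#' Generates an ancestral in-frame CDS from a codon-usage distribution
#' and a descendant by acceptance-rejection evolution at the codon
#' level: single-nucleotide changes are proposed uniformly at random;
#' synonymous proposals are always accepted, nonsynonymous proposals are
#' accepted with probability \code{omega}, and proposals creating a stop
#' codon are always rejected. In the low-divergence regime the
#' Nei-Gojobori estimate of Ka/Ks on the pair recovers \code{omega}.
#' Both sequences are gap-free and therefore already aligned.
#'
#' @param nCodons number of codons in the CDS.
#' @param omega target dN/dS (acceptance probability of nonsynonymous
#'   proposals), \code{>= 0}.
#' @param subsPerCodon expected number of proposed single-nucleotide
#'   changes per codon along the branch (default 0.5; the NG86 estimator
#'   is a low-divergence method, so the default keeps pairwise
#'   divergence well below saturation).
#' @param codonWeights optional codon sampling weights for the ancestor;
#'   default calibrated from the package's standard composition target.
#' @param codeId translation table (default 5).
#' @param seed integer seed.
#' @return list with elements \code{cdsA} (ancestor) and \code{cdsB}
#'   (descendant), equal-length character strings.
#' @examples
#' pair <- evolvePair(nCodons = 200, omega = 0.2, seed = 7)
#' ng86(pair$cdsA, pair$cdsB)[, c("Ka", "Ks", "KaKs")]
#' @export
evolvePair <- function(nCodons = 2000L, omega = 0.2,
                       subsPerCodon = 0.5, codonWeights = NULL,
                       codeId = 5L, seed = 1L) {
  stopifnot(nCodons >= 1L, omega >= 0)
  set.seed(seed)
  anc <- .sampleAncestor(nCodons, codonWeights, codeId)
  des <- .evolveBranch(anc, omega, subsPerCodon, codeId)
  list(cdsA = paste(anc, collapse = ""), cdsB = paste(des, collapse = ""))
}

.sampleAncestor <- function(nCodons, codonWeights, codeId) {
  if (is.null(codonWeights))
    codonWeights <- calibratedCodonWeights(codeId = codeId)
  code <- geneticCode(codeId)
  w <- codonWeights
  w[names(w) %in% code$stops] <- 0
  .sampleCodons(nCodons, w / sum(w))
}

.evolveBranch <- function(codons, omega, subsPerCodon, codeId) {
  code <- geneticCode(codeId)
  n <- length(codons)
  nprop <- stats::rpois(1L, subsPerCodon * n)
  if (nprop == 0L) return(codons)
  idx <- sample.int(n, nprop, replace = TRUE)
  pos <- sample.int(3L, nprop, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(nprop)) {
    cur <- codons[idx[k]]
    ## viable targets: the non-stop single-nucleotide neighbours at this
    ## position, proposed uniformly -- the mutational opportunity model
    ## under which per-position site fractions are syn/viable
    cand <- setdiff(bases, substr(cur, pos[k], pos[k]))
    muts <- vapply(cand, function(b) {
      m <- cur; substr(m, pos[k], pos[k]) <- b; m
    }, "")
    muts <- muts[code$aa[muts] != "*"]        # stops never arise
    if (length(muts) == 0L) next
    mut <- if (length(muts) == 1L) muts else sample(muts, 1L)
    if (code$aa[[mut]] == code$aa[[cur]]) {
      codons[idx[k]] <- mut                   # synonymous: accepted
    } else if (stats::runif(1L) < omega) {
      codons[idx[k]] <- mut                   # nonsynonymous: prob omega
    }
  }
  codons
}

#' Generate an aligned multi-species CDS panel
#'
#' One ancestor per gene, with each species' sequence evolved
#' independently from it (star topology) under that gene's target dN/dS.
#' The default shape (13 genes, 6 species) mirrors a typical
#' mitogenome-wide selection scan across a small species panel.
#'
#' @param nGenes number of genes (at most 13 to use the canonical PCG
#'   names; more genes get generic names).
#' @param nSpecies number of species per gene.
#' @param omega per-gene target dN/dS, recycled to \code{nGenes}.
#' @param nCodons per-gene CDS length in codons, recycled (default 280,
#'   about the mean mitochondrial PCG length).
#' @param subsPerCodon expected proposed changes per codon per branch.
#' @param codeId translation table (default 5).
#' @param seed integer seed.
#' @return named list gene -> named character vector of aligned CDS
#'   (\code{species_1} ... \code{species_n}), the input shape of
#'   \code{\link{panelKaKs}}.
#' @export
generatePanel <- function(nGenes = 13L, nSpecies = 6L, omega = 0.3,
                          nCodons = 280L, subsPerCodon = 0.5,
                          codeId = 5L, seed = 1L) {
  set.seed(seed)
  omega <- rep_len(omega, nGenes)
  nCodons <- rep_len(as.integer(nCodons), nGenes)
  gnames <- if (nGenes <= 13L) mitoGeneTokens("PCG")[seq_len(nGenes)]
            else paste0("gene_", seq_len(nGenes))
  panel <- lapply(seq_len(nGenes), function(g) {
    anc <- .sampleAncestor(nCodons[g], NULL, codeId)
    seqs <- vapply(seq_len(nSpecies), function(s)
      paste(.evolveBranch(anc, omega[g], subsPerCodon, codeId),
            collapse = ""), "")
    stats::setNames(seqs, paste0("species_", seq_len(nSpecies)))
  })
  names(panel) <- gnames
  panel
}

#' Write a CDS panel as per-gene FASTA files
#'
#' @param panel output of \code{\link{generatePanel}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths, named by gene.
#' @export
writeCdsPanel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(panel), function(g) {
    p <- file.path(dir, paste0(g, ".fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(panel[[g]]), p)
    p
  }, "")
  invisible(paths)
}
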