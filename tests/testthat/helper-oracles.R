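# Independent brute-force oracles used to validate the analytical
# implementations, written as literal enumerations.

.oracle_code <- function(codeId = 5L) Biostrings::getGeneticCode(as.character(codeId))

# synonymous/nonsynonymous site counts by explicit enumeration of all
# one-step mutants, mutations to stops excluded from the denominator
oracle_sites <- function(codon, codeId = 5L) {
  gc <- .oracle_code(codeId)
  bases <- c("A", "C", "G", "T")
  S <- 0
  for (p in 1:3) {
    syn <- 0; viable <- 0
    for (b in bases) {
      if (b == substr(codon, p, p)) next
      mut <- codon
      substr(mut, p, p) <- b
      if (gc[[mut]] == "*") next
      viable <- viable + 1
      if (gc[[mut]] == gc[[codon]]) syn <- syn + 1
    }
    if (viable > 0) S <- S + syn / viable
  }
  c(S = S, N = 3 - S)
}

# all orderings of a set, by recursion
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  res <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) res[[length(res) + 1]] <- c(v[i], rest)
  }
  res
}

# pathway-averaged differences by walking every ordering of the changed
# positions, dropping paths through stops (all paths if none survive)
oracle_pathdiff <- function(a, b, codeId = 5L) {
  gc <- .oracle_code(codeId)
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  walk <- function(order, skip_stops) {
    cur <- a; sd <- 0; nd <- 0
    for (k in seq_along(order)) {
      nxt <- cur
      substr(nxt, order[k], order[k]) <- substr(b, order[k], order[k])
      if (skip_stops && k < length(order) && gc[[nxt]] == "*") return(NULL)
      if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  paths <- oracle_perms(pos)
  ok <- Filter(Negate(is.null), lapply(paths, walk, skip_stops = TRUE))
  if (length(ok) == 0) ok <- lapply(paths, walk, skip_stops = FALSE)
  avg <- Reduce(`+`, ok) / length(ok)
  c(sd = avg[1], nd = avg[2])
}

# full NG86 on a codon-aligned pair, assembled only from the two oracles
oracle_ng86 <- function(A, B, codeId = 5L) {
  gc <- .oracle_code(codeId)
  ca <- substring(A, seq(1, nchar(A), 3), seq(3, nchar(A), 3))
  cb <- substring(B, seq(1, nchar(B), 3), seq(3, nchar(B), 3))
  keep <- gc[ca] != "*" & gc[cb] != "*"
  ca <- ca[keep]; cb <- cb[keep]
  S <- N <- Sd <- Nd <- 0
  for (i in seq_along(ca)) {
    sa <- oracle_sites(ca[i], codeId); sb <- oracle_sites(cb[i], codeId)
    S <- S + (sa[["S"]] + sb[["S"]]) / 2
    N <- N + (sa[["N"]] + sb[["N"]]) / 2
    d <- oracle_pathdiff(ca[i], cb[i], codeId)
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       Ks = jc(Sd / S), Ka = jc(Nd / N))
}

# every outcome of one tandem duplication/random loss of a linear
# reference segment: duplicate the segment, keep one copy of each gene
oracle_tdrl_reachable <- function(derived, reference) {
  n <- length(reference)
  for (mask in 0:(2^n - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    result <- c(reference[bits], reference[!bits])
    if (identical(result, derived)) return(TRUE)
  }
  FALSE
}

# random sense codons under a code
random_sense_codons <- function(n, codeId = 5L) {
  gc <- .oracle_code(codeId)
  sense <- names(gc)[gc != "*"]
  sample(sense, n, replace = TRUE)
}

# small hand-built annotation on a known sequence
toy_annotation <- function() {
  # 60 bp circle: gene A (+) 1..15, gene B (-) 21..35, CR 41..55
  seqn <- paste0("ATGAAACCCGGGTAA", "TTTTT",
                 "TTACCCGGGTTTCAT", "TTTTT",
                 "ACGTACGTACGTACG", "TTTTT")
  ft <- data.frame(name = c("cox1", "nad1", "CR"),
                   strand = c("+", "-", "+"),
                   start = c(1L, 21L, 41L), end = c(15L, 35L, 55L))
  MitoAnnotation(ft, genomeLength = 60L, sequence = seqn)
}
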