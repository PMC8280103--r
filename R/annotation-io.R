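## Readers and writers for annotated mitogenomes: GenBank flat files,
## plain feature tables (the shape of a published gene-organization
## table), and FASTA genome sequences.

#' Parse a GenBank flat file into a MitoAnnotation
#'
#' Reads a GenBank record of an annotated mitogenome (such as accession
#' MK681888) and maps its \code{CDS}, \code{tRNA}, \code{rRNA},
#' \code{D-loop} and control-region-like \code{misc_feature} entries onto
#' canonical gene features. Strand is taken from \code{complement(...)}
#' location flags; a \code{join(a..L,1..b)} location is interpreted as a
#' feature wrapping the circular origin. The sequence is attached when an
#' \code{ORIGIN} block is present. Features whose \code{/gene} or
#' \code{/product} cannot be canonicalized are retained verbatim with a
#' warning, never dropped. \code{gene} features that merely duplicate a
#' CDS/tRNA/rRNA annotation are ignored.
#'
#' @param path path to a GenBank flat file containing one record.
#' @return a \code{\linkS4class{MitoAnnotation}}.
#' @seealso \code{\link{writeGenBank}} for the inverse.
#' @export
parseGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L)
    stop("not a GenBank flat file (no LOCUS line): ", path)
  locus <- locus[1]
  m <- regmatches(locus, regexpr("[0-9]+(?= bp)", locus, perl = TRUE))
  if (length(m) == 0L)
    stop("cannot read genome length from LOCUS line: ", locus)
  genome_length <- as.integer(m)
  circular <- grepl("circular", locus, ignore.case = TRUE)

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  fend <- if (length(ostart)) ostart[1] - 1L else length(lines)
  if (length(fstart) == 0L) stop("GenBank record has no FEATURES block")
  flines <- lines[(fstart[1] + 1L):fend]
  flines <- flines[!grepl("^//", flines)]

  ## group feature blocks: a new feature starts with key at column 6
  is_key <- grepl("^ {5}\\S", flines)
  grp <- cumsum(is_key)
  keep_types <- c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")
  feats <- list()
  for (g in unique(grp[grp > 0])) {
    block <- flines[grp == g]
    key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
    if (!key %in% keep_types) next
    loc <- sub("^ {5}\\S+\\s+", "", block[1])
    ## location may continue on following lines until a qualifier
    i <- 2L
    while (i <= length(block) && !grepl("^\\s*/", block[i])) {
      loc <- paste0(loc, trimws(block[i]))
      i <- i + 1L
    }
    quals <- .parseQualifiers(block[i - 1L + seq_len(length(block) - i + 1L)])
    pos <- .parseLocation(loc, genome_length)
    nm <- quals[["gene"]] %||% quals[["product"]] %||% key
    ftype <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                    "CR")
    ac <- NA_character_
    if (!is.null(quals[["anticodon"]])) {
      acm <- regmatches(quals[["anticodon"]],
                        regexpr("seq:([acgtuACGTU]{3})",
                                quals[["anticodon"]]))
      if (length(acm)) ac <- toupper(sub("seq:", "", acm))
    }
    feats[[length(feats) + 1L]] <- data.frame(
      name = nm, type = ftype, strand = pos$strand,
      start = pos$start, end = pos$end, anticodon = ac,
      stringsAsFactors = FALSE)
  }
  if (length(feats) == 0L)
    stop("GenBank record has no usable features")
  f <- do.call(rbind, feats)
  cn <- canonicalizeGeneName(f$name)
  if (any(attr(cn, "flagged")))
    warning("retained features with non-canonical names: ",
            paste(unique(f$name[attr(cn, "flagged")]), collapse = ", "))
  f$flagged <- attr(cn, "flagged")
  f$name <- as.character(cn)
  ## type of canonical names wins over the GenBank key for known genes
  known <- geneFeatureType(f$name)
  f$type[known != "other"] <- known[known != "other"]

  seqn <- NULL
  if (length(ostart)) {
    sl <- lines[(ostart[1] + 1L):length(lines)]
    sl <- sl[!grepl("^//", sl)]
    seqn <- toupper(gsub("[^A-Za-z]", "", paste(sl, collapse = "")))
    if (!nzchar(seqn)) seqn <- NULL
  }
  MitoAnnotation(f, genome_length, circular = circular, sequence = seqn,
                 canonicalize = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parseQualifiers <- function(lines) {
  txt <- paste(trimws(lines), collapse = " ")
  out <- list()
  m <- gregexpr('/([A-Za-z_]+)=("[^"]*"|[^ ]+)', txt)
  for (q in regmatches(txt, m)[[1]]) {
    key <- sub("^/([A-Za-z_]+)=.*$", "\\1", q)
    val <- sub("^/[A-Za-z_]+=", "", q)
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
  }
  out
}

.parseLocation <- function(loc, genome_length) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- as.integer(regmatches(loc,
            gregexpr("[0-9]+", gsub("[<>]", "", loc)))[[1]])
  if (length(nums) < 2L) stop("cannot parse location: ", loc)
  if (grepl("join", loc) && length(nums) >= 4L &&
      nums[2] == genome_length && nums[3] == 1L) {
    ## wraps the circular origin
    list(strand = strand, start = nums[1], end = nums[4])
  } else {
    list(strand = strand, start = min(nums), end = max(nums))
  }
}

#' Write a MitoAnnotation as a GenBank flat file
#'
#' Emits a minimal GenBank record (LOCUS, FEATURES with
#' \code{CDS}/\code{tRNA}/\code{rRNA}/\code{D-loop} keys and \code{/gene}
#' qualifiers, ORIGIN when a sequence is attached) that
#' \code{\link{parseGenBank}} reads back to the same annotation.
#'
#' @param ann a \code{\linkS4class{MitoAnnotation}}.
#' @param path output path.
#' @param name record name for the LOCUS line.
#' @return invisibly, \code{path}.
#' @export
writeGenBank <- function(ann, path, name = "synthetic_mitogenome") {
  f <- features(ann)
  L <- genomeLength(ann)
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s     INV",
                   name, L, if (isCircular(ann)) "circular" else "linear"),
           "FEATURES             Location/Qualifiers")
  key_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", CR = "D-loop",
              other = "misc_feature")
  for (i in seq_len(nrow(f))) {
    span <- if (f$end[i] >= f$start[i])
      sprintf("%d..%d", f$start[i], f$end[i])
    else
      sprintf("join(%d..%d,1..%d)", f$start[i], L, f$end[i])
    if (f$strand[i] == "-") span <- sprintf("complement(%s)", span)
    out <- c(out,
             sprintf("     %-16s%s", key_of[[f$type[i]]], span),
             sprintf('                     /gene="%s"', f$name[i]))
    if (!is.na(f$anticodon[i]))
      out <- c(out, sprintf(
        '                     /anticodon="(seq:%s)"',
        tolower(f$anticodon[i])))
  }
  s <- genomeSequence(ann)
  if (!is.null(s)) {
    out <- c(out, "ORIGIN")
    sc <- tolower(as.character(s))
    for (off in seq(1L, nchar(sc), by = 60L)) {
      chunk <- substr(sc, off, min(off + 59L, nchar(sc)))
      tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      out <- c(out, sprintf("%9d %s", off, paste(tens, collapse = " ")))
    }
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Parse a plain feature table into a MitoAnnotation
#'
#' Reads a delimited gene-organization table of the shape commonly
#' printed in mitogenome papers: one row per feature with its name,
#' strand/direction and 1-based inclusive coordinates. Column names are
#' matched case-insensitively: name/gene, direction/strand, start, end
#' (or a single \code{position} column \code{"start-end"}), and optional
#' anticodon. A row whose end precedes its start is taken to wrap the
#' circular origin.
#'
#' @param table path to a delimited file, or a \code{data.frame}.
#' @param genomeLength genome size in bp (coordinates are validated
#'   against it).
#' @param sequence optional genome sequence (\code{DNAString}, character,
#'   or path to a FASTA file).
#' @param circular logical, default \code{TRUE}.
#' @param sep field separator when \code{table} is a path (default tab).
#' @return a \code{\linkS4class{MitoAnnotation}}.
#' @examples
#' tab <- data.frame(Gene = "nad4", Direction = "-",
#'                   Start = 13, End = 1239)
#' featureLengths(parseFeatureTable(tab, genomeLength = 16350))
#' @export
parseFeatureTable <- function(table, genomeLength, sequence = NULL,
                              circular = TRUE, sep = "\t") {
  if (is.character(table) && length(table) == 1L) {
    table <- utils::read.delim(table, sep = sep, header = TRUE,
                               comment.char = "#",
                               stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(table))
  nm <- tolower(names(table))
  pick <- function(...) {
    for (cand in c(...)) {
      j <- which(nm == cand)
      if (length(j)) return(table[[j[1]]])
    }
    NULL
  }
  gene <- pick("name", "gene")
  strand <- pick("direction", "strand")
  start <- pick("start")
  end <- pick("end")
  pos <- pick("position")
  if (is.null(start) && !is.null(pos)) {
    pos <- gsub("[, ]", "", pos)
    parts <- strsplit(pos, "–|—|-")
    start <- as.integer(vapply(parts, `[`, "", 1L))
    end <- as.integer(vapply(parts, `[`, "", 2L))
  }
  if (is.null(gene) || is.null(strand) || is.null(start) || is.null(end))
    stop("feature table needs name/gene, direction/strand and coordinates")
  start <- as.integer(gsub("[, ]", "", start))
  end <- as.integer(gsub("[, ]", "", end))
  strand <- trimws(as.character(strand))
  strand[strand %in% c("−", "–")] <- "-"  # unicode minus/dash
  if (!all(strand %in% c("+", "-")))
    stop("direction column must be '+' or '-'")
  if (any(is.na(start) | is.na(end)))
    stop("unparseable coordinates in feature table")
  if (any(start < 1L | start > genomeLength | end < 1L |
          end > genomeLength))
    stop("feature coordinates outside [1, ", genomeLength, "]")
  ac <- pick("anticodon")
  f <- data.frame(name = as.character(gene), strand = strand,
                  start = start, end = end,
                  anticodon = if (is.null(ac)) NA_character_
                              else .cleanAnticodon(ac),
                  stringsAsFactors = FALSE)
  if (is.character(sequence) && length(sequence) == 1L &&
      file.exists(sequence))
    sequence <- readGenomeFasta(sequence)
  MitoAnnotation(f, genomeLength, circular = circular,
                 sequence = sequence)
}

.cleanAnticodon <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[!grepl("^[ACGTU]{3}$", x)] <- NA_character_
  chartr("U", "T", x)
}

#' Write a MitoAnnotation as a plain feature table
#'
#' Writes a tab-separated table with columns \code{Gene}, \code{Direction},
#' \code{Start}, \code{End}, \code{Length}, \code{Anticodon},
#' \code{Start_codon}, \code{Stop_codon}. The codon columns are filled for
#' protein-coding genes when the annotation carries a sequence, and left
#' empty otherwise. \code{\link{parseFeatureTable}} reads the table back
#' to the same features.
#'
#' @param ann a \code{\linkS4class{MitoAnnotation}}.
#' @param path output path.
#' @param codeId translation table used to recognize stop codons
#'   (default 5).
#' @return invisibly, \code{path}.
#' @export
writeAnnotationTable <- function(ann, path, codeId = 5L) {
  f <- features(ann)
  len <- featureLengths(ann)
  startc <- stopc <- rep("", nrow(f))
  if (!is.null(genomeSequence(ann))) {
    for (i in which(f$type == "PCG")) {
      cds <- extractCDS(ann, f$name[i])
      ss <- detectStartStop(cds, codeId = codeId)
      startc[i] <- ss$start
      stopc[i] <- ss$stop
    }
  }
  out <- data.frame(Gene = f$name, Direction = f$strand,
                    Start = f$start, End = f$end, Length = unname(len),
                    Anticodon = ifelse(is.na(f$anticodon), "",
                                       f$anticodon),
                    Start_codon = startc, Stop_codon = stopc,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a single-record FASTA genome sequence
#'
#' @param path FASTA file with one record.
#' @return a \code{DNAString}.
#' @export
readGenomeFasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L)
    stop("expected a single-record FASTA, found ", length(set))
  set[[1]]
}

#' Write the genome sequence of an annotation as FASTA
#'
#' @param ann a \code{\linkS4class{MitoAnnotation}} carrying a sequence.
#' @param path output path.
#' @param name record header.
#' @return invisibly, \code{path}.
#' @export
writeGenomeFasta <- function(ann, path, name = "mitogenome") {
  s <- genomeSequence(ann)
  if (is.null(s)) stop("annotation carries no sequence")
  set <- Biostrings::DNAStringSet(stats::setNames(as.character(s), name))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

## wrap-aware extraction of positions [start, end] on the heavy strand,
## reverse-complemented when strand == "-"
.extractRegion <- function(ann, start, end, strand = "+") {
  s <- genomeSequence(ann)
  if (is.null(s)) stop("annotation carries no sequence")
  seqc <- if (end >= start) {
    as.character(Biostrings::subseq(s, start, end))
  } else {
    paste0(as.character(Biostrings::subseq(s, start, length(s))),
           as.character(Biostrings::subseq(s, 1L, end)))
  }
  if (strand == "-") seqc <- .revcomp(seqc)
  seqc
}
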