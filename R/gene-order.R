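## Signed circular gene-order comparison: breakpoint distance,
## rearrangement event detection, and single-event tandem
## duplication/random loss (TDRL) reachability.

#' Gene order of an annotated mitogenome
#'
#' Features sorted by start position around the circle, the control
#' region included as a positional token, orientation taken from the
#' strand.
#'
#' @param ann a \code{\linkS4class{MitoAnnotation}}.
#' @return a \code{\linkS4class{GeneOrder}}.
#' @export
orderFromAnnotation <- function(ann) {
  f <- features(ann)
  GeneOrder(f$name, f$strand)  # features are stored sorted by start
}

#' Normalize a circular gene order to a deterministic rotation
#'
#' Rotates the order so the anchor gene comes first. If the anchor lies
#' on the light strand, the whole circle is first flipped (order
#' reversed, all orientations inverted) so the anchor reads
#' \code{"+"} - the same molecule read from the other strand. Two orders
#' describe the same circular arrangement iff their normalized forms are
#' identical.
#'
#' @param order a \code{\linkS4class{GeneOrder}}.
#' @param anchor anchor token (default \code{"cox1"}); must be present.
#' @return the normalized \code{GeneOrder}.
#' @export
normalizeOrder <- function(order, anchor = "cox1") {
  tok <- orderTokens(order)
  ori <- orientations(order)
  i <- match(anchor, tok)
  if (is.na(i)) stop("anchor gene ", anchor, " absent from order")
  if (ori[i] == "-") {
    tok <- rev(tok)
    ori <- rev(ifelse(ori == "+", "-", "+"))
    i <- match(anchor, tok)
  }
  idx <- c(i:length(tok), if (i > 1L) 1:(i - 1L))
  GeneOrder(tok[idx], ori[idx])
}

## rotation equality of two signed circular orders
.rotationEqual <- function(a, b) {
  ta <- orderTokens(a); tb <- orderTokens(b)
  if (length(ta) != length(tb)) return(FALSE)
  if (length(ta) == 0L) return(TRUE)
  sa <- paste0(" ", paste(paste0(orientations(a), ta), collapse = " "), " ")
  sb2 <- paste0(" ",
                paste(rep(paste0(orientations(b), tb), 2L), collapse = " "),
                " ")
  grepl(sa, sb2, fixed = TRUE)
}

## signed circular adjacency set: "+(a)>-(b)" strings
.adjacencies <- function(order) {
  tok <- orderTokens(order)
  ori <- orientations(order)
  n <- length(tok)
  if (n < 2L) return(character())
  nxt <- c(seq_len(n)[-1], 1L)
  paste0(ori, tok, ">", ori[nxt], tok[nxt])
}

## restrict an order to a token subset, keeping circular sequence
.restrictOrder <- function(order, keep) {
  sel <- orderTokens(order) %in% keep
  GeneOrder(orderTokens(order)[sel], orientations(order)[sel])
}

#' Breakpoint distance between two signed circular gene orders
#'
#' Counts the signed circular adjacencies (ordered gene pairs with their
#' orientations) of the derived order that are absent from the reference.
#' Tokens present in only one order are skipped with a message before
#' counting. The distance is 0 iff the orders are identical up to
#' rotation, and is invariant under rotation of either order.
#'
#' @param derived,reference \code{\linkS4class{GeneOrder}} objects over a
#'   shared token universe.
#' @return integer breakpoint count.
#' @examples
#' ref <- GeneOrder("cox1,trnL2,cox2,trnK")
#' der <- GeneOrder("cox1,cox2,trnL2,trnK")
#' breakpointDistance(der, ref)
#' @export
breakpointDistance <- function(derived, reference) {
  shared <- intersect(orderTokens(derived), orderTokens(reference))
  if (length(shared) == 0L) stop("orders share no tokens")
  dropped <- c(setdiff(orderTokens(derived), shared),
               setdiff(orderTokens(reference), shared))
  if (length(dropped))
    message("tokens absent from one order skipped: ",
            paste(dropped, collapse = ", "))
  d <- .restrictOrder(derived, shared)
  r <- .restrictOrder(reference, shared)
  sum(!(.adjacencies(d) %in% .adjacencies(r)))
}

#' Detect rearrangement events between two gene orders
#'
#' Searches exhaustively over removal subsets of at most \code{maxMoved}
#' shared tokens for the minimal set of translocated genes: the smallest
#' set whose removal leaves the two circular orders equal up to rotation.
#' Inversions are genes whose orientation differs between the orders (the
#' control region, which has no transcriptional polarity of its own, is
#' excluded); duplications are tokens occurring more often in the derived
#' order than in the reference. If no subset of size \code{maxMoved} or
#' smaller explains the difference, the report is flagged complex and
#' carries the breakpoint count only.
#'
#' @param derived,reference \code{\linkS4class{GeneOrder}} objects.
#' @param maxMoved largest translocated set searched for (default 3).
#' @return list of class \code{"RearrangementReport"}: \code{breakpoints},
#'   \code{translocated}, \code{inverted}, \code{duplicated},
#'   \code{complex}, and \code{moves} (data.frame \code{gene},
#'   \code{after}, \code{orientation} describing where each translocated
#'   gene sits in the derived order; input to
#'   \code{\link{applyTranslocations}}).
#' @export
detectEvents <- function(derived, reference, maxMoved = 3L) {
  dtok <- orderTokens(derived); rtok <- orderTokens(reference)
  shared <- intersect(dtok, rtok)
  if (length(shared) == 0L) stop("orders share no tokens")
  bp <- breakpointDistance(derived, reference)
  base <- function(x) sub("#[0-9]+$", "", x)
  dup_counts <- table(base(dtok))
  ref_counts <- table(base(rtok))
  common <- intersect(names(dup_counts), names(ref_counts))
  duplicated_genes <- common[dup_counts[common] > ref_counts[common]]
  ori_d <- stats::setNames(orientations(derived), dtok)
  ori_r <- stats::setNames(orientations(reference), rtok)
  inv <- shared[ori_d[shared] != ori_r[shared]]
  inv <- inv[base(inv) != "CR"]

  d <- .restrictOrder(derived, shared)
  r <- .restrictOrder(reference, shared)
  translocated <- NULL
  if (.rotationEqual(d, r)) {
    translocated <- character()
  } else {
    for (k in seq_len(maxMoved)) {
      sols <- Filter(function(s) {
        keep <- setdiff(shared, s)
        .rotationEqual(.restrictOrder(d, keep), .restrictOrder(r, keep))
      }, utils::combn(shared, k, simplify = FALSE))
      if (length(sols)) {
        ## several minimal sets can explain the same rearrangement (a
        ## tRNA hopping over a PCG looks like the PCG hopping the other
        ## way); prefer the set with the fewest non-tRNA members, as
        ## tRNAs are the mobile elements of mitogenome rearrangement,
        ## then break remaining ties lexicographically
        score <- vapply(sols, function(s)
          sum(geneFeatureType(s) != "tRNA"), 0L)
        sols <- sols[score == min(score)]
        keys <- vapply(sols, function(s)
          paste(sort(s), collapse = "|"), "")
        translocated <- sols[[order(keys)[1]]]
        break
      }
    }
  }
  complex <- is.null(translocated)
  moves <- NULL
  if (!complex && length(translocated)) {
    ## record each moved gene's derived position as "insert after its
    ## immediate left neighbour"; the derived circle is rotated to start
    ## at an unmoved token and moves are listed left to right, so each
    ## anchor is already in place when the list is replayed in order
    n <- length(dtok)
    s <- which(!(dtok %in% translocated))[1]
    rot <- c(s:n, if (s > 1L) 1:(s - 1L))
    rtoks <- dtok[rot]
    pos <- which(rtoks %in% translocated)
    moves <- data.frame(gene = rtoks[pos], after = rtoks[pos - 1L],
                        orientation = unname(ori_d[rtoks[pos]]),
                        stringsAsFactors = FALSE)
  }
  res <- list(breakpoints = bp,
              translocated = if (complex) NA else sort(translocated),
              inverted = sort(unname(inv)),
              duplicated = sort(unname(as.character(duplicated_genes))),
              complex = complex,
              moves = moves)
  class(res) <- "RearrangementReport"
  res
}

#' @export
print.RearrangementReport <- function(x, ...) {
  cat("RearrangementReport\n")
  cat("  breakpoints:", x$breakpoints, "\n")
  if (x$complex) {
    cat("  complex rearrangement (no small translocated set found)\n")
  } else {
    fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "none"
    cat("  translocated:", fmt(x$translocated), "\n")
    cat("  inverted:    ", fmt(x$inverted), "\n")
    cat("  duplicated:  ", fmt(x$duplicated), "\n")
  }
  invisible(x)
}

#' Replay translocation events onto a reference order
#'
#' Applies the \code{moves} table of a
#' \code{\link{detectEvents}} report to a reference order: each moved
#' gene is deleted and re-inserted after its recorded predecessor with
#' its recorded orientation. Replaying the report of
#' \code{detectEvents(derived, reference)} onto \code{reference}
#' reproduces \code{derived} up to rotation.
#'
#' @param reference a \code{\linkS4class{GeneOrder}}.
#' @param moves data.frame with columns \code{gene}, \code{after},
#'   \code{orientation}.
#' @return the rearranged \code{GeneOrder}.
#' @export
applyTranslocations <- function(reference, moves) {
  tok <- orderTokens(reference)
  ori <- orientations(reference)
  if (is.null(moves) || nrow(moves) == 0L) return(reference)
  keep <- !(tok %in% moves$gene)
  tok <- tok[keep]; ori <- ori[keep]
  for (i in seq_len(nrow(moves))) {
    j <- match(moves$after[i], tok)
    if (is.na(j)) stop("insertion anchor ", moves$after[i],
                       " absent from order")
    tok <- append(tok, moves$gene[i], after = j)
    ori <- append(ori, moves$orientation[i], after = j)
  }
  GeneOrder(tok, ori)
}

#' Single-event TDRL reachability test
#'
#' Tests whether the derived arrangement of a gene segment is reachable
#' from the reference arrangement by one tandem duplication/random loss
#' event: the segment is duplicated in tandem and one copy of each gene
#' is lost at random. The survivors of the first copy (in reference
#' order) are followed by the survivors of the second copy (in reference
#' order), so a single TDRL produces exactly the orders whose genes,
#' mapped to their reference positions, form at most two increasing
#' runs (at most one descent in the reference-index sequence). A single
#' TDRL event can never invert a gene. This test agrees with exhaustive
#' enumeration of every per-gene copy-loss pattern.
#'
#' @param derived,reference \code{\linkS4class{GeneOrder}} objects.
#' @param segment character vector of tokens defining the segment
#'   tested, taken in their derived order and compared linearly. When
#'   \code{NULL} (default) the whole shared circular order is tested:
#'   because the duplicated segment may sit anywhere on the circle, all
#'   rotations of both orders are searched before declaring the
#'   arrangement unreachable.
#' @return logical flag with attribute \code{"reason"} when \code{FALSE}.
#' @examples
#' ref <- GeneOrder("cox1,trnL2,cox2,trnK")
#' der <- GeneOrder("cox1,cox2,trnL2,trnK")
#' tdrlOneStep(der, ref, segment = c("cox1", "cox2", "trnL2", "trnK"))
#' @export
tdrlOneStep <- function(derived, reference, segment = NULL) {
  dtok <- orderTokens(derived); rtok <- orderTokens(reference)
  circular <- is.null(segment)
  if (circular) segment <- intersect(dtok, rtok)
  if (!all(segment %in% dtok) || !all(segment %in% rtok))
    stop("segment tokens must be present in both orders")
  ori_d <- stats::setNames(orientations(derived), dtok)
  ori_r <- stats::setNames(orientations(reference), rtok)
  if (any(ori_d[segment] != ori_r[segment])) {
    out <- FALSE
    attr(out, "reason") <- "TDRL cannot invert"
    return(out)
  }
  seg_d <- dtok[dtok %in% segment]          # segment in derived order
  ref_index <- match(seg_d, rtok[rtok %in% segment])
  n <- length(ref_index)
  if (!circular) {
    if (.nDescents(ref_index) <= 1L) return(TRUE)
  } else {
    ## circular comparison: cut the derived circle at every position and
    ## renumber the reference from every origin
    for (a in 0:(n - 1L)) {
      idx <- ref_index[((seq_len(n) - 1L + a) %% n) + 1L]
      for (b in 0:(n - 1L)) {
        if (.nDescents(((idx - 1L + b) %% n) + 1L) <= 1L)
          return(TRUE)
      }
    }
  }
  out <- FALSE
  attr(out, "reason") <- "needs more than two tandem copies"
  out
}

## descents (strict drops between consecutive elements) of an index
## sequence: a one-step TDRL outcome has at most one
.nDescents <- function(x) {
  if (length(x) < 2L) return(0L)
  sum(diff(x) < 0L)
}

#' Built-in ancestral mitochondrial gene orders
#'
#' The plesiomorphic (pancrustacean ground pattern) arrangement of the
#' 37 mitochondrial genes plus the control region shared by ancestral
#' decapods, and the identical arrangement inferred for the caridean
#' ancestor. Entered once here as signed token strings; users can supply
#' their own orders as strings via \code{\link{GeneOrder}}.
#'
#' @param name \code{"decapoda"} or \code{"caridea"}.
#' @return a \code{\linkS4class{GeneOrder}} of 38 tokens.
#' @export
ancestralGeneOrder <- function(name = c("decapoda", "caridea")) {
  name <- tolower(name)
  if (!name[1] %in% c("decapoda", "caridea"))
    stop("unknown reference order '", name[1],
         "'; available: decapoda, caridea")
  ## ground-pattern arrangement, heavy strand +, starting at cox1
  GeneOrder(paste(
    "cox1,trnL2,cox2,trnK,trnD,atp8,atp6,cox3,trnG,nad3,trnA,trnR,trnN",
    "trnS1,trnE,-trnF,-nad5,-trnH,-nad4,-nad4l,trnT,-trnP,nad6,cob",
    "trnS2,-nad1,-trnL1,-rrnL,-trnV,-rrnS,CR,trnI,-trnQ,trnM,nad2,trnW",
    "-trnC,-trnY", sep = ","))
}
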