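test_that("gene order construction, parsing and normalization", {
  o <- GeneOrder("cox1, -nad1, trnV")
  expect_equal(orderTokens(o), c("cox1", "nad1", "trnV"))
  expect_equal(orientations(o), c("+", "-", "+"))
  expect_equal(as.character(o), "cox1,-nad1,trnV")
  # normalization rotates the anchor to the front
  rot <- GeneOrder(c("trnV", "cox1", "nad1"), c("+", "+", "-"))
  expect_equal(orderTokens(normalizeOrder(rot)),
               c("cox1", "nad1", "trnV"))
  # anchor on the light strand: circle is flipped so cox1 reads +
  flip <- GeneOrder(c("cox1", "nad1", "trnV"), c("-", "+", "+"))
  norm <- normalizeOrder(flip)
  expect_equal(orientations(norm)[1], "+")
  expect_error(normalizeOrder(GeneOrder("nad1")), "absent")
  # built-in ancestral references carry all 38 tokens
  ref <- ancestralGeneOrder("decapoda")
  expect_equal(length(ref), 38L)
  expect_equal(sum(orientations(ref) == "-"), 14L)
  expect_error(ancestralGeneOrder("nonsense"), "available")
})

test_that("breakpoint distance is zero iff rotation-equal, rotation-invariant", {
  ref <- ancestralGeneOrder("decapoda")
  expect_equal(breakpointDistance(ref, ref), 0L)
  set.seed(31)
  tok <- orderTokens(ref); ori <- orientations(ref)
  for (r in sample(1:37, 5)) {
    idx <- c((r + 1):38, 1:r)
    rot <- GeneOrder(tok[idx], ori[idx])
    expect_equal(breakpointDistance(rot, ref), 0L)
    expect_equal(breakpointDistance(ref, rot), 0L)
  }
  # a genuinely shuffled order is never rotation-equal and has bp > 0
  shuf <- GeneOrder(tok[c(2, 1, 3:38)], ori[c(2, 1, 3:38)])
  expect_gt(breakpointDistance(shuf, ref), 0L)
  # one gene reversed in place on a 5-token toy: 2 new adjacencies
  toy <- GeneOrder(letters[1:5])
  rev1 <- GeneOrder(letters[1:5], c("+", "-", "+", "+", "+"))
  expect_equal(breakpointDistance(rev1, toy), 2L)
})

test_that("the published arrangement differs from the ancestor as reported", {
  ord <- orderFromAnnotation(mk681888Annotation())
  ref <- ancestralGeneOrder("decapoda")
  # cox2 precedes trnL2 in the observed genome (coordinates decide)
  tok <- orderTokens(ord)
  expect_lt(match("cox2", tok) - match("cox1", tok),
            match("trnL2", tok) - match("cox1", tok))
  expect_equal(breakpointDistance(ord, ref), 3L)
  ev <- detectEvents(ord, ref)
  expect_equal(ev$translocated, "trnL2")
  expect_equal(ev$inverted, character(0))
  expect_equal(ev$duplicated, character(0))
  expect_false(ev$complex)
  # a single tandem duplication/random loss explains the swap
  expect_true(tdrlOneStep(ord, ref))
  expect_true(tdrlOneStep(ord, ref,
                          segment = c("cox1", "cox2", "trnL2", "trnK")))
})

test_that("detected events replay onto the reference (round trip)", {
  ref <- ancestralGeneOrder("decapoda")
  set.seed(37)
  genes <- setdiff(orderTokens(ref), "cox1")
  for (trial in 1:8) {
    k <- sample(1:2, 1)
    moved <- sample(genes, k)
    ops <- lapply(moved, function(g)
      list(op = "translocate", gene = g,
           after = sample(setdiff(orderTokens(ref), g), 1)))
    der <- applyOrderOps(ref, ops)
    ev <- detectEvents(der, ref, maxMoved = 2L)
    if (ev$complex) next  # moves can compound into larger events
    back <- applyTranslocations(ref, ev$moves)
    expect_true(MitoCircle:::.rotationEqual(back, der))
    # k single-gene translocations break at most 3k adjacencies
    expect_lte(breakpointDistance(der, ref), 3L * k)
  }
})

test_that("event detection reads inversions, duplications and complexity", {
  ref <- ancestralGeneOrder("decapoda")
  # trnE translocated next to trnP with reversed orientation
  alp <- applyOrderOps(ref, list(list(op = "translocate", gene = "trnE",
                                      after = "trnT", orientation = "-")))
  ev <- detectEvents(alp, ref)
  expect_equal(ev$translocated, "trnE")
  expect_equal(ev$inverted, "trnE")
  f <- tdrlOneStep(alp, ref)
  expect_false(as.logical(f))
  expect_equal(attr(f, "reason"), "TDRL cannot invert")
  # an extra trnQ copy downstream of nad4l
  dup <- applyOrderOps(ref, list(list(op = "duplicate", gene = "trnQ",
                                      after = "nad4l")))
  evd <- detectEvents(dup, ref)
  expect_equal(evd$duplicated, "trnQ")
  expect_equal(evd$breakpoints, 0L)  # shared tokens keep their adjacencies
  # identical orders: empty report
  ev0 <- detectEvents(ref, ref)
  expect_equal(ev0$breakpoints, 0L)
  expect_equal(ev0$translocated, character(0))
  # a long block move exceeds maxMoved and is flagged complex
  block <- c("nad1", "trnL1", "rrnL", "trnV", "rrnS", "CR", "trnI",
             "trnQ")
  ops <- lapply(rev(block), function(g)
    list(op = "translocate", gene = g, after = "nad4l"))
  hym <- applyOrderOps(ref, ops)
  evh <- detectEvents(hym, ref, maxMoved = 3L)
  expect_true(evh$complex)
  expect_gt(evh$breakpoints, 0L)
})

test_that("single-TDRL reachability matches duplication/loss enumeration", {
  expect_true(tdrlOneStep(GeneOrder(letters[1:4]), GeneOrder(letters[1:4]),
                          segment = letters[1:4]))
  expect_false(as.logical(
    tdrlOneStep(GeneOrder(c("c", "b", "a")), GeneOrder(c("a", "b", "c")),
                segment = c("a", "b", "c"))))
  set.seed(43)
  trials <- 0L
  while (trials < 500L) {
    n <- sample(3:7, 1)
    refv <- letters[1:n]
    derv <- sample(refv)
    got <- as.logical(tdrlOneStep(GeneOrder(derv), GeneOrder(refv),
                                  segment = refv))
    want <- oracle_tdrl_reachable(derv, refv)
    expect_identical(got, want)
    trials <- trials + 1L
  }
})
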