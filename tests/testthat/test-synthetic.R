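test_that("generated genomes are deterministic and template-faithful", {
  a <- generateGenome(seed = 8)
  b <- generateGenome(seed = 8)
  expect_identical(as.character(genomeSequence(a)),
                   as.character(genomeSequence(b)))
  expect_identical(features(a), features(b))
  c2 <- generateGenome(seed = 9)
  expect_false(identical(as.character(genomeSequence(a)),
                         as.character(genomeSequence(c2))))
  # round trip: the annotation's order is the template order
  expect_true(MitoCircle:::.rotationEqual(orderFromAnnotation(a),
                                          ancestralGeneOrder("decapoda")))
  f <- features(a)
  expect_equal(sum(f$type == "PCG"), 13L)
  expect_equal(sum(f$type == "tRNA"), 22L)
  expect_equal(sum(f$type == "rRNA"), 2L)
})

test_that("generated PCGs are clean ORFs on their reading strands", {
  ann <- generateGenome(seed = 12)
  code <- geneticCode(5)
  for (g in mitoGeneTokens("PCG")) {
    cds <- extractCDS(ann, g)
    expect_false(attr(cds, "incomplete_frame"))
    ss <- detectStartStop(cds)
    expect_equal(ss$start, "ATG")
    expect_equal(ss$stop, "TAA")
    inner <- MitoCircle:::.splitCodons(as.character(cds))
    inner <- inner[-length(inner)]
    expect_false(any(inner[-1] %in% code$stops))
  }
})

test_that("realized composition hits the target within sampling error", {
  # 2 x binomial sd at ~16 kb is about 0.75 percentage points
  ann <- generateGenome(seed = 21)
  at <- regionComposition(ann, "mitogenome")$AT_pct
  expect_lt(abs(at - 64.43), 0.75)
  # calibrated codon weights have the target composition in expectation
  w <- calibratedCodonWeights(c(A = 32.51, T = 31.91, G = 14.24,
                                C = 21.33))
  pos <- lapply(1:3, function(k) substr(names(w), k, k))
  target <- c(A = 32.51, T = 31.91, G = 14.24, C = 21.33)
  target <- target / sum(target)  # printed percentages sum to 99.99
  for (b in c("A", "T", "G", "C")) {
    e <- sum(w * ((pos[[1]] == b) + (pos[[2]] == b) + (pos[[3]] == b)) / 3)
    expect_equal(e, target[[b]], tolerance = 1e-6)
  }
  expect_equal(sum(w[geneticCode(5)$stops]), 0)
})

test_that("requested rearrangements are detected downstream", {
  ann <- generateGenome(seed = 14,
                        ops = list(list(op = "translocate", gene = "trnL2",
                                        after = "cox2")))
  ev <- detectEvents(orderFromAnnotation(ann),
                     ancestralGeneOrder("decapoda"))
  expect_equal(ev$translocated, "trnL2")
  expect_true(tdrlOneStep(orderFromAnnotation(ann),
                          ancestralGeneOrder("decapoda")))
})

test_that("evolvePair respects omega limits and determinism", {
  p0 <- evolvePair(nCodons = 400, omega = 0, seed = 2)
  expect_equal(ng86(p0$cdsA, p0$cdsB)$Ka, 0)
  expect_identical(evolvePair(nCodons = 100, omega = 0.5, seed = 5),
                   evolvePair(nCodons = 100, omega = 0.5, seed = 5))
  p1 <- evolvePair(nCodons = 3000, omega = 1, seed = 4)
  expect_lt(abs(ng86(p1$cdsA, p1$cdsB)$KaKs - 1), 0.1)  # neutral limit
  expect_equal(nchar(p0$cdsA), nchar(p0$cdsB))
})

test_that("panels have the requested shape and reduce to pairs", {
  panel <- generatePanel(nGenes = 2, nSpecies = 3, omega = c(0.2, 0.8),
                         nCodons = 150, seed = 6)
  expect_equal(names(panel), c("atp6", "atp8"))
  expect_true(all(vapply(panel, length, 0L) == 3L))
  one <- generatePanel(nGenes = 1, nSpecies = 2, omega = 0.3,
                       nCodons = 200, seed = 7)
  res <- panelKaKs(one)
  expect_equal(res$n_pairs, 1L)
  # distinct seeds give distinct sequences
  other <- generatePanel(nGenes = 1, nSpecies = 2, omega = 0.3,
                         nCodons = 200, seed = 8)
  expect_false(identical(one, other))
})

test_that("generator output flows through every pipeline stage", {
  ann <- generateGenome(seed = 33)
  gb <- withr::local_tempfile(fileext = ".gb")
  writeGenBank(ann, gb)
  back <- parseGenBank(gb)
  expect_equal(features(back)$name, features(ann)$name)
  comp <- compositionReport(back)
  expect_equal(nrow(comp), 18L)
  adj <- adjacencyReport(back)
  expect_equal(nrow(adj$pairs), 38L)
  usage <- annotationCodonUsage(back)
  r <- rscuValues(usage)
  leu <- chartr("T", "U", geneticCode(5)$families[["L"]])
  expect_equal(sum(r[leu]), 6)
  expect_equal(breakpointDistance(orderFromAnnotation(back),
                                  ancestralGeneOrder("decapoda")), 0L)
})
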