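test_that("genetic code 5 has the expected family structure", {
  code <- geneticCode(5)
  expect_equal(sort(code$stops), c("TAA", "TAG"))
  expect_true(all(c("AGA", "AGG") %in% code$families[["S"]]))
  expect_equal(length(code$families[["S"]]), 8L)
  expect_true("TGA" %in% code$families[["W"]])
  expect_equal(sum(lengths(code$families)), 64L)
})

test_that("CDS extraction honours strand, wrap and frame flags", {
  ann <- toy_annotation()
  expect_equal(as.character(extractCDS(ann, "cox1")), "ATGAAACCCGGGTAA")
  expect_equal(as.character(extractCDS(ann, "nad1")), "ATGAAACCCGGGTAA")
  expect_false(attr(extractCDS(ann, "cox1"), "incomplete_frame"))
  expect_error(extractCDS(ann, "CR"), "not a protein-coding")
  # the published nad2 coordinates give 982 bp: not a multiple of 3
  tab <- data.frame(Gene = "nad2", Direction = "+",
                    Start = 8223L, End = 9204L)
  ann2 <- parseFeatureTable(tab, genomeLength = 16350L,
                            sequence = strrep("AC", 8175L))
  cds <- extractCDS(ann2, "nad2")
  expect_equal(nchar(cds), 982L)
  expect_true(attr(cds, "incomplete_frame"))
})

test_that("start/stop detection handles complete and truncated stops", {
  expect_equal(detectStartStop("ATGAAATAA")[c("start", "stop")],
               list(start = "ATG", stop = "TAA"))
  ic <- detectStartStop("ATGAAACCCTA")  # trailing TA beyond last codon
  expect_equal(ic$stop, "TA")
  expect_true(ic$incomplete)
  full <- detectStartStop("ATAAAACCCTAG")
  expect_equal(full[c("start", "stop")], list(start = "ATA", stop = "TAG"))
  expect_false(full$incomplete)
  nostop <- detectStartStop("ATGAAACCC")
  expect_true(nostop$incomplete)
})

test_that("codon counting tallies in-frame triplets and skips ambiguity", {
  tab <- countCodons("ATGATG")
  expect_equal(unname(codonCounts(tab)[["AUG"]]), 2)
  expect_equal(totalCodons(tab), 2)
  # trailing partial codon ignored; N-containing triplet skipped
  tab2 <- countCodons(c("ATGAANTTTC"))
  expect_equal(totalCodons(tab2), 2)
  expect_equal(attr(tab2, "skipped"), 1L)
  # stop codons excluded on request
  tab3 <- countCodons("ATGTAAATG", includeStop = FALSE)
  expect_equal(totalCodons(tab3), 2)
  expect_equal(unname(codonCounts(tab3)[["UAA"]]), 0)
})

test_that("sampled codon frequencies track the generating distribution", {
  w <- calibratedCodonWeights()
  set.seed(41)
  n <- 3617
  cds <- paste(sample(names(w), n, replace = TRUE, prob = w),
               collapse = "")
  tab <- countCodons(cds)
  counts <- codonCounts(tab)[chartr("T", "U", names(w))]
  expected <- n * w
  sds <- sqrt(n * w * (1 - w))
  dev <- abs(counts - expected)[w > 0]
  expect_true(all(dev <= 3 * sds[w > 0] + 1e-9))
})

test_that("RSCU reproduces published Leu/Ser values and its invariants", {
  leu <- c(UUA = 106, UUG = 32, CUU = 95, CUC = 74, CUA = 99, CUG = 29)
  tab <- codonUsageTable(leu)
  expect_equal(round(rscuValues(tab)[["UUA"]], 2), 1.46)
  ser <- c(UCU = 101, UCC = 58, UCA = 74, UCG = 9, AGU = 37, AGC = 61,
           AGA = 82, AGG = 47)
  expect_equal(round(rscuValues(codonUsageTable(ser))[["UCU"]], 2), 1.72)
  # uniform family -> all RSCU 1; scaling invariance; family sums
  unif <- codonUsageTable(c(GGU = 7, GGC = 7, GGA = 7, GGG = 7))
  expect_equal(unname(rscuValues(unif)[c("GGU", "GGC", "GGA", "GGG")]),
               rep(1, 4))
  scaled <- codonUsageTable(leu * 13)
  expect_equal(rscuValues(scaled), rscuValues(tab))
  code <- geneticCode(5)
  fams <- lapply(code$families, chartr, old = "T", new = "U")
  r <- rscuValues(tab)
  for (fam in fams) {
    tot <- sum(codonCounts(tab)[fam])
    if (tot > 0) expect_equal(sum(r[fam]), length(fam))
    else expect_equal(unname(r[fam]), rep(0, length(fam)))
  }
})
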