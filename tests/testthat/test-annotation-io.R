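test_that("gene name canonicalization maps synonyms and is idempotent", {
  got <- canonicalizeGeneName(c("COIII", "COI", "tRNA-Ser2", "trnL(UUR)",
                                "D-loop", "16S rRNA", "l-rRNA",
                                "tRNA-Leu1", "ND4L", "CYTB", "unknownORF"))
  expect_equal(as.character(got),
               c("cox3", "cox1", "trnS2", "trnL2", "CR", "rrnL", "rrnL",
                 "trnL1", "nad4l", "cob", "unknownORF"))
  expect_equal(attr(got, "flagged"),
               c(rep(FALSE, 10), TRUE))
  # idempotent on canonical tokens, and duplicate suffixes survive
  twice <- canonicalizeGeneName(as.character(got))
  expect_equal(as.character(twice), as.character(got))
  expect_equal(as.character(canonicalizeGeneName("trnQ#2")), "trnQ#2")
})

test_that("feature table rows reproduce published lengths, with wrap", {
  tab <- data.frame(Gene = c("nad4", "CR", "x"),
                    Direction = c("-", "+", "+"),
                    Start = c(13L, 6738L, 16340L),
                    End = c(1239L, 7986L, 20L))
  ann <- parseFeatureTable(tab, genomeLength = 16350L)
  len <- featureLengths(ann)
  expect_equal(unname(len[["nad4"]]), 1227L)
  expect_equal(unname(len[["CR"]]), 1249L)
  expect_equal(unname(len[["x"]]), 31L)  # wraps the origin
  expect_error(parseFeatureTable(
    data.frame(Gene = "y", Direction = "+", Start = 0L, End = 5L),
    genomeLength = 100L), "outside")
})

test_that("annotation table write/parse is the identity on features", {
  ann <- generateGenome(seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeAnnotationTable(ann, path)
  back <- parseFeatureTable(path, genomeLength = genomeLength(ann))
  expect_equal(features(back)[, c("name", "strand", "start", "end")],
               features(ann)[, c("name", "strand", "start", "end")])
  expect_equal(nrow(features(back)), 38L)
  # without sequence the codon columns stay empty
  ann2 <- mk681888Annotation()
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeAnnotationTable(ann2, path2)
  raw <- utils::read.delim(path2)
  expect_true(all(is.na(raw$Start_codon) | raw$Start_codon == ""))
})

test_that("GenBank writer/parser round-trips a generated genome", {
  ann <- generateGenome(seed = 5)
  path <- withr::local_tempfile(fileext = ".gb")
  writeGenBank(ann, path)
  back <- parseGenBank(path)
  expect_true(isCircular(back))
  expect_equal(genomeLength(back), genomeLength(ann))
  expect_equal(features(back)[, c("name", "type", "strand", "start", "end")],
               features(ann)[, c("name", "type", "strand", "start", "end")])
  expect_equal(as.character(genomeSequence(back)),
               as.character(genomeSequence(ann)))
})

test_that("GenBank parser canonicalizes names and keeps unknowns", {
  gb <- c(
    "LOCUS       toy 120 bp    DNA     circular     INV",
    "FEATURES             Location/Qualifiers",
    "     CDS             5..40",
    '                     /gene="COI"',
    "     tRNA            complement(50..80)",
    '                     /product="tRNA-Leu1"',
    "     misc_feature    90..110",
    '                     /note="mystery"',
    '                     /gene="unknownORF"',
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  expect_warning(ann <- parseGenBank(path), "unknownORF")
  f <- features(ann)
  expect_equal(f$name, c("cox1", "trnL1", "unknownORF"))
  expect_equal(f$type, c("PCG", "tRNA", "CR"))
  expect_equal(f$strand, c("+", "-", "+"))
  expect_true(f$flagged[3])
  expect_error(parseGenBank(withr::local_tempfile(lines = "not genbank")),
               "LOCUS")
})

test_that("annotation validity rejects inconsistent objects", {
  ft <- data.frame(name = "cox1", strand = "+", start = 1L, end = 50L)
  expect_error(MitoAnnotation(ft, genomeLength = 40L), "coordinates")
  expect_error(MitoAnnotation(ft, genomeLength = 100L,
                              sequence = strrep("A", 99L)),
               "sequence length")
})
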