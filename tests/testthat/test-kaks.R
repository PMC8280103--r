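test_that("site counts match exhaustive enumeration for all sense codons", {
  code <- geneticCode(5)
  sense <- setdiff(names(code$aa), code$stops)
  for (cod in sense) {
    expect_equal(unname(codonSites(cod)), unname(oracle_sites(cod)),
                 tolerance = 1e-12)
  }
  expect_equal(unname(codonSites("GGA")[["S"]]), 1)  # 4-fold third position
  expect_error(codonSites("TAA"), "not a sense codon")
})

test_that("pathway differences match brute-force pathway enumeration", {
  expect_equal(codonPathDifferences("ATG", "ATG"), c(sd = 0, nd = 0))
  expect_equal(unname(codonPathDifferences("TTA", "TTG")),
               c(1, 0))  # single synonymous change (Leu)
  set.seed(17)
  cods <- random_sense_codons(400)
  for (i in seq(1, 400, by = 2)) {
    a <- cods[i]; b <- cods[i + 1]
    got <- codonPathDifferences(a, b)
    want <- oracle_pathdiff(a, b)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
    expect_equal(sum(got),
                 sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]))
  }
})

test_that("ng86 is symmetric, conserves sites, zero on identity", {
  set.seed(23)
  a <- paste(random_sense_codons(50), collapse = "")
  b <- paste(random_sense_codons(50), collapse = "")
  self <- ng86(a, a)
  expect_equal(self$Ka, 0)
  expect_equal(self$Ks, 0)
  ab <- ng86(a, b); ba <- ng86(b, a)
  expect_equal(ab[, c("S_sites", "N_sites", "Sd", "Nd", "Ks", "Ka")],
               ba[, c("S_sites", "N_sites", "Sd", "Nd", "Ks", "Ka")])
  expect_equal(ab$S_sites + ab$N_sites, 3 * ab$n_codons)
  expect_error(ng86("ATGAAA", "ATG"), "equal length")
  expect_error(ng86("ATGA", "ATGA"), "multiple of 3")
})

test_that("ng86 equals the literal NG86 oracle on short codon pairs", {
  set.seed(29)
  for (trial in 1:60) {
    n <- sample(1:5, 1)
    a <- paste(random_sense_codons(n), collapse = "")
    b <- paste(random_sense_codons(n), collapse = "")
    got <- ng86(a, b)
    want <- oracle_ng86(a, b)
    expect_equal(got$S_sites, want$S, tolerance = 1e-12)
    expect_equal(got$N_sites, want$N, tolerance = 1e-12)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
    if (!is.na(want$Ks)) expect_equal(got$Ks, want$Ks, tolerance = 1e-12)
    if (!is.na(want$Ka)) expect_equal(got$Ka, want$Ka, tolerance = 1e-12)
  }
})

test_that("estimated Ka/Ks increases with the generating omega", {
  omegas <- c(0.1, 0.3, 0.6, 0.9)
  est <- vapply(seq_along(omegas), function(i) {
    p <- evolvePair(nCodons = 1200, omega = omegas[i], seed = 100 + i)
    ng86(p$cdsA, p$cdsB)$KaKs
  }, 0)
  expect_true(all(diff(est) > 0) ||
                stats::coef(stats::lm(est ~ omegas))[2] > 0)
  # purifying-selection panels stay below one
  expect_true(all(est[omegas < 1] < 1))
})

test_that("panel averaging reduces, excludes undefined, survives errors", {
  p <- evolvePair(nCodons = 300, omega = 0.4, seed = 9)
  panel <- list(g1 = c(spA = p$cdsA, spB = p$cdsB))
  res <- panelKaKs(panel)
  expect_equal(res$mean_KaKs, ng86(p$cdsA, p$cdsB)$KaKs)
  expect_equal(res$n_pairs, 1L)
  # identical sequences: Ka = Ks = 0, ratio undefined and flagged
  ident <- list(g1 = c(a = p$cdsA, b = p$cdsA, c = p$cdsA))
  res2 <- panelKaKs(ident)
  expect_equal(res2$mean_Ka, 0)
  expect_true(is.na(res2$mean_KaKs))
  expect_equal(res2$n_undefined, 3L)
  # one broken gene does not sink the panel
  mixed <- list(bad = c(a = "ATGAAA", b = "ATG"),
                good = c(a = p$cdsA, b = p$cdsB))
  res3 <- panelKaKs(mixed)
  expect_true(is.na(res3$mean_KaKs[res3$gene == "bad"]))
  expect_false(is.na(res3$mean_KaKs[res3$gene == "good"]))
  # focal mode limits pairs
  tri <- list(g = c(s1 = p$cdsA, s2 = p$cdsB, s3 = p$cdsA))
  expect_equal(panelKaKs(tri, focal = "s1")$n_pairs, 2L)
})
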