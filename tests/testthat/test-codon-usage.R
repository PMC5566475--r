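test_that("CDS validity checks report the first failure", {
  expect_true(validateForCodonAnalysis("ATGAAATAA")$valid)
  expect_equal(validateForCodonAnalysis("TTGAAATAA")$reason, "start")
  expect_equal(validateForCodonAnalysis("ATGANATAA")$reason, "ambiguous")
  expect_equal(validateForCodonAnalysis("ATGTAAAAATAA")$reason,
               "internal_stop")
  expect_equal(validateForCodonAnalysis("ATGAAACCC")$reason, "stop")
  expect_equal(validateForCodonAnalysis("ATGAAATA")$reason, "length")
})

test_that("optimal codons derive from the top expression quantile", {
  # plant an optimal set: bias = 1 makes the top corpus use only it
  planted <- c(K = "AAG", E = "GAA", F = "TTC", L = "CTT", V = "GTA")
  w <- setNames(rep(1, length(planted)), planted)
  set.seed(6)
  top <- setNames(replicate(3, genCds(120, weights = w)),
                  paste0("hi", 1:3))
  rest <- setNames(replicate(27, genCds(120)), paste0("lo", 1:27))
  cdss <- c(top, rest)
  expr <- setNames(c(rep(100, 3), rep(1, 27)), names(cdss))
  opt <- deriveOptimalCodons(cdss, expr, top_fraction = 0.1)
  expect_equal(attr(opt, "provenance"), "derived")
  expect_equal(opt[names(planted)], planted)
  expect_false(any(c("M", "W") %in% names(opt)))

  expect_error(deriveOptimalCodons(cdss, NULL), "expression")

  # exact tie broken toward the lexicographically smaller codon
  tied <- setNames(rep(paste0("ATG", strrep("AAA", 5), strrep("AAG", 5),
                              "TAA"), 10), paste0("t", 1:10))
  e2 <- setNames(rep(1, 10), names(tied))
  opt2 <- deriveOptimalCodons(tied, e2, top_fraction = 0.5)
  expect_equal(unname(opt2["K"]), "AAA")
})

test_that("optimal-codon tables round-trip through TSV with validation", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("K\tAAG", "E\tGAA"), p)
  opt <- readOptimalCodons(p)
  expect_equal(unname(opt["K"]), "AAG")
  writeLines(c("K\tGAA"), p)             # GAA encodes E, not K
  expect_error(readOptimalCodons(p), "line 1")
  writeLines(c("M\tATG"), p)
  expect_error(readOptimalCodons(p), "M, W")
})

test_that("Fop counts optimal codons over countable codons", {
  opt <- c(K = "AAG", F = "TTC")
  # countable: AAG AAG TTC AAA -> 3 of 4 optimal
  cds <- paste0("ATG", "AAG", "AAG", "TTC", "AAA", "TAA")
  expect_equal(computeFop(cds, opt), 0.75)
  expect_equal(computeFop(paste0("ATG", "AAG", "AAG", "TAA"), opt), 1)
  # only Met codons: no countable codon, Fop undefined
  expect_true(is.na(computeFop("ATGATGATGTAA", opt)))
  expect_error(computeFop("ATGAAA", opt), "invalid")

  # replacing a non-optimal codon by the optimal one never lowers Fop
  set.seed(8)
  for (i in 1:5) {
    s <- genCds(60)
    f1 <- computeFop(s, opt)
    swapped <- gsub("AAA", "AAG", s)   # codon-aligned: length multiple of 3
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    codons[codons == "AAA"] <- "AAG"
    s2 <- paste(codons, collapse = "")
    f2 <- computeFop(s2, opt)
    if (!is.na(f1) && !is.na(f2)) expect_gte(f2, f1)
  }

  # concatenation lies between the two component Fop values
  a <- paste0("ATG", "AAG", "AAG", "TTC", "TAA")    # 1.0
  b <- paste0("ATG", "AAA", "AAA", "TTC", "TAA")    # 1/3
  ab <- paste0(substr(a, 1, nchar(a) - 3), substr(b, 4, nchar(b)))
  fab <- computeFop(ab, opt)
  expect_true(fab >= computeFop(b, opt) && fab <= computeFop(a, opt))
})

test_that("amino-acid length is the codon count minus the stop", {
  expect_equal(aaLength("ATGAAATAA"), 2L)
  expect_equal(aaLength(genCds(100, seed = 1)), 100L)
  expect_error(aaLength("ATGAAATAAC"), "length")
})

test_that("usage tables carry validity reasons alongside Fop", {
  opt <- c(K = "AAG")
  tab <- codonUsageTable(c(good = "ATGAAGTAA", bad = "TTGAAGTAA"), opt)
  expect_equal(tab$valid, c(TRUE, FALSE))
  expect_equal(tab$reason, c("ok", "start"))
  expect_equal(tab$fop, c(1, NA))
})
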