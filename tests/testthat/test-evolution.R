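sense <- setdiff(names(Biostrings::GENETIC_CODE),
                 c("TAA", "TAG", "TGA"))

test_that("codon site counts match enumeration of single-base neighbours", {
  expect_equal(codonSites("AAA"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(codonSites("ATG"), c(s = 0, n = 3))
  expect_error(codonSites("TAA"), "sense")
  set.seed(2)
  for (cd in sample(sense, 12)) {
    expect_equal(codonSites(cd), oracle_codon_sites(cd), info = cd)
    expect_equal(sum(codonSites(cd)), 3)      # conservation
  }
})

test_that("codon differences average over stop-free mutational pathways", {
  expect_equal(codonDifferences("AAA", "AAG"), c(sd = 1, nd = 0))
  expect_equal(codonDifferences("AAA", "AAC"), c(sd = 0, nd = 1))
  expect_equal(codonDifferences("TTA", "CTG"), c(sd = 2, nd = 0))
  set.seed(3)
  for (i in 1:20) {
    a <- sample(sense, 1); b <- sample(sense, 1)
    got <- codonDifferences(a, b)
    k <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(sum(got), k, info = paste(a, b))          # sd + nd = k
    expect_equal(got, codonDifferences(b, a))              # symmetry
  }
})

test_that("Ka/Ks estimation satisfies the NG86 accounting identities", {
  ca <- CodonAlignment("a", "b", rep("AAA", 10),
                       c(rep("AAA", 9), "AAG"))
  e <- estimateKaKs(ca)
  expect_equal(e$S, 10 / 3)
  expect_equal(e$N, 80 / 3)
  expect_equal(e$Sd, 1); expect_equal(e$Nd, 0)
  expect_equal(e$pS, 0.3)
  expect_equal(e$Ks, -0.75 * log(0.6), tolerance = 1e-10)
  expect_equal(e$Ka, 0)
  expect_equal(e$omega, 0)
  expect_equal(e$status, "ok")

  # identical sequences: 0/0 leaves omega undefined
  e0 <- estimateKaKs(CodonAlignment("a", "b", rep("AAA", 5),
                                    rep("AAA", 5)))
  expect_equal(e0$Ka, 0); expect_equal(e0$Ks, 0)
  expect_true(is.na(e0$omega))
  expect_equal(e0$status, "omega_undefined")

  expect_error(estimateKaKs(CodonAlignment("a", "b", "---", "AAA")),
               "gapless")
})

test_that("estimates are symmetric and satisfy conservation on random pairs", {
  set.seed(13)
  for (i in 1:5) {
    a <- genCds(40); b <- mutate_dna(a, 0.06)
    if (!isFullLength(b)) next
    ca <- codonAlignPair(a, b, gene_a = "x", gene_b = "y")
    cb <- CodonAlignment("y", "x", ca@codonsB, ca@codonsA)
    ea <- as.data.frame(estimateKaKs(ca))
    eb <- as.data.frame(estimateKaKs(cb))
    expect_equal(ea$S, eb$S); expect_equal(ea$N, eb$N)
    expect_equal(ea$Sd, eb$Sd); expect_equal(ea$Nd, eb$Nd)
    expect_equal(ea$Ka, eb$Ka); expect_equal(ea$Ks, eb$Ks)
    idx <- gaplessColumns(ca)
    expect_equal(ea$S + ea$N, 3 * length(idx))
    ndiff <- sum(mapply(function(p, q)
      sum(strsplit(p, "")[[1]] != strsplit(q, "")[[1]]),
      ca@codonsA[idx], ca@codonsB[idx]))
    expect_equal(ea$Sd + ea$Nd, ndiff)
  }
})

test_that("one extra synonymous difference raises Ks and leaves Ka fixed", {
  base <- rep("AAA", 30)
  one <- c(rep("AAA", 29), "AAG")
  two <- c(rep("AAA", 28), "AAG", "AAG")
  e1 <- estimateKaKs(CodonAlignment("a", "b", base, one))
  e2 <- estimateKaKs(CodonAlignment("a", "b", base, two))
  expect_true(e2$Ks > e1$Ks)
  expect_equal(e2$Ka, e1$Ka)
})

test_that("Ks filter keeps the closed interval and names exclusion reasons", {
  est <- DataFrame(Ks = c(0.005, 0.01, 0.21, 0.30, 0.35, NA))
  out <- ksFilter(est)
  expect_equal(out$retained, c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$filter_reason,
               c("ks_too_low", "ok", "ok", "ok", "ks_too_high",
                 "ks_undefined"))
})

test_that("selection regimes split at omega = 1", {
  expect_equal(classifySelection(c(0.56, 1, 1.2)),
               c("purifying", "neutral", "positive"))
  expect_equal(classifySelection(1 + 1e-12), "neutral")
  expect_error(classifySelection(NA_real_), "undefined")
})

test_that("group means equal a brute-force recomputation", {
  set.seed(4)
  est <- ksFilter(DataFrame(
    Ka = runif(20, 0, 0.2), Ks = runif(20, 0, 0.4),
    omega = runif(20, 0, 1.5),
    expression_class = sample(c("homogeneous", "heterogeneous"), 20,
                              replace = TRUE),
    composition = sample(c("somatic_somatic", "somatic_sex"), 20,
                         replace = TRUE)))
  expect_message(gm <- groupMeans(est), "sex_sex")
  keep <- as.data.frame(est[est$retained, ])
  for (g in unique(keep$expression_class)) {
    row <- gm$expression_class[gm$expression_class$expression_class == g, ]
    sub <- keep[keep$expression_class == g, ]
    expect_equal(row$mean_ka, sum(sub$Ka) / nrow(sub))
    expect_equal(row$mean_ks, sum(sub$Ks) / nrow(sub))
    expect_equal(row$mean_omega, sum(sub$omega) / nrow(sub))
  }
  expect_equal(gm$overall$mean_ka, mean(keep$Ka))
  # single-pair group mean is that pair's value
  one <- ksFilter(DataFrame(Ka = 0.08, Ks = 0.2, omega = 0.4,
                            expression_class = "homogeneous",
                            composition = "sex_sex"))
  expect_equal(suppressMessages(groupMeans(one))$overall$mean_ka, 0.08)
})
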