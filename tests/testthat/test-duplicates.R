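test_that("full-length coding-frame predicate", {
  expect_true(isFullLength("ATGAAATAA"))
  expect_false(isFullLength("ATGAAA"))          # no stop
  expect_false(isFullLength("ATGTAAAAATAA"))    # internal stop
  expect_false(isFullLength("ATGAANTAA"))       # ambiguous base
  expect_false(isFullLength("ATGAAATA"))        # frame broken
})

test_that("all-vs-all reports identical sequences as a perfect hit", {
  s <- genCds(99, seed = 3)
  hits <- allVsAll(c(g1 = s, g2 = s))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 100)
  expect_equal(hits$coverage, 100)
  expect_true(hits$evalue < 1e-10)
  expect_error(allVsAll(c(g1 = s)), "at least 2")
})

test_that("unrelated sequences with no shared word produce no hit", {
  a <- genCds(40, seed = 11)
  b <- genCds(40, seed = 12)
  # frozen fixture: verify the premise, then the conclusion
  kmers <- function(s) unique(substring(s, 1:(nchar(s) - 10), 11:nchar(s)))
  expect_length(intersect(kmers(a), kmers(b)), 0)
  expect_equal(nrow(allVsAll(c(g1 = a, g2 = b))), 0L)
})

test_that("planted ~90% identity is recovered within 2 points", {
  set.seed(21)
  a <- genCds(100)
  b <- mutate_dna(a, 0.10)
  hits <- allVsAll(c(g1 = a, g2 = b))
  expect_equal(nrow(hits), 1L)
  expect_true(abs(hits$identity - 90) <= 2)
  # independent Smith-Waterman oracle agrees on the alignment score
  expect_equal(hits$score, oracle_sw(a, b))
})

test_that("hit tables are invariant under input order", {
  set.seed(31)
  a <- genCds(80); b <- mutate_dna(a, 0.05); c <- genCds(80)
  h1 <- allVsAll(c(x1 = a, x2 = b, x3 = c))
  h2 <- allVsAll(c(x3 = c, x2 = b, x1 = a))
  expect_equal(as.data.frame(h1), as.data.frame(h2))
})

test_that("pair criteria are strict for identity and coverage", {
  hits <- DataFrame(gene_a = paste0("a", 1:4), gene_b = paste0("b", 1:4),
                    identity = c(90, 80, 95, 85),
                    coverage = c(85, 95, 80, 90),
                    score = c(100, 100, 100, 100),
                    evalue = c(1e-20, 1e-20, 1e-20, 1e-5),
                    aligned_length = rep(300L, 4))
  kept <- applyPairCriteria(hits)
  expect_equal(kept$gene_a, "a1")       # a2: identity == 80; a3: coverage
  kept2 <- applyPairCriteria(hits, use_evalue = FALSE)
  expect_setequal(kept2$gene_a, c("a1", "a4"))
  # tightening any threshold never adds pairs
  expect_true(all(applyPairCriteria(hits, min_identity = 92)$gene_a %in%
                    kept$gene_a))
})

test_that("best hit per unordered pair survives deduplication", {
  hits <- DataFrame(gene_a = c("a", "a"), gene_b = c("b", "b"),
                    identity = c(95, 94), coverage = c(90, 99),
                    score = c(50, 80), evalue = c(1e-30, 1e-40),
                    aligned_length = c(250L, 290L))
  kept <- applyPairCriteria(hits)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$score, 80)
})

test_that("pairs are labelled by tissue match and group composition", {
  cls <- DataFrame(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    status = c(rep("tissue_specific", 5), "common"),
    specific_tissue = c("root", "root", "gynoecium", "androecium",
                        "stalk", NA),
    group = c("somatic_specific", "somatic_specific", "sex_specific",
              "sex_specific", "somatic_specific", "not_applicable"))
  pairs <- DataFrame(gene_a = c("g1", "g3", "g3", "g1"),
                     gene_b = c("g2", "g5", "g4", "g6"))
  expect_message(lab <- labelPairs(pairs, cls), "not tissue-specific")
  expect_equal(nrow(lab), 3L)   # g1-g6 dropped
  expect_equal(lab$expression_class,
               c("homogeneous", "heterogeneous", "heterogeneous"))
  expect_equal(lab$composition,
               c("somatic_somatic", "somatic_sex", "sex_sex"))
})
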