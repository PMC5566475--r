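test_that("FPKM TSV round-trips with subgenome assignment", {
  m <- matrix(c(5, 0, 1, 2, 3, 4), nrow = 3,
              dimnames = list(c("Aradu.G1", "Araip.G2", "X.G3"),
                              c("root", "leaf")))
  te <- readFpkmMatrix(write_fpkm_tsv(m))
  expect_s4_class(te, "TissueExpression")
  expect_equal(dim(te), c(3L, 2L))
  expect_equal(unname(fpkm(te)), unname(m))
  expect_equal(unname(subgenome(te)), c("A", "B", "unknown"))
  expect_equal(tissueNames(te), c("root", "leaf"))
})

test_that("malformed FPKM input is rejected with the offender named", {
  m <- matrix(1:4, 2, dimnames = list(c("g1", "g1"), c("t1", "t2")))
  expect_error(readFpkmMatrix(write_fpkm_tsv(m)), "g1")

  p <- tempfile()
  writeLines(c("gene\tt1\tt2", "g1\t1\t-1.0", "g2\t1\t2"), p)
  expect_error(readFpkmMatrix(p), "g1.*t2")

  writeLines(c("gene\tt1\tt2", "g1\t1\tx", "g2\t1\t2"), p)
  expect_error(readFpkmMatrix(p), "g1")

  writeLines(c("gene\tt1\tt2", "g1\t1", "g2\t1\t2"), p)
  expect_error(readFpkmMatrix(p), "ragged")

  expect_error(TissueExpression(matrix(c(1, Inf), 1,
    dimnames = list("g", c("a", "b")))), "finite")
})

test_that("log2 levels transform monotonically with a zero sentinel", {
  m <- TissueExpression(matrix(c(8, 0, 1, 3), 2,
    dimnames = list(c("g1", "g2"), c("t1", "t2"))))
  lv0 <- log2Levels(m, pseudocount = 0)
  expect_equal(lv0["g1", "t1"], 3)
  expect_true(is.na(lv0["g2", "t1"]))     # not expressed, not -Inf
  lv1 <- log2Levels(m, pseudocount = 1)
  expect_equal(lv1["g2", "t1"], 0)
  vals <- sort(runif(50, 0.01, 100))
  mt <- TissueExpression(matrix(vals, nrow = 1,
    dimnames = list("g", paste0("t", 1:50))))
  expect_true(all(diff(log2Levels(mt, 0)[1, ]) > 0))
})

test_that("gene classification follows the one-tissue / all-tissue rules", {
  tis <- peanutTissues()
  x <- matrix(0, 5, 22, dimnames = list(paste0("g", 1:5), tis))
  x[1, "gynoecium"] <- 5                 # sex tissue-specific
  x[2, ] <- 2                            # common
  x[3, c("root", "stalk")] <- 5          # two tissues -> intermediate
  x[4, "root"] <- 0.5                    # below threshold -> intermediate
  x[5, "root"] <- 3                      # somatic tissue-specific
  cls <- classifyGenes(TissueExpression(x), expressed_threshold = 1)
  expect_equal(cls$status,
               c("tissue_specific", "common", "intermediate",
                 "intermediate", "tissue_specific"))
  expect_equal(cls$specific_tissue[c(1, 5)], c("gynoecium", "root"))
  expect_equal(cls$group[c(1, 5)], c("sex_specific", "somatic_specific"))
  expect_equal(cls$group[2:4], rep("not_applicable", 3))
  expect_equal(cls$expression_level[1], log2(5))

  expect_error(classifyGenes(TissueExpression(x), sex_tissues = "petal"),
               "petal")
})

test_that("classification is a partition and common count is threshold-monotone", {
  set.seed(42)
  for (rep in 1:5) {
    x <- matrix(rexp(40 * 8, 1 / 3), 40, 8,
                dimnames = list(paste0("g", 1:40), paste0("t", 1:8)))
    x[sample(length(x), 60)] <- 0
    te <- TissueExpression(x)
    counts <- sapply(c(0.5, 1, 2, 4), function(thr) {
      cls <- classifyGenes(te, expressed_threshold = thr,
                           sex_tissues = "t1")
      expect_equal(sum(table(cls$status)), 40)   # exact partition
      sum(cls$status == "common")
    })
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("summaries report two-decimal percentages that add up", {
  cls <- DataFrame(
    gene_id = paste0("g", 1:10),
    status = c(rep("tissue_specific", 4), rep("common", 3),
               rep("intermediate", 3)),
    specific_tissue = c("gynoecium", "root", "root", "nodule",
                        rep(NA, 6)),
    group = c("sex_specific", rep("somatic_specific", 3),
              rep("not_applicable", 6)),
    subgenome = rep(c("A", "B"), 5))
  s <- summarizeClassification(cls, total_genes = 10)
  expect_equal(s$status$percent[s$status$level == "tissue_specific"], 40)
  # tissue table sorted descending, ties broken alphabetically
  expect_equal(s$tissue$tissue, c("root", "gynoecium", "nodule"))
  # disjoint categories of one denominator sum to their union's percent
  expect_equal(sum(s$group$percent),
               s$status$percent[s$status$level == "tissue_specific"],
               tolerance = 0.011)
  # absent categories are reported as zero
  cls0 <- cls[cls$status != "common", ]
  s0 <- summarizeClassification(cls0, total_genes = 10)
  expect_equal(s0$status$count[s0$status$level == "common"], 0L)
  expect_equal(s0$status$percent[s0$status$level == "common"], 0)

  expect_error(summarizeClassification(cls, total_genes = 0), "positive")
  expect_error(summarizeClassification(cls, total_genes = 5), "smaller")
})
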