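#' TissueExpression: a gene-by-tissue FPKM matrix
#'
#' An S4 container for per-tissue gene expression, extending
#' \link[SummarizedExperiment]{SummarizedExperiment}. The single assay,
#' \code{"fpkm"}, holds non-negative finite FPKM values with one row per gene
#' and one column per tissue; the per-gene subgenome of origin (\code{"A"},
#' \code{"B"} or \code{"unknown"}) is kept in \code{rowData}.
#'
#' @param fpkm numeric matrix of FPKM values, genes in rows (rownames
#'   required), tissues in columns (colnames required).
#' @param subgenome character vector, one of \code{"A"}, \code{"B"},
#'   \code{"unknown"} per gene; recycled \code{"unknown"} when \code{NULL}.
#'
#' @return a \code{TissueExpression} object.
#' @examples
#' m <- matrix(c(5, 0, 2, 3), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("root", "leaf")))
#' te <- TissueExpression(m, subgenome = c("A", "B"))
#' fpkm(te)
#' @export
#' @aliases TissueExpression-class
setClass("TissueExpression", contains = "SummarizedExperiment")

setValidity("TissueExpression", function(object) {
  msg <- character()
  if (!"fpkm" %in% names(assays(object)))
    msg <- c(msg, "assay 'fpkm' is required")
  else {
    x <- assay(object, "fpkm")
    if (nrow(x) == 0L || ncol(x) == 0L)
      msg <- c(msg, "matrix must have at least one gene and one tissue")
    if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
      msg <- c(msg, "gene ids (rownames) must be present and unique")
    if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
      msg <- c(msg, "tissue ids (colnames) must be present and unique")
    if (any(!is.finite(x)) || any(x < 0))
      msg <- c(msg, "FPKM values must be finite and non-negative")
  }
  if (!"subgenome" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData column 'subgenome' is required")
  else if (!all(rowData(object)$subgenome %in% c("A", "B", "unknown")))
    msg <- c(msg, "subgenome labels must be 'A', 'B' or 'unknown'")
  if (length(msg)) msg else TRUE
})

#' @rdname TissueExpression-class
#' @export
TissueExpression <- function(fpkm, subgenome = NULL) {
  fpkm <- as.matrix(fpkm)
  if (is.null(subgenome)) subgenome <- rep("unknown", nrow(fpkm))
  se <- SummarizedExperiment(
    assays  = list(fpkm = fpkm),
    rowData = DataFrame(subgenome = subgenome, row.names = rownames(fpkm))
  )
  new("TissueExpression", se)
}

#' @describeIn TissueExpression-class the FPKM matrix.
#' @param x,object a \code{TissueExpression}.
#' @export
setGeneric("fpkm", function(x) standardGeneric("fpkm"))

#' @rdname TissueExpression-class
#' @export
setMethod("fpkm", "TissueExpression", function(x) assay(x, "fpkm"))

#' @describeIn TissueExpression-class per-gene subgenome labels.
#' @export
setGeneric("subgenome", function(x) standardGeneric("subgenome"))

#' @rdname TissueExpression-class
#' @export
setMethod("subgenome", "TissueExpression", function(x)
  setNames(as.character(rowData(x)$subgenome), rownames(x)))

#' @describeIn TissueExpression-class tissue names, in column order.
#' @export
setGeneric("tissueNames", function(x) standardGeneric("tissueNames"))

#' @rdname TissueExpression-class
#' @export
setMethod("tissueNames", "TissueExpression", function(x) colnames(x))

#' @describeIn TissueExpression-class gene identifiers, in row order.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname TissueExpression-class
#' @export
setMethod("geneIds", "TissueExpression", function(x) rownames(x))

setMethod("show", "TissueExpression", function(object) {
  cat("TissueExpression:", nrow(object), "genes x", ncol(object),
      "tissues\n")
  tab <- table(rowData(object)$subgenome)
  cat("subgenome:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

#' CodonAlignment: a codon-level pairwise alignment
#'
#' Holds the aligned codon columns of two coding sequences after protein
#' alignment and back-translation. Each row is a vector of triplets where
#' \code{"---"} is a gap codon; terminal stop codons are not part of the
#' alignment. Ungapping either row reproduces the original CDS minus its
#' stop codon.
#'
#' @param geneA,geneB gene identifiers.
#' @param codonsA,codonsB character vectors of triplets (or \code{"---"}),
#'   equal length.
#' @return a \code{CodonAlignment} object.
#' @examples
#' ca <- CodonAlignment("g1", "g2", c("ATG", "AAA"), c("ATG", "AAG"))
#' gaplessColumns(ca)
#' @export
#' @aliases CodonAlignment-class
setClass("CodonAlignment",
  representation(geneA = "character", geneB = "character",
                 codonsA = "character", codonsB = "character"))

setValidity("CodonAlignment", function(object) {
  msg <- character()
  if (length(object@codonsA) != length(object@codonsB))
    msg <- c(msg, "rows must have the same number of codon columns")
  ok <- function(v) all(nchar(v) == 3L) &&
    all(grepl("^([ACGT]{3}|---)$", v))
  if (!ok(object@codonsA) || !ok(object@codonsB))
    msg <- c(msg, "codons must be ACGT triplets or the gap triplet '---'")
  if (any(object@codonsA == "---" & object@codonsB == "---"))
    msg <- c(msg, "a column cannot be gap in both rows")
  if (length(msg)) msg else TRUE
})

#' @rdname CodonAlignment-class
#' @export
CodonAlignment <- function(geneA, geneB, codonsA, codonsB) {
  new("CodonAlignment", geneA = geneA, geneB = geneB,
      codonsA = codonsA, codonsB = codonsB)
}

#' @describeIn CodonAlignment-class indices of columns with no gap in
#'   either row (the columns used for substitution-rate estimation).
#' @param x,object a \code{CodonAlignment}.
#' @export
setGeneric("gaplessColumns", function(x) standardGeneric("gaplessColumns"))

#' @rdname CodonAlignment-class
#' @export
setMethod("gaplessColumns", "CodonAlignment", function(x)
  which(x@codonsA != "---" & x@codonsB != "---"))

setMethod("show", "CodonAlignment", function(object) {
  n <- length(object@codonsA)
  cat("CodonAlignment:", object@geneA, "vs", object@geneB, "-", n,
      "codon columns,", length(gaplessColumns(object)), "gapless\n")
})
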