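#' The 22 peanut tissues profiled by the reference RNA-seq panel
#'
#' Developmental stages of one organ (e.g. the Pattee seed stages) count as
#' distinct tissues. Gynoecium and androecium are the sexual tissues.
#'
#' @return character vector of 22 tissue names.
#' @export
peanutTissues <- function() {
  c("gynoecium", "root", "nodule", "pattee5_seed", "reproductive_shoot",
    "pattee6_seed", "main_stem_leaf", "lateral_leaf", "pattee8_seed",
    "perianth", "stalk", "pattee7_seed", "pattee3_pod", "aerial_gynophore",
    "pattee5_pericarp", "vegetative_shoot", "androecium",
    "subterranean_gynophore", "pattee6_pericarp", "pattee1_pod",
    "pattee10_seed", "seedling_leaf")
}

#' Read a gene-by-tissue FPKM matrix from TSV
#'
#' Expects a tab-delimited file with a header row of tissue names, one row
#' per gene, and the gene identifier in column 1. Ragged rows, duplicate
#' gene ids, and negative or non-numeric cells are errors that name the
#' offending row or cell.
#'
#' @param path TSV file path.
#' @param subgenome_rule named character vector of regular expressions; a
#'   gene id matching \code{subgenome_rule[["A"]]} is assigned subgenome A,
#'   etc. Unmatched ids get \code{"unknown"}. Default maps the
#'   \emph{A. duranensis} / \emph{A. ipaensis} id prefixes.
#' @return a \link{TissueExpression}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\troot\tleaf", "Aradu.G1\t5\t0", "Araip.G2\t1\t2"), tf)
#' te <- readFpkmMatrix(tf)
#' subgenome(te)
#' @export
readFpkmMatrix <- function(path,
                           subgenome_rule = c(A = "^Aradu", B = "^Araip")) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    stop("ragged TSV: row(s) ", paste(which(nf != nf[1L]), collapse = ", "),
         " have a different number of fields")
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   check.names = FALSE, colClasses = "character")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tissues <- colnames(df)[-1L]
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, tissues))
  bad <- which(is.na(vals) | vals < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric or negative FPKM at gene '", ids[bad[1L, 1L]],
         "', tissue '", tissues[bad[1L, 2L]], "'")
  sg <- rep("unknown", length(ids))
  for (lab in names(subgenome_rule))
    sg[grepl(subgenome_rule[[lab]], ids)] <- lab
  TissueExpression(vals, subgenome = sg)
}

#' Log2-transformed expression levels
#'
#' FPKM values are log2-transformed to give normalised expression levels.
#' With \code{pseudocount = 0}, zero FPKM (not expressed) maps to \code{NA}
#' rather than \code{-Inf}; the transform is strictly monotone on positive
#' values.
#'
#' @param m a \link{TissueExpression}.
#' @param pseudocount non-negative value added before the log.
#' @return numeric matrix of log2 levels (genes x tissues).
#' @export
log2Levels <- function(m, pseudocount = 0) {
  stopifnot(is(m, "TissueExpression"), pseudocount >= 0)
  x <- fpkm(m) + pseudocount
  out <- suppressWarnings(log2(x))
  out[x == 0] <- NA_real_   # explicit not-expressed sentinel
  out
}

#' Classify genes as tissue-specific, common, or intermediate
#'
#' A gene expressed (FPKM at or above \code{expressed_threshold}) in exactly
#' one tissue and below the threshold in all others is tissue-specific to
#' that tissue; a gene expressed in every tissue is common; everything else
#' is intermediate. Tissue-specific genes are grouped as sex-specific when
#' their tissue is one of \code{sex_tissues}, otherwise somatic-specific.
#'
#' @param m a \link{TissueExpression}.
#' @param expressed_threshold positive FPKM threshold for "expressed"
#'   (default 1, matching the upstream minimum-coverage filter of the
#'   reference FPKM panel).
#' @param sex_tissues names of the sexual tissues; must be a subset of the
#'   matrix's tissues.
#' @return \code{DataFrame} with one row per gene: \code{gene_id},
#'   \code{status} (\code{tissue_specific}/\code{common}/
#'   \code{intermediate}), \code{specific_tissue} (\code{NA} unless
#'   tissue-specific), \code{group} (\code{sex_specific}/
#'   \code{somatic_specific}/\code{not_applicable}), \code{subgenome}, and
#'   \code{expression_level} (mean log2 FPKM over the expressing tissues,
#'   \code{NA} when nowhere expressed).
#' @examples
#' m <- matrix(c(5, 2, 0, 3), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("gynoecium", "root")))
#' classifyGenes(TissueExpression(m))
#' @export
classifyGenes <- function(m, expressed_threshold = 1,
                          sex_tissues = c("gynoecium", "androecium")) {
  stopifnot(is(m, "TissueExpression"))
  if (nrow(m) == 0L) stop("empty expression matrix")
  if (expressed_threshold <= 0) stop("expressed_threshold must be > 0")
  unknown <- setdiff(sex_tissues, tissueNames(m))
  if (length(unknown))
    stop("unknown sex tissue(s): ", paste(unknown, collapse = ", "))
  x <- fpkm(m)
  expressed <- x >= expressed_threshold
  n_expr <- rowSums(expressed)
  status <- ifelse(n_expr == 1L, "tissue_specific",
                   ifelse(n_expr == ncol(x), "common", "intermediate"))
  specific_tissue <- rep(NA_character_, nrow(x))
  idx <- which(n_expr == 1L)
  specific_tissue[idx] <- colnames(x)[max.col(expressed[idx, , drop = FALSE],
                                              ties.method = "first")]
  group <- ifelse(status != "tissue_specific", "not_applicable",
                  ifelse(specific_tissue %in% sex_tissues,
                         "sex_specific", "somatic_specific"))
  lv <- x
  lv[!expressed] <- NA
  expression_level <- rowMeans(log2(lv), na.rm = TRUE)
  expression_level[n_expr == 0L] <- NA_real_
  DataFrame(gene_id = rownames(x), status = unname(status),
            specific_tissue = specific_tissue, group = unname(group),
            subgenome = unname(subgenome(m)),
            expression_level = unname(expression_level))
}

#' Count and percentage summaries of a gene classification
#'
#' Percentages are 100 * count / \code{total_genes}, reported to two
#' decimals. \code{total_genes} may exceed the number of classified genes
#' (e.g. when the denominator is the full annotated gene complement while
#' only expressed genes were classified).
#'
#' @param cls classification table from \link{classifyGenes} (any
#'   data-frame-like object with columns \code{status}, \code{group},
#'   \code{subgenome}, \code{specific_tissue}).
#' @param total_genes positive denominator; defaults to \code{nrow(cls)}.
#' @return list of \code{DataFrame}s: \code{status} (counts/percent per
#'   status), \code{group} (per sex/somatic group), \code{subgenome}
#'   (subgenome x status), \code{subgenome_group} (subgenome x group), and
#'   \code{tissue} (tissue-specific counts per tissue, descending).
#' @export
summarizeClassification <- function(cls, total_genes = nrow(cls)) {
  if (is.null(total_genes) || total_genes <= 0)
    stop("total_genes must be a positive integer")
  if (total_genes < nrow(cls))
    stop("total_genes is smaller than the number of classified genes")
  pct <- function(k) round(100 * k / total_genes, 2)
  count_tab <- function(f, levels) {
    tab <- table(factor(f, levels = levels))
    DataFrame(level = names(tab), count = as.integer(tab),
              percent = pct(as.integer(tab)))
  }
  status <- count_tab(cls$status,
                      c("tissue_specific", "common", "intermediate"))
  ts <- cls[cls$status == "tissue_specific", , drop = FALSE]
  group <- count_tab(ts$group, c("sex_specific", "somatic_specific"))
  sg <- as.data.frame(table(subgenome = cls$subgenome, status = cls$status))
  subg <- DataFrame(subgenome = as.character(sg$subgenome),
                    status = as.character(sg$status),
                    count = as.integer(sg$Freq),
                    percent = pct(as.integer(sg$Freq)))
  gg <- as.data.frame(table(subgenome = ts$subgenome, group = ts$group))
  subg_group <- DataFrame(subgenome = as.character(gg$subgenome),
                          group = as.character(gg$group),
                          count = as.integer(gg$Freq),
                          percent = pct(as.integer(gg$Freq)))
  tt <- table(ts$specific_tissue)
  ord <- order(-as.integer(tt), names(tt))
  tissue <- DataFrame(tissue = names(tt)[ord],
                      count = as.integer(tt)[ord],
                      percent = pct(as.integer(tt)[ord]))
  list(status = status, group = group, subgenome = subg,
       subgenome_group = subg_group, tissue = tissue,
       total_genes = total_genes)
}
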