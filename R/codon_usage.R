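#' Validity of a CDS for codon-usage analysis
#'
#' Checks, in order: length divisible by 3; starts with ATG; ends with
#' TAA, TAG or TGA; no ambiguous base; no premature (internal) stop codon.
#' The first failing check is reported.
#'
#' @param cds character string or \code{DNAString}.
#' @return list with \code{valid} (logical) and \code{reason} (one of
#'   \code{ok}, \code{length}, \code{start}, \code{stop},
#'   \code{ambiguous}, \code{internal_stop}).
#' @examples
#' validateForCodonAnalysis("TTGAAATAA")$reason  # "start"
#' @export
validateForCodonAnalysis <- function(cds) {
  s <- toupper(as.character(cds))
  fail <- function(reason) list(valid = FALSE, reason = reason)
  if (nchar(s) == 0L || nchar(s) %% 3L != 0L) return(fail("length"))
  if (substr(s, 1L, 3L) != "ATG") return(fail("start"))
  codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  last <- codons[length(codons)]
  if (!last %in% c("TAA", "TAG", "TGA")) return(fail("stop"))
  if (grepl("[^ACGT]", s)) return(fail("ambiguous"))
  gc <- .geneticCode()
  internal <- codons[-length(codons)]
  if (any(gc[internal] == "*")) return(fail("internal_stop"))
  list(valid = TRUE, reason = "ok")
}

# codon families per amino acid, excluding stops and the single-codon
# amino acids Met and Trp
.degenerateFamilies <- function() {
  gc <- .geneticCode()
  fam <- split(names(gc), gc)
  fam[["*"]] <- NULL
  fam[vapply(fam, length, integer(1)) > 1L]
}

#' Derive an optimal-codon set from highly expressed genes
#'
#' For each degenerate amino acid (all except Met and Trp), the optimal
#' codon is the one with the highest relative frequency among the
#' \code{top_fraction} most highly expressed valid CDSs. Ties are broken
#' lexicographically, so the result is deterministic. Amino acids absent
#' from the top corpus are left out of the set.
#'
#' @param cdss named character vector or \code{DNAStringSet} of CDSs.
#' @param expression named numeric vector of per-gene expression levels
#'   (names matching \code{cdss}); genes without a value are ignored.
#' @param top_fraction fraction of the expression-ranked genes used
#'   (default 0.05, i.e. the top 5 percent; at least one gene is used).
#' @return named character vector, amino acid -> optimal codon, with
#'   attribute \code{provenance = "derived"}.
#' @export
deriveOptimalCodons <- function(cdss, expression, top_fraction = 0.05) {
  if (is.null(expression) || !length(expression))
    stop("no expression data; supply an optimal-codon table instead ",
         "(see readOptimalCodons)")
  stopifnot(top_fraction > 0, top_fraction <= 0.5)
  seqs <- .asSeqChar(cdss)
  valid <- vapply(seqs, function(s) validateForCodonAnalysis(s)$valid,
                  logical(1))
  seqs <- seqs[valid]
  if (length(seqs) < 10L) stop("need at least 10 valid CDSs")
  expr <- expression[names(seqs)]
  seqs <- seqs[!is.na(expr)]
  expr <- expr[!is.na(expr)]
  if (!length(seqs)) stop("no expression values match the sequence names")
  n_top <- max(1L, floor(length(seqs) * top_fraction))
  top <- names(sort(expr, decreasing = TRUE))[seq_len(n_top)]
  codons <- unlist(lapply(seqs[top], function(s) {
    cd <- .codonSplit(s)
    cd[-c(1L, length(cd))]   # drop start and stop codons from the corpus
  }), use.names = FALSE)
  counts <- table(codons)
  fams <- .degenerateFamilies()
  out <- character()
  for (aa in names(fams)) {
    cnt <- setNames(as.integer(counts[fams[[aa]]]), fams[[aa]])
    cnt[is.na(cnt)] <- 0L
    if (sum(cnt) == 0L) next
    cnt <- cnt[order(names(cnt))]      # lexicographic tie-break
    out[[aa]] <- names(cnt)[which.max(cnt)]
  }
  structure(out, provenance = "derived")
}

#' Read an optimal-codon table from a two-column TSV
#'
#' File format: two tab-separated columns, amino acid (one-letter code)
#' and codon, no header. Each codon must encode its amino acid;
#' single-codon amino acids (Met, Trp) are not allowed in the set.
#'
#' @param path TSV file.
#' @return named character vector, amino acid -> codon, with attribute
#'   \code{provenance} set to the file name.
#' @export
readOptimalCodons <- function(path) {
  df <- read.delim(path, header = FALSE, sep = "\t",
                   col.names = c("aa", "codon"),
                   colClasses = "character", quote = "")
  gc <- .geneticCode()
  codon <- toupper(df$codon)
  bad <- which(gc[codon] != df$aa | is.na(gc[codon]))
  if (length(bad))
    stop("codon does not encode its amino acid at line ", bad[1L])
  if (any(!df$aa %in% names(.degenerateFamilies())))
    stop("single-codon amino acids (M, W) cannot have an optimal codon")
  if (anyDuplicated(df$aa)) stop("duplicate amino acid in table")
  structure(setNames(codon, df$aa), provenance = basename(path))
}

#' Frequency of optimal codons (Fop)
#'
#' Fop is the number of codons that are their amino acid's designated
#' optimal codon divided by the number of codons whose amino acid is in
#' the optimal set. The stop codon is excluded; Met and Trp codons never
#' count (single-codon families). A value near 1 indicates extreme codon
#' usage bias. When no codon is countable the value is undefined
#' (\code{NA}).
#'
#' @param cds a valid CDS (per \link{validateForCodonAnalysis}).
#' @param opt optimal-codon set from \link{deriveOptimalCodons} or
#'   \link{readOptimalCodons}.
#' @return numeric in [0, 1], or \code{NA}.
#' @export
computeFop <- function(cds, opt) {
  v <- validateForCodonAnalysis(cds)
  if (!v$valid) stop("invalid CDS (", v$reason, ")")
  codons <- .codonSplit(cds)
  codons <- codons[-length(codons)]   # drop stop
  gc <- .geneticCode()
  aa <- gc[codons]
  countable <- aa %in% names(opt)
  if (!any(countable)) return(NA_real_)
  sum(codons[countable] == opt[aa[countable]]) / sum(countable)
}

#' Amino-acid length of a valid CDS
#'
#' Codon count minus the stop codon.
#'
#' @param cds a valid CDS.
#' @return integer.
#' @examples
#' aaLength("ATGAAATAA")  # 2
#' @export
aaLength <- function(cds) {
  v <- validateForCodonAnalysis(cds)
  if (!v$valid) stop("invalid CDS (", v$reason, ")")
  as.integer(nchar(as.character(cds)) / 3L) - 1L
}

#' Codon-usage records for a set of CDSs
#'
#' Applies the validity filters and computes Fop and amino-acid length for
#' each valid sequence.
#'
#' @param cdss named character vector or \code{DNAStringSet}.
#' @param opt optimal-codon set.
#' @return \code{DataFrame}: \code{gene_id}, \code{valid}, \code{reason},
#'   \code{fop}, \code{aa_length}.
#' @export
codonUsageTable <- function(cdss, opt) {
  seqs <- .asSeqChar(cdss)
  if (is.null(names(seqs))) stop("sequences must be named")
  rows <- lapply(names(seqs), function(id) {
    v <- validateForCodonAnalysis(seqs[[id]])
    if (v$valid)
      DataFrame(gene_id = id, valid = TRUE, reason = "ok",
                fop = computeFop(seqs[[id]], opt),
                aa_length = aaLength(seqs[[id]]))
    else
      DataFrame(gene_id = id, valid = FALSE, reason = v$reason,
                fop = NA_real_, aa_length = NA_integer_)
  })
  do.call(rbind, rows)
}
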