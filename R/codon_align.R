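# as.character() drops names on plain character vectors; keep them
.asSeqChar <- function(x) {
  s <- as.character(x)
  if (is.null(names(s))) names(s) <- names(x)
  s
}

.codonSplit <- function(cds) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

.geneticCode <- function() Biostrings::GENETIC_CODE

.blosum62 <- function() {
  if (is.null(.tp_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .tp_cache$BLOSUM62 <- e$BLOSUM62
  }
  .tp_cache$BLOSUM62
}

#' Translate a coding sequence
#'
#' One residue per codon under the standard genetic code; the terminal stop
#' codon is dropped. Ambiguous bases and internal stop codons are errors
#' (the CDS is expected to pass \link{isFullLength}).
#'
#' @param cds character string or \code{DNAString}.
#' @return character string of amino acids.
#' @examples
#' translateCds("ATGAAATAA")  # "MK"
#' @export
translateCds <- function(cds) {
  codons <- .codonSplit(cds)
  if (any(grepl("[^ACGT]", codons)))
    stop("ambiguous base in CDS")
  gc <- .geneticCode()
  aa <- gc[codons]
  if (anyNA(aa)) stop("untranslatable codon in CDS")
  n <- length(aa)
  if (aa[n] == "*") aa <- aa[-n]
  if (any(aa == "*"))
    stop("internal stop codon at codon ", which(aa == "*")[1L])
  paste(aa, collapse = "")
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch-style optimal global alignment under BLOSUM62 with
#' affine gap penalties and a fixed deterministic traceback (ties resolved
#' diagonal > up > left). A gap of length L costs
#' \code{gap_open + L * gap_extend}.
#'
#' @param a,b non-empty amino-acid strings.
#' @param gap_open,gap_extend positive gap penalties (defaults 10 and 1).
#' @return list with \code{aligned_a}, \code{aligned_b} (strings with
#'   \code{"-"} gaps) and \code{score}.
#' @examples
#' alignProteins("MKV", "MV")
#' @export
alignProteins <- function(a, b, gap_open = 10, gap_extend = 1) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  sm <- .blosum62()
  av <- match(strsplit(a, "")[[1L]], rownames(sm))
  bv <- match(strsplit(b, "")[[1L]], rownames(sm))
  if (anyNA(av) || anyNA(bv))
    stop("residue not covered by the scoring matrix")
  res <- nw_align_idx(av, bv, sm, gap_open, gap_extend)
  achr <- strsplit(a, "")[[1L]]
  bchr <- strsplit(b, "")[[1L]]
  list(
    aligned_a = paste(ifelse(res$a_idx == 0L, "-", achr[pmax(res$a_idx, 1L)]),
                      collapse = ""),
    aligned_b = paste(ifelse(res$b_idx == 0L, "-", bchr[pmax(res$b_idx, 1L)]),
                      collapse = ""),
    score = res$score
  )
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Replaces each aligned residue by its source codon and each gap by the
#' gap triplet \code{"---"}. The ungapped protein rows must equal the
#' translations of the source CDSs exactly; ungapping either codon row
#' reproduces the original CDS minus its stop codon.
#'
#' @param aligned_a,aligned_b gapped protein strings of equal length.
#' @param cds_a,cds_b source CDSs (with stop codons).
#' @param gene_a,gene_b identifiers carried into the result.
#' @return a \link{CodonAlignment}.
#' @export
backTranslate <- function(aligned_a, aligned_b, cds_a, cds_b,
                          gene_a = "a", gene_b = "b") {
  if (nchar(aligned_a) != nchar(aligned_b))
    stop("aligned rows differ in length")
  fill <- function(aligned, cds) {
    res <- strsplit(aligned, "")[[1L]]
    prot <- translateCds(cds)
    ungapped <- paste(res[res != "-"], collapse = "")
    if (ungapped != prot) {
      pos <- which(strsplit(ungapped, "")[[1L]] !=
                     strsplit(prot, "")[[1L]])[1L]
      stop("aligned protein does not match translation of CDS at residue ",
           if (is.na(pos)) nchar(prot) + 1L else pos)
    }
    codons <- .codonSplit(cds)[seq_len(nchar(prot))]  # drop stop codon
    out <- rep("---", length(res))
    out[res != "-"] <- codons
    out
  }
  CodonAlignment(gene_a, gene_b,
                 fill(aligned_a, cds_a), fill(aligned_b, cds_b))
}

#' Codon-level alignment of a duplicate gene pair
#'
#' Translates both CDSs, aligns the proteins globally
#' (\link{alignProteins}), and back-translates to codons
#' (\link{backTranslate}).
#'
#' @param cds_a,cds_b full-length CDSs.
#' @param gene_a,gene_b identifiers.
#' @inheritParams alignProteins
#' @return a \link{CodonAlignment}.
#' @export
codonAlignPair <- function(cds_a, cds_b, gene_a = "a", gene_b = "b",
                           gap_open = 10, gap_extend = 1) {
  aln <- alignProteins(translateCds(cds_a), translateCds(cds_b),
                       gap_open = gap_open, gap_extend = gap_extend)
  backTranslate(aln$aligned_a, aln$aligned_b, cds_a, cds_b,
                gene_a = gene_a, gene_b = gene_b)
}

#' Write a codon alignment as aligned FASTA
#'
#' @param x a \link{CodonAlignment}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCodonAlignment <- function(x, path) {
  stopifnot(is(x, "CodonAlignment"))
  lines <- c(paste0(">", x@geneA), paste(x@codonsA, collapse = ""),
             paste0(">", x@geneB), paste(x@codonsB, collapse = ""))
  writeLines(lines, path)
  invisible(path)
}
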