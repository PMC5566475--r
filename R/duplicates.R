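#' Full-length coding-frame predicate
#'
#' TRUE iff the sequence length is divisible by 3, it starts with ATG, ends
#' with a stop codon (TAA/TAG/TGA), contains no internal stop codon and no
#' ambiguous base. Queries failing this are partial sequences and are kept
#' out of duplicate detection.
#'
#' @param cds character string or \code{DNAString} of nucleotides.
#' @return logical.
#' @examples
#' isFullLength("ATGAAATAA")   # TRUE
#' isFullLength("ATGAAA")      # FALSE: no stop
#' @export
isFullLength <- function(cds) {
  validateForCodonAnalysis(cds)$valid
}

# unique unordered candidate pairs sharing at least one k-mer
.kmerCandidatePairs <- function(seq_chars, k) {
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(seq_chars)) {
    s <- seq_chars[[i]]
    n <- nchar(s)
    if (n < k) next
    kmers <- unique(substring(s, 1:(n - k + 1L), k:n))
    for (w in kmers) idx[[w]] <- c(idx[[w]], i)
  }
  pairs <- new.env(parent = emptyenv(), hash = TRUE)
  for (w in ls(idx, sorted = FALSE)) {
    ids <- idx[[w]]
    if (length(ids) < 2L) next
    for (a in seq_len(length(ids) - 1L))
      for (b in (a + 1L):length(ids))
        pairs[[paste0(ids[a], "_", ids[b])]] <- TRUE
  }
  keys <- ls(pairs, sorted = TRUE)
  if (!length(keys))
    return(matrix(integer(), ncol = 2L))
  out <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  mode(out) <- "integer"
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

# Karlin-Altschul lambda for an ungapped match/mismatch score system under
# uniform base composition; memoised per (match, mismatch)
.kaLambda <- function(match, mismatch) {
  key <- paste0("lambda_", match, "_", mismatch)
  if (!is.null(.tp_cache[[key]])) return(.tp_cache[[key]])
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  lam <- uniroot(f, c(1e-6, 10), tol = 1e-10)$root
  .tp_cache[[key]] <- lam
  lam
}

#' All-vs-all duplicate candidate search
#'
#' Seed-and-extend search over a set of coding sequences: unordered pairs
#' sharing at least one exact word of \code{word_size} nucleotides are
#' locally aligned (Smith-Waterman via
#' \code{Biostrings::pairwiseAlignment}), and each aligned pair is reported
#' with percent identity (matches / aligned columns), coverage (aligned
#' columns as percent of the longer sequence) and a Karlin-Altschul style
#' E-value computed from the alignment score with the database size equal
#' to the total number of residues searched. Self-hits are excluded; each
#' unordered pair is reported at most once, with members in lexicographic
#' order, so the output is invariant under reordering the input.
#'
#' @param cdss named \code{DNAStringSet} (or named character vector) of at
#'   least two full-length CDSs.
#' @param word_size exact-match seed length (default 11).
#' @param match,mismatch,gap_open,gap_extend alignment scores; defaults
#'   +1/-2 with affine gap penalties 5/2 (megablast-like, suited to
#'   high-identity nucleotide duplicates).
#' @param ka_K Karlin-Altschul K constant used in the E-value (fixed
#'   conservative default 0.3; lambda is solved from the score system).
#' @return \code{DataFrame}: \code{gene_a}, \code{gene_b}, \code{identity},
#'   \code{coverage}, \code{score}, \code{evalue}, \code{aligned_length}.
#' @seealso \link{applyPairCriteria}
#' @export
allVsAll <- function(cdss, word_size = 11, match = 1, mismatch = -2,
                     gap_open = 5, gap_extend = 2, ka_K = 0.3) {
  if (is.character(cdss)) cdss <- DNAStringSet(cdss)
  if (length(cdss) < 2L) stop("need at least 2 sequences")
  if (is.null(names(cdss)) || anyDuplicated(names(cdss)))
    stop("sequences must carry unique names")
  chars <- as.character(cdss)
  cand <- .kmerCandidatePairs(chars, k = word_size)
  empty <- DataFrame(gene_a = character(), gene_b = character(),
                     identity = numeric(), coverage = numeric(),
                     score = numeric(), evalue = numeric(),
                     aligned_length = integer())
  if (nrow(cand) == 0L) return(empty)
  submat <- nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                         baseOnly = TRUE)
  lam <- .kaLambda(match, mismatch)
  db_size <- sum(nchar(chars))
  rows <- vector("list", nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    # lexicographic member order keeps output orientation-independent
    if (names(cdss)[i] > names(cdss)[j]) { tmp <- i; i <- j; j <- tmp }
    aln <- pairwiseAlignment(cdss[[i]], cdss[[j]], type = "local",
                             substitutionMatrix = submat,
                             gapOpening = gap_open,
                             gapExtension = gap_extend)
    cols <- nchar(as.character(pattern(aln)))
    if (cols == 0L) next
    sc <- BiocGenerics::score(aln)
    rows[[r]] <- data.frame(
      gene_a = names(cdss)[i], gene_b = names(cdss)[j],
      identity = 100 * nmatch(aln) / cols,
      coverage = 100 * cols / max(nchar(chars[i]), nchar(chars[j])),
      score = sc,
      evalue = ka_K * max(nchar(chars[i]), nchar(chars[j])) * db_size *
        exp(-lam * sc),
      aligned_length = cols, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  as(do.call(rbind, rows), "DataFrame")
}

#' Retain duplicate pairs passing the similarity criteria
#'
#' Criteria (strict for identity and coverage, inclusive for the E-value):
#' identity > \code{min_identity}, coverage > \code{min_coverage} of the
#' longer sequence, E-value <= \code{max_evalue}. When several hits exist
#' for one unordered pair, the best-scoring hit is kept (ties broken by
#' longer aligned length, then lexicographic gene ids).
#'
#' @param hits output of \link{allVsAll}.
#' @param min_identity,min_coverage percent thresholds (default 80).
#' @param max_evalue significance ceiling (default 1e-10).
#' @param use_evalue set \code{FALSE} to rely on identity + coverage alone
#'   (E-value dialects differ across aligners).
#' @return \code{DataFrame} of retained pairs, one row per unordered pair.
#' @export
applyPairCriteria <- function(hits, min_identity = 80, min_coverage = 80,
                              max_evalue = 1e-10, use_evalue = TRUE) {
  stopifnot(min_identity > 0, min_coverage > 0, max_evalue > 0)
  keep <- hits$identity > min_identity & hits$coverage > min_coverage
  if (use_evalue) keep <- keep & hits$evalue <= max_evalue
  out <- hits[keep, , drop = FALSE]
  if (nrow(out) > 1L) {
    key <- paste(out$gene_a, out$gene_b, sep = "\r")
    ord <- order(key, -out$score, -out$aligned_length, out$gene_a,
                 out$gene_b)
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(key[ord]), , drop = FALSE]
  }
  out
}

#' Label duplicate pairs by expression class and composition
#'
#' Both members must be tissue-specific. A pair whose members are specific
#' to the same tissue is homogeneous; members specific to different tissues
#' make a heterogeneous pair (developmental stages of one organ are
#' distinct tissues). Composition comes from the members' groups:
#' somatic/somatic, sex/sex, or somatic/sex. Pairs with a member lacking
#' tissue-specific status are dropped with a message.
#'
#' @param pairs \code{DataFrame} of pairs (from \link{applyPairCriteria}).
#' @param cls classification from \link{classifyGenes}.
#' @return \code{pairs} with \code{expression_class} and \code{composition}
#'   columns, restricted to pairs whose members are both tissue-specific.
#' @export
labelPairs <- function(pairs, cls) {
  ia <- match(pairs$gene_a, cls$gene_id)
  ib <- match(pairs$gene_b, cls$gene_id)
  ok <- !is.na(ia) & !is.na(ib) &
    cls$status[ia] == "tissue_specific" &
    cls$status[ib] == "tissue_specific"
  if (any(!ok))
    message(sum(!ok), " pair(s) dropped: member not tissue-specific")
  pairs <- pairs[ok, , drop = FALSE]
  ia <- ia[ok]; ib <- ib[ok]
  ta <- cls$specific_tissue[ia]; tb <- cls$specific_tissue[ib]
  ga <- cls$group[ia]; gb <- cls$group[ib]
  pairs$expression_class <- ifelse(ta == tb, "homogeneous", "heterogeneous")
  pairs$composition <- ifelse(
    ga == "somatic_specific" & gb == "somatic_specific", "somatic_somatic",
    ifelse(ga == "sex_specific" & gb == "sex_specific", "sex_sex",
           "somatic_sex"))
  pairs
}
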