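.BASES <- c("A", "C", "G", "T")

.senseCodons <- function() {
  gc <- .geneticCode()
  names(gc)[gc != "*"]
}

# all permutations of a small vector (k <= 3 here)
.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Nei-Gojobori (1986) site counting: at each of the three codon positions,
#' the synonymous-site contribution is the fraction of the three possible
#' single-nucleotide changes that leave the amino acid unchanged; changes
#' creating a stop codon count as nonsynonymous. For every sense codon
#' \code{s + n = 3}.
#'
#' @param codon a sense codon (triplet over ACGT).
#' @return named numeric vector \code{c(s, n)}.
#' @examples
#' codonSites("AAA")  # s = 1/3
#' @export
codonSites <- function(codon) {
  tab <- .ng86SiteTable()
  codon <- toupper(codon)
  if (!codon %in% rownames(tab))
    stop("not a sense codon: ", codon)
  c(s = tab[codon, "s"], n = tab[codon, "n"])
}

.ng86SiteTable <- function() {
  if (!is.null(.tp_cache$sites)) return(.tp_cache$sites)
  gc <- .geneticCode()
  sense <- .senseCodons()
  tab <- matrix(0, nrow = length(sense), ncol = 2L,
                dimnames = list(sense, c("s", "n")))
  for (cd in sense) {
    ch <- strsplit(cd, "")[[1L]]
    syn <- 0
    for (pos in 1:3) {
      for (b in setdiff(.BASES, ch[pos])) {
        mut <- ch
        mut[pos] <- b
        mcd <- paste(mut, collapse = "")
        if (gc[[mcd]] != "*" && gc[[mcd]] == gc[[cd]]) syn <- syn + 1
      }
    }
    tab[cd, "s"] <- syn / 3
    tab[cd, "n"] <- 3 - syn / 3
  }
  .tp_cache$sites <- tab
  tab
}

#' Synonymous and nonsynonymous differences between two codons
#'
#' Nei-Gojobori pathway averaging: with k differing positions, the
#' synonymous/nonsynonymous step counts are averaged over all k! mutational
#' pathways between the codons. Pathways passing through a stop codon are
#' excluded; if every pathway does, the average is taken over all pathways
#' (a step is synonymous iff the translations of its two endpoint codons
#' are equal). Always \code{sd + nd = k}.
#'
#' @param a,b sense codons.
#' @return named numeric vector \code{c(sd, nd)}.
#' @examples
#' codonDifferences("AAA", "AAG")  # sd = 1
#' @export
codonDifferences <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  sense <- .senseCodons()
  if (!a %in% sense) stop("not a sense codon: ", a)
  if (!b %in% sense) stop("not a sense codon: ", b)
  m <- .ng86DiffTables()
  c(sd = m$sd[a, b], nd = m$nd[a, b])
}

.pathwaySteps <- function(a, b, gc) {
  ach <- strsplit(a, "")[[1L]]
  bch <- strsplit(b, "")[[1L]]
  diffpos <- which(ach != bch)
  k <- length(diffpos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  paths <- .perms(diffpos)
  tally <- function(path, allow_stop) {
    cur <- ach
    sd <- 0; nd <- 0
    for (pos in path) {
      nxt <- cur
      nxt[pos] <- bch[pos]
      ccur <- paste(cur, collapse = ""); cnxt <- paste(nxt, collapse = "")
      if (!allow_stop && gc[[cnxt]] == "*" && cnxt != b) return(NULL)
      if (gc[[ccur]] == gc[[cnxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- lapply(paths, tally, allow_stop = FALSE)
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))  # every pathway stop-blocked: average over all of them
    res <- lapply(paths, tally, allow_stop = TRUE)
  cnt <- Reduce(`+`, res) / length(res)
  c(sd = unname(cnt["sd"]), nd = unname(cnt["nd"]))
}

.ng86DiffTables <- function() {
  if (!is.null(.tp_cache$diffs)) return(.tp_cache$diffs)
  gc <- .geneticCode()
  sense <- .senseCodons()
  nS <- length(sense)
  sd <- matrix(0, nS, nS, dimnames = list(sense, sense))
  nd <- sd
  for (i in seq_len(nS)) {
    for (j in seq_len(nS)) {
      if (i == j) next
      if (i < j) {
        st <- .pathwaySteps(sense[i], sense[j], gc)
        sd[i, j] <- st["sd"]; nd[i, j] <- st["nd"]
      } else {            # pathway averaging is symmetric
        sd[i, j] <- sd[j, i]; nd[i, j] <- nd[j, i]
      }
    }
  }
  .tp_cache$diffs <- list(sd = sd, nd = nd)
  .tp_cache$diffs
}

#' Ka/Ks estimation from a codon alignment (NG86 + Jukes-Cantor)
#'
#' Over the gapless codon columns: synonymous (S) and nonsynonymous (N)
#' site totals are averaged between the two sequences; synonymous (Sd) and
#' nonsynonymous (Nd) differences are summed with pathway averaging
#' (\link{codonDifferences}); the proportions pS = Sd/S and pN = Nd/N are
#' corrected for multiple hits with the Jukes-Cantor formula
#' d = -(3/4) ln(1 - (4/3) p). A proportion of 0.75 or more is saturated
#' (no finite correction). Ks = 0 leaves omega undefined. The estimate is
#' symmetric in the two sequences.
#'
#' @param x a \link{CodonAlignment} with at least one gapless column.
#' @return one-row \code{DataFrame}: \code{gene_a}, \code{gene_b},
#'   \code{codons} (gapless columns), \code{S}, \code{N}, \code{Sd},
#'   \code{Nd}, \code{pS}, \code{pN}, \code{Ka}, \code{Ks}, \code{omega},
#'   \code{status} in \code{ok}/\code{saturated}/\code{omega_undefined}.
#' @examples
#' ca <- codonAlignPair(
#'   paste0("ATG", strrep("AAA", 9), "TAA"),
#'   paste0("ATG", strrep("AAA", 8), "AAG", "TAA"))
#' estimateKaKs(ca)
#' @export
estimateKaKs <- function(x) {
  stopifnot(is(x, "CodonAlignment"))
  idx <- gaplessColumns(x)
  if (!length(idx)) stop("no gapless codon columns")
  ca <- x@codonsA[idx]
  cb <- x@codonsB[idx]
  stab <- .ng86SiteTable()
  dtabs <- .ng86DiffTables()
  bad <- c(setdiff(ca, rownames(stab)), setdiff(cb, rownames(stab)))
  if (length(bad))
    stop("non-sense codon in gapless columns: ", bad[1L])
  Sa <- sum(stab[ca, "s"]); Sb <- sum(stab[cb, "s"])
  S <- (Sa + Sb) / 2
  N <- 3 * length(idx) - S
  pairs_idx <- cbind(ca, cb)
  Sd <- sum(dtabs$sd[pairs_idx])
  Nd <- sum(dtabs$nd[pairs_idx])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  Ks <- jc(pS); Ka <- jc(pN)
  if (pS >= 0.75 || pN >= 0.75) {
    status <- "saturated"; omega <- NA_real_
  } else if (Ks == 0) {
    status <- "omega_undefined"; omega <- NA_real_
  } else {
    status <- "ok"; omega <- Ka / Ks
  }
  DataFrame(gene_a = x@geneA, gene_b = x@geneB, codons = length(idx),
            S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
            Ka = Ka, Ks = Ks, omega = omega, status = status)
}

#' Ks admissibility filter
#'
#' Pairs with Ks below \code{low} (unreliably low divergence) or above
#' \code{high} (approaching saturation) are excluded; the boundaries
#' themselves are retained (exclusion is strictly outside
#' \code{[low, high]}). Undefined Ks is excluded.
#'
#' @param est estimate table (rows from \link{estimateKaKs}).
#' @param low,high Ks bounds (defaults 0.01 and 0.30).
#' @return \code{est} with logical \code{retained} and character
#'   \code{filter_reason} (\code{ok}, \code{ks_too_low},
#'   \code{ks_too_high}, \code{ks_undefined}) columns added.
#' @export
ksFilter <- function(est, low = 0.01, high = 0.30) {
  stopifnot(low <= high)
  ks <- est$Ks
  reason <- rep("ok", length(ks))
  reason[!is.na(ks) & ks < low] <- "ks_too_low"
  reason[!is.na(ks) & ks > high] <- "ks_too_high"
  reason[is.na(ks)] <- "ks_undefined"
  est$retained <- reason == "ok"
  est$filter_reason <- reason
  est
}

#' Selection regime from omega
#'
#' omega < 1: purifying; omega = 1 (within \code{tol}): neutral;
#' omega > 1: positive.
#'
#' @param omega non-negative Ka/Ks value(s); \code{NA} is an error.
#' @param tol equality tolerance for the neutral boundary.
#' @return character vector over
#'   \code{purifying}/\code{neutral}/\code{positive}.
#' @export
classifySelection <- function(omega, tol = 1e-9) {
  if (anyNA(omega)) stop("omega is undefined")
  if (any(omega < 0)) stop("omega must be >= 0")
  ifelse(abs(omega - 1) <= tol, "neutral",
         ifelse(omega < 1, "purifying", "positive"))
}

#' Group means of Ka, Ks and omega over retained pairs
#'
#' Arithmetic means per expression class (homogeneous/heterogeneous) and
#' per composition (somatic/somatic, sex/sex, somatic/sex), restricted to
#' pairs retained by \link{ksFilter}. Empty groups are omitted with a
#' message.
#'
#' @param est estimate table carrying \code{retained},
#'   \code{expression_class} and \code{composition} columns.
#' @return list of \code{DataFrame}s \code{overall},
#'   \code{expression_class}, \code{composition}.
#' @export
groupMeans <- function(est) {
  keep <- est[est$retained, , drop = FALSE]
  if (nrow(keep) == 0L) stop("no retained estimates")
  mk <- function(df) DataFrame(
    n = nrow(df),
    mean_ka = mean(df$Ka), mean_ks = mean(df$Ks),
    mean_omega = mean(df$omega, na.rm = TRUE))
  by_group <- function(col) {
    lv <- unique(keep[[col]])
    out <- do.call(rbind, lapply(lv, function(g)
      mk(keep[keep[[col]] == g, , drop = FALSE])))
    out[[col]] <- lv
    out[, c(col, "n", "mean_ka", "mean_ks", "mean_omega")]
  }
  res <- list(overall = mk(keep))
  for (col in c("expression_class", "composition")) {
    if (col %in% colnames(keep)) {
      res[[col]] <- by_group(col)
      missing <- setdiff(
        switch(col,
               expression_class = c("homogeneous", "heterogeneous"),
               composition = c("somatic_somatic", "sex_sex", "somatic_sex")),
        keep[[col]])
      if (length(missing))
        message("empty ", col, " group(s) omitted: ",
                paste(missing, collapse = ", "))
    }
  }
  res
}
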