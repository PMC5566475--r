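#' Mann-Whitney U test (two-sided, mid-ranks)
#'
#' The U statistic of the first sample is computed from joint mid-ranks.
#' In exact mode the two-sided p-value is obtained by full enumeration of
#' all rank splits (doubled smaller tail, capped at 1), which handles ties
#' through the observed mid-rank multiset; in approximate mode a normal
#' approximation with tie correction and (optionally) continuity
#' correction is used. \code{mode = "auto"} uses enumeration when both
#' samples have at most 8 observations.
#'
#' @param x,y non-empty numeric samples.
#' @param mode \code{"auto"}, \code{"exact"} or \code{"approximate"}.
#' @param continuity apply the continuity correction in the normal
#'   approximation (default TRUE).
#' @param alpha significance level for the \code{significant} flag.
#' @return list of class \code{"tp_comparison"}: \code{test},
#'   \code{statistic} (U of \code{x}), \code{p_value}, \code{n},
#'   \code{mode_used}, \code{significant}.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1 by enumeration
#' @export
mannWhitneyU <- function(x, y, mode = c("auto", "exact", "approximate"),
                         continuity = TRUE, alpha = 0.05) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("empty sample")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  use_exact <- mode == "exact" || (mode == "auto" && n1 <= 8 && n2 <= 8)
  if (use_exact) {
    splits <- combn(N, n1)
    Us <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(Us <= U + eps), mean(Us >= U - eps)))
    mode_used <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      cc <- if (continuity) 0.5 * sign(U - mu) else 0
      z <- (U - mu - cc) / sqrt(sig2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    mode_used <- "approximate"
  }
  structure(list(test = "mann_whitney_u", statistic = U, p_value = p,
                 n = c(n1, n2), mode_used = mode_used,
                 significant = p < alpha),
            class = "tp_comparison")
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom (computed by \code{stats::kruskal.test}).
#'
#' @param groups list of two or more non-empty numeric samples.
#' @param alpha significance level.
#' @return list of class \code{"tp_comparison"}: \code{test},
#'   \code{statistic} (H, reported as a chi-square), \code{df},
#'   \code{p_value}, \code{n}, \code{significant}.
#' @export
kruskalWallis <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (any(!vapply(groups, length, integer(1))))
    stop("empty group")
  kt <- kruskal.test(groups)
  H <- unname(kt$statistic)
  p <- kt$p.value
  if (!is.finite(H) && length(unique(unlist(groups))) == 1L) {
    H <- 0; p <- 1   # every observation tied: no evidence of any shift
  }
  structure(list(test = "kruskal_wallis",
                 statistic = H,
                 df = unname(kt$parameter),
                 p_value = p,
                 n = vapply(groups, length, integer(1)),
                 significant = p < alpha),
            class = "tp_comparison")
}

#' @export
print.tp_comparison <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic), ", p = ",
      format(x$p_value), if (isTRUE(x$significant)) " *" else "", "\n",
      sep = "")
  invisible(x)
}

.mw_row <- function(comparison, x, y, labels, alpha) {
  if (!length(x) || !length(y))
    return(DataFrame(comparison = comparison, test = "mann_whitney_u",
                     statistic = NA_real_, p_value = NA_real_,
                     direction = NA_character_, significant = NA))
  res <- mannWhitneyU(x, y, alpha = alpha)
  dir <- if (median(x) > median(y)) " > " else
    if (median(x) < median(y)) " < " else " = "
  DataFrame(comparison = comparison, test = "mann_whitney_u",
            statistic = res$statistic, p_value = res$p_value,
            direction = paste0(labels[1L], dir, labels[2L]),
            significant = res$significant)
}

.kw_row <- function(comparison, groups, alpha) {
  groups <- groups[vapply(groups, length, integer(1)) > 0L]
  if (length(groups) < 2L)
    return(DataFrame(comparison = comparison, test = "kruskal_wallis",
                     statistic = NA_real_, p_value = NA_real_,
                     direction = NA_character_, significant = NA))
  res <- kruskalWallis(groups, alpha = alpha)
  DataFrame(comparison = comparison, test = "kruskal_wallis",
            statistic = res$statistic, p_value = res$p_value,
            direction = paste0(length(groups), " groups"),
            significant = res$significant)
}

#' The study's eleven group comparisons
#'
#' Runs the rank-based comparisons of expression level, substitution
#' rates, Fop and amino-acid length across the gene and pair groups:
#' tissue-specific vs common expression; expression of tissue-specific
#' genes across tissues; sex vs somatic expression; gynoecium vs
#' androecium expression; Ka, Ks and omega for homogeneous vs
#' heterogeneous pairs; Fop across tissues and sex vs somatic; amino-acid
#' length across tissues and sex vs somatic. Raw (unadjusted) two-sided
#' p-values are reported.
#'
#' @param cls classification from \link{classifyGenes}.
#' @param usage codon-usage table from \link{codonUsageTable}.
#' @param estimates estimate table with \code{retained},
#'   \code{expression_class}, \code{Ka}, \code{Ks}, \code{omega} columns
#'   (\link{estimateKaKs} + \link{ksFilter} + \link{labelPairs} labels).
#' @param alpha significance level (default 0.05).
#' @return \code{DataFrame} with one row per comparison: \code{comparison},
#'   \code{test}, \code{statistic}, \code{p_value}, \code{direction},
#'   \code{significant}. Comparisons with an empty side carry \code{NA}s.
#' @export
compareReport <- function(cls, usage, estimates, alpha = 0.05) {
  for (nm in c("cls", "usage", "estimates"))
    if (is.null(get(nm))) stop("missing upstream table: ", nm)
  ts <- cls[cls$status == "tissue_specific", , drop = FALSE]
  common <- cls[cls$status == "common", , drop = FALSE]
  sex <- ts[ts$group == "sex_specific", , drop = FALSE]
  som <- ts[ts$group == "somatic_specific", , drop = FALSE]
  gyn <- ts[!is.na(ts$specific_tissue) &
              ts$specific_tissue == "gynoecium", , drop = FALSE]
  andr <- ts[!is.na(ts$specific_tissue) &
               ts$specific_tissue == "androecium", , drop = FALSE]
  by_tissue <- function(values, tissues)
    split(values, tissues)
  u <- usage[usage$valid, , drop = FALSE]
  uts <- u[u$gene_id %in% ts$gene_id, , drop = FALSE]
  ugrp <- ts$group[match(uts$gene_id, ts$gene_id)]
  utis <- ts$specific_tissue[match(uts$gene_id, ts$gene_id)]
  est <- estimates[estimates$retained, , drop = FALSE]
  hom <- est[est$expression_class == "homogeneous", , drop = FALSE]
  het <- est[est$expression_class == "heterogeneous", , drop = FALSE]
  lv <- function(df) df$expression_level[!is.na(df$expression_level)]
  rows <- list(
    .mw_row("expression_specific_vs_common", lv(ts), lv(common),
            c("tissue_specific", "common"), alpha),
    .kw_row("expression_across_tissues",
            by_tissue(lv(ts), ts$specific_tissue[!is.na(ts$expression_level)]),
            alpha),
    .mw_row("expression_sex_vs_somatic", lv(sex), lv(som),
            c("sex_specific", "somatic_specific"), alpha),
    .mw_row("expression_gynoecium_vs_androecium", lv(gyn), lv(andr),
            c("gynoecium", "androecium"), alpha),
    .mw_row("ka_homogeneous_vs_heterogeneous", hom$Ka, het$Ka,
            c("homogeneous", "heterogeneous"), alpha),
    .mw_row("ks_homogeneous_vs_heterogeneous", hom$Ks, het$Ks,
            c("homogeneous", "heterogeneous"), alpha),
    .mw_row("omega_homogeneous_vs_heterogeneous",
            hom$omega[!is.na(hom$omega)], het$omega[!is.na(het$omega)],
            c("homogeneous", "heterogeneous"), alpha),
    .kw_row("fop_across_tissues", split(uts$fop, utis), alpha),
    .mw_row("fop_sex_vs_somatic",
            uts$fop[ugrp == "sex_specific"],
            uts$fop[ugrp == "somatic_specific"],
            c("sex_specific", "somatic_specific"), alpha),
    .kw_row("aa_length_across_tissues", split(uts$aa_length, utis), alpha),
    .mw_row("aa_length_sex_vs_somatic",
            uts$aa_length[ugrp == "sex_specific"],
            uts$aa_length[ugrp == "somatic_specific"],
            c("sex_specific", "somatic_specific"), alpha)
  )
  do.call(rbind, rows)
}
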