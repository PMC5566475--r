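#' Pipeline configuration
#'
#' Collects the input paths and every stage threshold, with the study's
#' defaults: expressed threshold 1 FPKM; duplicate criteria identity > 80,
#' coverage > 80, E-value <= 1e-10; Ks admissibility [0.01, 0.30];
#' optimal-codon derivation from the top 5 percent; alpha 0.05.
#'
#' @param fasta CDS FASTA path.
#' @param fpkm FPKM TSV path.
#' @param out_dir output directory for stage TSVs and the summary.
#' @param expressed_threshold,sex_tissues,subgenome_rule classification
#'   settings (see \link{classifyGenes}, \link{readFpkmMatrix}).
#' @param min_identity,min_coverage,max_evalue,use_evalue,word_size
#'   duplicate-detection settings (see \link{allVsAll},
#'   \link{applyPairCriteria}).
#' @param ks_low,ks_high Ks filter bounds (see \link{ksFilter}).
#' @param top_fraction optimal-codon derivation quantile (see
#'   \link{deriveOptimalCodons}).
#' @param optimal_table optional path to a two-column optimal-codon TSV;
#'   overrides derivation.
#' @param alpha significance level.
#' @param write_alignments optional directory for per-pair codon-alignment
#'   FASTA files.
#' @return config list of class \code{"tp_pipeline_config"}.
#' @export
pipelineConfig <- function(fasta, fpkm, out_dir,
                           expressed_threshold = 1,
                           sex_tissues = c("gynoecium", "androecium"),
                           subgenome_rule = c(A = "^Aradu", B = "^Araip"),
                           min_identity = 80, min_coverage = 80,
                           max_evalue = 1e-10, use_evalue = TRUE,
                           word_size = 11,
                           ks_low = 0.01, ks_high = 0.30,
                           top_fraction = 0.05, optimal_table = NULL,
                           alpha = 0.05, write_alignments = NULL) {
  structure(list(fasta = fasta, fpkm = fpkm, out_dir = out_dir,
                 expressed_threshold = expressed_threshold,
                 sex_tissues = sex_tissues,
                 subgenome_rule = subgenome_rule,
                 min_identity = min_identity, min_coverage = min_coverage,
                 max_evalue = max_evalue, use_evalue = use_evalue,
                 word_size = word_size, ks_low = ks_low, ks_high = ks_high,
                 top_fraction = top_fraction,
                 optimal_table = optimal_table, alpha = alpha,
                 write_alignments = write_alignments),
            class = "tp_pipeline_config")
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

.writeTsv <- function(df, path) {
  write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' classify -> duplicate detection -> codon alignment -> Ka/Ks ->
#' codon usage -> group comparisons, from one configuration. Every stage
#' writes its table to the output directory, so each stage is
#' independently re-runnable; stage timings and record counts go to the
#' message stream. A stage failure aborts with the stage name; tables
#' already written are retained.
#'
#' @param config a \link{pipelineConfig}.
#' @return list: \code{classification}, \code{summary}, \code{hits},
#'   \code{pairs}, \code{estimates}, \code{group_means}, \code{usage},
#'   \code{comparisons}, \code{optimal_codons}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "tp_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  te <- .stage("load_fpkm", readFpkmMatrix(config$fpkm,
                                           config$subgenome_rule))
  cls <- .stage("classify", classifyGenes(
    te, expressed_threshold = config$expressed_threshold,
    sex_tissues = intersect(config$sex_tissues, tissueNames(te))))
  summ <- summarizeClassification(cls)
  .writeTsv(cls, file.path(config$out_dir, "classification.tsv"))
  .writeTsv(summ$status, file.path(config$out_dir, "summary_status.tsv"))
  .writeTsv(summ$tissue, file.path(config$out_dir, "summary_tissue.tsv"))
  message("classified ", nrow(cls), " genes")

  cdss <- .stage("read_fasta", readDNAStringSet(config$fasta))
  full <- vapply(as.character(cdss), isFullLength, logical(1))
  message(sum(full), "/", length(cdss), " full-length CDSs")
  hits <- .stage("all_vs_all", allVsAll(cdss[full],
                                        word_size = config$word_size))
  pairs <- .stage("criteria", applyPairCriteria(
    hits, min_identity = config$min_identity,
    min_coverage = config$min_coverage,
    max_evalue = config$max_evalue, use_evalue = config$use_evalue))
  pairs <- .stage("label_pairs", labelPairs(pairs, cls))
  .writeTsv(pairs, file.path(config$out_dir, "pairs.tsv"))
  message(nrow(pairs), " duplicate pairs retained")

  est <- .stage("kaks", {
    if (nrow(pairs) == 0L) NULL else {
      sc <- as.character(cdss)
      rows <- lapply(seq_len(nrow(pairs)), function(i) {
        ca <- codonAlignPair(sc[[pairs$gene_a[i]]], sc[[pairs$gene_b[i]]],
                             gene_a = pairs$gene_a[i],
                             gene_b = pairs$gene_b[i])
        if (!is.null(config$write_alignments)) {
          dir.create(config$write_alignments, showWarnings = FALSE,
                     recursive = TRUE)
          writeCodonAlignment(ca, file.path(
            config$write_alignments,
            paste0(pairs$gene_a[i], "__", pairs$gene_b[i], ".fasta")))
        }
        estimateKaKs(ca)
      })
      e <- do.call(rbind, rows)
      e$expression_class <- pairs$expression_class
      e$composition <- pairs$composition
      e <- ksFilter(e, low = config$ks_low, high = config$ks_high)
      e$selection_class <- NA_character_
      ok <- e$retained & !is.na(e$omega)
      e$selection_class[ok] <- classifySelection(e$omega[ok])
      e
    }
  })
  gm <- NULL
  if (!is.null(est)) {
    .writeTsv(est, file.path(config$out_dir, "estimates.tsv"))
    if (any(est$retained)) gm <- groupMeans(est)
  }

  usage <- .stage("codon_usage", {
    opt <- if (!is.null(config$optimal_table))
      readOptimalCodons(config$optimal_table)
    else {
      lev <- setNames(cls$expression_level, cls$gene_id)
      deriveOptimalCodons(cdss, lev, top_fraction = config$top_fraction)
    }
    list(table = codonUsageTable(cdss, opt), optimal = opt)
  })
  .writeTsv(usage$table, file.path(config$out_dir, "usage.tsv"))

  cmp <- .stage("stats", compareReport(
    cls, usage$table,
    if (is.null(est)) DataFrame(retained = logical(0),
                                expression_class = character(0),
                                Ka = numeric(0), Ks = numeric(0),
                                omega = numeric(0)) else est,
    alpha = config$alpha))
  .writeTsv(cmp, file.path(config$out_dir, "comparisons.tsv"))

  .stage("summary", .writeSummaryText(config, summ, pairs, est, gm, cmp))

  invisible(list(classification = cls, summary = summ, hits = hits,
                 pairs = pairs, estimates = est, group_means = gm,
                 usage = usage$table, comparisons = cmp,
                 optimal_codons = usage$optimal))
}

.writeSummaryText <- function(config, summ, pairs, est, gm, cmp) {
  path <- file.path(config$out_dir, "summary.txt")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("Analysis summary")
  w("================")
  w("Ka/Ks estimator: NG86 pathway counting with Jukes-Cantor correction")
  w("thresholds: expressed FPKM >= ", config$expressed_threshold,
    "; identity > ", config$min_identity, "%; coverage > ",
    config$min_coverage, "%; E <= ", format(config$max_evalue),
    "; Ks in [", config$ks_low, ", ", config$ks_high, "]; alpha = ",
    config$alpha)
  w("")
  w("Gene classification (denominator ", summ$total_genes, "):")
  st <- as.data.frame(summ$status)
  for (i in seq_len(nrow(st)))
    w("  ", st$level[i], ": ", st$count[i], " (", st$percent[i], "%)")
  gr <- as.data.frame(summ$group)
  for (i in seq_len(nrow(gr)))
    w("  ", gr$level[i], ": ", gr$count[i], " (", gr$percent[i], "%)")
  w("")
  w("Duplicate pairs retained by similarity criteria: ", nrow(pairs))
  if (!is.null(est)) {
    w("Pairs with admissible Ks: ", sum(est$retained))
    sel <- table(est$selection_class[est$retained])
    for (s in names(sel)) w("  ", s, ": ", sel[[s]])
    if (!is.null(gm)) {
      ov <- as.data.frame(gm$overall)
      w(sprintf("mean Ka = %.4f, mean Ks = %.4f, mean Ka/Ks = %.4f",
                ov$mean_ka, ov$mean_ks, ov$mean_omega))
    }
  }
  w("")
  w("Comparisons (raw two-sided p-values):")
  cd <- as.data.frame(cmp)
  for (i in seq_len(nrow(cd)))
    w(sprintf("  %-38s %-15s p=%s %s", cd$comparison[i], cd$test[i],
              format(cd$p_value[i], digits = 4),
              ifelse(isTRUE(cd$significant[i]), "*", "")))
  path
}
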