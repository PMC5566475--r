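#' Configuration for the synthetic-data generator
#'
#' Defines a complete synthetic study: a gene-by-tissue FPKM matrix with
#' planted tissue-specific / common / intermediate structure over 22
#' tissues, and a CDS set with duplicate pairs evolved at controlled
#' synonymous divergence (target Ks) and dN/dS (omega) plus unrelated
#' background sequences. Planted expressed cells sit at twice the
#' expressed threshold or above, so classification margins are
#' constructive and recovery is exact. All randomness flows from one
#' stream seeded with \code{seed}.
#'
#' @param n_genes number of genes in the matrix (default 1000).
#' @param tissues tissue names (default the 22-tissue peanut panel).
#' @param frac_specific,frac_common fractions of genes planted as
#'   tissue-specific / common (defaults 0.15 and 0.49; the remainder is
#'   intermediate). The tissue-specific fraction must accommodate the
#'   duplicate-pair members, which are all tissue-specific.
#' @param sex_tissues the sexual tissues (default gynoecium, androecium).
#' @param expressed_threshold FPKM threshold the classifier will use
#'   (default 1); planted expressed values are at least twice this.
#' @param log2_mean,log2_sd log-normal expression model: expressed cells
#'   draw log2 FPKM from N(\code{log2_mean}, \code{log2_sd}) (defaults 3
#'   and 1).
#' @param sex_shift additive log2 shift for sex-specific genes (default 1).
#' @param gynoecium_shift additional log2 shift for gynoecium-specific
#'   genes (default 0.5), making gynoecium > androecium in expectation.
#' @param n_duplicate_pairs planted duplicate pairs (default 50).
#' @param pair_counts named integer vector partitioning the pairs into
#'   composition/expression classes: \code{hom_somatic} (same somatic
#'   tissue), \code{het_somatic} (two somatic tissues), \code{hom_sex}
#'   (same sexual tissue), \code{het_sex} (gynoecium vs androecium),
#'   \code{somatic_sex}. Must sum to \code{n_duplicate_pairs}.
#' @param codon_length codons per generated CDS, excluding the stop
#'   (default 300).
#' @param target_ks,omega per-pair evolution targets (recycled across
#'   pairs; defaults 0.2 and 0.5).
#' @param n_background unrelated background CDSs with no planted homology
#'   (default 100); they occupy common-gene slots in the matrix.
#' @param seed integer RNG seed (default 1).
#' @return validated config list of class \code{"tp_synth_config"}.
#' @export
syntheticConfig <- function(n_genes = 1000, tissues = peanutTissues(),
                            frac_specific = 0.15, frac_common = 0.49,
                            sex_tissues = c("gynoecium", "androecium"),
                            expressed_threshold = 1,
                            log2_mean = 3, log2_sd = 1,
                            sex_shift = 1, gynoecium_shift = 0.5,
                            n_duplicate_pairs = 50,
                            pair_counts = c(hom_somatic = 20,
                                            het_somatic = 15,
                                            hom_sex = 5, het_sex = 2,
                                            somatic_sex = 8),
                            codon_length = 300, target_ks = 0.2,
                            omega = 0.5, n_background = 100, seed = 1) {
  cfg <- list(n_genes = n_genes, tissues = tissues,
              frac_specific = frac_specific, frac_common = frac_common,
              sex_tissues = sex_tissues,
              expressed_threshold = expressed_threshold,
              log2_mean = log2_mean, log2_sd = log2_sd,
              sex_shift = sex_shift, gynoecium_shift = gynoecium_shift,
              n_duplicate_pairs = n_duplicate_pairs,
              pair_counts = pair_counts, codon_length = codon_length,
              target_ks = target_ks, omega = omega,
              n_background = n_background, seed = seed)
  if (any(c(frac_specific, frac_common) < 0) ||
      frac_specific + frac_common > 1)
    stop("fractions must be in [0,1] and sum to at most 1")
  if (!all(sex_tissues %in% tissues)) stop("sex tissues not in tissue set")
  n_spec <- round(frac_specific * n_genes)
  n_common <- round(frac_common * n_genes)
  if (n_spec < 2 * n_duplicate_pairs)
    stop("infeasible fractions: ", n_spec, " tissue-specific slots for ",
         2 * n_duplicate_pairs, " duplicate-pair members")
  if (n_background > n_common)
    stop("infeasible fractions: background sequences exceed common slots")
  if (n_duplicate_pairs > 0 &&
      sum(pair_counts) != n_duplicate_pairs)
    stop("pair_counts must sum to n_duplicate_pairs")
  if (codon_length < 10) stop("codon_length must be at least 10 codons")
  structure(cfg, class = "tp_synth_config")
}

# deterministic gene plan: ids, roles, planted statuses/tissues.
# Consumes RNG; callers seed first.
.planGenes <- function(cfg) {
  n_spec <- round(cfg$frac_specific * cfg$n_genes)
  n_common <- round(cfg$frac_common * cfg$n_genes)
  n_inter <- cfg$n_genes - n_spec - n_common
  somatic <- setdiff(cfg$tissues, cfg$sex_tissues)
  pc <- cfg$pair_counts
  np <- cfg$n_duplicate_pairs
  pair_id <- integer(0); member <- integer(0)
  tissue <- character(0)
  if (np > 0) {
    classes <- rep(names(pc), pc)
    for (p in seq_len(np)) {
      tt <- switch(classes[p],
        hom_somatic = rep(sample(somatic, 1L), 2L),
        het_somatic = sample(somatic, 2L),
        hom_sex = rep(sample(cfg$sex_tissues, 1L), 2L),
        het_sex = sample(cfg$sex_tissues, 2L),
        somatic_sex = c(sample(somatic, 1L), sample(cfg$sex_tissues, 1L)))
      pair_id <- c(pair_id, p, p); member <- c(member, 1L, 2L)
      tissue <- c(tissue, tt)
    }
  }
  n_extra_spec <- n_spec - 2L * np
  ids <- c(
    if (np > 0) paste0(ifelse(member == 1L, "Aradu.P", "Araip.P"),
                       sprintf("%04d", pair_id),
                       ifelse(member == 1L, "a", "b")),
    sprintf("%s.S%04d",
            sample(c("Aradu", "Araip"), n_extra_spec, replace = TRUE),
            seq_len(n_extra_spec)),
    sprintf("%s.B%04d",
            sample(c("Aradu", "Araip"), cfg$n_background, replace = TRUE),
            seq_len(cfg$n_background)),
    sprintf("%s.C%04d",
            sample(c("Aradu", "Araip"), n_common - cfg$n_background,
                   replace = TRUE),
            seq_len(n_common - cfg$n_background)),
    sprintf("%s.I%04d",
            sample(c("Aradu", "Araip"), n_inter, replace = TRUE),
            seq_len(n_inter))
  )
  status <- c(rep("tissue_specific", n_spec), rep("common", n_common),
              rep("intermediate", n_inter))
  tissue <- c(tissue, sample(cfg$tissues, n_extra_spec, replace = TRUE),
              rep(NA_character_, n_common + n_inter))
  role <- c(rep("pair_member", 2L * np), rep("filler", n_extra_spec),
            rep("background", cfg$n_background),
            rep("filler", n_common - cfg$n_background + n_inter))
  data.frame(gene_id = ids, status = status, tissue = tissue, role = role,
             pair = c(pair_id, rep(NA_integer_, cfg$n_genes - 2L * np)),
             stringsAsFactors = FALSE)
}

.fillExpression <- function(cfg, plan) {
  nt <- length(cfg$tissues)
  x <- matrix(0, nrow = nrow(plan), ncol = nt,
              dimnames = list(plan$gene_id, cfg$tissues))
  floorv <- 2 * cfg$expressed_threshold
  draw <- function(k, shift = 0)
    pmax(floorv, 2^(rnorm(k, cfg$log2_mean + shift, cfg$log2_sd)))
  for (i in seq_len(nrow(plan))) {
    st <- plan$status[i]
    if (st == "tissue_specific") {
      tis <- plan$tissue[i]
      shift <- 0
      if (tis %in% cfg$sex_tissues) shift <- cfg$sex_shift
      if (tis == "gynoecium") shift <- shift + cfg$gynoecium_shift
      x[i, tis] <- draw(1L, shift)
    } else if (st == "common") {
      x[i, ] <- draw(nt)
    } else {
      k <- sample(2:(nt - 1L), 1L)
      cols <- sample(nt, k)
      x[i, cols] <- draw(k)
    }
  }
  x
}

#' Generate a synthetic expression matrix with planted classification
#'
#' Planted tissue-specific genes carry FPKM at twice the expressed
#' threshold (or above) in exactly one tissue and 0 elsewhere; common
#' genes are at or above that floor in every tissue; intermediates are
#' expressed in 2..21 tissues. Sex-specific genes receive the configured
#' log2 shifts. \link{classifyGenes} run at the config threshold recovers
#' the planted structure with zero errors.
#'
#' @param config a \link{syntheticConfig}.
#' @return list: \code{matrix} (a \link{TissueExpression}) and
#'   \code{truth} (\code{DataFrame}: \code{gene_id}, \code{status},
#'   \code{tissue}, \code{group}).
#' @export
genExpression <- function(config) {
  stopifnot(inherits(config, "tp_synth_config"))
  set.seed(config$seed)
  plan <- .planGenes(config)
  x <- .fillExpression(config, plan)
  sg <- ifelse(grepl("^Aradu", plan$gene_id), "A",
               ifelse(grepl("^Araip", plan$gene_id), "B", "unknown"))
  group <- ifelse(plan$status != "tissue_specific", "not_applicable",
                  ifelse(plan$tissue %in% config$sex_tissues,
                         "sex_specific", "somatic_specific"))
  list(matrix = TissueExpression(x, subgenome = sg),
       truth = DataFrame(gene_id = plan$gene_id, status = plan$status,
                         tissue = plan$tissue, group = group))
}

#' Generate a random full-length CDS
#'
#' Starts with ATG, ends with a uniformly chosen stop codon; internal
#' codons are drawn uniformly over the 61 sense codons, or from
#' \code{weights} when supplied (named over sense codons) to plant codon
#' usage bias.
#'
#' @param length_codons codon count excluding the stop (minimum 10).
#' @param seed optional seed; when \code{NULL} the current RNG stream is
#'   used.
#' @param weights optional named sampling weights over sense codons.
#' @return character string of \code{3 * (length_codons + 1)} nucleotides.
#' @export
genCds <- function(length_codons, seed = NULL, weights = NULL) {
  if (length_codons < 10) stop("length_codons must be at least 10")
  if (!is.null(seed)) set.seed(seed)
  sense <- .senseCodons()
  prob <- NULL
  if (!is.null(weights)) {
    prob <- rep(0, length(sense))
    names(prob) <- sense
    prob[names(weights)] <- weights
  }
  internal <- sample(sense, length_codons - 1L, replace = TRUE,
                     prob = prob)
  paste0("ATG", paste(internal, collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

#' Evolve a duplicate pair at controlled Ks and omega
#'
#' Rejection-sampling substitution process: single-nucleotide changes are
#' proposed at uniform random internal positions of a randomly chosen
#' lineage; proposals touching the start or stop codon, or creating a stop
#' codon, are rejected outright; synonymous proposals are accepted with
#' probability 1 and nonsynonymous ones with probability \code{omega}
#' (for \code{omega > 1} the roles flip: nonsynonymous accepted with
#' probability 1, synonymous with \code{1/omega}). Proposals continue
#' until the realized synonymous substitutions per ancestral synonymous
#' site reach \code{target_ks}. Ground-truth omega therefore equals the
#' acceptance ratio by construction.
#'
#' @param ancestor full-length CDS (from \link{genCds}).
#' @param target_ks target synonymous divergence, in (0, 0.5] (0 returns
#'   identical descendants).
#' @param omega dN/dS acceptance ratio, >= 0.
#' @param seed optional seed.
#' @param max_iter proposal budget (default scales with the target).
#' @return list: \code{a}, \code{b} (descendant CDSs), \code{syn},
#'   \code{nonsyn} (realized substitution counts across both lineages),
#'   \code{S_anc} (ancestral synonymous sites).
#' @export
evolvePair <- function(ancestor, target_ks, omega, seed = NULL,
                       max_iter = NULL) {
  if (target_ks < 0 || target_ks > 0.5)
    stop("target_ks must be in [0, 0.5]")
  if (omega < 0) stop("omega must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  gc <- .geneticCode()
  stab <- .ng86SiteTable()
  anc <- strsplit(toupper(ancestor), "")[[1L]]
  L <- length(anc) / 3L
  codons <- function(v) paste0(v[seq(1, 3 * L, 3)], v[seq(2, 3 * L, 3)],
                               v[seq(3, 3 * L, 3)])
  anc_codons <- codons(anc)[-L]          # start..last sense codon
  S_anc <- sum(stab[anc_codons, "s"])
  lineages <- list(a = anc, b = anc)
  syn_count <- 0L; nonsyn_count <- 0L
  needed <- round(target_ks * S_anc)
  if (needed == 0L)
    return(list(a = ancestor, b = ancestor, syn = 0L, nonsyn = 0L,
                S_anc = S_anc))
  if (is.null(max_iter)) max_iter <- 500L * needed + 10000L
  positions <- 4L:(3L * (L - 1L))       # internal sense codons only
  p_syn <- if (omega <= 1) 1 else 1 / omega
  p_non <- if (omega <= 1) omega else 1
  for (iter in seq_len(max_iter)) {
    who <- if (runif(1) < 0.5) "a" else "b"
    seqv <- lineages[[who]]
    pos <- sample(positions, 1L)
    old <- seqv[pos]
    new <- sample(setdiff(.BASES, old), 1L)
    cstart <- pos - (pos - 1L) %% 3L
    oldc <- paste0(seqv[cstart], seqv[cstart + 1L], seqv[cstart + 2L])
    tmp <- seqv[cstart:(cstart + 2L)]
    tmp[pos - cstart + 1L] <- new
    newc <- paste(tmp, collapse = "")
    if (gc[[newc]] == "*") next
    is_syn <- gc[[oldc]] == gc[[newc]]
    p_accept <- if (is_syn) p_syn else p_non
    if (p_accept < 1 && runif(1) >= p_accept) next
    seqv[pos] <- new
    lineages[[who]] <- seqv
    if (is_syn) syn_count <- syn_count + 1L else
      nonsyn_count <- nonsyn_count + 1L
    if (syn_count >= needed) break
  }
  if (syn_count < needed)
    stop("target_ks unreachable within the proposal budget")
  list(a = paste(lineages$a, collapse = ""),
       b = paste(lineages$b, collapse = ""),
       syn = syn_count, nonsyn = nonsyn_count, S_anc = S_anc)
}

#' Generate a complete synthetic dataset bundle
#'
#' Produces a CDS FASTA (duplicate-pair members plus unrelated background
#' sequences), a gene-by-tissue FPKM TSV, and a ground-truth JSON covering
#' every gene and pair. Duplicate-pair members are tissue-specific with
#' tissues assigned so that the configured homogeneous/heterogeneous and
#' somatic/sex/somatic-sex compositions occur in known numbers. Identical
#' configs produce identical bundles.
#'
#' @param config a \link{syntheticConfig}.
#' @param out_dir output directory (created if needed); when \code{NULL}
#'   nothing is written and only objects are returned.
#' @return list: \code{expression} (\link{TissueExpression}),
#'   \code{cdss} (named \code{DNAStringSet}), \code{truth_genes},
#'   \code{truth_pairs} (\code{DataFrame}s), and \code{paths} (when
#'   written: \code{fasta}, \code{fpkm}, \code{truth}).
#' @export
genDataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "tp_synth_config"))
  set.seed(config$seed)
  plan <- .planGenes(config)
  x <- .fillExpression(config, plan)
  sg <- ifelse(grepl("^Aradu", plan$gene_id), "A",
               ifelse(grepl("^Araip", plan$gene_id), "B", "unknown"))
  group <- ifelse(plan$status != "tissue_specific", "not_applicable",
                  ifelse(plan$tissue %in% config$sex_tissues,
                         "sex_specific", "somatic_specific"))
  truth_genes <- DataFrame(gene_id = plan$gene_id, status = plan$status,
                           tissue = plan$tissue, group = group,
                           subgenome = sg)

  np <- config$n_duplicate_pairs
  tks <- rep(config$target_ks, length.out = max(np, 1L))
  om <- rep(config$omega, length.out = max(np, 1L))
  seqs <- character(0)
  pair_rows <- vector("list", np)
  members <- plan[plan$role == "pair_member", , drop = FALSE]
  for (p in seq_len(np)) {
    mem <- members[members$pair == p, , drop = FALSE]
    anc <- genCds(config$codon_length)
    ev <- evolvePair(anc, tks[p], om[p])
    seqs[mem$gene_id[1L]] <- ev$a
    seqs[mem$gene_id[2L]] <- ev$b
    same <- mem$tissue[1L] == mem$tissue[2L]
    grp <- ifelse(mem$tissue %in% config$sex_tissues, "sex", "somatic")
    comp <- if (all(grp == "somatic")) "somatic_somatic"
            else if (all(grp == "sex")) "sex_sex" else "somatic_sex"
    pair_rows[[p]] <- DataFrame(
      gene_a = mem$gene_id[1L], gene_b = mem$gene_id[2L],
      omega = om[p], target_ks = tks[p],
      syn_subs = ev$syn, nonsyn_subs = ev$nonsyn, S_anc = ev$S_anc,
      expression_class = if (same) "homogeneous" else "heterogeneous",
      composition = comp)
  }
  truth_pairs <- if (np > 0) do.call(rbind, pair_rows) else
    DataFrame(gene_a = character(0), gene_b = character(0))
  bg <- plan$gene_id[plan$role == "background"]
  for (id in bg) seqs[id] <- genCds(config$codon_length)
  cdss <- DNAStringSet(seqs)

  te <- TissueExpression(x, subgenome = sg)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(fasta = file.path(out_dir, "cds.fasta"),
                  fpkm = file.path(out_dir, "fpkm.tsv"),
                  truth = file.path(out_dir, "truth.json"))
    writeXStringSet(cdss, paths$fasta)
    df <- data.frame(gene = rownames(x), x, check.names = FALSE)
    write.table(df, paths$fpkm, sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(
      list(genes = as.data.frame(truth_genes),
           pairs = as.data.frame(truth_pairs),
           config = config[c("n_genes", "frac_specific", "frac_common",
                             "n_duplicate_pairs", "codon_length",
                             "target_ks", "omega", "n_background",
                             "seed")]),
      paths$truth, auto_unbox = TRUE, digits = NA, na = "null")
  }
  list(expression = te, cdss = cdss, truth_genes = truth_genes,
       truth_pairs = truth_pairs, paths = paths)
}
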