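---
title: "Methods: tissue-specific genes and the molecular evolution of duplicate pairs"
author: "TissueParalogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-specific genes and duplicate-pair evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

TissueParalogs analyses an allotetraploid transcriptome — the motivating
system is cultivated peanut, whose A and B subgenomes descend from
*Arachis duranensis* and *Arachis ipaënsis* — in five connected steps:

1. classify genes from a gene × tissue FPKM matrix as **tissue-specific**
   (expressed in exactly one of the profiled tissues), **common**
   (expressed in all of them) or **intermediate**, and split the
   tissue-specific class into **sex-specific** (gynoecium or androecium)
   vs **somatic-specific** genes;
2. detect **duplicate gene pairs** by all-vs-all CDS similarity;
3. build **codon alignments** of each pair by global protein alignment
   and back-translation;
4. estimate **Ka, Ks and ω = Ka/Ks** per pair with Nei–Gojobori (1986)
   counting plus Jukes–Cantor correction, filter on Ks admissibility, and
   classify the selection regime;
5. compare groups (expression level, Fop, amino-acid length, Ka/Ks) with
   **Mann–Whitney U** and **Kruskal–Wallis** tests.

A synthetic-data generator plants known classification structure and
evolves duplicate pairs at controlled divergence, so every step can be
validated against ground truth.

# Expression classification

"Expressed" needs a numeric definition; we use FPKM ≥ 1 by default,
consistent with the upstream minimum-coverage filter commonly applied
when the FPKM panels are built (transcripts under 1 FPKM everywhere are
dropped). The threshold is a parameter of `classifyGenes()`. A gene is
tissue-specific iff it clears the threshold in exactly one tissue, common
iff it clears it in every tissue; the three statuses partition the gene
set by construction. Developmental stages of one organ (the Pattee seed
stages, the leaf stages, ...) are treated as distinct tissues, so a pair
specific to two stages of the same organ is heterogeneous downstream.

Log2 FPKM is the normalised expression level. We use pseudocount 0 by
default and map zero FPKM to an explicit `NA` sentinel instead of
letting `-Inf` propagate; a positive pseudocount is available for users
who prefer a dense matrix. Per-gene expression level is the mean log2
FPKM over the expressing tissues.

Percentages in `summarizeClassification()` are rounded to two decimals
against a caller-supplied denominator, because the natural denominator
(the full annotated gene complement of both progenitors, 78,574 in the
peanut setting) can exceed the number of classified genes.

# Duplicate detection

The published criteria for calling a duplicate pair are: aligned length
> 80% of the longer sequence, identity > 80%, and E-value ≤ 1e-10, with
full-length coding frames required of all queries. We re-implement the
search at desk scale as seed-and-extend: unordered pairs sharing an exact
11-mer are locally aligned (Smith–Waterman, match +1, mismatch −2, gap
open 5, extend 2 — megablast-like settings appropriate for high-identity
nucleotide duplicates), and the E-value is a Karlin–Altschul computation
`E = K·m·n·exp(−λS)` with λ solved exactly for the ungapped score system
under uniform base composition and K fixed at a conservative 0.3. Exact
E-values are dialect-dependent across aligners, so `use_evalue = FALSE`
lets identity + coverage carry the decision alone; at the >80/>80
thresholds the E-value criterion is essentially never the binding one.
Identity and coverage use strict inequalities (a pair at exactly 80 is
rejected); the best hit per unordered pair is kept, ties broken by longer
aligned length, then lexicographic ids, so output is deterministic and
invariant under input order.

# Codon alignment

Each pair is aligned at the protein level with Needleman–Wunsch under
BLOSUM62 and affine gaps (open 10, extend 1), then back-translated to
codons, gaps becoming `---` triplets. A dedicated pairwise global aligner
replaces a general multiple-alignment program here deliberately: with
two sequences the optimal pairwise alignment is the whole problem, the
fixed tie-break (diagonal > up > left) makes results reproducible, and
in the high-identity regime that survives the >80% criteria the choice
of aligner is immaterial. Gapped codon columns are excluded from rate
estimation (the standard convention when converting protein alignments
to codon alignments for Ka/Ks programs).

# Ka/Ks estimation

We author the estimator rather than shelling out to an external ML
package: NG86 counting is exactly testable against an independent
pathway enumerator, and below the admissibility ceiling (Ks ≤ 0.30)
counting and ML estimates agree closely. Per codon, the synonymous site
count is the fraction of the nine single-base neighbours that preserve
the amino acid (changes into stop codons count as nonsynonymous); per
differing codon pair, synonymous/nonsynonymous step counts are averaged
over all k! mutational pathways, excluding pathways that pass through a
stop codon — unless every pathway does, in which case all pathways are
averaged and a step is synonymous iff its endpoints translate
identically. These dialect choices (one of several NG86 variants) are
fixed and tested. Sites are averaged over the two sequences; proportions
pS = Sd/S and pN = Nd/N are corrected with Jukes–Cantor,
d = −(3/4)·ln(1 − (4/3)p), undefined (saturated) at p ≥ 0.75.

Degenerate outcomes are explicit statuses rather than infinities:
identical sequences give Ks = Ka = 0 with ω undefined (0/0), and Ka > 0
with Ks = 0 is reported as `omega_undefined` rather than ∞ (such pairs
fail the Ks filter regardless). The Ks admissibility window is the
closed interval [0.01, 0.30] — values below are unreliable at low
divergence, values above approach saturation; exclusion is strictly
outside the interval, mirroring the wording "less than 0.01 and greater
than 0.30". Selection classes split at ω = 1 with a 1e-9 equality
tolerance.

# Codon usage

Fop is the fraction of a gene's codons, among amino acids that have a
designated optimal codon, that are the optimal codon; Met, Trp and stop
codons never count. The provenance of the optimal-codon set is explicit:
either supplied as a two-column TSV, or derived from the data as the
most frequent codon per degenerate amino acid among the top 5% most
highly expressed valid CDSs (ties broken lexicographically, so the
derivation is deterministic). We ship no built-in "published" table: the
species-appropriate set cannot be pinned down reliably, and a derived or
user-supplied set keeps provenance auditable. Sequence validity for
codon analysis requires ATG start, TAA/TAG/TGA end, no premature stop
and no ambiguous codon.

# Statistics

All tests are two-sided on mid-ranks. The Mann–Whitney U statistic is
exact by full enumeration of rank splits when both samples are ≤ 8
(ties handled through the mid-rank multiset; two-sided p is the doubled
smaller tail, capped at 1), otherwise a normal approximation with tie
and continuity corrections. Kruskal–Wallis uses the tie-corrected H with
a chi-square reference (k − 1 df); when every observation is tied we
report H = 0, p = 1. No multiple-testing adjustment is applied across
the eleven reported comparisons — the comparison table carries raw
p-values, matching how such panels are conventionally reported. The
sidedness of the original significance statements is not recoverable;
two-sided tests are the conservative default.

`compareReport()` emits eleven contrasts (expression: specific vs
common, across tissues, sex vs somatic, gynoecium vs androecium; Ka, Ks
and ω: homogeneous vs heterogeneous pairs; Fop and amino-acid length:
across tissues and sex vs somatic) with the direction of the median
difference and a significance flag at α = 0.05.

# Synthetic data: what it emulates, and what it does not

The generator plants structure with constructive margins: expressed
cells sit at ≥ 2× the classification threshold and unexpressed cells at
exactly 0, so classification recovery is exact by design — recovery
tests validate the classifier's logic, not its robustness to borderline
expression. Log2 levels are Gaussian (mean 3, sd 1, i.e. median FPKM
≈ 8); sex-specific genes get a +1 log2 shift and gynoecium-specific
genes +0.5 more, reproducing the qualitative ordering gynoecium >
androecium > somatic reported for the real panel.

Duplicate pairs evolve from a random ancestor by rejection sampling:
uniform single-base proposals on internal codons, proposals creating
stops (or touching the start/stop codon) rejected, synonymous proposals
accepted with probability 1 and nonsynonymous with probability ω (roles
flipped for ω > 1). Ground-truth ω is therefore the acceptance ratio by
construction — a property a full codon rate matrix would not give so
directly — and proposals continue until realized synonymous
substitutions per ancestral synonymous site reach the target Ks. At the
default study conditions (300 codons, target Ks 0.2, ω 0.5) descendants
remain above ~87% identity, comfortably detectable at the >80% criteria.
At the extreme corner (Ks 0.3 with ω = 1) overall divergence reaches
~0.3 substitutions/site and identity drops toward ~75%, below the
detection criteria — a real property of the divergence ceiling, not a
generator defect.

Defaults are the scaled-down study conditions used throughout the tests:
1,000 genes × 22 tissues, 50 duplicate pairs (20 homogeneous-somatic,
15 heterogeneous-somatic, 5 homogeneous-sex, 2 heterogeneous-sex, 8
somatic–sex), 100 unrelated background CDSs of 300 codons. The
tissue-specific fraction is 0.15 rather than the ~4% observed at full
genome scale: at 1,000 genes the 100 pair members (all tissue-specific
by design) must fit inside the tissue-specific class with room for
singletons. The common fraction 0.49 matches the full-scale proportion.
The generator does not emulate: replicate libraries and FPKM estimation
noise, indels (so codon alignments of synthetic pairs are gapless),
mutation bias (transition/transversion or codon-frequency effects), or
genuine homoeologous synteny. Passing recovery tests therefore
demonstrates correctness of the implemented definitions, not performance
on noisy real data.

# Numerical and design notes

- Problem sizes in the test-suite and acceptance runs: ω recovery uses
  50 replicate pairs per regime at 300 codons; test calibration uses 500
  null replicates at n = m = 30; bundle recovery uses the default
  1,000-gene configuration. These sizes give stable means (Monte-Carlo
  s.e. of the ω means ≈ 0.01–0.03) while keeping runs quick.
- All randomness flows from a single seeded stream per bundle;
  identical configurations give byte-identical output files.
- The Jukes–Cantor correction is applied independently to pS and pN;
  tolerances: site-count conservation holds to 1e-9, ω = 1 equality to
  1e-9, the closed-form ten-codon example to 1e-10.
- Known limitations: NG86 without transition/transversion weighting
  slightly underestimates Ks under transition-biased evolution (not
  present in the synthetic process); E-values are approximate
  (ungapped λ, fixed K) and meant as a coarse significance screen behind
  the identity/coverage criteria; the exact Mann–Whitney enumerator is
  O(C(n+m, n)) and is auto-selected only for n, m ≤ 8.
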