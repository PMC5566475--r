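# shared fixture builders

write_fpkm_tsv <- function(mat, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a small, fast synthetic study used by several module tests
small_config <- function(seed = 7) {
  syntheticConfig(n_genes = 120, n_duplicate_pairs = 6,
                  pair_counts = c(hom_somatic = 2, het_somatic = 1,
                                  hom_sex = 1, het_sex = 1,
                                  somatic_sex = 1),
                  frac_specific = 0.15, frac_common = 0.4,
                  codon_length = 120, n_background = 10, seed = seed)
}
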