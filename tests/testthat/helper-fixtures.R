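# Shared fixture builders: everything is generated in code, no files.

make_annotation <- function(genes_df) {
  arms <- unique(genes_df$arm)
  lens <- vapply(arms, function(a)
    max(genes_df$end[genes_df$arm == a]) + 1000, numeric(1))
  names(lens) <- arms
  genome_annotation(genes_df, lens)
}

simple_genes <- function(mids, arm = "2L", width = 1) {
  half <- (width - 1) / 2
  data.frame(gene_id = sprintf("g%03d", seq_along(mids)),
             arm = arm,
             start = mids - half, end = mids + half,
             is_hrpg = FALSE)
}

# one-sided binomial Monte-Carlo SE
mc_se <- function(p, n) sqrt(p * (1 - p) / n)
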