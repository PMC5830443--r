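.datatable.aware <- TRUE

utils::globalVariables(c(
  "n_snp", "mean_fst", "pi_domestic", "pi_wild", "ln_ratio",
  "sum_a", "sum_abc", "theta", "a", "abc", "pid", "piw",
  "matched", "p_start", "p_end", "t_chrom", "score", "q", "chain"))
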