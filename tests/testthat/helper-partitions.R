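# contiguous relabeling used when building random partition ensembles
normalize_partition_for_test <- function(m) {
  as.integer(factor(m, levels = unique(m)))
}
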