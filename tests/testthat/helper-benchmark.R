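# MCC column (augmented arm) of the printed benchmark table, used as a
# frozen score function for replaying the backward-elimination procedure.
benchmark_mcc <- c(
  "RNAseq" = 0.01, "Met" = 0.13, "SNP" = 0.08, "miRNA" = 0.00, "sncRNA" = 0.00,
  "Met-RNAseq" = 0.79, "RNAseq-SNP" = 0.38, "RNAseq-miRNA" = 0.02,
  "RNAseq-sncRNA" = 0.08, "Met-SNP" = 0.43, "Met-miRNA" = 0.61,
  "Met-sncRNA" = 0.43, "SNP-miRNA" = 1.00, "SNP-sncRNA" = 0.90,
  "miRNA-sncRNA" = 0.06,
  "Met-RNAseq-SNP" = 0.56, "Met-RNAseq-miRNA" = 0.29, "Met-RNAseq-sncRNA" = 0.32,
  "RNAseq-SNP-miRNA" = 0.81, "RNAseq-SNP-sncRNA" = 0.90,
  "RNAseq-miRNA-sncRNA" = 0.01, "Met-SNP-miRNA" = 0.91, "Met-SNP-sncRNA" = 1.00,
  "Met-miRNA-sncRNA" = 0.52, "SNP-miRNA-sncRNA" = 0.90,
  "Met-RNAseq-SNP-miRNA" = 0.90, "Met-RNAseq-SNP-sncRNA" = 0.80,
  "Met-RNAseq-miRNA-sncRNA" = 0.31, "RNAseq-SNP-miRNA-sncRNA" = 0.70,
  "Met-SNP-miRNA-sncRNA" = 0.91,
  "Met-RNAseq-SNP-miRNA-sncRNA" = 0.73
)

lookup_score <- function(subset) {
  key <- paste(sort(subset, method = "radix"), collapse = "-")
  if (!key %in% names(benchmark_mcc)) stop("unknown subset ", key)
  unname(benchmark_mcc[key])
}

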