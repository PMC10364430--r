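#!/usr/bin/env Rscript
# Differential expression per dataset (two-tailed t-test p < 0.05 and
# absolute fold change > 1.5) and the sets of genes consistently
# differentially expressed across all six datasets, for mRNAs and lncRNAs
# separately.

suppressPackageStartupMessages(library(comodhom))

data_dir <- "results/data"
out <- "results/de"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
datasets <- sprintf("SYN%d", 1:6)

des <- list()
summary_rows <- list()
for (ds in datasets) {
  data <- read_expression_tsv(file.path(data_dir, paste0(ds, "_matrix.tsv")),
                              file.path(data_dir, paste0(ds, "_conditions.tsv")),
                              file.path(data_dir, paste0(ds, "_biotypes.tsv")), ds)
  de <- compute_de(data, alpha = 0.05, fc_threshold = 1.5)
  write_de_tsv(de, file.path(out, paste0("de_", ds, ".tsv")))
  des[[ds]] <- de
  for (bt in c("mRNA", "lncRNA")) {
    sub <- de[de$biotype == bt, ]
    class(sub) <- class(de)
    fr <- de_fraction(sub, nrow(sub))
    summary_rows[[paste(ds, bt)]] <- cbind(dataset = ds, biotype = bt, fr)
    message(sprintf("%s %-6s: %4d significant (%5.2f%%), %2.0f%% up",
                    ds, bt, fr$n_significant, fr$total_pct, fr$up_pct))
  }
}
tab2 <- do.call(rbind, c(summary_rows, list(make.row.names = FALSE)))
utils::write.table(tab2, file.path(out, "de_summary.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (bt in c("mRNA", "lncRNA")) {
  de_bt <- lapply(des, function(de) {
    sub <- de[de$biotype == bt, ]; class(sub) <- class(de); sub
  })
  sets <- consistent_de(de_bt)
  writeLines(sets$consistent_up,
             file.path(out, paste0("consistent_up_", bt, ".txt")))
  writeLines(sets$consistent_down,
             file.path(out, paste0("consistent_down_", bt, ".txt")))
  n_bt <- nrow(de_bt[[1]])
  message(sprintf(
    "%s: %d up + %d down consistent across all %d datasets (%.2f%% of %d)",
    bt, length(sets$consistent_up), length(sets$consistent_down),
    length(des), percent_of(length(sets$consistent_up) +
                            length(sets$consistent_down), n_bt), n_bt))
}
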