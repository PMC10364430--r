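#!/usr/bin/env Rscript
# Classify every detected module as up-regulated, down-regulated or mixed
# (strictly over 90% of members sharing a direction) and contrast module
# homogeneity between the sepsis-like case state and the control state:
# per-dataset summary tables, pooled homogeneous fractions, a rank test on
# the per-module homogeneity score, and the score-versus-size correlation.

suppressPackageStartupMessages(library(comodhom))

de_dir <- "results/de"
net_dir <- "results/networks"
out <- "results/homogeneity"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
datasets <- sprintf("SYN%d", 1:6)
threshold <- 0.9

read_partition <- function(path, min_size) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  labels <- stats::setNames(as.integer(tab$module), tab$symbol)
  sizes <- table(labels[labels != 0])
  structure(list(labels = labels,
                 sizes = stats::setNames(as.integer(sizes), names(sizes)),
                 n_modules = length(sizes), min_module_size = min_size,
                 cut_height_used = NA_real_),
            class = "module_partition")
}

summaries <- list()
rows <- list()
for (ds in datasets) {
  de <- utils::read.table(file.path(de_dir, paste0("de_", ds, ".tsv")),
                          header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  class(de) <- c("differential_result", "data.frame")
  for (state in c("case", "control")) {
    for (bt in c("mRNA", "lncRNA")) {
      path <- file.path(net_dir, sprintf("modules_%s.%s.%s.tsv", ds, state, bt))
      if (!file.exists(path)) next
      part <- read_partition(path, if (bt == "mRNA") 10L else 5L)
      s <- summarize_state(part, de, threshold, state = state, dataset_id = ds)
      summaries[[paste(ds, state, bt)]] <- s
      rows[[paste(ds, state, bt)]] <- data.frame(
        dataset = ds, state = state, biotype = bt, n_modules = s$n_modules,
        n_up = unname(s$counts["up"]), up_pct = unname(s$pct["up"]),
        n_mixed = unname(s$counts["mixed"]), mixed_pct = unname(s$pct["mixed"]),
        n_down = unname(s$counts["down"]), down_pct = unname(s$pct["down"]),
        stringsAsFactors = FALSE)
    }
  }
}
tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
utils::write.table(tab, file.path(out, "module_summary.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(tab, row.names = FALSE)

for (bt in c("mRNA", "lncRNA")) {
  keep <- summaries[grepl(paste0(" ", bt, "$"), names(summaries))]
  prof <- suppressWarnings(homogeneity_profile(keep))
  utils::write.table(prof$modules,
                     file.path(out, paste0("module_profile_", bt, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf(
    "%s: homogeneous fraction case %.2f vs control %.2f (rank test p = %.3g); rho(score, log2 size): case %.2f, control %.2f",
    bt, prof$homogeneous_fraction["case"], prof$homogeneous_fraction["control"],
    prof$rank_test_p, prof$spearman_rho["case"], prof$spearman_rho["control"]))
}
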