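#!/usr/bin/env Rscript
# Cross-dataset common modules: intersect direction-consistent DE genes,
# select the sepsis-state module with the highest overlap percentage per
# dataset and direction, and take the shared genes of the selected modules.
# Recovery is scored against the planted shared module genes.

suppressPackageStartupMessages(library(comodhom))

data_dir <- "results/data"
de_dir <- "results/de"
net_dir <- "results/networks"
out <- "results/common"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
datasets <- sprintf("SYN%d", 1:6)

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

des <- lapply(datasets, function(ds) {
  de <- utils::read.table(file.path(de_dir, paste0("de_", ds, ".tsv")),
                          header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  class(de) <- c("differential_result", "data.frame")
  de
})
names(des) <- datasets
planted <- utils::read.table(file.path(data_dir, "SYN1_planted.tsv"),
                             header = TRUE, sep = "\t", stringsAsFactors = FALSE)

for (bt in c("mRNA", "lncRNA")) {
  de_bt <- lapply(des, function(de) {
    sub <- de[de$biotype == bt, ]; class(sub) <- class(de); sub
  })
  parts <- list(); sums <- list()
  for (ds in datasets) {
    path <- file.path(net_dir, sprintf("modules_%s.case.%s.tsv", ds, bt))
    if (!file.exists(path)) next
    parts[[ds]] <- read_partition(path, if (bt == "mRNA") 10L else 5L)
    sums[[ds]] <- summarize_state(parts[[ds]], des[[ds]], 0.9,
                                  state = "case", dataset_id = ds)
  }
  for (direction in c("up", "down")) {
    ov <- overlap_gene_set(de_bt, direction)
    res <- tryCatch(find_common_modules(parts, sums, ov, direction),
                    error = function(e) {
                      message(bt, " ", direction, ": ", conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) next
    key <- paste0(bt, "_", direction)
    writeLines(res$common_genes, file.path(out, paste0("common_genes_", key, ".txt")))
    utils::write.table(res$selections,
                       file.path(out, paste0("selections_", key, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    shared <- planted$symbol[planted$biotype == bt & planted$state == "case" &
                             planted$direction == direction]
    message(sprintf(
      "%s %s: %d datasets, %d common genes; planted recovery %.0f%%%s",
      bt, direction, res$n_datasets, length(res$common_genes),
      if (length(shared)) 100 * mean(shared %in% res$common_genes) else NA,
      if (length(res$excluded)) paste0(" (excluded: ",
        paste(names(res$excluded), collapse = ","), ")") else ""))
  }
}
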