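#!/usr/bin/env Rscript
# Guilt-by-association annotation of the common lncRNAs: each lncRNA is
# represented by its 15 most correlated mRNAs, which are tested for
# hypergeometric over-representation against the gene-set ontology.

suppressPackageStartupMessages(library(comodhom))

data_dir <- "results/data"
common_dir <- "results/common"
out <- "results/annotation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ref <- read_expression_tsv(file.path(data_dir, "SYN1_matrix.tsv"),
                           file.path(data_dir, "SYN1_conditions.tsv"),
                           file.path(data_dir, "SYN1_biotypes.tsv"), "SYN1")
onto <- read_gmt(file.path(data_dir, "gene_sets.gmt"),
                 universe_n = sum(ref$biotype == "mRNA"))
lnc_expr <- select_biotype(ref, "lncRNA")
mrna_expr <- select_biotype(ref, "mRNA")

lncs <- character(0)
for (direction in c("up", "down")) {
  path <- file.path(common_dir, paste0("common_genes_lncRNA_", direction, ".txt"))
  if (file.exists(path)) lncs <- c(lncs, readLines(path))
}
lncs <- unique(lncs[nzchar(lncs)])
if (!length(lncs)) {
  message("no common lncRNAs found; nothing to annotate")
  quit(save = "no", status = 0)
}

for (lnc in lncs) {
  res <- annotate_lncrna(lnc, lnc_expr, mrna_expr, onto, k = 15)
  utils::write.table(res, file.path(out, paste0("annotation_", lnc, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  top <- res[1, ]
  message(sprintf(
    "%s: top term %s (overlap %d/%d, adjusted p %.2e); %d terms under 0.05",
    lnc, top$term_id, top$overlap_k, top$term_m, top$adjusted_p,
    sum(res$adjusted_p < 0.05)))
}
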