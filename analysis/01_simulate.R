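#!/usr/bin/env Rscript
# Build the synthetic study collection: six case/control expression datasets
# on a shared feature space (2,000 mRNAs + 300 reannotatable lncRNAs,
# 20 samples per arm), with direction-coherent sepsis-state modules, mixed
# normal-state modules, a probe-annotation fixture and a gene-set ontology.
# Writes everything as TSV/GMT under results/data/.

suppressPackageStartupMessages(library(comodhom))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

specs <- list(
  planted_module(25, "mRNA", "up", effect_log2 = 2, loading = 1,
                 homogeneity = 1, state = "case"),
  planted_module(25, "mRNA", "down", effect_log2 = 2, loading = 1,
                 homogeneity = 1, state = "case"),
  planted_module(25, "mRNA", "mixed", effect_log2 = 2, loading = 1,
                 state = "control"),
  planted_module(25, "mRNA", "mixed", effect_log2 = 2, loading = 1,
                 state = "control"),
  planted_module(25, "mRNA", "mixed", effect_log2 = 2, loading = 1,
                 state = "control"),
  planted_module(25, "mRNA", "mixed", effect_log2 = 2, loading = 1,
                 state = "control"),
  planted_module(8, "lncRNA", "up", effect_log2 = 2, loading = 1,
                 homogeneity = 1, state = "case"),
  planted_module(8, "lncRNA", "down", effect_log2 = 2, loading = 1,
                 homogeneity = 1, state = "case"),
  planted_module(8, "lncRNA", "mixed", effect_log2 = 2, loading = 1,
                 state = "control"),
  planted_module(8, "lncRNA", "mixed", effect_log2 = 2, loading = 1,
                 state = "control"))

cfg <- synthetic_config(n_mrna = 2000, n_lncrna = 300, n_case = 20,
                        n_control = 20, module_specs = specs, noise_sd = 0.5,
                        baseline_mean = 8, n_datasets = 6,
                        shared_gene_fraction = 1, seed = 20260920)

for (d in seq_len(cfg$n_datasets)) {
  data <- generate_dataset(cfg, d)
  write_expression_tsv(data, out)
  planted <- attr(data, "planted")
  truth <- do.call(rbind, lapply(seq_along(planted), function(k) {
    data.frame(module = k, symbol = planted[[k]]$symbols,
               direction = planted[[k]]$direction, state = planted[[k]]$state,
               biotype = planted[[k]]$biotype, stringsAsFactors = FALSE)
  }))
  utils::write.table(truth, file.path(out, paste0(data$dataset_id, "_planted.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d features x %d samples", data$dataset_id,
                  nrow(data$matrix), ncol(data$matrix)))
}

tab <- generate_probe_table(cfg)
utils::write.table(tab, file.path(out, "probe_annotation.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("probe table: %d probes (%d lncRNA-classified)",
                nrow(tab), sum(classify_probes(tab) == "lncRNA")))

write_gmt(generate_ontology(cfg, n_decoy_terms = 50),
          file.path(out, "gene_sets.gmt"))
message("gene sets: results/data/gene_sets.gmt")
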