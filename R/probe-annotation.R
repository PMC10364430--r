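#' Probe retention and filter rules for lncRNA reannotation
#'
#' Coding-gene microarrays carry many probes that actually measure long
#' non-coding RNAs. The reannotation rules are: (1) probes whose RefSeq id is
#' prefixed `NR_` or `XR_` (non-coding RNA) are retained as lncRNA; (2) probes
#' whose Ensembl biotype is one of the retained non-coding classes are
#' retained as lncRNA; (3) pseudogenes, rRNAs, microRNAs and other small RNAs
#' (tRNA, snRNA, snoRNA) are filtered out. Discard rules take precedence over
#' retention rules, so e.g. an `NR_`-prefixed rRNA probe is discarded.
#'
#' @param refseq_keep_prefixes RefSeq prefixes indicating non-coding RNA.
#' @param ensembl_keep Retained Ensembl biotypes (classified lncRNA).
#' @param discard Filtered-out Ensembl biotypes.
#' @return A list of class `biotype_rules`.
#' @export
biotype_rules <- function(refseq_keep_prefixes = c("NR_", "XR_"),
                          ensembl_keep = c("antisense", "processed transcript",
                                           "sense overlapping",
                                           "non-sense mediated decay",
                                           "sense intronic", "lincRNA"),
                          discard = c("pseudogene", "rRNA", "microRNA",
                                      "tRNA", "snRNA", "snoRNA")) {
  if (length(intersect(ensembl_keep, discard))) {
    stop("keep and discard biotype lists must be disjoint", call. = FALSE)
  }
  structure(list(refseq_keep_prefixes = refseq_keep_prefixes,
                 ensembl_keep = ensembl_keep, discard = discard),
            class = "biotype_rules")
}

#' Classify probes as lncRNA, mRNA or discard
#'
#' Applies [biotype_rules] to one record (`classify_probe`) or to a whole
#' [generate_probe_table]-style table (`classify_probes`). A probe is
#' discarded if it maps to multiple symbols, has an empty symbol, or its
#' Ensembl biotype is on the discard list (discard overrides RefSeq/biotype
#' retention); it is lncRNA if a retention rule fires; otherwise mRNA. A
#' record with no annotation fields at all is discarded with a warning.
#'
#' @param record A one-row data.frame (or list) with fields `symbol`,
#'   `refseq_id`, `ensembl_biotype`, `n_symbols`.
#' @param table An `annotation_table` data.frame of such records.
#' @param rules A [biotype_rules] object.
#' @return `classify_probe`: one of `"lncRNA"`, `"mRNA"`, `"discard"`.
#'   `classify_probes`: a character vector, one entry per row.
#' @export
classify_probe <- function(record, rules = biotype_rules()) {
  classify_probes(as.data.frame(record, stringsAsFactors = FALSE), rules)[1]
}

#' @rdname classify_probe
#' @export
classify_probes <- function(table, rules = biotype_rules()) {
  symbol <- as.character(table$symbol)
  refseq <- as.character(table$refseq_id)
  biotype <- as.character(table$ensembl_biotype)
  n_symbols <- as.integer(table$n_symbols)
  symbol[is.na(symbol)] <- ""
  refseq[is.na(refseq)] <- ""
  biotype[is.na(biotype)] <- ""

  no_annot <- refseq == "" & biotype == ""
  if (any(no_annot & symbol != "")) {
    warning(sum(no_annot & symbol != ""),
            " probe(s) without RefSeq or Ensembl annotation discarded")
  }
  out <- rep("mRNA", length(symbol))
  prefix_hit <- Reduce(`|`, lapply(rules$refseq_keep_prefixes,
                                   function(p) startsWith(refseq, p)))
  out[prefix_hit | biotype %in% rules$ensembl_keep] <- "lncRNA"
  out[biotype %in% rules$discard] <- "discard"
  out[symbol == "" | n_symbols > 1L | no_annot] <- "discard"
  out
}

#' Collapse probe-level expression to unique gene symbols
#'
#' Applies the reannotation rules, removes discarded and multi-symbol probes,
#' and averages (arithmetic mean on the log2 scale) the rows of probes that
#' map to the same retained symbol. If a symbol has both lncRNA- and
#' mRNA-classified probes, the lncRNA classification wins (the purpose of
#' reannotation is recovering non-coding transcripts).
#'
#' @param data An [expr_dataset] whose row names are probe ids.
#' @param table An annotation table with a record for every matrix row.
#' @param rules A [biotype_rules] object.
#' @return An [expr_dataset] with one row per retained unique symbol, symbols
#'   sorted, and `biotype` set from the probe classification.
#' @export
collapse_replicates <- function(data, table, rules = biotype_rules()) {
  stopifnot(inherits(data, "expr_dataset"))
  idx <- match(rownames(data$matrix), table$probe_id)
  if (all(is.na(idx))) {
    stop("no matrix row maps to an annotation record", call. = FALSE)
  }
  if (anyNA(idx)) {
    stop(sum(is.na(idx)), " matrix row(s) missing from the annotation table",
         call. = FALSE)
  }
  tab <- table[idx, , drop = FALSE]
  cls <- classify_probes(tab, rules)
  keep <- cls != "discard"
  if (!any(keep)) stop("no probes retained after filtering", call. = FALSE)
  mat <- data$matrix[keep, , drop = FALSE]
  symbol <- as.character(tab$symbol)[keep]
  cls <- cls[keep]

  summed <- rowsum(mat, group = symbol)
  counts <- as.vector(table(symbol)[rownames(summed)])
  avg <- summed / counts
  # per-symbol biotype: lncRNA if any probe of the symbol classified lncRNA
  has_lnc <- tapply(cls == "lncRNA", symbol, any)[rownames(avg)]
  ord <- order(rownames(avg))
  expr_dataset(avg[ord, , drop = FALSE], data$condition,
               ifelse(has_lnc[ord], "lncRNA", "mRNA"), data$dataset_id)
}
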