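#' Gene-set collection with a fixed background universe
#'
#' The enrichment background is a universe *size*, matching the convention of
#' testing against the number of genes a platform detects (21,655 for the
#' Affymetrix U133 Plus 2.0 array) rather than an explicit gene list.
#'
#' @param terms Named list of non-empty character vectors (term id -> genes).
#' @param names Optional named character vector of human-readable term names.
#' @param universe_n Background universe size; must be at least the largest
#'   term. Default 21655.
#' @return A list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(terms, names = NULL, universe_n = 21655) {
  if (!length(terms)) stop("empty collection", call. = FALSE)
  if (is.null(base::names(terms)) || any(base::names(terms) == "")) {
    stop("terms must be named", call. = FALSE)
  }
  sizes <- lengths(terms)
  if (any(sizes == 0L)) stop("every term's gene set must be non-empty", call. = FALSE)
  if (universe_n < max(sizes)) {
    stop("universe_n must be >= the largest term", call. = FALSE)
  }
  if (is.null(names)) {
    names <- stats::setNames(base::names(terms), base::names(terms))
  }
  structure(list(terms = lapply(terms, unique), names = names,
                 universe_n = as.integer(universe_n)),
            class = "gene_set_collection")
}

#' Read and write gene sets in GMT format
#'
#' GMT is tab-delimited: term id, description, then member genes, one term
#' per line.
#'
#' @param path GMT file path.
#' @param universe_n Background size for the resulting collection.
#' @param collection A [gene_set_collection] to write.
#' @return `read_gmt`: a [gene_set_collection]; `write_gmt`: `path`,
#'   invisibly.
#' @export
read_gmt <- function(path, universe_n = 21655) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1)
  descs <- vapply(parts, `[`, "", 2)
  genes <- lapply(parts, function(p) p[-(1:2)][nzchar(p[-(1:2)])])
  gene_set_collection(stats::setNames(genes, ids),
                      stats::setNames(descs, ids), universe_n)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  ids <- names(collection$terms)
  lines <- vapply(ids, function(id) {
    paste(c(id, collection$names[[id]], collection$terms[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of a gene set
#'
#' For every term, the upper-tail hypergeometric probability of observing at
#' least the seen overlap between query and term, drawing `|query|` genes
#' from a universe of `universe_n` containing `|term|` term genes
#' (equivalently a one-sided Fisher test). P-values are Benjamini-Hochberg
#' adjusted across the tested terms and results are sorted by p-value, ties
#' by term id.
#'
#' @param query Character vector of gene symbols. An empty query yields a
#'   zero-row result with a warning.
#' @param collection A [gene_set_collection].
#' @return A `data.frame` of class `enrichment_result`: `term_id`, `name`,
#'   `overlap_k`, `term_m`, `query_n`, `p_value`, `adjusted_p`,
#'   `overlap_genes` (comma-separated).
#' @export
enrich <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(query)
  empty <- data.frame(term_id = character(0), name = character(0),
                      overlap_k = integer(0), term_m = integer(0),
                      query_n = integer(0), p_value = numeric(0),
                      adjusted_p = numeric(0), overlap_genes = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("enrichment_result", "data.frame")
  if (!length(query)) {
    warning("empty query: returning no enrichment rows")
    return(empty)
  }
  n_q <- length(query)
  N <- collection$universe_n
  if (n_q > N) stop("query larger than the universe", call. = FALSE)
  rows <- lapply(names(collection$terms), function(id) {
    genes <- collection$terms[[id]]
    ov <- intersect(query, genes)
    k <- length(ov)
    m <- length(genes)
    p <- stats::phyper(k - 1, m, N - m, n_q, lower.tail = FALSE)
    data.frame(term_id = id, name = unname(collection$names[id]),
               overlap_k = k, term_m = m, query_n = n_q, p_value = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term_id),
             c("term_id", "name", "overlap_k", "term_m", "query_n",
               "p_value", "adjusted_p", "overlap_genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Most correlated mRNAs of a lncRNA (guilt-by-association neighbours)
#'
#' Computes the Pearson correlation of one lncRNA's expression profile with
#' every mRNA over the shared samples and returns the top `k` by absolute
#' correlation (ties broken by symbol order). The default `k = 15` follows
#' the convention of representing a lncRNA by its 15 most correlated mRNAs.
#'
#' @param lnc Symbol of the lncRNA (must be present in `lnc_expr`).
#' @param lnc_expr An [expr_dataset] holding the lncRNA profiles.
#' @param mrna_expr An [expr_dataset] holding the mRNA profiles, same
#'   samples in the same order.
#' @param k Number of neighbours (>= 1, default 15). If fewer mRNAs exist,
#'   all are returned with a warning.
#' @param state Optional `"case"` or `"control"` restricting the samples
#'   used for correlation (default: all samples).
#' @return A `data.frame`: `symbol`, `pcc`, `abs_pcc`, `rank`, ordered by
#'   decreasing `abs_pcc`.
#' @export
lncrna_neighbors <- function(lnc, lnc_expr, mrna_expr, k = 15, state = NULL) {
  stopifnot(inherits(lnc_expr, "expr_dataset"), inherits(mrna_expr, "expr_dataset"))
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (!identical(colnames(lnc_expr$matrix), colnames(mrna_expr$matrix))) {
    stop("lncRNA and mRNA matrices must share the same samples", call. = FALSE)
  }
  if (!lnc %in% rownames(lnc_expr$matrix)) {
    stop("lncRNA '", lnc, "' not found", call. = FALSE)
  }
  if (!is.null(state)) {
    lnc_expr <- select_state(lnc_expr, state)
    mrna_expr <- select_state(mrna_expr, state)
  }
  profile <- lnc_expr$matrix[lnc, ]
  r <- suppressWarnings(as.vector(stats::cor(t(mrna_expr$matrix), profile)))
  r[is.na(r)] <- 0
  symbols <- rownames(mrna_expr$matrix)
  ord <- order(-abs(r), symbols)
  if (k > length(symbols)) {
    warning("only ", length(symbols), " mRNAs available; returning all")
    k <- length(symbols)
  }
  top <- ord[seq_len(k)]
  data.frame(symbol = symbols[top], pcc = r[top], abs_pcc = abs(r[top]),
             rank = seq_len(k), stringsAsFactors = FALSE)
}

#' Guilt-by-association functional annotation of a lncRNA
#'
#' Enriches the lncRNA's top-`k` correlated mRNAs ([lncrna_neighbors])
#' against a gene-set collection: the lncRNA inherits the functions its
#' co-expressed coding genes are enriched for.
#'
#' @inheritParams lncrna_neighbors
#' @param collection A [gene_set_collection].
#' @return An [enrich] result, with attribute `"neighbors"` holding the
#'   neighbour table.
#' @export
annotate_lncrna <- function(lnc, lnc_expr, mrna_expr, collection, k = 15,
                            state = NULL) {
  neighbors <- lncrna_neighbors(lnc, lnc_expr, mrna_expr, k, state)
  out <- enrich(neighbors$symbol, collection)
  attr(out, "neighbors") <- neighbors
  out
}
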