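#' Two-condition expression dataset
#'
#' The container every stage of the workflow consumes: a log2 expression
#' matrix (features x samples) together with a per-sample condition label
#' (`case` / `control`), a per-feature biotype (`mRNA` / `lncRNA`) and a
#' dataset identifier.
#'
#' @param matrix Numeric matrix of log2 intensities, features in rows and
#'   samples in columns. Row names are gene symbols (must be unique), column
#'   names are sample ids. No missing values are allowed.
#' @param condition Character or factor of length `ncol(matrix)` with values
#'   `"case"` or `"control"`; each condition needs at least two samples.
#' @param biotype Character of length `nrow(matrix)` with values `"mRNA"` or
#'   `"lncRNA"`. Defaults to all `"mRNA"`.
#' @param dataset_id Single string naming the dataset.
#'
#' @return An object of class `expr_dataset`: a list with elements `matrix`,
#'   `condition` (factor), `biotype` (factor) and `dataset_id`.
#' @export
expr_dataset <- function(matrix, condition, biotype = NULL, dataset_id = "dataset") {
  mat <- as.matrix(matrix)
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("expression matrix contains missing values", call. = FALSE)
  if (is.null(rownames(mat))) stop("expression matrix needs row names (gene symbols)", call. = FALSE)
  if (anyDuplicated(rownames(mat))) stop("feature symbols must be unique", call. = FALSE)
  if (is.null(colnames(mat))) colnames(mat) <- paste0("S", seq_len(ncol(mat)))
  cond <- factor(as.character(condition), levels = c("case", "control"))
  if (length(cond) != ncol(mat)) stop("condition length must match sample count", call. = FALSE)
  if (anyNA(cond)) stop("condition labels must be 'case' or 'control'", call. = FALSE)
  if (any(table(cond) < 2L)) stop("need at least 2 samples per condition", call. = FALSE)
  if (is.null(biotype)) biotype <- rep("mRNA", nrow(mat))
  bio <- factor(as.character(biotype), levels = c("mRNA", "lncRNA"))
  if (length(bio) != nrow(mat) || anyNA(bio)) {
    stop("biotype must be 'mRNA'/'lncRNA' for every feature", call. = FALSE)
  }
  structure(
    list(matrix = mat, condition = cond, biotype = bio,
         dataset_id = as.character(dataset_id)[1]),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf(
    "expr_dataset '%s': %d features (%d mRNA, %d lncRNA) x %d samples (%d case, %d control)\n",
    x$dataset_id, nrow(x$matrix), sum(x$biotype == "mRNA"), sum(x$biotype == "lncRNA"),
    ncol(x$matrix), sum(x$condition == "case"), sum(x$condition == "control")
  ))
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$matrix)

#' Subset an expression dataset
#'
#' Helpers to restrict an [expr_dataset] to one condition's samples, to one
#' biotype's features, or to a named feature set. Subsetting samples drops the
#' two-per-condition requirement check only for the absent condition.
#'
#' @param data An [expr_dataset].
#' @param state `"case"` or `"control"`.
#' @param biotype `"mRNA"` or `"lncRNA"`.
#' @param symbols Character vector of feature symbols (all must be present).
#' @return A list with the same elements as [expr_dataset] (class preserved);
#'   single-condition subsets keep the original `condition` factor levels.
#' @name expr_subset
NULL

#' @rdname expr_subset
#' @export
select_state <- function(data, state) {
  stopifnot(inherits(data, "expr_dataset"))
  state <- match.arg(state, c("case", "control"))
  keep <- data$condition == state
  if (sum(keep) < 3L) stop("need at least 3 samples in the selected state", call. = FALSE)
  out <- data
  out$matrix <- data$matrix[, keep, drop = FALSE]
  out$condition <- data$condition[keep]
  out
}

#' @rdname expr_subset
#' @export
select_biotype <- function(data, biotype) {
  stopifnot(inherits(data, "expr_dataset"))
  biotype <- match.arg(biotype, c("mRNA", "lncRNA"))
  keep <- data$biotype == biotype
  out <- data
  out$matrix <- data$matrix[keep, , drop = FALSE]
  out$biotype <- data$biotype[keep]
  out
}

#' @rdname expr_subset
#' @export
select_features <- function(data, symbols) {
  stopifnot(inherits(data, "expr_dataset"))
  missing <- setdiff(symbols, rownames(data$matrix))
  if (length(missing)) {
    stop("features not in dataset: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  out <- data
  out$matrix <- data$matrix[symbols, , drop = FALSE]
  out$biotype <- data$biotype[match(symbols, rownames(data$matrix))]
  out
}

#' Read and write expression datasets as TSV
#'
#' The on-disk form is three tab-separated files: the matrix (first column
#' `symbol`, then one column per sample), a two-column condition map
#' (`sample`, `condition`) and a two-column biotype map (`symbol`, `biotype`).
#'
#' @param data An [expr_dataset].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; defaults to the dataset id.
#' @return `write_expression_tsv` returns the three file paths invisibly;
#'   `read_expression_tsv` returns an [expr_dataset].
#' @export
write_expression_tsv <- function(data, dir, prefix = data$dataset_id) {
  stopifnot(inherits(data, "expr_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_matrix.tsv", "_conditions.tsv", "_biotypes.tsv")))
  mat_df <- data.frame(symbol = rownames(data$matrix), data$matrix,
                       check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(mat_df, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(data$matrix), condition = as.character(data$condition)),
    paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(symbol = rownames(data$matrix), biotype = as.character(data$biotype)),
    paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' @param matrix_file,condition_file,biotype_file Paths written by
#'   `write_expression_tsv`. `biotype_file` may be `NULL` (all mRNA).
#' @param dataset_id Dataset identifier for the reconstructed object.
#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(matrix_file, condition_file, biotype_file = NULL,
                                dataset_id = "dataset") {
  mat_df <- utils::read.table(matrix_file, sep = "\t", header = TRUE,
                              check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(mat_df[, -1, drop = FALSE])
  rownames(mat) <- mat_df[[1]]
  cond_df <- utils::read.table(condition_file, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  cond <- cond_df$condition[match(colnames(mat), cond_df$sample)]
  bio <- NULL
  if (!is.null(biotype_file)) {
    bio_df <- utils::read.table(biotype_file, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
    bio <- bio_df$biotype[match(rownames(mat), bio_df$symbol)]
  }
  expr_dataset(mat, cond, bio, dataset_id)
}
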