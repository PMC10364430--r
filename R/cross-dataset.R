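#' Cross-dataset consistent genes of one direction
#'
#' Step 1 of the common-module search: the genes significant with the given
#' direction in every dataset's differential result.
#'
#' @param de_results List of [compute_de] results (>= 2).
#' @param direction `"up"` or `"down"`.
#' @return Sorted character vector of consistent gene symbols.
#' @export
overlap_gene_set <- function(de_results, direction = c("up", "down")) {
  direction <- match.arg(direction)
  sets <- consistent_de(de_results)
  if (direction == "up") sets$consistent_up else sets$consistent_down
}

#' Identify the common module of one direction across datasets
#'
#' Steps 2 and 3 of the common-module search: per dataset, among the modules
#' classified with the requested direction, select the one maximising the
#' percentage of overlap genes it contains (ties broken by larger overlap
#' count, then by smaller module label); the common genes are the
#' intersection of all selected modules' member sets with the overlap set.
#' Datasets with no module of the requested category are excluded
#' automatically and recorded; `exclude` removes datasets up front (for
#' studies where one cohort's expression pattern deviates from the rest).
#'
#' @param partitions Named list of [detect_modules] partitions, one per
#'   dataset.
#' @param classifications Named list of [summarize_state] objects aligned
#'   with `partitions`.
#' @param overlap Character vector of cross-dataset consistent genes
#'   (non-empty), e.g. from [overlap_gene_set].
#' @param direction `"up"` or `"down"`.
#' @param exclude Character vector of dataset names to drop up front.
#' @return An object of class `common_module_result`: list with `direction`,
#'   `selections` (one row per included dataset: `dataset`, `module`,
#'   `module_size`, `overlap_count`, `overlap_pct`), `excluded` (named
#'   character vector of reasons), `common_genes` (sorted), `n_datasets`.
#' @export
find_common_modules <- function(partitions, classifications, overlap,
                                direction = c("up", "down"), exclude = NULL) {
  direction <- match.arg(direction)
  if (!length(overlap)) stop("overlap gene set is empty", call. = FALSE)
  if (is.null(names(partitions)) || is.null(names(classifications))) {
    stop("partitions and classifications must be named by dataset", call. = FALSE)
  }
  if (!setequal(names(partitions), names(classifications))) {
    stop("partitions and classifications name different datasets", call. = FALSE)
  }
  datasets <- sort(names(partitions))
  excluded <- character(0)
  if (length(exclude)) {
    excluded[intersect(exclude, datasets)] <- "excluded by request"
    datasets <- setdiff(datasets, exclude)
  }
  sel_rows <- list()
  member_sets <- list()
  for (ds in datasets) {
    cls <- classifications[[ds]]$modules
    cand <- cls$module[cls$category == direction]
    if (!length(cand)) {
      excluded[ds] <- paste0("no ", direction, "-regulated module")
      next
    }
    stats_df <- do.call(rbind, lapply(cand, function(m) {
      members <- module_members(partitions[[ds]], m)
      k <- length(intersect(members, overlap))
      data.frame(module = m, module_size = length(members), overlap_count = k,
                 overlap_pct = percent_of(k, length(members)))
    }))
    ord <- order(-stats_df$overlap_pct, -stats_df$overlap_count, stats_df$module)
    best <- stats_df[ord[1], , drop = FALSE]
    sel_rows[[ds]] <- cbind(dataset = ds, best, stringsAsFactors = FALSE)
    member_sets[[ds]] <- module_members(partitions[[ds]], best$module)
  }
  if (!length(sel_rows)) {
    stop("no dataset has a module of category '", direction, "'", call. = FALSE)
  }
  selections <- do.call(rbind, c(sel_rows, list(make.row.names = FALSE)))
  common <- sort(intersect(Reduce(intersect, member_sets), overlap))
  structure(list(direction = direction, selections = selections,
                 excluded = excluded, common_genes = common,
                 n_datasets = length(member_sets)),
            class = "common_module_result")
}

#' @export
print.common_module_result <- function(x, ...) {
  cat(sprintf("common_module_result (%s): %d datasets, %d common genes",
              x$direction, x$n_datasets, length(x$common_genes)))
  if (length(x$excluded)) {
    cat(sprintf(" [%d dataset(s) excluded]", length(x$excluded)))
  }
  cat("\n")
  invisible(x)
}
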