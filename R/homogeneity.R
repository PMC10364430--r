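#' Classify a module by the expression direction of its members
#'
#' A module is up-regulated when strictly more than a `threshold` fraction of
#' its members are up-regulated, down-regulated when strictly more than
#' `threshold` are down-regulated, and mixed otherwise. The inequality is
#' strict, so a module with exactly 90% up members at threshold 0.9 is mixed.
#'
#' @param member_directions Character vector of `"up"` / `"down"`, one per
#'   member (non-empty).
#' @param threshold Homogeneity threshold in (0.5, 1); 0.90 is the default,
#'   0.95 the common stricter alternative.
#' @return A one-row `data.frame`: `size`, `n_up`, `n_down`, `up_ratio`,
#'   `category`.
#' @export
classify_module <- function(member_directions, threshold = 0.9) {
  if (!length(member_directions)) stop("empty member list", call. = FALSE)
  if (threshold <= 0.5 || threshold >= 1) {
    stop("threshold must be in (0.5, 1)", call. = FALSE)
  }
  if (!all(member_directions %in% c("up", "down"))) {
    stop("member directions must be 'up' or 'down'", call. = FALSE)
  }
  size <- length(member_directions)
  n_up <- sum(member_directions == "up")
  up_ratio <- n_up / size
  category <- if (up_ratio > threshold) "up"
  else if ((1 - up_ratio) > threshold) "down"
  else "mixed"
  data.frame(size = size, n_up = n_up, n_down = size - n_up,
             up_ratio = up_ratio, category = category,
             stringsAsFactors = FALSE)
}

#' Classify every module of a partition and summarise one state
#'
#' Every assigned module (label > 0) is classified via [classify_module]
#' from its members' differential-expression directions; unassigned features
#' never enter. Aggregate counts of up / mixed / down modules and their
#' percentages mirror the usual per-dataset per-state summary tables.
#'
#' @param partition A [detect_modules] partition.
#' @param de A [compute_de] result covering every assigned member.
#' @param threshold Homogeneity threshold, see [classify_module].
#' @param digits Reporting precision for percentages (2, with 1 as the
#'   common alternative).
#' @param state Optional state label (`"case"`/`"control"`) carried through
#'   for bookkeeping.
#' @param dataset_id Optional dataset id carried through.
#' @return An object of class `state_summary`: list with `modules` (one row
#'   per module: `module`, `size`, `n_up`, `n_down`, `up_ratio`,
#'   `category`), `n_modules`, `counts` and `pct` (named up/mixed/down),
#'   `threshold`, `state`, `dataset_id`.
#' @export
summarize_state <- function(partition, de, threshold = 0.9, digits = 2,
                            state = NULL, dataset_id = NULL) {
  stopifnot(inherits(partition, "module_partition"))
  labels <- partition$labels[partition$labels != 0L]
  mods <- sort(unique(labels))
  rows <- lapply(mods, function(m) {
    members <- names(labels)[labels == m]
    idx <- match(members, de$symbol)
    if (anyNA(idx)) {
      stop("module member(s) missing from the differential result: ",
           paste(utils::head(members[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    }
    cbind(module = m, classify_module(de$direction[idx], threshold))
  })
  modules <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = integer(0), size = integer(0), n_up = integer(0),
               n_down = integer(0), up_ratio = numeric(0),
               category = character(0), stringsAsFactors = FALSE)
  counts <- c(up = sum(modules$category == "up"),
              mixed = sum(modules$category == "mixed"),
              down = sum(modules$category == "down"))
  n_mod <- nrow(modules)
  pct <- if (n_mod > 0) percent_of(counts, n_mod, digits) else
    c(up = NA_real_, mixed = NA_real_, down = NA_real_)
  structure(list(modules = modules, n_modules = n_mod, counts = counts,
                 pct = pct, threshold = threshold, state = state,
                 dataset_id = dataset_id),
            class = "state_summary")
}

#' @export
print.state_summary <- function(x, ...) {
  cat(sprintf("state_summary%s%s: %d modules (up %d, mixed %d, down %d), threshold %.2f\n",
              if (!is.null(x$dataset_id)) paste0(" ", x$dataset_id) else "",
              if (!is.null(x$state)) paste0("/", x$state) else "",
              x$n_modules, x$counts["up"], x$counts["mixed"], x$counts["down"],
              x$threshold))
  invisible(x)
}

#' Compare module direction-homogeneity between states
#'
#' Pools per-module rows across summaries, computes each module's
#' homogeneity score `max(up_ratio, 1 - up_ratio)`, the per-state fraction
#' of homogeneous (non-mixed) modules, a two-sided Wilcoxon rank-sum test
#' comparing the score between states, and the Spearman correlation of the
#' score with `log2(module size)` per state (the size-independence check).
#'
#' @param summaries List of [summarize_state] objects, each with its
#'   `state` field set; states with no modules are excluded with a warning.
#' @return A list: `modules` (pooled per-module rows with `state`,
#'   `dataset_id`, `score`, `log2_size`), `homogeneous_fraction` (named by
#'   state), `rank_test_p`, `spearman_rho` (named by state).
#' @export
homogeneity_profile <- function(summaries) {
  if (!length(summaries)) stop("no summaries supplied", call. = FALSE)
  rows <- lapply(summaries, function(s) {
    stopifnot(inherits(s, "state_summary"))
    if (s$n_modules == 0L) return(NULL)
    cbind(state = if (is.null(s$state)) NA_character_ else s$state,
          dataset_id = if (is.null(s$dataset_id)) NA_character_ else s$dataset_id,
          s$modules, stringsAsFactors = FALSE)
  })
  empty <- vapply(rows, is.null, TRUE)
  if (any(empty)) warning(sum(empty), " summary(ies) with no modules excluded")
  mods <- do.call(rbind, rows[!empty])
  if (is.null(mods) || !nrow(mods)) stop("no modules in any summary", call. = FALSE)
  mods$score <- pmax(mods$up_ratio, 1 - mods$up_ratio)
  mods$log2_size <- log2(mods$size)
  states <- unique(mods$state)
  hfrac <- vapply(states, function(st) {
    mean(mods$category[mods$state == st] != "mixed")
  }, numeric(1))
  names(hfrac) <- states
  p <- NA_real_
  if (length(states) == 2L) {
    p <- suppressWarnings(stats::wilcox.test(
      score ~ state, data = mods, exact = FALSE, correct = FALSE))$p.value
  }
  rho <- vapply(states, function(st) {
    sub <- mods[mods$state == st, ]
    if (nrow(sub) < 3L || stats::sd(sub$score) == 0 || stats::sd(sub$log2_size) == 0) {
      return(NA_real_)
    }
    suppressWarnings(stats::cor(sub$score, sub$log2_size, method = "spearman"))
  }, numeric(1))
  names(rho) <- states
  list(modules = mods, homogeneous_fraction = hfrac,
       rank_test_p = p, spearman_rho = rho)
}
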