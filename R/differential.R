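# Row-wise two-sample t statistics (Welch or pooled), closed form.
# x: features x samples matrix; g1/g2: column indices of the two groups.
row_t_test <- function(x, g1, g2, var_equal = FALSE) {
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 samples per group", call. = FALSE)
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  v1 <- rowSums((x[, g1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((x[, g2, drop = FALSE] - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate: zero variance in both groups
  zero_se <- se == 0
  p[zero_se & m1 == m2] <- 1      # identical constants: no evidence
  p[zero_se & m1 != m2] <- 0      # separated constants: infinite t
  list(statistic = tstat, df = df, p_value = p, delta = m1 - m2)
}

#' Per-feature differential expression between case and control
#'
#' For every feature, a two-tailed two-sample t-test on the log2 values and a
#' fold change computed as `2^(mean_case - mean_control)` (the ratio of
#' geometric means, the standard microarray convention). A feature is
#' significant when `p < alpha` and the absolute fold change
#' `max(FC, 1/FC)` exceeds `fc_threshold`, both strict; its direction is
#' `up` when `FC > 1`, else `down`.
#'
#' @param data An [expr_dataset].
#' @param alpha Significance threshold on the (optionally adjusted) p-value.
#' @param fc_threshold Absolute fold-change threshold on the linear scale.
#' @param var_equal `FALSE` (default) for the Welch unequal-variance test,
#'   `TRUE` for Student's pooled-variance test.
#' @param adjust `"none"` (default, raw p-values as the criterion) or `"BH"`
#'   for Benjamini-Hochberg adjustment before thresholding.
#' @return A `data.frame` of class `differential_result` with columns
#'   `symbol`, `biotype`, `p_value`, `fold_change`, `direction`,
#'   `significant`, and attributes `alpha`, `fc_threshold`, `dataset_id`.
#' @export
compute_de <- function(data, alpha = 0.05, fc_threshold = 1.5,
                       var_equal = FALSE, adjust = c("none", "BH")) {
  stopifnot(inherits(data, "expr_dataset"))
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (fc_threshold < 1) stop("fc_threshold must be >= 1", call. = FALSE)
  g1 <- which(data$condition == "case")
  g2 <- which(data$condition == "control")
  tt <- row_t_test(data$matrix, g1, g2, var_equal = var_equal)
  fc <- 2^tt$delta
  p_crit <- if (adjust == "BH") stats::p.adjust(tt$p_value, "BH") else tt$p_value
  out <- data.frame(
    symbol = rownames(data$matrix),
    biotype = as.character(data$biotype),
    p_value = tt$p_value,
    fold_change = fc,
    direction = ifelse(fc > 1, "up", "down"),
    significant = p_crit < alpha & pmax(fc, 1 / fc) > fc_threshold,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "alpha") <- alpha
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "dataset_id") <- data$dataset_id
  attr(out, "adjust") <- adjust
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Cross-dataset consistent differential-expression sets
#'
#' Genes significant with direction `up` in every supplied result form
#' `consistent_up`; analogously for `consistent_down`. The two sets are
#' disjoint by construction.
#'
#' @param results A list of [compute_de] results (>= 2).
#' @return A list with sorted character vectors `consistent_up` and
#'   `consistent_down`.
#' @export
consistent_de <- function(results) {
  if (!length(results)) stop("empty result list", call. = FALSE)
  if (length(results) < 2L) stop("need at least 2 results", call. = FALSE)
  pick <- function(r, dir) r$symbol[r$significant & r$direction == dir]
  up <- Reduce(intersect, lapply(results, pick, dir = "up"))
  down <- Reduce(intersect, lapply(results, pick, dir = "down"))
  list(consistent_up = sort(up), consistent_down = sort(down))
}

#' Percentage with rounding at reporting precision
#'
#' @param count Numerator count.
#' @param total Denominator count (> 0).
#' @param digits Decimal places for reporting (default 2).
#' @return `round(100 * count / total, digits)`.
#' @export
percent_of <- function(count, total, digits = 2) {
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  round(100 * count / total, digits)
}

#' Summarise a differential result as percentages of a background
#'
#' Mirrors the usual per-dataset summary table: the significant fraction of
#' the background universe, and the up/down split of the significant set.
#'
#' @param result A [compute_de] result.
#' @param background_n Background universe size (>= number of significant
#'   features, > 0).
#' @param digits Reporting precision (default two decimals).
#' @return A one-row `data.frame`: `n_significant`, `total_pct`, `n_up`,
#'   `up_pct`, `n_down`, `down_pct`.
#' @export
de_fraction <- function(result, background_n, digits = 2) {
  stopifnot(inherits(result, "differential_result"))
  if (background_n <= 0) stop("background_n must be positive", call. = FALSE)
  n_sig <- sum(result$significant)
  if (background_n < n_sig) {
    stop("background_n smaller than the significant count", call. = FALSE)
  }
  n_up <- sum(result$significant & result$direction == "up")
  n_down <- n_sig - n_up
  data.frame(
    n_significant = n_sig,
    total_pct = percent_of(n_sig, background_n, digits),
    n_up = n_up,
    up_pct = if (n_sig > 0) percent_of(n_up, n_sig, digits) else 0,
    n_down = n_down,
    down_pct = if (n_sig > 0) percent_of(n_down, n_sig, digits) else 0
  )
}

#' Write a differential result as TSV
#'
#' @param result A [compute_de] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_de_tsv <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
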