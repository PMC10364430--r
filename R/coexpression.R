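#' Pairwise Pearson correlation over a condition's samples
#'
#' Networks are built separately for case and control samples, each from the
#' differentially expressed features of one biotype, so correlations are
#' computed over the selected samples only.
#'
#' @param data An [expr_dataset].
#' @param features Optional character vector restricting the features
#'   (default: all rows).
#' @param state Optional `"case"` or `"control"` restricting the samples
#'   (default: all samples).
#' @return A symmetric correlation matrix with unit diagonal. Zero-variance
#'   features get correlation 0 with everything (with a warning).
#' @export
pcc_matrix <- function(data, features = NULL, state = NULL) {
  stopifnot(inherits(data, "expr_dataset"))
  if (!is.null(state)) data <- select_state(data, state)
  if (!is.null(features)) data <- select_features(data, features)
  x <- t(data$matrix)
  if (nrow(x) < 3L) stop("need at least 3 samples for correlation", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance feature(s); their correlations set to 0")
  }
  r <- suppressWarnings(stats::cor(x))
  r[flat, ] <- 0
  r[, flat] <- 0
  diag(r) <- 1
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivities `k`, then regresses `log10(frequency)` on
#' `log10(mean k per bin)`; under a power-law degree distribution the
#' relation is linear with negative slope. Bins are equal-width over the
#' range of `k`; when there are at most `n_bins` distinct values each
#' distinct value forms its own bin.
#'
#' @param k Numeric vector of connectivities (non-negative).
#' @param n_bins Number of bins (default 10).
#' @return A list: `r_squared`, `slope`, `table` (per-bin mean k and
#'   frequency), `ok` (FALSE when the fit is undefined, e.g. all `k`
#'   identical or fewer than 3 populated bins).
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  undefined <- list(r_squared = NA_real_, slope = NA_real_,
                    table = NULL, ok = FALSE)
  if (length(k) < 3L || length(unique(k)) == 1L) return(undefined)
  if (length(unique(k)) <= n_bins) {
    bin <- factor(k)
  } else {
    bin <- cut(k, breaks = n_bins, include.lowest = TRUE)
  }
  mean_k <- tapply(k, bin, mean)
  freq <- tapply(k, bin, length) / length(k)
  keep <- !is.na(mean_k) & freq > 0
  mean_k <- mean_k[keep]; freq <- freq[keep]
  if (length(mean_k) < 3L || length(unique(freq)) == 1L) return(undefined)
  fit <- stats::lm(log10(freq) ~ log10(mean_k))
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       table = data.frame(mean_k = as.vector(mean_k), freq = as.vector(freq)),
       ok = TRUE)
}

#' Soft-thresholding adjacency
#'
#' @param corr A correlation matrix.
#' @param power Soft-thresholding exponent `b`; adjacency is `|r|^b`.
#' @return The adjacency matrix with zero diagonal (so connectivity is the
#'   off-diagonal row sum) and attribute `"power"`.
#' @export
adjacency_matrix <- function(corr, power) {
  if (power < 1) stop("power must be >= 1", call. = FALSE)
  a <- abs(corr)^power
  diag(a) <- 0
  attr(a, "power") <- power
  a
}

#' Select a soft-thresholding power by scale-free topology fit
#'
#' For every candidate power, computes the adjacency `|r|^b`, the per-node
#' connectivity, and the [scale_free_fit]; returns the smallest power whose
#' fit reaches `r2_target` with negative slope. If none qualifies, the power
#' maximising the fit is returned with `reached_target = FALSE`.
#'
#' @param corr A correlation matrix.
#' @param candidate_powers Integer candidates (default 1:20).
#' @param r2_target Required fit R-squared (default 0.8).
#' @param n_bins Bins for [scale_free_fit].
#' @return A list: `power`, `r_squared`, `slope`, `reached_target`, and
#'   `table` with one row per candidate.
#' @export
select_power <- function(corr, candidate_powers = 1:20, r2_target = 0.8,
                         n_bins = 10) {
  if (!length(candidate_powers)) stop("no candidate powers", call. = FALSE)
  rows <- lapply(candidate_powers, function(b) {
    a <- adjacency_matrix(corr, b)
    fit <- scale_free_fit(colSums(a), n_bins)
    data.frame(power = b, r_squared = fit$r_squared, slope = fit$slope,
               ok = fit$ok)
  })
  tab <- do.call(rbind, rows)
  qualifies <- tab$ok & !is.na(tab$r_squared) &
    tab$r_squared >= r2_target & tab$slope < 0
  if (any(qualifies)) {
    i <- which(qualifies)[1]
    reached <- TRUE
  } else if (any(tab$ok)) {
    i <- which.max(ifelse(tab$ok, tab$r_squared, -Inf))
    reached <- FALSE
    warning("no candidate power reached the scale-free fit target; ",
            "returning the best fit (power ", tab$power[i], ")")
  } else {
    warning("scale-free fit undefined for every candidate power; ",
            "falling back to the smallest candidate")
    i <- 1
    reached <- FALSE
  }
  list(power = tab$power[i], r_squared = tab$r_squared[i],
       slope = tab$slope[i], reached_target = reached, table = tab)
}

#' Topological overlap matrix
#'
#' The unsigned topological overlap of nodes i and j combines their direct
#' connection with their shared neighbourhood:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu`, and `TOM_ii = 1`. Values lie in \[0, 1\]; two fully
#' isolated nodes get overlap 0.
#'
#' @param adj An adjacency matrix from [adjacency_matrix] (zero diagonal,
#'   off-diagonal values in \[0, 1\]).
#' @return The TOM, symmetric with unit diagonal.
#' @export
tom_matrix <- function(adj) {
  a <- unclass(adj)
  if (any(a < 0) || any(a > 1)) stop("adjacency values must be in [0, 1]", call. = FALSE)
  diag(a) <- 0
  k <- colSums(a)
  shared <- a %*% a
  num <- shared + a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- num / denom
  tom[denom <= 0] <- 0
  # guard numeric noise from the matrix product
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`;
#' clusters smaller than `min_module_size` are pooled into the unassigned
#' label 0, and the remaining modules are labelled 1, 2, ... in decreasing
#' size order.
#'
#' By default the tree is cut adaptively: with block-structured TOMs the
#' merge heights are bimodal (within-module merges low, between-module and
#' background merges near the top), so the cut is placed in the largest gap
#' between consecutive sorted merge heights in the upper half of the height
#' distribution. This keeps recovery stable across soft-thresholding powers,
#' where a fixed height fraction either fragments modules (high powers
#' compress all dissimilarities towards 1) or absorbs background genes (low
#' powers). A numeric `cut_height` gives the classical fixed cut at that
#' fraction of the maximum merge height instead.
#'
#' @param tomatrix A TOM from [tom_matrix].
#' @param min_module_size Minimum members per module (10 is the usual mRNA
#'   default, 5 for the smaller lncRNA networks).
#' @param cut_height `NULL` (default) for the adaptive largest-gap cut, or
#'   a fraction of the maximum merge height for a fixed cut.
#' @return An object of class `module_partition`: list with `labels` (named
#'   integer vector, 0 = unassigned), `sizes` (named, excluding 0),
#'   `n_modules`, `min_module_size`, `cut_height_used`.
#' @export
detect_modules <- function(tomatrix, min_module_size = 10, cut_height = NULL) {
  n <- nrow(tomatrix)
  feats <- rownames(tomatrix)
  if (is.null(feats)) feats <- paste0("F", seq_len(n))
  if (n < min_module_size || n < 2L) {
    labels <- stats::setNames(rep(0L, n), feats)
    return(structure(list(labels = labels, sizes = integer(0), n_modules = 0L,
                          min_module_size = as.integer(min_module_size),
                          cut_height_used = NA_real_),
                     class = "module_partition"))
  }
  h <- stats::hclust(stats::as.dist(1 - tomatrix), method = "average")
  cut_h <- if (is.null(cut_height)) gap_cut_height(h$height)
  else cut_height * max(h$height)
  raw <- stats::cutree(h, h = cut_h)
  tab <- table(raw)
  small <- as.integer(names(tab)[tab < min_module_size])
  labels <- ifelse(raw %in% small, 0L, raw)
  # relabel surviving clusters by decreasing size (ties: original id order)
  surv <- sort(table(labels[labels != 0L]), decreasing = TRUE)
  remap <- stats::setNames(seq_along(surv), names(surv))
  labels[labels != 0L] <- remap[as.character(labels[labels != 0L])]
  labels <- stats::setNames(as.integer(labels), feats)
  sizes <- table(labels[labels != 0L])
  structure(list(labels = labels,
                 sizes = stats::setNames(as.integer(sizes), names(sizes)),
                 n_modules = length(sizes),
                 min_module_size = as.integer(min_module_size),
                 cut_height_used = cut_h),
            class = "module_partition")
}

# Adaptive cut height: the midpoint of the largest gap between consecutive
# sorted merge heights, considering gaps starting at or above the median
# height (within-module merges occupy the lower heights and must not host
# the cut).
gap_cut_height <- function(heights) {
  h <- sort(heights)
  n <- length(h)
  if (n < 3L) return(0.99 * max(h))
  lo <- stats::quantile(h, 0.5, names = FALSE)
  idx <- which(h[-n] >= lo)
  if (!length(idx)) idx <- n - 1L
  gaps <- h[idx + 1L] - h[idx]
  i <- idx[which.max(gaps)]
  (h[i] + h[i + 1L]) / 2
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d features, %d modules (min size %d), %d unassigned\n",
              length(x$labels), x$n_modules, x$min_module_size,
              sum(x$labels == 0L)))
  invisible(x)
}

#' Members of one module
#'
#' @param partition A [detect_modules] partition.
#' @param module Integer module label (> 0).
#' @return Character vector of member symbols.
#' @export
module_members <- function(partition, module) {
  stopifnot(inherits(partition, "module_partition"))
  names(partition$labels)[partition$labels == as.integer(module)]
}

#' WGCNA-style colour aliases for module labels
#'
#' @param labels Integer module labels (0 = unassigned, reported as "grey").
#' @return Character vector of colour names; labels beyond the palette are
#'   reported as `module<label>`.
#' @export
module_colors <- function(labels) {
  palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
               "black", "pink", "magenta", "purple", "greenyellow", "tan",
               "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
               "lightgreen", "lightyellow", "royalblue")
  out <- ifelse(labels == 0L, "grey",
                ifelse(labels <= length(palette), palette[pmax(labels, 1L)],
                       paste0("module", labels)))
  out
}

#' Strongly co-expressed gene pairs
#'
#' @param corr A correlation matrix.
#' @param threshold Absolute-correlation cutoff in (0, 1); the usual
#'   conventions are 0.7 for mRNA and 0.5 for lncRNA networks. Strict
#'   inequality.
#' @return A `data.frame` with columns `source`, `target`, `weight`
#'   (signed correlation), each unordered pair once with
#'   `source < target`, rows in lexicographic order.
#' @export
strong_edges <- function(corr, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)", call. = FALSE)
  feats <- rownames(corr)
  if (is.null(feats)) feats <- paste0("F", seq_len(nrow(corr)))
  idx <- which(upper.tri(corr) & abs(corr) > threshold, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(source = character(0), target = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  }
  a <- feats[idx[, 1]]; b <- feats[idx[, 2]]
  src <- pmin(a, b); tgt <- pmax(a, b)
  out <- data.frame(source = src, target = tgt,
                    weight = corr[idx], stringsAsFactors = FALSE)
  out[order(out$source, out$target), , drop = FALSE]
}

#' Write an edge list as SIF or TSV (Cytoscape-loadable)
#'
#' @param edges A [strong_edges] data.frame.
#' @param path Output file.
#' @param relation SIF relation type (default `"co"`).
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path, relation = "co") {
  lines <- sprintf("%s\t%s\t%s", edges$source, relation, edges$target)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sif
#' @export
write_edges_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
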