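# Evaluate code under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, stream, index = 0L) {
  (abs(as.numeric(seed)) %% 1e6) * 1009 + stream * 9973 + index * 131071
}

#' Specify a planted co-expression module
#'
#' A planted module is a block of features that (a) shift between case and
#' control by `effect_log2` with per-member signs set by `direction` and
#' `homogeneity`, and (b) share a latent factor (one standard-normal draw per
#' sample) scaled by `loading`, which induces within-module correlation. The
#' `state` field says in which samples the latent factor is active, i.e. in
#' which condition's co-expression network the module exists.
#'
#' @param size Member count (>= 1).
#' @param biotype `"mRNA"` or `"lncRNA"`.
#' @param direction `"up"`, `"down"` or `"mixed"`. For `"up"`/`"down"` a
#'   `homogeneity` fraction of members carry the majority sign and the rest
#'   the opposite sign; for `"mixed"` signs are Bernoulli(0.5) and
#'   `homogeneity` is ignored.
#' @param effect_log2 Mean case-minus-control shift in log2 units (>= 0).
#' @param loading Weight of the shared latent factor (>= 0).
#' @param homogeneity Target fraction of members carrying the majority
#'   direction, in \[0.5, 1\].
#' @param state Samples in which the latent factor is active: `"case"`,
#'   `"control"` or `"both"`.
#' @return A list of class `planted_module`.
#' @export
planted_module <- function(size, biotype = c("mRNA", "lncRNA"),
                           direction = c("up", "down", "mixed"),
                           effect_log2 = 2, loading = 1, homogeneity = 1,
                           state = c("case", "control", "both")) {
  biotype <- match.arg(biotype)
  direction <- match.arg(direction)
  state <- match.arg(state)
  if (size < 1) stop("module size must be >= 1", call. = FALSE)
  if (loading < 0) stop("loading must be >= 0", call. = FALSE)
  if (effect_log2 < 0) stop("effect_log2 must be >= 0", call. = FALSE)
  if (homogeneity < 0.5 || homogeneity > 1) {
    stop("homogeneity must be in [0.5, 1]", call. = FALSE)
  }
  structure(list(size = as.integer(size), biotype = biotype, direction = direction,
                 effect_log2 = effect_log2, loading = loading,
                 homogeneity = homogeneity, state = state),
            class = "planted_module")
}

#' Configuration for the synthetic expression-data generator
#'
#' Describes a collection of two-condition microarray-like datasets sharing a
#' feature space (as datasets from one platform do): thousands of mRNA
#' features, a smaller lncRNA set, homoscedastic Gaussian noise on the log2
#' scale, and planted modules per [planted_module]. A `shared_gene_fraction`
#' core of every module keeps identical gene symbols across datasets; the
#' remaining members occupy dataset-specific symbols.
#'
#' @param n_mrna,n_lncrna Feature counts per biotype.
#' @param n_case,n_control Samples per condition (>= 2 each).
#' @param module_specs List of [planted_module] objects.
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise, log2 units.
#' @param baseline_mean Baseline log2 intensity.
#' @param n_datasets Number of datasets in the collection.
#' @param shared_gene_fraction Fraction of each module's members reused
#'   identically across datasets, in \[0, 1\].
#' @param seed Integer random seed governing every draw.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_mrna = 2000, n_lncrna = 300,
                             n_case = 20, n_control = 20,
                             module_specs = list(),
                             noise_sd = 0.5, baseline_mean = 8,
                             n_datasets = 1, shared_gene_fraction = 1,
                             seed = 1) {
  counts <- c(n_mrna = n_mrna, n_lncrna = n_lncrna, n_case = n_case,
              n_control = n_control, n_datasets = n_datasets)
  if (any(counts < 1)) stop("all counts must be strictly positive", call. = FALSE)
  if (n_case < 2 || n_control < 2) stop("need >= 2 samples per condition", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (shared_gene_fraction < 0 || shared_gene_fraction > 1) {
    stop("shared_gene_fraction must be in [0, 1]", call. = FALSE)
  }
  if (length(module_specs) && !all(vapply(module_specs, inherits, TRUE, "planted_module"))) {
    stop("module_specs must be a list of planted_module objects", call. = FALSE)
  }
  cfg <- structure(
    list(n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
         n_case = as.integer(n_case), n_control = as.integer(n_control),
         module_specs = module_specs, noise_sd = noise_sd,
         baseline_mean = baseline_mean, n_datasets = as.integer(n_datasets),
         shared_gene_fraction = shared_gene_fraction, seed = as.integer(seed)),
    class = "synthetic_config")
  # fails if the planted modules exceed the per-biotype feature budget
  invisible(allocate_members(cfg))
  cfg
}

feature_symbols <- function(config) {
  list(mRNA = sprintf("G%05d", seq_len(config$n_mrna)),
       lncRNA = sprintf("L%05d", seq_len(config$n_lncrna)))
}

# Deterministic symbol allocation: each module gets a shared core (identical
# across datasets) followed by one dataset-specific block per dataset.
# Returns, per module, a matrix-free list: shared symbols + per-dataset extras.
allocate_members <- function(config) {
  syms <- feature_symbols(config)
  ptr <- c(mRNA = 0L, lncRNA = 0L)
  out <- vector("list", length(config$module_specs))
  for (m in seq_along(config$module_specs)) {
    spec <- config$module_specs[[m]]
    n_shared <- if (config$n_datasets > 1L) {
      as.integer(round(config$shared_gene_fraction * spec$size))
    } else spec$size
    n_extra <- spec$size - n_shared
    need <- n_shared + n_extra * config$n_datasets
    pool <- syms[[spec$biotype]]
    if (ptr[[spec$biotype]] + need > length(pool)) {
      stop("planted module sizes exceed the ", spec$biotype, " feature budget",
           call. = FALSE)
    }
    shared <- pool[ptr[[spec$biotype]] + seq_len(n_shared)]
    ptr[[spec$biotype]] <- ptr[[spec$biotype]] + n_shared
    extras <- vector("list", config$n_datasets)
    for (d in seq_len(config$n_datasets)) {
      extras[[d]] <- pool[ptr[[spec$biotype]] + seq_len(n_extra)]
      ptr[[spec$biotype]] <- ptr[[spec$biotype]] + n_extra
    }
    out[[m]] <- list(shared = shared, extras = extras)
  }
  out
}

# Per-member effect signs, identical across datasets (drawn from the config
# seed only) so that shared genes are cross-dataset consistent.
module_signs <- function(config) {
  with_seed(derive_seed(config$seed, 1L), {
    lapply(config$module_specs, function(spec) {
      if (spec$direction == "mixed") {
        sample(c(1, -1), spec$size, replace = TRUE)
      } else {
        major <- if (spec$direction == "up") 1 else -1
        n_major <- as.integer(round(spec$homogeneity * spec$size))
        c(rep(major, n_major), rep(-major, spec$size - n_major))
      }
    })
  })
}

#' Generate one synthetic two-condition expression dataset
#'
#' Expression for gene g in sample s is
#' `baseline + I(s is case) * sign_g * effect_log2 + loading * latent_{m,s} + noise`,
#' where `latent_{m,s}` is one standard-normal draw per module per sample,
#' applied only in the module's active `state`, and background genes are
#' `baseline + noise`. Gene names and module membership are deterministic
#' given the config seed; noise and latent draws depend on `dataset_index`.
#'
#' @param config A [synthetic_config].
#' @param dataset_index Which dataset of the collection to generate
#'   (1-based, `<= config$n_datasets`).
#' @return An [expr_dataset] with attribute `"planted"`: a list with one
#'   entry per planted module giving `symbols`, `signs`, `direction`,
#'   `state` and `biotype` — ground truth for recovery checks.
#' @export
generate_dataset <- function(config, dataset_index = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  dataset_index <- as.integer(dataset_index)
  if (dataset_index < 1L || dataset_index > config$n_datasets) {
    stop("dataset_index must be in 1..n_datasets", call. = FALSE)
  }
  syms <- feature_symbols(config)
  all_syms <- c(syms$mRNA, syms$lncRNA)
  biotype <- rep(c("mRNA", "lncRNA"), c(config$n_mrna, config$n_lncrna))
  n_s <- config$n_case + config$n_control
  condition <- rep(c("case", "control"), c(config$n_case, config$n_control))
  members <- allocate_members(config)
  signs <- module_signs(config)
  dataset_id <- sprintf("SYN%d", dataset_index)

  mat <- with_seed(derive_seed(config$seed, 2L, dataset_index), {
    m <- config$baseline_mean +
      matrix(stats::rnorm(length(all_syms) * n_s, sd = config$noise_sd),
             nrow = length(all_syms), ncol = n_s)
    for (k in seq_along(config$module_specs)) {
      spec <- config$module_specs[[k]]
      mem <- c(members[[k]]$shared, members[[k]]$extras[[dataset_index]])
      rows <- match(mem, all_syms)
      # condition effect in case samples
      case_cols <- which(condition == "case")
      m[rows, case_cols] <- m[rows, case_cols] + signs[[k]] * spec$effect_log2
      # shared latent factor in the active state's samples
      if (spec$loading > 0) {
        latent <- stats::rnorm(n_s)
        active <- if (spec$state == "both") seq_len(n_s) else which(condition == spec$state)
        m[rows, active] <- m[rows, active] +
          spec$loading * matrix(latent[active], nrow = length(rows),
                                ncol = length(active), byrow = TRUE)
      }
    }
    m
  })
  rownames(mat) <- all_syms
  colnames(mat) <- sprintf("%s_%s_%02d", dataset_id, condition,
                           stats::ave(seq_len(n_s), condition, FUN = seq_along))
  data <- expr_dataset(mat, condition, biotype, dataset_id)
  attr(data, "planted") <- lapply(seq_along(config$module_specs), function(k) {
    spec <- config$module_specs[[k]]
    list(symbols = c(members[[k]]$shared, members[[k]]$extras[[dataset_index]]),
         shared_symbols = members[[k]]$shared,
         signs = signs[[k]], direction = spec$direction,
         state = spec$state, biotype = spec$biotype)
  })
  data
}

#' Generate a probe-annotation fixture table
#'
#' Builds a deterministic probe-level annotation table exercising every
#' branch of the reannotation rules: coding probes (`NM_` RefSeq ids, a
#' fraction replicated), lncRNA probes labelled either by `NR_`/`XR_` RefSeq
#' ids or by each retained Ensembl biotype, decoy probes for every discard
#' biotype (including an `NR_`-prefixed rRNA probe, the precedence case),
#' multi-symbol probes, and one probe with no annotation at all.
#'
#' @param config A [synthetic_config]; its feature symbols become the probe
#'   targets.
#' @return A `data.frame` of class `annotation_table` with columns
#'   `probe_id`, `symbol`, `refseq_id`, `ensembl_biotype`, `n_symbols`.
#' @export
generate_probe_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  syms <- feature_symbols(config)
  rules <- biotype_rules()
  keep_bt <- rules$ensembl_keep

  n_rep_m <- max(1L, config$n_mrna %/% 20L)
  i_m <- seq_along(syms$mRNA)
  m_sym <- syms$mRNA
  m_ref <- sprintf("NM_%06d", i_m)
  # replicated coding probes: a second probe for the first few symbols
  rep_m <- seq_len(n_rep_m)

  i_l <- seq_along(syms$lncRNA)
  branch <- (i_l - 1L) %% (2L + length(keep_bt))
  l_ref <- ifelse(branch == 0L, sprintf("NR_%06d", i_l),
                  ifelse(branch == 1L, sprintf("XR_%06d", i_l), ""))
  l_bt <- ifelse(branch >= 2L, keep_bt[pmax(branch - 1L, 1L)], "")
  n_rep_l <- max(1L, config$n_lncrna %/% 10L)
  rep_l <- seq_len(n_rep_l)

  symbol <- c(m_sym, m_sym[rep_m], syms$lncRNA, syms$lncRNA[rep_l],
              sprintf("DECOY%02d", seq_along(rules$discard)),
              paste(m_sym[1], m_sym[2], sep = "///"),
              paste(syms$lncRNA[1], syms$lncRNA[2], sep = "///"),
              "")
  refseq <- c(m_ref, m_ref[rep_m], l_ref, sprintf("NR_%06d", rep_l),
              # first decoy carries an NR_ prefix: discard must override RefSeq retention
              c("NR_900001", rep("", length(rules$discard) - 1L)),
              "NM_900001", "NR_900002", "")
  biotype <- c(rep("protein_coding", length(m_sym) + n_rep_m),
               l_bt, rep("", n_rep_l),
               rules$discard, "protein_coding", "lincRNA", "")
  n_symbols <- rep(1L, length(symbol))
  n_symbols[length(symbol) - c(1L, 2L)] <- 2L
  out <- data.frame(probe_id = sprintf("P%06d", seq_along(symbol)),
                    symbol = symbol, refseq_id = refseq,
                    ensembl_biotype = biotype, n_symbols = n_symbols,
                    stringsAsFactors = FALSE)
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Generate a gene-set collection with planted terms
#'
#' Builds a GMT-style collection in which each planted mRNA module's gene set
#' is embedded in exactly one term, plus uniformly drawn decoy terms, so that
#' enrichment of a correctly recovered module must rank its term first.
#'
#' @param config A [synthetic_config].
#' @param n_decoy_terms Number of random decoy terms (>= 1).
#' @param decoy_size_range Length-2 integer range of decoy term sizes.
#' @param dataset_index Which dataset's module membership to embed.
#' @return A [gene_set_collection] whose universe is the mRNA feature space.
#' @export
generate_ontology <- function(config, n_decoy_terms = 50,
                              decoy_size_range = c(10, 40),
                              dataset_index = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (n_decoy_terms < 1) stop("need at least one decoy term", call. = FALSE)
  syms <- feature_symbols(config)$mRNA
  members <- allocate_members(config)
  terms <- list()
  is_mrna <- vapply(config$module_specs, function(s) s$biotype == "mRNA", TRUE)
  for (k in which(is_mrna)) {
    mem <- c(members[[k]]$shared, members[[k]]$extras[[min(dataset_index, config$n_datasets)]])
    terms[[sprintf("PLANTED_M%02d", k)]] <- mem
  }
  decoys <- with_seed(derive_seed(config$seed, 3L), {
    lapply(seq_len(n_decoy_terms), function(j) {
      size <- sample(seq(decoy_size_range[1], decoy_size_range[2]), 1L)
      sample(syms, size)
    })
  })
  names(decoys) <- sprintf("DECOY_T%03d", seq_len(n_decoy_terms))
  gene_set_collection(c(terms, decoys), universe_n = length(syms))
}
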