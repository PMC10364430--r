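# Shared fixture builders for the test suite. Everything is generated in
# code at test time; no data files.

# The study-conditions regime: strong effects (2 log2 units), latent loading
# 1, noise sd 0.5, 20 samples per arm, ~2000 genes; case-state modules fully
# direction-coherent, control-state modules mixed.
contrast_specs <- function(n_case_mod = 4, n_control_mod = 4, size = 25) {
  case_dirs <- rep(c("up", "down"), length.out = n_case_mod)
  c(
    lapply(case_dirs, function(d) {
      planted_module(size, "mRNA", d, effect_log2 = 2, loading = 1,
                     homogeneity = 1, state = "case")
    }),
    lapply(seq_len(n_control_mod), function(i) {
      planted_module(size, "mRNA", "mixed", effect_log2 = 2, loading = 1,
                     state = "control")
    })
  )
}

contrast_config <- function(seed = 1, n_datasets = 1, shared = 1,
                            n_mrna = 2000, ...) {
  synthetic_config(n_mrna = n_mrna, n_lncrna = 10, n_case = 20, n_control = 20,
                   module_specs = contrast_specs(...), noise_sd = 0.5,
                   n_datasets = n_datasets, shared_gene_fraction = shared,
                   seed = seed)
}

# A small null config: no planted structure at all.
null_config <- function(seed = 1, n_mrna = 500, n_lncrna = 10,
                        n_case = 10, n_control = 10) {
  synthetic_config(n_mrna = n_mrna, n_lncrna = n_lncrna, n_case = n_case,
                   n_control = n_control, module_specs = list(),
                   noise_sd = 0.5, seed = seed)
}

# Ground-truth labels for the modules active in one state, 0 elsewhere.
planted_labels <- function(data, features, state) {
  planted <- attr(data, "planted")
  truth <- stats::setNames(rep(0L, length(features)), features)
  for (k in seq_along(planted)) {
    if (planted[[k]]$state == state) {
      truth[intersect(planted[[k]]$symbols, features)] <- k
    }
  }
  truth
}

# Run one state's network from DE features of one biotype.
run_network <- function(data, de, state, biotype = "mRNA", min_size = 10) {
  feats <- de$symbol[de$significant & de$biotype == biotype]
  corr <- pcc_matrix(data, feats, state)
  pw <- suppressWarnings(select_power(corr))
  tomat <- tom_matrix(adjacency_matrix(corr, pw$power))
  part <- detect_modules(tomat, min_size)
  list(features = feats, corr = corr, power = pw, tom = tomat,
       partition = part)
}

# Brute-force TOM by triple loop: the independent oracle.
tom_bruteforce <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      num <- a[i, j]
      for (u in seq_len(n)) {
        if (u != i && u != j) num <- num + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      denom <- min(ki, kj) + 1 - a[i, j]
      out[i, j] <- if (denom <= 0) 0 else num / denom
    }
  }
  out
}

# Exact upper-tail hypergeometric by combinatorial summation: the oracle.
hyper_upper_oracle <- function(k, m, N, n) {
  i <- k:min(m, n)
  sum(choose(m, i) * choose(N - m, n - i)) / choose(N, n)
}
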