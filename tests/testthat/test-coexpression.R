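test_that("pcc_matrix matches a hand-rolled covariance computation", {
  set.seed(51)
  mat <- matrix(rnorm(4 * 12), 4, 12,
                dimnames = list(paste0("G", 1:4), paste0("S", 1:12)))
  data <- expr_dataset(mat, rep(c("case", "control"), each = 6))
  r <- pcc_matrix(data, state = "case")
  # brute force: centred cross products over the case samples only
  x <- mat[, 1:6]
  manual <- matrix(1, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    xi <- x[i, ] - mean(x[i, ]); xj <- x[j, ] - mean(x[j, ])
    manual[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  expect_equal(unname(r), manual, tolerance = 1e-12)
  expect_equal(diag(r), setNames(rep(1, 4), paste0("G", 1:4)))

  # affine copies correlate +1 / -1
  mat2 <- rbind(a = mat[1, ], b = 2 * mat[1, ] + 1, c = -mat[1, ])
  d2 <- expr_dataset(mat2, rep(c("case", "control"), each = 6))
  r2 <- pcc_matrix(d2)
  expect_equal(r2["a", "b"], 1)
  expect_equal(r2["a", "c"], -1)

  # zero-variance feature: warned, correlations forced to 0
  mat3 <- rbind(a = mat[1, ], flat = rep(3, 12))
  d3 <- expr_dataset(mat3, rep(c("case", "control"), each = 6))
  expect_warning(r3 <- pcc_matrix(d3), "zero-variance")
  expect_equal(r3["flat", "a"], 0)
  expect_equal(r3["flat", "flat"], 1)
})

test_that("tom_matrix reproduces closed-form cases", {
  # two isolated nodes: overlap 0
  a0 <- matrix(0, 2, 2)
  expect_equal(tom_matrix(a0), diag(2))
  # i and j connected only to each other with full weight: overlap 1
  a1 <- matrix(c(0, 1, 1, 0), 2, 2)
  t1 <- tom_matrix(a1)
  expect_equal(t1[1, 2], 1)
  # all-zero off-diagonals give the zero-overlap matrix
  a2 <- diag(4) * 0
  expect_equal(tom_matrix(a2) - diag(4), matrix(0, 4, 4))
})

test_that("tom_matrix equals the brute-force triple loop on random instances", {
  set.seed(53)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    expect_lt(max(abs(tom_matrix(a) - tom_bruteforce(a))), 1e-12)
  }
})

test_that("scale-free fit is exact on a planted power-law degree sequence", {
  # ten distinct connectivities k_j = 2^j with counts 2^(10-j):
  # frequency ~ k^-1, exactly linear in log-log
  k <- rep(2^(1:10), times = 2^(10:1))
  fit <- suppressWarnings(scale_free_fit(k, n_bins = 10))
  expect_true(fit$ok)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, -1, tolerance = 1e-12)
  # frequency scale invariance: duplicating every profile leaves R^2 alone
  fit2 <- suppressWarnings(scale_free_fit(rep(k, 2), n_bins = 10))
  expect_equal(fit2$r_squared, fit$r_squared, tolerance = 1e-12)
  # degenerate: identical connectivities -> undefined fit, flagged not thrown
  expect_false(scale_free_fit(rep(3, 50))$ok)
})

test_that("power-law degrees fit better than Erdos-Renyi degrees", {
  set.seed(54)
  wins <- replicate(20, {
    k_pl <- pmin(floor(2 * (1 - runif(800))^(-1 / 1.5)), 100)  # truncated Pareto
    k_er <- rpois(800, lambda = 15)                            # ER-like degrees
    f1 <- scale_free_fit(k_pl); f2 <- scale_free_fit(k_er)
    f1$r_squared >= f2$r_squared
  })
  expect_gte(mean(wins), 0.95)
})

test_that("select_power returns deterministic diagnostics and respects the target", {
  cfg <- contrast_config(seed = 55, n_mrna = 800, n_case_mod = 2,
                         n_control_mod = 0, size = 20)
  d <- generate_dataset(cfg)
  de <- compute_de(d)
  corr <- pcc_matrix(d, de$symbol[de$significant & de$biotype == "mRNA"], "case")
  pw <- suppressWarnings(select_power(corr))
  pw_again <- suppressWarnings(select_power(corr))
  expect_identical(pw$power, pw_again$power)
  expect_equal(nrow(pw$table), 20)
  if (pw$reached_target) {
    expect_gte(pw$r_squared, 0.8)
    expect_lt(pw$slope, 0)
    # smallest qualifying power is returned
    earlier <- pw$table[pw$table$power < pw$power & pw$table$ok, ]
    expect_true(all(earlier$r_squared < 0.8 | earlier$slope >= 0))
  }
  expect_error(select_power(corr, integer(0)), "candidate")
})

test_that("module detection separates perfect blocks and honours min size", {
  block_tom <- function(sizes) {
    n <- sum(sizes)
    tm <- matrix(0, n, n)
    at <- 0
    for (s in sizes) { tm[at + 1:s, at + 1:s] <- 1; at <- at + s }
    diag(tm) <- 1
    dimnames(tm) <- list(paste0("F", 1:n), paste0("F", 1:n))
    tm
  }
  part <- detect_modules(block_tom(c(12, 15)), min_module_size = 10)
  expect_equal(part$n_modules, 2)
  expect_equal(unname(sort(part$sizes)), c(12, 15))
  # labels are size-ranked: module 1 is the largest
  expect_equal(unname(part$sizes["1"]), 15)

  # a block below min size joins the unassigned label 0
  part2 <- detect_modules(block_tom(c(12, 9)), min_module_size = 10)
  expect_equal(part2$n_modules, 1)
  expect_equal(sum(part2$labels == 0), 9)

  # fewer features than min size: everything unassigned
  part3 <- detect_modules(block_tom(5), min_module_size = 10)
  expect_equal(part3$n_modules, 0)
  expect_true(all(part3$labels == 0))

  expect_equal(module_colors(c(0, 1, 2)), c("grey", "turquoise", "blue"))
})

test_that("module detection is invariant to feature permutation up to labels", {
  cfg <- contrast_config(seed = 57, n_mrna = 600, n_case_mod = 3,
                         n_control_mod = 0, size = 15)
  d <- generate_dataset(cfg)
  de <- compute_de(d)
  net <- run_network(d, de, "case", min_size = 10)
  set.seed(58)
  perm <- sample(seq_len(nrow(net$tom)))
  part_p <- detect_modules(net$tom[perm, perm], 10)
  lab1 <- net$partition$labels[rownames(net$tom)]
  lab2 <- part_p$labels[rownames(net$tom)]
  # same partition as a set system: cross-table has one nonzero per row/col
  ct <- table(lab1, lab2)
  expect_true(all(rowSums(ct > 0) == 1) && all(colSums(ct > 0) == 1))
})

test_that("planted modules are recovered with high adjusted Rand index", {
  skip_if_not_installed("mclust")
  aris <- vapply(c(101, 202, 303), function(s) {
    cfg <- contrast_config(seed = s)
    d <- generate_dataset(cfg)
    de <- compute_de(d)
    net <- run_network(d, de, "case")
    truth <- planted_labels(d, net$features, "case")
    mclust::adjustedRandIndex(truth, net$partition$labels[net$features])
  }, numeric(1))
  expect_gte(median(aris), 0.7)
  expect_gte(min(aris), 0.5)
})

test_that("strong_edges thresholds absolute correlation with monotone nesting", {
  r <- diag(4)
  dimnames(r) <- list(paste0("G", 1:4), paste0("G", 1:4))
  expect_equal(nrow(strong_edges(r * 0 + diag(4), 0.7)), 0)
  r[1, 2] <- r[2, 1] <- 0.9
  r[1, 3] <- r[3, 1] <- -0.8
  r[2, 3] <- r[3, 2] <- 0.6
  e07 <- strong_edges(r, 0.7)
  e05 <- strong_edges(r, 0.5)
  expect_equal(nrow(e07), 2)
  expect_equal(nrow(e05), 3)
  key <- function(e) paste(e$source, e$target)
  expect_true(all(key(e07) %in% key(e05)))
  # negative correlations count by magnitude and keep their sign
  expect_equal(e07$weight[key(e07) == "G1 G3"], -0.8)
  # complete triangle at 0.9
  r3 <- matrix(0.9, 3, 3); diag(r3) <- 1
  dimnames(r3) <- list(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(nrow(strong_edges(r3, 0.7)), 3)
  # boundary is strict
  expect_equal(nrow(strong_edges(r3, 0.9)), 0)
})
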