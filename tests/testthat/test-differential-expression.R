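make_dataset <- function(mat, cond) {
  colnames(mat) <- paste0("S", seq_len(ncol(mat)))
  rownames(mat) <- paste0("G", seq_len(nrow(mat)))
  expr_dataset(mat, cond)
}

test_that("row-wise t statistics agree with stats::t.test", {
  set.seed(41)
  mat <- matrix(rnorm(30 * 9), 30, 9)
  cond <- rep(c("case", "control"), c(4, 5))
  data <- make_dataset(mat, cond)
  for (ve in c(FALSE, TRUE)) {
    de <- compute_de(data, var_equal = ve)
    ref <- apply(mat, 1, function(x) {
      t.test(x[1:4], x[5:9], var.equal = ve)$p.value
    })
    expect_equal(de$p_value, unname(ref), tolerance = 1e-12)
  }
})

test_that("fold change, direction and significance follow the declared rules", {
  set.seed(42)
  jitter <- matrix(rnorm(8, sd = 1e-3), 1)
  mat <- rbind(c(8, 8, 8, 8, 6, 6, 6, 6) + jitter,
               c(5, 5, 5, 5, 5, 5, 5, 5))
  cond <- rep(c("case", "control"), each = 4)
  de <- compute_de(make_dataset(mat, cond))
  # case ~8 vs control ~6: FC ~ 2^2 = 4, up, significant
  expect_equal(de$fold_change[1], 4, tolerance = 0.01)
  expect_equal(de$direction[1], "up")
  expect_true(de$significant[1])
  # identical constant values: FC 1, p 1 (degenerate zero-variance case)
  expect_equal(de$fold_change[2], 1)
  expect_equal(de$p_value[2], 1)
  expect_false(de$significant[2])

  # label swap inverts FC, flips direction, leaves p unchanged
  de_sw <- compute_de(make_dataset(mat, rev(cond)))
  expect_equal(de_sw$fold_change, 1 / de$fold_change, tolerance = 1e-12)
  expect_equal(de_sw$p_value, de$p_value, tolerance = 1e-12)
  expect_equal(de_sw$direction[1], "down")

  # down-significance requires max(FC, 1/FC) > threshold, strict
  mat3 <- rbind(rep(c(6, 8), each = 4) + matrix(rnorm(8, sd = 1e-3), 1))
  de3 <- compute_de(make_dataset(mat3, cond))
  expect_equal(de3$direction[1], "down")
  expect_true(de3$significant[1])
})

test_that("significant set shrinks as thresholds tighten", {
  set.seed(43)
  cfg <- null_config(seed = 43, n_mrna = 300)
  d <- generate_dataset(cfg)
  loose <- compute_de(d, alpha = 0.2, fc_threshold = 1.1)
  tight_a <- compute_de(d, alpha = 0.01, fc_threshold = 1.1)
  tight_f <- compute_de(d, alpha = 0.2, fc_threshold = 1.5)
  sig <- function(de) de$symbol[de$significant]
  expect_true(all(sig(tight_a) %in% sig(loose)))
  expect_true(all(sig(tight_f) %in% sig(loose)))
  # BH adjustment is at least as conservative
  bh <- compute_de(d, alpha = 0.2, fc_threshold = 1.1, adjust = "BH")
  expect_true(all(sig(bh) %in% sig(loose)))
})

test_that("null p-values are approximately uniform", {
  cfg <- synthetic_config(n_mrna = 10000, n_lncrna = 10, n_case = 10,
                          n_control = 10, module_specs = list(),
                          noise_sd = 0.5, seed = 17)
  de <- compute_de(generate_dataset(cfg))
  ks <- suppressWarnings(ks.test(de$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("consistent_de intersects direction-specific significant sets", {
  mk <- function(sig_up, sig_down, other = character(0)) {
    syms <- c(sig_up, sig_down, other)
    out <- data.frame(
      symbol = syms, biotype = "mRNA", p_value = 0.001,
      fold_change = c(rep(2, length(sig_up)), rep(0.5, length(sig_down)),
                      rep(1.1, length(other))),
      direction = c(rep("up", length(sig_up)), rep("down", length(sig_down)),
                    rep("up", length(other))),
      significant = c(rep(TRUE, length(sig_up) + length(sig_down)),
                      rep(FALSE, length(other))),
      stringsAsFactors = FALSE)
    class(out) <- c("differential_result", "data.frame")
    out
  }
  r1 <- mk(c("A", "B"), "C", "D")
  r2 <- mk(c("A", "D"), c("C", "B"))
  r3 <- mk("A", "C")
  sets <- consistent_de(list(r1, r2, r3))
  expect_equal(sets$consistent_up, "A")     # up-significant everywhere
  expect_equal(sets$consistent_down, "C")
  # B flips direction across datasets -> in neither set
  expect_false("B" %in% unlist(sets))
  expect_length(intersect(sets$consistent_up, sets$consistent_down), 0)
  expect_error(consistent_de(list(r1)), "at least 2")
  expect_error(consistent_de(list()), "empty")
})

test_that("strong planted shared modules are recovered as consistent DE genes", {
  cfg <- contrast_config(seed = 29, n_datasets = 3, shared = 1,
                         n_mrna = 600, n_case_mod = 2, n_control_mod = 0,
                         size = 20)
  des <- lapply(1:3, function(d) compute_de(generate_dataset(cfg, d)))
  sets <- consistent_de(des)
  d1 <- generate_dataset(cfg, 1)
  up_planted <- attr(d1, "planted")[[1]]$symbols
  down_planted <- attr(d1, "planted")[[2]]$symbols
  expect_gte(mean(up_planted %in% sets$consistent_up), 0.95)
  expect_gte(mean(down_planted %in% sets$consistent_down), 0.95)
})

test_that("de_fraction reports counts as rounded percentages of the background", {
  mk_counts <- function(n_up, n_down, n_null = 0) {
    out <- data.frame(
      symbol = paste0("G", seq_len(n_up + n_down + n_null)),
      biotype = "mRNA", p_value = 0.001,
      fold_change = rep(c(2, 0.5, 1), c(n_up, n_down, n_null)),
      direction = rep(c("up", "down", "up"), c(n_up, n_down, n_null)),
      significant = rep(c(TRUE, TRUE, FALSE), c(n_up, n_down, n_null)),
      stringsAsFactors = FALSE)
    class(out) <- c("differential_result", "data.frame")
    out
  }
  fr <- de_fraction(mk_counts(1888, 1609), 21655)
  expect_equal(fr$total_pct, 16.15)
  expect_equal(fr$up_pct, 53.99)
  fr2 <- de_fraction(mk_counts(1155, 1227), 21655)
  expect_equal(fr2$up_pct, 48.49)
  expect_equal(fr2$down_pct, 51.51)
  # no significant features: all zero, no division error
  fr0 <- de_fraction(mk_counts(0, 0, 5), 100)
  expect_equal(fr0$total_pct, 0)
  expect_equal(fr0$up_pct, 0)
  expect_error(de_fraction(mk_counts(5, 5), 0), "positive")
  expect_error(de_fraction(mk_counts(5, 5), 3), "smaller")
})
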