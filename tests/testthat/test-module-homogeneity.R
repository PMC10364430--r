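test_that("module classification uses a strict over-threshold rule", {
  # 19 up of 20: ratio 0.95, over 0.90 -> up
  row <- classify_module(rep(c("up", "down"), c(19, 1)), 0.9)
  expect_equal(row$category, "up")
  expect_equal(row$up_ratio, 0.95)
  # all members one direction
  expect_equal(classify_module(rep("up", 7))$category, "up")
  expect_equal(classify_module(rep("down", 7))$category, "down")
  # boundary: exactly the threshold is mixed, for both conventions
  expect_equal(classify_module(rep(c("up", "down"), c(9, 1)), 0.9)$category,
               "mixed")
  expect_equal(classify_module(rep(c("up", "down"), c(19, 1)), 0.95)$category,
               "mixed")
  # just over the stricter threshold
  expect_equal(classify_module(rep(c("up", "down"), c(39, 1)), 0.95)$category,
               "up")
  expect_error(classify_module(character(0)), "empty")
  expect_error(classify_module(rep("up", 5), threshold = 0.4), "threshold")
})

test_that("classification is symmetric under direction flip", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    dirs <- sample(c("up", "down"), n, replace = TRUE)
    flip <- ifelse(dirs == "up", "down", "up")
    a <- classify_module(dirs, 0.9)$category
    b <- classify_module(flip, 0.9)$category
    expect_equal(b, switch(a, up = "down", down = "up", mixed = "mixed"))
  }
})

fake_partition <- function(members_by_module) {
  labels <- integer(0)
  for (m in seq_along(members_by_module)) {
    labels <- c(labels, setNames(rep(m, length(members_by_module[[m]])),
                                 members_by_module[[m]]))
  }
  structure(list(labels = labels,
                 sizes = setNames(lengths(members_by_module),
                                  seq_along(members_by_module)),
                 n_modules = length(members_by_module),
                 min_module_size = 5L, cut_height_used = NA_real_),
            class = "module_partition")
}

fake_de <- function(up, down) {
  out <- data.frame(symbol = c(up, down), biotype = "mRNA", p_value = 1e-4,
                    fold_change = rep(c(2, 0.5), c(length(up), length(down))),
                    direction = rep(c("up", "down"), c(length(up), length(down))),
                    significant = TRUE, stringsAsFactors = FALSE)
  class(out) <- c("differential_result", "data.frame")
  out
}

test_that("summarize_state aggregates module categories with printed-table rounding", {
  # module of 12 up, module of 12 down, module of 6/6 mixed
  part <- fake_partition(list(paste0("U", 1:12), paste0("D", 1:12),
                              c(paste0("MU", 1:6), paste0("MD", 1:6))))
  de <- fake_de(c(paste0("U", 1:12), paste0("MU", 1:6)),
                c(paste0("D", 1:12), paste0("MD", 1:6)))
  s <- summarize_state(part, de, 0.9, state = "case", dataset_id = "X")
  expect_equal(s$n_modules, 3)
  expect_equal(unname(s$counts), c(1, 1, 1))
  expect_equal(unname(s$pct), c(33.33, 33.33, 33.33))
  expect_equal(sum(s$counts), s$n_modules)
  # rounded percentages sum to 100 within rounding error
  expect_lt(abs(sum(s$pct) - 100), 0.05)

  # member missing from the DE table: error names it
  part_bad <- fake_partition(list(c(paste0("U", 1:11), "GHOST")))
  expect_error(summarize_state(part_bad, de), "GHOST")

  # empty partition: empty summary, no division
  s0 <- summarize_state(fake_partition(list()), de)
  expect_equal(s0$n_modules, 0)
  expect_true(all(is.na(s0$pct)))
})

test_that("percentage cells match printed-table reference values", {
  expect_equal(percent_of(15, 54), 27.78)
  expect_equal(percent_of(26, 55), 47.27)
  expect_equal(percent_of(3, 57), 5.26)
  expect_equal(percent_of(21, 54), 38.89)
  expect_equal(percent_of(42, 49, 1), 85.7)
  expect_equal(percent_of(29, 34, 1), 85.3)
})

test_that("homogeneity_profile contrasts states and reports size independence", {
  part_case <- fake_partition(list(paste0("A", 1:10), paste0("B", 1:14)))
  # scores 1.0 and 13/14: both over threshold, but not tied
  de_case <- fake_de(c(paste0("A", 1:10), paste0("B", 1:13)), "B14")
  s_case <- summarize_state(part_case, de_case, state = "case", dataset_id = "D1")
  part_ctrl <- fake_partition(list(paste0("C", 1:10), paste0("E", 1:14)))
  de_ctrl <- fake_de(c(paste0("C", 1:5), paste0("E", 1:7)),
                     c(paste0("C", 6:10), paste0("E", 8:14)))
  s_ctrl <- summarize_state(part_ctrl, de_ctrl, state = "control", dataset_id = "D1")

  prof <- homogeneity_profile(list(s_case, s_ctrl))
  expect_equal(unname(prof$homogeneous_fraction["case"]), 1)
  expect_equal(unname(prof$homogeneous_fraction["control"]), 0)
  expect_lt(prof$rank_test_p, 0.2)
  expect_equal(nrow(prof$modules), 4)

  # identical score distributions in both states: rank test p ~ 1
  s_ctrl2 <- s_case; s_ctrl2$state <- "control"
  prof2 <- homogeneity_profile(list(s_case, s_ctrl2))
  expect_gt(prof2$rank_test_p, 0.95)

  # a state with no modules is excluded with a warning
  s_empty <- summarize_state(fake_partition(list()), de_case, state = "control")
  expect_warning(prof3 <- homogeneity_profile(list(s_case, s_empty)),
                 "excluded")
  expect_equal(names(prof3$homogeneous_fraction), "case")
})

test_that("case-state modules classify homogeneous, control-state mixed, in synthesis", {
  cfg <- contrast_config(seed = 71)
  d <- generate_dataset(cfg)
  de <- compute_de(d)
  net_case <- run_network(d, de, "case")
  net_ctrl <- run_network(d, de, "control")
  s_case <- summarize_state(net_case$partition, de, 0.9, state = "case")
  s_ctrl <- summarize_state(net_ctrl$partition, de, 0.9, state = "control")
  expect_gte(mean(s_case$modules$category != "mixed"), 0.8)
  expect_lte(mean(s_ctrl$modules$category != "mixed"), 0.3)
})
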