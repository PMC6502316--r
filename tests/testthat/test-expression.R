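toy_matrix <- function() {
  m <- rbind(g1 = c(0, 0, 0), g2 = c(0, 1, 3), g3 = c(2, 2, 2))
  colnames(m) <- c("root", "leaf", "flower")
  m
}

test_that("filter_and_transform removes all-zero genes and log-transforms", {
  lm <- filter_and_transform(toy_matrix())
  expect_equal(attr(lm, "n_removed"), 1L)
  expect_equal(attr(lm, "removed_genes"), "g1")
  expect_equal(rownames(lm), c("g2", "g3"))  # order preserved
  expect_equal(lm["g2", ], c(root = 0, leaf = 1, flower = 2))  # log2(x+1)

  bad <- toy_matrix(); bad[2L, 1L] <- -1
  expect_error(filter_and_transform(bad), "non-negative")
  dup <- toy_matrix(); colnames(dup) <- c("root", "root", "flower")
  expect_error(filter_and_transform(dup), "unique")
})

test_that("clustering merges identical profiles first and recovers groups", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  colnames(m) <- c("t1", "t2", "t3")
  cl <- cluster_expression(m, k = 2L)
  expect_equal(cl$tree$height[1L], 0)
  expect_equal(cl$groups[["a"]], cl$groups[["b"]])
  expect_false(cl$groups[["a"]] == cl$groups[["c"]])

  sim <- simulate_expression(
    groups = list(list(size = 20L, high = "root"),
                  list(size = 20L, high = "flower")), seed = 14)
  lm <- filter_and_transform(sim$fpkm)
  cl2 <- cluster_expression(lm, k = 2L)
  expect_equal(length(unique(paste(cl2$groups, sim$truth))), 2L)

  single <- m[1L, , drop = FALSE]
  expect_equal(unname(cluster_expression(single, 1L)$groups), 1L)
  expect_error(cluster_expression(m, 5L), "exceeds")
})

test_that("clustering is invariant to gene order up to relabelling", {
  sim <- simulate_expression(
    groups = list(list(size = 12L, high = c("root", "stem")),
                  list(size = 10L, high = "flower"),
                  list(size = 8L, high = character(0))), seed = 15)
  lm <- filter_and_transform(sim$fpkm)
  set.seed(16)
  perm <- sample(nrow(lm))
  g1 <- cluster_expression(lm, k = 2L)$groups
  g2 <- cluster_expression(lm[perm, ], k = 2L)$groups[names(g1)]
  # size-ranked relabelling makes the partitions directly comparable
  expect_equal(unname(g1), unname(g2))
})

test_that("expression_by_subset cross-tabulates with percentages", {
  groups <- c(g1 = 1L, g2 = 1L)
  subsets <- c(g1 = "Br-1i-Q-SF", g2 = "Br-1i-Q-SF")
  xt <- expression_by_subset(groups, subsets)
  expect_equal(xt$counts["1", "Br-1i-Q-SF"], 2L)
  expect_equal(xt$percent["1", "Br-1i-Q-SF"], 100)

  expect_warning(empty <- expression_by_subset(c(a = 1L),
                                               c(b = "Br-3i-SF")),
                 "no genes shared")
  expect_equal(sum(empty$counts), 0L)
  expect_setequal(empty$dropped, c("a", "b"))

  # independent tally oracle on a synthetic joint labelling
  set.seed(17)
  ids <- sprintf("g%02d", 1:30)
  g <- setNames(sample(1:3, 30, replace = TRUE), ids)
  s <- setNames(sample(SUBSET_LEVELS[1:4], 30, replace = TRUE), ids)
  xt2 <- expression_by_subset(g, s)
  for (gi in 1:3) for (si in SUBSET_LEVELS[1:4]) {
    expect_equal(xt2$counts[as.character(gi), si],
                 sum(g == gi & s == si))
  }
})

test_that("ortholog expression correlation: per-pair and aggregate", {
  tissues <- c("root", "stem", "leaf", "flower", "silique")
  ma <- rbind(a1 = c(1, 2, 3, 4, 5), a2 = c(5, 4, 3, 2, 1),
              a3 = c(2, 2, 2, 2, 2))
  colnames(ma) <- tissues
  mb <- rbind(b1 = c(2, 4, 6, 8, 10), b2 = c(1, 2, 3, 4, 5),
              b3 = c(1, 1, 1, 1, 1))
  colnames(mb) <- tissues
  pairs <- data.frame(id_a = c("a1", "a2", "a3", "zz"),
                      id_b = c("b1", "b2", "b3", "b1"),
                      stringsAsFactors = FALSE)
  res <- ortholog_expression_correlation(pairs, ma, mb, tissues)
  expect_equal(res$n_pairs, 3L)  # zz skipped
  expect_equal(res$per_pair$r[1L], 1)
  expect_equal(res$per_pair$r[2L], -1)
  expect_true(is.na(res$per_pair$r[3L]))  # zero variance flagged
  expect_true(res$aggregate_r >= -1 && res$aggregate_r <= 1)
  expect_equal(res$n_high, 1L)
})

test_that("ddct_fold_change implements 2^-ddCt over replicate means", {
  tbl <- expand.grid(gene = "g1", condition = c("CK", "salt"),
                     timepoint = c(1L, 3L), replicate = 1:3,
                     stringsAsFactors = FALSE)
  tbl$ct_target <- 20
  tbl$ct_reference <- 15
  fc <- ddct_fold_change(tbl, control = "CK")
  expect_equal(fc$fold_change, c(1, 1))  # treated == control

  drop1 <- tbl
  drop1$ct_target[drop1$condition == "salt"] <- 19  # one-cycle drop
  expect_equal(ddct_fold_change(drop1, "CK")$fold_change, c(2, 2))

  # replicates averaged before dCt: hand-computed arithmetic
  reps <- data.frame(gene = "g1", condition = rep(c("CK", "salt"), each = 3),
                     timepoint = 1L, replicate = 1:3,
                     ct_target = c(20.0, 20.2, 19.8, 18.0, 18.4, 18.2),
                     ct_reference = c(15.0, 15.1, 14.9, 15.2, 15.0, 15.1))
  fc2 <- ddct_fold_change(reps, "CK")
  dct_ck <- mean(c(20.0, 20.2, 19.8)) - mean(c(15.0, 15.1, 14.9))
  dct_sa <- mean(c(18.0, 18.4, 18.2)) - mean(c(15.2, 15.0, 15.1))
  expect_equal(fc2$fold_change, 2^(-(dct_sa - dct_ck)))
  expect_gt(fc2$fold_change, 0)

  missing_ref <- tbl; missing_ref$ct_reference[1L] <- NA
  expect_error(ddct_fold_change(missing_ref, "CK"), "reference")
  no_ctrl <- tbl[tbl$condition != "CK", ]
  expect_error(ddct_fold_change(no_ctrl, "CK"), "control")
})
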