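test_that("bagged trees emit vote fractions, separate blobs, and are deterministic", {
  b <- blob_data(n = 80, p = 4, gap = 5, seed = 21)
  fit <- bagged_trees(b$x, b$y, seed = 2)
  pr <- predict(fit, b$x)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_gte(mean(pr[b$y == 1]), 0.9)
  expect_lte(mean(pr[b$y == 0]), 0.1)
  fit2 <- bagged_trees(b$x, b$y, seed = 2)
  expect_identical(predict(fit2, b$x), pr)
  fit3 <- bagged_trees(b$x, b$y, seed = 3)
  expect_false(identical(predict(fit3, b$x), pr))
  expect_error(bagged_trees(b$x, rep(0, 80)), class = "fusedr_degenerate_label")
  expect_error(predict(fit, b$x[, 1:2]), class = "fusedr_shape")
})

test_that("AUC matches the pairwise-counting oracle and its invariances", {
  expect_equal(compute_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(compute_auc(1:6, c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(compute_auc(6:1, c(0, 0, 0, 1, 1, 1)), 0)
  # brute-force pair counting oracle on random instances with ties
  withr::with_seed(22, {
    for (i in 1:100) {
      n <- sample(6:20, 1)
      s <- sample(seq(0, 1, 0.1), n, replace = TRUE)
      y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      pos <- s[y == 1]; neg <- s[y == 0]
      pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
      expect_equal(compute_auc(s, y), mean(pairs))
    }
  })
  # invariance under strictly monotone transforms
  s <- c(0.2, 0.9, 0.4, 0.55, 0.1)
  y <- c(0, 1, 1, 0, 0)
  expect_equal(compute_auc(exp(3 * s) - 1, y), compute_auc(s, y))
  expect_error(compute_auc(s, rep(1, 5)), class = "fusedr_undefined_auc")
})

test_that("AUC agrees with an established ROC implementation", {
  withr::with_seed(27, {
    for (i in 1:10) {
      s <- runif(40)
      y <- c(0, 1, rbinom(38, 1, 0.4))
      expect_equal(compute_auc(s, y),
                   as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                  direction = "<"))))
    }
  })
})

test_that("grouped CV never splits a group and has the configured length", {
  withr::with_seed(23, {
    groups <- rep(sprintf("g%02d", 1:12), each = 5)
    labels <- rep(rep(0:1, 6), each = 5)
    for (s in 1:5) {
      fid <- fusedr:::group_folds(groups, labels, 3, s)
      expect_true(all(tapply(fid, groups, function(v) length(unique(v))) == 1))
      expect_equal(sort(unique(fid)), 1:3)
    }
  })
  b <- blob_data(n = 60, p = 4, gap = 5, seed = 24)
  ev <- repeated_grouped_cv(b$x, b$y, repeats = 4, seed = 1)
  expect_length(ev$auc_per_repeat, 4)
  expect_equal(ev$mean, mean(ev$auc_per_repeat))
  expect_true(all(ev$auc_per_repeat >= 0.95))
  expect_error(repeated_grouped_cv(b$x, b$y, groups = rep("g1", 60)),
               class = "fusedr_fold")
})

test_that("grouped CV with per-patient groups keeps group members together", {
  withr::with_seed(25, {
    groups <- rep(sprintf("p%02d", 1:10), each = 6)
    y <- rep(rep(0:1, 5), each = 6)
    x <- matrix(rnorm(60 * 3), 60, 3) + 3 * y
    ev <- repeated_grouped_cv(x, y, groups = groups, repeats = 3, seed = 9)
    expect_length(ev$auc_per_repeat, 3)
    expect_true(all(ev$auc_per_repeat > 0.9))
  })
})

test_that("Kruskal-Wallis matches the rank-sum formula oracle", {
  kw <- kruskal_wallis(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(kw$H, 7.2)   # 12/(N(N+1)) * sum(R_j^2/n_j) - 3(N+1), N = 9
  expect_equal(kw$df, 2)
  expect_equal(kw$p, stats::pchisq(7.2, 2, lower.tail = FALSE))
  # identical groups: H = 0 under tie correction, p ~ 1
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  kw0 <- kruskal_wallis(same)
  expect_equal(kw0$H, 0)
  expect_gte(kw0$p, 0.99)
  # invariance under a common strictly monotone transform
  g <- list(a = c(0.61, 0.70, 0.66), b = c(0.71, 0.74, 0.80))
  g2 <- lapply(g, function(v) log(v + 1) * 10)
  expect_equal(kruskal_wallis(g)$H, kruskal_wallis(g2)$H)
  expect_error(kruskal_wallis(list(a = 1:3)), class = "fusedr_input")
})

test_that("Dunn-Bonferroni flags separated groups and respects monotonicity", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  pc0 <- pairwise_compare(same)
  expect_false(any(pc0$significant))
  withr::with_seed(26, {
    a <- rnorm(25, 0, 1)
    b <- rnorm(25, 0.2, 1)        # overlapping
    c <- rnorm(25, 10, 1)         # far separated
    pc <- pairwise_compare(list(a = a, b = b, c = c))
    sig <- pc[pc$significant, ]
    expect_setequal(paste(sig$group1, sig$group2),
                    c("a c", "b c"))
    expect_true(all(pc$p_adj >= pc$p))
  })
})

test_that("evaluation results summarize and compare cleanly", {
  e1 <- fusedr:::new_evaluation_result(c(0.7, 0.72, 0.74), "s1", 1)
  e2 <- fusedr:::new_evaluation_result(c(0.9, 0.92, 0.91), "s2", 1)
  cmp <- compare_strategies(list(s1 = e1, s2 = e2))
  expect_equal(nrow(cmp$auc), 6)
  expect_true(cmp$kruskal$H > 0)
  expect_equal(nrow(cmp$pairwise), 1)
  g <- glance(e1)
  expect_equal(g$mean_auc, mean(c(0.7, 0.72, 0.74)))
  expect_equal(nrow(tidy(e1)), 3)
})
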