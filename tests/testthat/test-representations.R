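test_that("gaussian kernel matches closed forms and is PSD", {
  x <- matrix(c(0, 0, 1, 0, 0, 2), ncol = 2, byrow = TRUE)
  k <- compute_kernel(x, "gaussian", sigma = 1)
  expect_equal(diag(k$matrix), rep(1, 3))
  expect_equal(k$matrix[1, 2], exp(-0.5))        # ||x - z|| = 1, sigma = 1
  expect_equal(k$matrix[1, 3], exp(-2))          # distance 2
  withr::with_seed(4, {
    for (i in 1:5) {
      xx <- matrix(rnorm(8 * 3), 8, 3)
      km <- compute_kernel(xx, "gaussian")$matrix
      expect_lt(max(abs(km - t(km))), 1e-10)
      ev <- eigen(km, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-8 * max(ev))
      expect_true(all(km > 0 & km <= 1 + 1e-12))
    }
  })
  expect_error(compute_kernel(x, "gaussian", sigma = -1),
               class = "fusedr_parameter")
})

test_that("linear kernel equals the all-pairs dot-product oracle", {
  x <- withr::with_seed(7, matrix(rnorm(18), 6, 3))
  k <- compute_kernel(x, "linear")
  oracle <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) oracle[i, j] <- sum(x[i, ] * x[j, ])
  expect_equal(unname(k$matrix), oracle, tolerance = 1e-12)
})

test_that("PCA matches the covariance-eigendecomposition oracle", {
  x <- withr::with_seed(9, matrix(rnorm(40), 10, 4))
  p <- fit_pca(x, 3)
  eo <- eigen(cov(x), symmetric = TRUE)
  centered <- scale(x, center = TRUE, scale = FALSE)
  for (j in 1:3) {
    oracle_scores <- centered %*% eo$vectors[, j]
    # equality up to column sign
    err <- min(max(abs(p$coords[, j] - oracle_scores)),
               max(abs(p$coords[, j] + oracle_scores)))
    expect_lt(err, 1e-8)
  }
  expect_equal(p$eigenvalues, eo$values[1:3], tolerance = 1e-10)
  # scores are centered, total variance equals retained eigenvalue sum
  expect_lt(max(abs(colMeans(p$coords))), 1e-10)
  expect_equal(sum(apply(p$coords, 2, var)), sum(p$eigenvalues),
               tolerance = 1e-8)
})

test_that("PCA on collinear points puts all variance on one component", {
  t_par <- seq(0, 1, length.out = 12)
  x <- cbind(2 * t_par, -3 * t_par)
  p <- fit_pca(x, 2)
  expect_gt(p$eigenvalues[1], 0)
  expect_lt(p$eigenvalues[2] / p$eigenvalues[1], 1e-12)
  expect_error(fit_pca(x, 5), class = "fusedr_parameter")
})

test_that("LLE reconstruction weights sum to one and order a noiseless line", {
  x <- cbind(seq_len(40) * 0.5, rep(0, 40))
  l <- fit_lle(x, d = 1, k = 5)
  expect_lt(max(abs(rowSums(l$params$weights) - 1)), 1e-9)
  rho <- suppressWarnings(cor(l$coords[, 1], seq_len(40), method = "spearman"))
  expect_equal(abs(rho), 1)
  expect_error(fit_lle(x, d = 1, k = 40), class = "fusedr_parameter")
  expect_error(fit_lle(x, d = 6, k = 5), class = "fusedr_parameter")
})

test_that("affinity matrix has unit diagonal, symmetry, and closed-form entries", {
  x <- matrix(c(0, 1, 2), ncol = 1)
  a <- build_affinity(x, sigma = 1)
  expect_equal(diag(a$matrix), rep(1, 3))
  expect_lt(max(abs(a$matrix - t(a$matrix))), 1e-12)
  expect_equal(a$matrix[1, 3], exp(-2))
  expect_error(build_affinity(matrix(1, 4, 2)), class = "fusedr_sigma_degenerate")
})

test_that("graph_embed solves the 2x2 case analytically", {
  g <- graph_embed(matrix(c(0, 1, 1, 0), 2, 2), 1)
  expect_equal(g$eigenvalues, -1)
  expect_equal(abs(g$coords[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  expect_equal(sum(g$coords[, 1]), 0, tolerance = 1e-12)
})

test_that("graph_embed satisfies the generalized eigen contract on random affinities", {
  for (s in 1:10) {
    W <- random_affinity(20, seed = 100 + s)
    emb <- graph_embed(W, 4)
    D <- rowSums(W)
    for (j in 1:4) {
      y <- emb$coords[, j]
      expect_lt(max(abs(W %*% y - emb$eigenvalues[j] * D * y)), 1e-8)
      expect_lt(abs(sum(y^2 * D) - 1), 1e-8)
    }
    # eigenvalues below the trivial solution, within Perron-Frobenius bounds
    expect_true(all(emb$eigenvalues < 1))
    expect_true(all(abs(emb$eigenvalues) <= 1 + 1e-10))
    # agreement with a dense generalized-eigensolver oracle
    o <- dense_ge_oracle(W)
    expect_equal(emb$eigenvalues, o$values[2:5], tolerance = 1e-8)
  }
})

test_that("two disconnected cliques separate with opposite signs", {
  W <- matrix(0, 10, 10)
  W[1:5, 1:5] <- 1
  W[6:10, 6:10] <- 1
  g <- graph_embed(W, 1)
  expect_true(all(g$coords[1:5, 1] * g$coords[6:10, 1] < 0))
  expect_lt(diff(range(g$coords[1:5, 1])), 1e-10)
})

test_that("graph_embed rejects degenerate graphs and bad d", {
  W <- matrix(0, 3, 3)
  expect_error(graph_embed(W, 1), class = "fusedr_degenerate_graph")
  expect_error(graph_embed(random_affinity(5, 1), 5),
               class = "fusedr_parameter")
})

test_that("decision scores are probabilities, out-of-fold, and discriminative", {
  b <- blob_data(n = 100, p = 5, gap = 5, seed = 1)
  dec <- compute_decisions(b$x, b$y, folds = 3, seed = 1)
  expect_true(all(dec$scores >= 0 & dec$scores <= 1))
  expect_true(all(dec$out_of_fold))
  expect_gt(compute_auc(dec$scores, b$y), 0.95)
  # unlabeled samples get model-based scores
  y_semi <- b$y
  y_semi[1:10] <- NA
  dec2 <- compute_decisions(b$x, y_semi, folds = 3, seed = 1)
  expect_false(any(dec2$out_of_fold[1:10]))
  expect_true(all(dec2$scores[1:10] >= 0 & dec2$scores[1:10] <= 1))
  expect_error(compute_decisions(b$x, rep(1, 100)),
               class = "fusedr_degenerate_label")
})

test_that("decision scores on permuted labels stay near chance", {
  b <- blob_data(n = 80, p = 5, gap = 5, seed = 2)
  aucs <- vapply(1:10, function(s) {
    yp <- withr::with_seed(s, sample(b$y))
    dec <- compute_decisions(b$x, yp, folds = 3, seed = s)
    compute_auc(dec$scores, yp)
  }, 0)
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})
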