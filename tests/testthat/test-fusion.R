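test_that("direct fusion handles concatenation, means, and degenerate weights", {
  a <- matrix(rnorm(15), 5, 3)
  b <- matrix(rnorm(20), 5, 4)
  cc <- direct_fuse(list(a, b), "concatenate")
  expect_equal(dim(cc$values), c(5, 7))
  expect_error(direct_fuse(list(a, b), "mean"), class = "fusedr_shape")
  m <- direct_fuse(list(a, a), "mean")
  expect_equal(m$values, a)
  w <- direct_fuse(list(a, matrix(0, 5, 3)), "weighted_sum", weights = c(1, 0))
  expect_equal(w$values, a)
  expect_error(direct_fuse(list(a, list())), class = "fusedr_type")
})

test_that("decision AND is the probability product with its algebraic laws", {
  expect_equal(decision_and(list(0.8, 0.5))$values[1, 1], 0.4)
  expect_equal(decision_and(list(c(0, 1), c(0.7, 1)))$values[, 1], c(0, 1))
  withr::with_seed(11, {
    h <- replicate(3, runif(20), simplify = FALSE)
    out <- decision_and(h)$values[, 1]
    # commutative and associative
    expect_equal(decision_and(rev(h))$values[, 1], out)
    # monotone: raising any one argument never lowers the output
    h2 <- h
    h2[[2]] <- pmin(1, h2[[2]] + runif(20, 0, 0.2))
    expect_true(all(decision_and(h2)$values[, 1] >= out - 1e-15))
  })
  expect_error(decision_and(list(c(0.5, 1.2))), class = "fusedr_validation")
})

test_that("co-association quantifications behave like metrics or identities", {
  y <- withr::with_seed(12, matrix(rnorm(20), 10, 2))
  y[2, ] <- y[7, ]  # duplicated point
  Wd <- build_coassociation(fusedr:::new_lowdim(y, "pca"), "distance")
  expect_equal(Wd$kind, "distance")
  expect_equal(diag(Wd$matrix), rep(0, 10))
  expect_lt(Wd$matrix[2, 7], 1e-6)
  # triangle inequality on random triples
  withr::with_seed(13, {
    for (t in 1:20) {
      ijk <- sample(10, 3)
      expect_lte(Wd$matrix[ijk[1], ijk[2]],
                 Wd$matrix[ijk[1], ijk[3]] + Wd$matrix[ijk[3], ijk[2]] + 1e-12)
    }
  })
  K <- compute_kernel(y, "gaussian")
  Wk <- build_coassociation(K, "kernel_values")
  expect_identical(Wk$matrix, K$matrix)
  expect_error(build_coassociation(K, "distance"), class = "fusedr_type")
})

test_that("median combination is idempotent, permutation-invariant, and matches a sort oracle", {
  mk <- function(seed) fusedr:::new_coassociation(random_affinity(8, seed),
                                                  "affinity")
  Ws <- lapply(1:5, mk)
  med <- combine_coassociation(Ws, "median")
  # per-entry sort oracle
  for (i in 1:8) for (j in 1:8) {
    vals <- sort(vapply(Ws, function(w) w$matrix[i, j], 0))
    expect_equal(med$matrix[i, j], (vals[3]), tolerance = 1e-12)
  }
  expect_equal(combine_coassociation(Ws[c(3, 1, 5, 2, 4)], "median")$matrix,
               med$matrix)
  same <- combine_coassociation(list(Ws[[1]], Ws[[1]], Ws[[1]]), "median")
  expect_equal(same$matrix, Ws[[1]]$matrix)
  expect_error(combine_coassociation(list(Ws[[1]],
    fusedr:::new_coassociation(matrix(0, 8, 8), "distance")), "median"),
    class = "fusedr_type")
})

test_that("coassociation_embed honors the generalized eigen contract", {
  for (s in 1:5) {
    W <- fusedr:::new_coassociation(random_affinity(15, 200 + s), "affinity")
    fr <- coassociation_embed(W, 4)
    D <- rowSums(W$matrix)
    # normalization R' D R = I per column
    expect_lt(max(abs(crossprod(fr$values, fr$values * D) - diag(4))), 1e-8)
    o <- dense_ge_oracle(W$matrix)
    expect_equal(fr$provenance$eigenvalues, o$values[2:5], tolerance = 1e-8)
    for (j in 1:4) {
      y <- fr$values[, j]
      expect_lt(max(abs(W$matrix %*% y -
                        fr$provenance$eigenvalues[j] * D * y)), 1e-8)
    }
  }
  # single-representation reduction: embed of one affinity equals graph_embed
  W1 <- fusedr:::new_coassociation(random_affinity(12, 250), "affinity")
  expect_equal(coassociation_embed(W1, 3)$values,
               unname(graph_embed(W1, 3)$coords), tolerance = 1e-12)
})

test_that("multi-kernel embedding reduces to the co-association problem and solves Eq's contract", {
  for (s in 1:5) {
    W <- fusedr:::new_coassociation(random_affinity(12, 300 + s), "affinity")
    ce <- coassociation_embed(W, 3)
    mk <- multikernel_embed(list(diag(12)), W, 3, ridge = 0)
    expect_lt(max(abs(ce$values - mk$values)), 1e-10)
  }
  # full-rank random kernel, ridge 0: residual against the dense oracle
  withr::with_seed(31, {
    for (s in 1:3) {
      Z <- matrix(rnorm(144), 12, 12)
      K <- crossprod(Z) + diag(12)          # full rank, symmetric PD
      W <- random_affinity(12, 400 + s)
      Dg <- rowSums(W)
      mk <- multikernel_embed(list(K), fusedr:::new_coassociation(W, "affinity"),
                              3, ridge = 0)
      A <- K %*% W %*% K
      B <- K %*% diag(Dg) %*% K
      # recover R from Y = K R and check A R = lambda B R
      for (j in 1:3) {
        r <- solve(K, mk$values[, j])
        lam <- mk$provenance$eigenvalues[j]
        expect_lt(max(abs(A %*% r - lam * B %*% r)) / max(abs(A %*% r)), 1e-8)
      }
    }
  })
  # degenerate weights select a single kernel exactly
  withr::with_seed(32, {
    K1 <- crossprod(matrix(rnorm(100), 10, 10)) + diag(10)
    K2 <- crossprod(matrix(rnorm(100), 10, 10)) + diag(10)
    W <- fusedr:::new_coassociation(random_affinity(10, 500), "affinity")
    both <- multikernel_embed(list(K1, K2), W, 2, weights = c(1, 0), ridge = 0)
    solo <- multikernel_embed(list(K1), W, 2, ridge = 0)
    expect_equal(both$values, solo$values, tolerance = 1e-10)
  })
  # rank-deficient right-hand side without ridge is a categorized error
  Klow <- tcrossprod(matrix(rnorm(12), 6, 2))
  Wok <- fusedr:::new_coassociation(random_affinity(6, 501), "affinity")
  expect_error(multikernel_embed(list(Klow), Wok, 2, ridge = 0),
               class = "fusedr_rank_deficiency")
})

test_that("weight learning recovers the informative kernel and the simplex contract", {
  expect_equal(learn_modality_weights(list(1), c(0, 1)), 1)
  b <- blob_data(n = 60, p = 4, gap = 4, seed = 14)
  noise <- withr::with_seed(15, matrix(rnorm(60 * 4), 60, 4))
  Ks <- list(compute_kernel(b$x, "gaussian"), compute_kernel(noise, "gaussian"))
  w <- learn_modality_weights(Ks, b$y, "fisher", grid_step = 0.1, d = 3)
  expect_gte(w[1], 0.5)
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1, tolerance = 1e-9)
  # the optimum is at least as good as the best simplex corner
  search <- attr(w, "search")
  corners <- search$objective[search$candidate %in% c("1/0", "0/1")]
  expect_gte(attr(w, "objective"), max(corners) - 1e-12)
})

test_that("Procrustes alignment inverts known similarity transforms", {
  y <- withr::with_seed(16, matrix(rnorm(40), 20, 2))
  self <- procrustes_align(y, y)
  expect_lt(self$residual, 1e-10)
  expect_equal(self$transform$scale, 1, tolerance = 1e-10)
  expect_lt(max(abs(self$transform$rotation - diag(2))), 1e-8)
  theta <- pi / 2
  R90 <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  rotated <- y %*% R90
  back <- procrustes_align(rotated, y)
  expect_lt(back$residual, 1e-8)
  expect_lt(max(abs(crossprod(back$transform$rotation) - diag(2))), 1e-8)
  # reflections are allowed and inverted too
  refl <- y %*% diag(c(-1, 1)) * 2.5 + 3
  backr <- procrustes_align(refl, y)
  expect_lt(backr$residual, 1e-8)
  expect_error(procrustes_align(y, y[, 1, drop = FALSE]),
               class = "fusedr_shape")
})

test_that("Procrustes residual is invariant under a common orthogonal transform", {
  withr::with_seed(17, {
    y1 <- matrix(rnorm(30), 15, 2)
    y2 <- matrix(rnorm(30), 15, 2)
    base <- procrustes_align(y1, y2)$residual
    for (t in 1:5) {
      th <- runif(1, 0, 2 * pi)
      Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      expect_equal(procrustes_align(y1 %*% Q, y2 %*% Q)$residual, base,
                   tolerance = 1e-8)
    }
  })
})

test_that("structural fusion is idempotent, rank-preserving, and shape-correct", {
  y <- withr::with_seed(18, matrix(rnorm(60), 30, 2))
  twice <- structural_fuse(list(y, y), "mean")
  expect_lt(max(abs(twice$values - y)), 1e-10)
  th <- 1.1
  Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  fused <- structural_fuse(list(y, y %*% Q), "mean")
  expect_equal(qr(fused$values)$rank, qr(y)$rank)
  cc <- structural_fuse(list(y, y %*% Q), "concatenate")
  expect_equal(dim(cc$values), c(30, 4))
})
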