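# small in-code fixtures shared across tests

# two-modality data-frame tables with aligned IDs
toy_tables <- function(n = 6, p1 = 3, p2 = 2, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("s%02d", seq_len(n))
    m1 <- data.frame(sample_id = ids,
                     matrix(rnorm(n * p1), n, p1,
                            dimnames = list(NULL, paste0("a", 1:p1))))
    m2 <- data.frame(sample_id = ids,
                     matrix(rnorm(n * p2), n, p2,
                            dimnames = list(NULL, paste0("b", 1:p2))))
    lab <- data.frame(sample_id = ids,
                      label = rep_len(c(0, 1), n),
                      group = ids)
    list(m1 = m1, m2 = m2, labels = lab)
  })
}

toy_dataset <- function(n = 6, p1 = 3, p2 = 2, seed = 1) {
  tt <- toy_tables(n, p1, p2, seed)
  multimodal_dataset(list(x = tt$m1, y = tt$m2), tt$labels)
}

# well-separated two-class feature matrix (gap in noise-sd units)
blob_data <- function(n = 100, p = 5, gap = 5, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    x <- matrix(rnorm(n * p), n, p) + gap * y
    rownames(x) <- sprintf("s%03d", seq_len(n))
    colnames(x) <- paste0("f", seq_len(p))
    list(x = x, y = y)
  })
}

random_affinity <- function(n, seed) {
  withr::with_seed(seed, {
    W <- matrix(runif(n * n, 0.05, 1), n, n)
    (W + t(W)) / 2
  })
}

# dense generalized-eigensolver oracle for W y = lambda D y (nonsymmetric
# solve route, independent of the package's symmetrized implementation)
dense_ge_oracle <- function(W) {
  D <- rowSums(W)
  e <- eigen(diag(1 / D) %*% W)
  ord <- order(Re(e$values), decreasing = TRUE)
  list(values = Re(e$values)[ord], vectors = Re(e$vectors)[, ord])
}
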