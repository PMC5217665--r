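#' @section Knowledge representations:
#' A modality is transformed into one of three common spaces before fusion:
#' classifier decision scores (probabilities in \[0,1\]), kernel similarity
#' matrices, or low-dimensional embeddings. All three remove modality-specific
#' scale and dimensionality differences so heterogeneous modalities can be
#' combined.
#' @name representations
NULL

new_lowdim <- function(coords, method, eigenvalues = NULL, params = list()) {
  structure(list(coords = coords, method = method,
                 eigenvalues = eigenvalues, params = params),
            class = "lowdim_representation")
}

new_kernel <- function(matrix, family, bandwidth = NULL, modality_name = NULL) {
  structure(list(matrix = matrix, family = family, bandwidth = bandwidth,
                 modality_name = modality_name),
            class = "kernel_representation")
}

new_coassociation <- function(matrix, kind, source = NULL, bandwidth = NULL) {
  structure(list(matrix = matrix, kind = kind, source = source,
                 bandwidth = bandwidth),
            class = "coassociation_matrix")
}

new_decision <- function(scores, modality_name, out_of_fold) {
  structure(list(scores = scores, modality_name = modality_name,
                 out_of_fold = out_of_fold),
            class = "decision_representation")
}

#' @export
print.lowdim_representation <- function(x, ...) {
  cat(sprintf("<lowdim_representation> %s: %d x %d\n",
              x$method, nrow(x$coords), ncol(x$coords)))
  invisible(x)
}

#' @export
print.kernel_representation <- function(x, ...) {
  cat(sprintf("<kernel_representation> %s kernel, %d x %d",
              x$family, nrow(x$matrix), ncol(x$matrix)))
  if (!is.null(x$bandwidth)) cat(sprintf(", bandwidth %.4g", x$bandwidth))
  cat("\n")
  invisible(x)
}

#' @export
print.coassociation_matrix <- function(x, ...) {
  cat(sprintf("<coassociation_matrix> kind=%s, %d x %d\n",
              x$kind, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

# extract an N x something coordinate matrix from whatever the caller passed
rep_coords <- function(x) {
  if (inherits(x, "lowdim_representation")) return(x$coords)
  if (inherits(x, "fused_representation")) return(x$values)
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) return(as.matrix(x))
  stop_fusedr("Expected a matrix, lowdim_representation or fused_representation.",
              "type")
}

squared_distances <- function(x) {
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  d2
}

# median pairwise Euclidean distance ("median heuristic" bandwidth)
median_distance <- function(x) {
  d2 <- squared_distances(x)
  median(sqrt(d2[upper.tri(d2)]))
}

# deterministic eigenvector sign: largest-magnitude entry positive
fix_signs <- function(coords) {
  for (j in seq_len(ncol(coords))) {
    v <- coords[, j]
    if (v[which.max(abs(v))] < 0) coords[, j] <- -v
  }
  coords
}

#' Kernel representation of a modality
#'
#' Computes the N x N kernel (implicit dot-product similarity) matrix of a
#' feature matrix. Gaussian: `K_ij = exp(-||x_i - x_j||^2 / (2 sigma^2))`;
#' linear: `K_ij = <x_i, x_j>`. The Gaussian bandwidth defaults to the median
#' pairwise Euclidean distance (median heuristic).
#'
#' @param x Numeric matrix (samples x features), data frame, or
#'   `lowdim_representation`.
#' @param family `"gaussian"` or `"linear"`.
#' @param sigma Positive bandwidth for the Gaussian kernel, or `"median"`.
#' @param modality_name Optional label carried in the result.
#' @return A `kernel_representation` (symmetric positive semidefinite matrix).
#' @export
compute_kernel <- function(x, family = c("gaussian", "linear"),
                           sigma = "median", modality_name = NULL) {
  family <- match.arg(family)
  x <- rep_coords(x)
  if (family == "linear") {
    K <- tcrossprod(x)
    bw <- NULL
  } else {
    if (identical(sigma, "median")) sigma <- median_distance(x)
    if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
      stop_fusedr("Gaussian bandwidth `sigma` must be a positive number.",
                  "parameter")
    }
    K <- exp(-squared_distances(x) / (2 * sigma^2))
    bw <- sigma
  }
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(x), rownames(x))
  new_kernel(K, family, bw, modality_name)
}

#' Gaussian affinity (co-association) matrix
#'
#' Pairwise-affinity quantification of a representation:
#' `W_ij = exp(-||x_i - x_j||^2 / (2 sigma^2))` with `sigma` defaulting to the
#' median pairwise distance. This is the `W` entering the graph-embedding
#' eigenproblem.
#'
#' @inheritParams compute_kernel
#' @return A `coassociation_matrix` of kind `"affinity"`.
#' @export
build_affinity <- function(x, sigma = "median") {
  x <- rep_coords(x)
  if (nrow(x) < 2) stop_fusedr("Need at least 2 samples.", "parameter")
  if (identical(sigma, "median")) {
    sigma <- median_distance(x)
    if (!is.finite(sigma) || sigma <= 0) {
      stop_fusedr("All points identical: median-heuristic bandwidth is degenerate.",
                  "sigma_degenerate")
    }
  }
  if (!is.numeric(sigma) || sigma <= 0) {
    stop_fusedr("`sigma` must be positive.", "parameter")
  }
  W <- exp(-squared_distances(x) / (2 * sigma^2))
  W <- (W + t(W)) / 2
  dimnames(W) <- list(rownames(x), rownames(x))
  new_coassociation(W, "affinity", source = "features", bandwidth = sigma)
}

#' Principal component representation
#'
#' Scores on the top-`d` eigenvectors of the sample covariance of the
#' column-centered data, in eigenvalue-descending order. Eigenvector sign is
#' fixed so the largest-magnitude loading is positive.
#'
#' @param x Numeric matrix (samples x features) or data frame.
#' @param d Number of components, `1 <= d <= min(N - 1, P)`.
#' @return A `lowdim_representation` with `method = "pca"` and the retained
#'   covariance eigenvalues.
#' @export
fit_pca <- function(x, d) {
  x <- rep_coords(x)
  n <- nrow(x); p <- ncol(x)
  if (!is.numeric(d) || d < 1 || d > min(n - 1, p)) {
    stop_fusedr(sprintf("`d` must lie in [1, %d].", min(n - 1, p)), "parameter")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  d <- as.integer(d)
  rot <- pc$rotation[, seq_len(d), drop = FALSE]
  scores <- pc$x[, seq_len(d), drop = FALSE]
  # sign convention applied to loadings; scores flip with them
  for (j in seq_len(d)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(x)
  new_lowdim(scores, "pca", eigenvalues = pc$sdev[seq_len(d)]^2,
             params = list(d = d, loadings = rot, center = pc$center))
}

#' Locally linear embedding
#'
#' Standard LLE: each sample is reconstructed from its `k` nearest neighbors
#' with weights summing to one; the embedding is given by the bottom non-zero
#' eigenvectors of `(I - W)'(I - W)` (eigenvalue-ascending column order).
#'
#' @param x Numeric matrix (samples x features) or data frame.
#' @param d Embedding dimensionality, `d < k`.
#' @param k Neighborhood size, `d < k < N`.
#' @param reg Regularization added to the local Gram matrix as
#'   `reg * trace(G) / k` (guards collinear or duplicated neighborhoods).
#' @return A `lowdim_representation` with `method = "lle"`; `params$weights`
#'   holds the N x N reconstruction-weight matrix (rows sum to 1).
#' @export
fit_lle <- function(x, d, k, reg = 1e-3) {
  x <- rep_coords(x)
  n <- nrow(x)
  if (k >= n) stop_fusedr("`k` must be smaller than the number of samples.",
                          "parameter")
  if (d >= k) stop_fusedr("`d` must be smaller than `k`.", "parameter")
  if (reg < 0) stop_fusedr("`reg` must be nonnegative.", "parameter")
  d2 <- squared_distances(x)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[-1][seq_len(k)]
    Z <- sweep(x[nb, , drop = FALSE], 2, x[i, ])
    G <- tcrossprod(Z)
    tr <- sum(diag(G))
    G <- G + diag(k) * (if (tr > 0) reg * tr / k else reg)
    w <- solve(G, rep(1, k))
    W[i, nb] <- w / sum(w)
  }
  IW <- diag(n) - W
  Mmat <- crossprod(IW)
  eig <- eigen(Mmat, symmetric = TRUE)
  # ascending eigenvalues, discard the bottom (constant, ~0) vector
  ord <- rev(seq_len(n))
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  coords <- fix_signs(vecs[, 1 + seq_len(d), drop = FALSE] * sqrt(n))
  rownames(coords) <- rownames(x)
  new_lowdim(coords, "lle", eigenvalues = vals[1 + seq_len(d)],
             params = list(d = d, k = k, reg = reg, weights = W))
}

# Generalized eigenproblem W y = lambda D y on the symmetrized random-walk
# form S = D^(-1/2) W D^(-1/2); the trivial constant solution (lambda = 1,
# y prop. 1) is removed by deflating its direction to eigenvalue -2, which
# stays correct even when lambda = 1 is degenerate (disconnected graphs).
spectral_solve <- function(W, d) {
  n <- nrow(W)
  D <- rowSums(W)
  if (any(D <= 0)) {
    stop_fusedr("Affinity matrix has a zero row sum (degenerate graph).",
                "degenerate_graph")
  }
  if (d >= n) stop_fusedr("`d` must be smaller than N.", "parameter")
  s <- 1 / sqrt(D)
  S <- W * outer(s, s)
  u0 <- sqrt(D) / sqrt(sum(D))
  S <- S - 3 * tcrossprod(u0)   # 1 - 3 = -2 < all retained eigenvalues
  eig <- eigen((S + t(S)) / 2, symmetric = TRUE)
  keep <- seq_len(d)
  y <- eig$vectors[, keep, drop = FALSE] * s   # y' D y = u'u = 1 per column
  list(coords = fix_signs(y), eigenvalues = eig$values[keep])
}

#' Graph embedding by generalized eigendecomposition
#'
#' Solves `W y = lambda D y` with degree matrix `D_ii = sum_j W_ij`, under the
#' normalization `y' D y = 1` per eigenvector. Returns the `d` eigenvectors
#' with the largest eigenvalues below the trivial constant solution
#' (`lambda = 1`), eigenvalue-descending, with the largest-magnitude entry of
#' each coordinate made positive.
#'
#' @param W A `coassociation_matrix` of kind `"affinity"`, or a symmetric
#'   nonnegative matrix.
#' @param d Number of embedding coordinates, `d < N`.
#' @return A `lowdim_representation` with `method = "graph_embed"`.
#' @export
graph_embed <- function(W, d) {
  if (inherits(W, "coassociation_matrix")) {
    if (W$kind != "affinity") {
      stop_fusedr("graph_embed needs an affinity matrix; convert distances first.",
                  "type")
    }
    W <- W$matrix
  }
  if (!is.matrix(W) || nrow(W) != ncol(W)) {
    stop_fusedr("`W` must be a square matrix.", "type")
  }
  sol <- spectral_solve(W, d)
  rownames(sol$coords) <- rownames(W)
  new_lowdim(sol$coords, "graph_embed", eigenvalues = sol$eigenvalues,
             params = list(d = d))
}

#' Decision representation of a modality
#'
#' Transforms a modality into per-sample class-1 probabilities from a bagged
#' decision-tree ensemble (see [bagged_trees()]). Labeled samples receive
#' out-of-fold scores from a stratified cross-fit (the scoring model never saw
#' the sample); unlabeled samples are scored by a model fit on all labeled
#' samples.
#'
#' @param x Numeric matrix (samples x features) or data frame.
#' @param labels 0/1 vector with `NA` for unlabeled samples.
#' @param folds Number of cross-fit folds among labeled samples.
#' @param seed Integer seed controlling fold assignment and tree growing.
#' @param n_trees,subsample_fraction Passed to [bagged_trees()].
#' @param modality_name Optional label carried in the result.
#' @return A `decision_representation` with scores in \[0,1\].
#' @export
compute_decisions <- function(x, labels, folds = 3, seed = 1,
                              n_trees = 100, subsample_fraction = 0.66,
                              modality_name = NULL) {
  x <- rep_coords(x)
  check_binary_labels(labels)
  lab_i <- which(!is.na(labels))
  y <- labels[lab_i]
  if (min(table(y)) < folds) {
    stop_fusedr("Need at least `folds` labeled samples per class.", "parameter")
  }
  scores <- rep(NA_real_, length(labels))
  oof <- rep(FALSE, length(labels))
  fold_id <- stratified_folds(y, folds, seed)
  for (f in seq_len(folds)) {
    tr <- lab_i[fold_id != f]
    te <- lab_i[fold_id == f]
    fit <- bagged_trees(x[tr, , drop = FALSE], labels[tr], n_trees,
                        subsample_fraction, seed = seed + f)
    scores[te] <- predict(fit, x[te, , drop = FALSE])
    oof[te] <- TRUE
  }
  unl <- which(is.na(labels))
  if (length(unl) > 0) {
    fit <- bagged_trees(x[lab_i, , drop = FALSE], labels[lab_i], n_trees,
                        subsample_fraction, seed = seed)
    scores[unl] <- predict(fit, x[unl, , drop = FALSE])
  }
  names(scores) <- rownames(x)
  new_decision(scores, modality_name, oof)
}

# class-stratified fold assignment: shuffle within class, deal round-robin
stratified_folds <- function(y, folds, seed) {
  fold_id <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}
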