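#' @section Knowledge fusion:
#' Given `n * M` representations of `M` modalities, fusion combines them into
#' a single result: directly (concatenation, averages, probabilistic AND of
#' decisions), through a combined co-association matrix that is then
#' eigendecomposed (including the multi-kernel variant), or structurally, by
#' Procrustes-aligning embeddings into one frame before combining.
#' @name fusion
NULL

new_fused <- function(values, kind, strategy_name = NULL, provenance = list()) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) {
    stop_fusedr("Fused representation contains non-finite values.", "validation")
  }
  structure(list(values = values, kind = kind, strategy_name = strategy_name,
                 provenance = provenance),
            class = "fused_representation")
}

#' @export
print.fused_representation <- function(x, ...) {
  cat(sprintf("<fused_representation> %s (%d x %d)%s\n", x$kind,
              nrow(x$values), ncol(x$values),
              if (!is.null(x$strategy_name)) paste0(", strategy ", x$strategy_name)
              else ""))
  invisible(x)
}

# coerce a homogeneous list of representations to matrices, checking kinds
reps_as_matrices <- function(reps) {
  kinds <- vapply(reps, function(r) {
    if (inherits(r, "decision_representation")) "decision"
    else if (inherits(r, "lowdim_representation")) "embedding"
    else if (inherits(r, "fused_representation")) "embedding"
    else if (is.matrix(r) || is.data.frame(r)) "matrix"
    else "other"
  }, "")
  if (any(kinds == "other")) {
    stop_fusedr("Unsupported representation type in fusion input.", "type")
  }
  if (length(unique(kinds)) > 1) {
    stop_fusedr("All representations must be of one kind.", "type")
  }
  mats <- map(reps, function(r) {
    if (inherits(r, "decision_representation")) matrix(r$scores, ncol = 1)
    else rep_coords(r)
  })
  ns <- vapply(mats, nrow, 0L)
  if (length(unique(ns)) > 1) {
    stop_fusedr("Representations differ in sample count.", "shape")
  }
  mats
}

#' Direct fusion of representations
#'
#' Combines a homogeneous list of representations (all decisions, all
#' embeddings, or all feature matrices) by column-wise concatenation,
#' element-wise mean/median, or an element-wise weighted sum.
#'
#' @param reps List of representations sharing a sample count.
#' @param rule `"concatenate"`, `"mean"`, `"median"`, or `"weighted_sum"`.
#' @param weights Nonnegative weights summing to 1 (required for
#'   `"weighted_sum"`).
#' @return A `fused_representation`.
#' @export
direct_fuse <- function(reps, rule = c("concatenate", "mean", "median",
                                       "weighted_sum"),
                        weights = NULL) {
  rule <- match.arg(rule)
  mats <- reps_as_matrices(reps)
  if (rule == "concatenate") {
    out <- do.call(cbind, mats)
  } else {
    ps <- vapply(mats, ncol, 0L)
    if (length(unique(ps)) > 1) {
      stop_fusedr(sprintf("'%s' needs equal shapes.", rule), "shape")
    }
    if (rule == "mean") {
      out <- Reduce(`+`, mats) / length(mats)
    } else if (rule == "median") {
      arr <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
      out <- apply(arr, c(1, 2), median)
    } else {
      weights <- check_weights(weights, length(mats))
      out <- Reduce(`+`, map2(mats, weights, function(m, w) m * w))
    }
  }
  kind <- if (ncol(out) == 1 && all(out >= 0 & out <= 1)) "score_vector"
          else "embedding"
  new_fused(out, kind, provenance = list(rule = rule, weights = weights,
                                         inputs = length(mats)))
}

#' Probabilistic AND fusion of decision representations
#'
#' `h_hat(c_i) = prod_m h_m(c_i)`: a sample is scored high only when every
#' modality's classifier scores it high.
#'
#' @param decisions List of `decision_representation`s (or numeric score
#'   vectors in \[0,1\]).
#' @return A `fused_representation` of kind `"score_vector"`.
#' @export
decision_and <- function(decisions) {
  if (length(decisions) < 1) stop_fusedr("Need at least one decision.", "parameter")
  vecs <- map(decisions, function(d) {
    v <- if (inherits(d, "decision_representation")) d$scores else as.numeric(d)
    if (any(v < 0 | v > 1)) stop_fusedr("Decision scores must lie in [0,1].",
                                        "validation")
    v
  })
  out <- Reduce(`*`, vecs)
  new_fused(matrix(out, ncol = 1, dimnames = list(names(vecs[[1]]), NULL)),
            "score_vector", provenance = list(rule = "product_and",
                                              inputs = length(vecs)))
}

check_weights <- function(weights, len) {
  if (is.null(weights)) stop_fusedr("Weights required.", "parameter")
  if (length(weights) != len) stop_fusedr("Weight length mismatch.", "parameter")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop_fusedr("Weights must be nonnegative and sum to 1.", "parameter")
  }
  as.numeric(weights)
}

#' Co-association matrix of a representation
#'
#' Quantifies the pairwise relationships within one representation as an
#' N x N matrix: Euclidean distances or Gaussian affinities of embedding
#' coordinates, or the kernel matrix itself.
#'
#' @param rep A `lowdim_representation` / coordinate matrix (for
#'   `"distance"` / `"affinity"`) or a `kernel_representation` (for
#'   `"kernel_values"`).
#' @param delta Quantification function.
#' @param sigma Bandwidth for `"affinity"` (default median heuristic).
#' @return A `coassociation_matrix`.
#' @export
build_coassociation <- function(rep, delta = c("distance", "affinity",
                                               "kernel_values"),
                                sigma = "median") {
  delta <- match.arg(delta)
  if (delta == "kernel_values") {
    if (!inherits(rep, "kernel_representation")) {
      stop_fusedr("'kernel_values' requires a kernel_representation.", "type")
    }
    return(new_coassociation(rep$matrix, "affinity", source = "kernel"))
  }
  if (inherits(rep, "kernel_representation")) {
    stop_fusedr(sprintf("'%s' requires an embedding, not a kernel.", delta),
                "type")
  }
  x <- rep_coords(rep)
  if (delta == "distance") {
    d2 <- squared_distances_na(x)
    W <- sqrt(d2)
    diag(W) <- 0
    new_coassociation(W, "distance", source = "embedding")
  } else {
    build_affinity(x, sigma)
  }
}

# squared distances tolerating NA rows (bootstrap-absent samples)
squared_distances_na <- function(x) {
  if (!anyNA(x)) return(squared_distances(x))
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(ifelse(is.na(x), 0, x))
  d2[is.na(outer(sq, sq, "+"))] <- NA
  d2[!is.na(d2) & d2 < 0] <- 0
  d2
}

#' Combine co-association matrices
#'
#' Element-wise median (the unweighted, data-driven maximum-likelihood
#' combination) or element-wise weighted sum of a stack of co-association
#' matrices. Entries missing in some replicates (sample-bootstrap pipelines)
#' are skipped by the median; a pair missing from every replicate is an
#' error.
#'
#' @param Ws List of `coassociation_matrix` objects of one kind and size.
#' @param rule `"median"` or `"weighted_sum"`.
#' @param weights Required for `"weighted_sum"`.
#' @return A combined `coassociation_matrix`.
#' @export
combine_coassociation <- function(Ws, rule = c("median", "weighted_sum"),
                                  weights = NULL) {
  rule <- match.arg(rule)
  if (length(Ws) < 1) stop_fusedr("Need at least one matrix.", "parameter")
  kinds <- vapply(Ws, function(w) w$kind, "")
  if (length(unique(kinds)) > 1) {
    stop_fusedr("All co-association matrices must share one kind.", "type")
  }
  mats <- map(Ws, function(w) w$matrix)
  dims <- vapply(mats, nrow, 0L)
  if (length(unique(dims)) > 1) stop_fusedr("Size mismatch.", "shape")
  if (rule == "median") {
    arr <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
    if (anyNA(arr)) {
      if (any(apply(is.na(arr), c(1, 2), all))) {
        stop_fusedr("Some sample pair is missing from every replicate.",
                    "coverage")
      }
      out <- apply(arr, c(1, 2), median, na.rm = TRUE)
    } else if (length(mats) == 1) {
      out <- mats[[1]]
    } else {
      out <- apply(arr, c(1, 2), median)
    }
  } else {
    weights <- check_weights(weights, length(mats))
    out <- Reduce(`+`, map2(mats, weights, function(m, w) m * w))
    if (anyNA(out)) stop_fusedr("Weighted sum requires complete matrices.",
                                "coverage")
  }
  out <- (out + t(out)) / 2
  if (kinds[1] == "distance") diag(out) <- 0
  dimnames(out) <- dimnames(mats[[1]])
  new_coassociation(out, kinds[1], source = "combined")
}

#' Convert a distance co-association matrix to an affinity
#'
#' `A_ij = exp(-W_ij^2 / (2 sigma^2))` with `sigma` defaulting to the median
#' off-diagonal distance; the bridge from distance-based combination to the
#' affinity required by the embedding eigenproblem.
#'
#' @param W A `coassociation_matrix` of kind `"distance"`.
#' @param sigma Positive bandwidth or `"median"`.
#' @return A `coassociation_matrix` of kind `"affinity"`.
#' @export
distance_to_affinity <- function(W, sigma = "median") {
  if (!inherits(W, "coassociation_matrix") || W$kind != "distance") {
    stop_fusedr("Expected a distance co-association matrix.", "type")
  }
  m <- W$matrix
  if (identical(sigma, "median")) {
    off <- m[upper.tri(m)]
    sigma <- median(off[is.finite(off)])
    if (!is.finite(sigma) || sigma <= 0) {
      stop_fusedr("Degenerate distances: median bandwidth is zero.",
                  "sigma_degenerate")
    }
  }
  A <- exp(-m^2 / (2 * sigma^2))
  new_coassociation(A, "affinity", source = "distance", bandwidth = sigma)
}

#' Embed a combined co-association matrix
#'
#' Eigendecomposes the combined matrix `W_hat y = lambda D_hat y`
#' (`D_hat_ii = sum_j W_hat_ij`, normalization `y' D_hat y = 1` per column)
#' to produce the fused embedding. Distance-kind input is first converted via
#' [distance_to_affinity()].
#'
#' @param What A `coassociation_matrix`.
#' @param d Embedding dimensionality.
#' @param strategy_name Optional label.
#' @return A `fused_representation` of kind `"embedding"` with the retained
#'   eigenvalues in `provenance$eigenvalues`.
#' @export
coassociation_embed <- function(What, d, strategy_name = NULL) {
  if (!inherits(What, "coassociation_matrix")) {
    stop_fusedr("Expected a coassociation_matrix.", "type")
  }
  if (What$kind == "distance") What <- distance_to_affinity(What)
  sol <- spectral_solve(What$matrix, d)
  rownames(sol$coords) <- rownames(What$matrix)
  new_fused(sol$coords, "embedding", strategy_name,
            provenance = list(eigenvalues = sol$eigenvalues, d = d,
                              fusion = "coassociation"))
}

#' Multi-kernel graph embedding
#'
#' Kernelized form of the co-association eigenproblem: with the weighted
#' kernel combination `K_hat = sum_t alpha_t K_t`, solves
#' `K_hat W_hat K_hat' R = Lambda (K_hat D_hat K_hat' + eps I) R` and returns
#' the embedding `Y = K_hat' R`, columns eigenvalue-descending and normalized
#' to `y' D_hat y = 1`. The ridge `eps` conditions the (typically
#' rank-deficient) kernel Gram product; with `K_hat = I` and `ridge = 0` the
#' problem reduces exactly to [coassociation_embed()].
#'
#' @param Ks List of `kernel_representation`s (or symmetric matrices) of one
#'   size.
#' @param What A `coassociation_matrix` (affinity; distances converted).
#' @param d Embedding dimensionality.
#' @param weights Kernel weights (default uniform), nonnegative, summing to 1.
#' @param ridge Ridge `eps >= 0`; default `1e-6 * trace(K D K) / N`.
#' @param strategy_name Optional label.
#' @return A `fused_representation` of kind `"embedding"`.
#' @export
multikernel_embed <- function(Ks, What, d, weights = NULL, ridge = NULL,
                              strategy_name = NULL) {
  mats <- map(Ks, function(k) {
    if (inherits(k, "kernel_representation")) k$matrix else as.matrix(k)
  })
  if (length(unique(vapply(mats, nrow, 0L))) > 1) {
    stop_fusedr("Kernels differ in size.", "shape")
  }
  weights <- if (is.null(weights)) rep(1 / length(mats), length(mats))
             else check_weights(weights, length(mats))
  K <- Reduce(`+`, map2(mats, weights, function(m, w) m * w))
  if (inherits(What, "coassociation_matrix")) {
    if (What$kind == "distance") What <- distance_to_affinity(What)
    W <- What$matrix
  } else W <- as.matrix(What)
  n <- nrow(W)
  if (d >= n) stop_fusedr("`d` must be smaller than N.", "parameter")
  Dg <- rowSums(W)
  if (any(Dg <= 0)) stop_fusedr("Zero row sum in W.", "degenerate_graph")
  A <- K %*% (W %*% K)
  B0 <- K %*% (Dg * K)
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(B0)) / n
  if (ridge < 0) stop_fusedr("`ridge` must be nonnegative.", "parameter")
  B <- (B0 + t(B0)) / 2 + diag(ridge, n)
  R <- tryCatch(chol(B), error = function(e) {
    stop_fusedr(paste("K D K' is rank deficient; use a positive `ridge`",
                      "to regularize the right-hand side."),
                "rank_deficiency")
  })
  A <- (A + t(A)) / 2
  T1 <- backsolve(R, A, transpose = TRUE)       # R^-T A
  M <- t(backsolve(R, t(T1), transpose = TRUE)) # R^-T A R^-1 (as t of t)
  M <- (M + t(M)) / 2
  # Remove the trivial constant solution: the direction u0 whose embedding
  # coordinate K R^-1 u0 best approximates the constant vector is projected
  # out, and the eigenproblem solved on its orthogonal complement. With an
  # invertible K this is exactly the lambda = 1 constant eigenvector.
  # near-solution of K v0 = 1 via a lightly ridged Cholesky solve (K is
  # symmetric PSD in all uses); fall back to the pseudoinverse if K is
  # indefinite. Only the direction matters, so the tiny ridge is harmless.
  v0 <- tryCatch({
    delta <- 1e-10 * sum(diag(K)) / n
    ch <- chol(K + diag(delta, n))
    solve1 <- function(b) backsolve(ch, backsolve(ch, b, transpose = TRUE))
    v <- solve1(rep(1, n))
    v + solve1(rep(1, n) - K %*% v)   # one refinement step
  }, error = function(e) {
    tryCatch(MASS::ginv(K) %*% rep(1, n), error = function(e2) NULL)
  })
  P <- NULL
  if (!is.null(v0)) {
    u0 <- as.numeric(R %*% v0)
    nu0 <- sqrt(sum(u0^2))
    if (nu0 > 1e-10) {
      Q <- qr.Q(qr(cbind(u0 / nu0)), complete = TRUE)
      P <- Q[, -1, drop = FALSE]
    }
  }
  if (is.null(P)) {
    eig <- eigen(M, symmetric = TRUE)
    U <- eig$vectors[, seq_len(d), drop = FALSE]
    vals <- eig$values[seq_len(d)]
  } else {
    Mp <- crossprod(P, M %*% P)
    eig <- eigen((Mp + t(Mp)) / 2, symmetric = TRUE)
    U <- P %*% eig$vectors[, seq_len(d), drop = FALSE]
    vals <- eig$values[seq_len(d)]
  }
  Y <- K %*% backsolve(R, U)                    # K' R^-1 U, K symmetric
  nrm <- sqrt(colSums(Y^2 * Dg))
  if (any(nrm < 1e-12)) {
    stop_fusedr("Degenerate embedding column (zero D-norm).", "rank_deficiency")
  }
  Y <- fix_signs(sweep(Y, 2, nrm, "/"))
  rownames(Y) <- rownames(W)
  new_fused(Y, "embedding", strategy_name,
            provenance = list(eigenvalues = vals, d = d, weights = weights,
                              ridge = ridge, fusion = "multikernel"))
}

#' Semi-supervised co-association matrix from labeled pairs and kernels
#'
#' Builds the `W_hat` used by weighted, semi-supervised kernel fusion. The
#' base affinity is the weighted mean of the diagonal-normalized kernels
#' (negative similarities clamped to 0), so every pair — labeled or not —
#' lives on one affinity scale. Label information then modulates the labeled
#' block: same-class pairs are boosted by `(1 + supervision)`, cross-class
#' pairs shrunk by `(1 - supervision)`. Keeping the supervised block on the
#' affinity scale is what lets the embedding place unlabeled (test) samples
#' in the same geometry as labeled ones; a label-only block (affinity 1/0 by
#' class) makes labeled rows separate at a scale the kernel extension of
#' unlabeled rows cannot reach, which destroys downstream classification.
#'
#' @param Ks List of `kernel_representation`s (or matrices).
#' @param labels 0/1 labels with `NA` marking unlabeled (e.g. test) samples.
#' @param weights Kernel weights (default uniform).
#' @param supervision Label-modulation strength in \[0, 1\]: 0 ignores
#'   labels, 1 zeroes cross-class affinities entirely (default 0.5).
#' @return A `coassociation_matrix` of kind `"affinity"`.
#' @export
semisupervised_coassociation <- function(Ks, labels, weights = NULL,
                                         supervision = 0.5) {
  mats <- map(Ks, function(k) {
    if (inherits(k, "kernel_representation")) k$matrix else as.matrix(k)
  })
  weights <- if (is.null(weights)) rep(1 / length(mats), length(mats))
             else check_weights(weights, length(mats))
  if (supervision < 0 || supervision > 1) {
    stop_fusedr("`supervision` must lie in [0, 1].", "parameter")
  }
  A <- Reduce(`+`, map2(mats, weights, function(m, w) {
    dg <- diag(m)
    dg[dg <= 0] <- 1
    w * (m / sqrt(outer(dg, dg)))
  }))
  A[A < 0] <- 0
  check_binary_labels(labels)
  W <- A
  lab <- which(!is.na(labels))
  if (length(lab) > 0 && supervision > 0) {
    y <- labels[lab]
    same <- outer(y, y, "==")
    block <- A[lab, lab, drop = FALSE]
    block[same] <- (1 + supervision) * block[same]
    block[!same] <- (1 - supervision) * block[!same]
    W[lab, lab] <- block
  }
  W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(mats[[1]])
  new_coassociation(W, "affinity", source = "semisupervised")
}

# all weight vectors with components that are multiples of `step`, summing
# to 1, in lexicographic order (first component varies slowest, descending
# from 1) — the documented deterministic tie-break order
simplex_grid <- function(m, step) {
  k <- round(1 / step)
  if (abs(k * step - 1) > 1e-9) {
    stop_fusedr("`grid_step` must divide 1.", "parameter")
  }
  compose <- function(m, k) {
    if (m == 1) return(list(k))
    out <- list()
    for (first in k:0) {
      rest <- compose(m - 1, k - first)
      out <- c(out, map(rest, function(r) c(first, r)))
    }
    out
  }
  map(compose(m, k), function(v) v / k)
}

#' Learn modality weights on a simplex grid
#'
#' Exhaustive search over weight vectors discretized at `grid_step`: each
#' candidate weighting is used to build the fused result on the labeled
#' (training) samples, the objective is scored, and the argmax is returned
#' (ties broken toward the lexicographically first candidate, i.e. most
#' weight on the earliest modality).
#'
#' Kernel candidates are fused by the multi-kernel embedding against the
#' supervised label-affinity matrix; embedding/matrix candidates by an
#' element-wise weighted sum. The `"fisher"` objective is the
#' between-/within-class scatter ratio of the fused coordinates;
#' `"train_auc"` is the out-of-fold AUC of a bagged-tree cross-fit on them.
#'
#' @param candidates List (length >= 1) of `kernel_representation`s, or of
#'   embeddings/matrices with identical shapes.
#' @param labels 0/1 labels; only labeled samples drive the search.
#' @param objective `"fisher"` or `"train_auc"`.
#' @param grid_step Simplex discretization in `(0, 0.5]` (default 0.1).
#' @param d Embedding dimensionality for kernel candidates.
#' @param seed Seed for the `"train_auc"` cross-fit.
#' @return A nonnegative weight vector summing to 1, with the evaluated grid
#'   in the `"search"` attribute.
#' @export
learn_modality_weights <- function(candidates, labels,
                                   objective = c("fisher", "train_auc"),
                                   grid_step = 0.1, d = 5, seed = 1) {
  objective <- match.arg(objective)
  if (length(candidates) < 1) stop_fusedr("Need candidates.", "parameter")
  if (length(candidates) == 1) return(1)
  if (grid_step <= 0 || grid_step > 0.5) {
    stop_fusedr("`grid_step` must lie in (0, 0.5].", "parameter")
  }
  check_binary_labels(labels)
  lab <- which(!is.na(labels))
  y <- labels[lab]
  kernelish <- all(vapply(candidates, inherits, TRUE,
                          what = "kernel_representation"))
  if (kernelish) {
    # candidates are embedded from their own (unsupervised) kernel geometry
    # and scored against the training labels: an uninformative kernel then
    # shows no class structure. Embedding the label-tilted affinity instead
    # would separate the classes for any kernel and blind the objective.
    Ktr <- map(candidates, function(k) k$matrix[lab, lab, drop = FALSE])
    build <- function(alpha) {
      Wtr <- semisupervised_coassociation(Ktr, y, weights = alpha,
                                          supervision = 0)
      multikernel_embed(Ktr, Wtr, d = min(d, length(lab) - 1),
                        weights = alpha)$values
    }
  } else {
    mats <- reps_as_matrices(candidates)
    build <- function(alpha) {
      Reduce(`+`, map2(mats, alpha, function(m, w) m * w))[lab, , drop = FALSE]
    }
  }
  score <- function(coords) {
    if (objective == "fisher") fisher_criterion(coords, y)
    else {
      dec <- compute_decisions(coords, y, folds = 3, seed = seed)
      compute_auc(dec$scores, y)
    }
  }
  grid <- simplex_grid(length(candidates), grid_step)
  objs <- vapply(grid, function(alpha) {
    tryCatch(score(build(alpha)), error = function(e) -Inf)
  }, 0)
  best <- which.max(objs)  # first max = lexicographic tie-break
  out <- grid[[best]]
  attr(out, "search") <- tibble(
    candidate = vapply(grid, function(a) paste(round(a, 6), collapse = "/"), ""),
    objective = objs
  )
  attr(out, "objective") <- objs[best]
  out
}

# between-class over within-class scatter (trace form)
fisher_criterion <- function(coords, y) {
  coords <- as.matrix(coords)
  mu <- colMeans(coords)
  sw <- 0; sb <- 0
  for (cls in unique(y)) {
    xc <- coords[y == cls, , drop = FALSE]
    mc <- colMeans(xc)
    sw <- sw + sum(sweep(xc, 2, mc)^2)
    sb <- sb + nrow(xc) * sum((mc - mu)^2)
  }
  if (sw <= 0) return(Inf)
  sb / sw
}

#' Orthogonal Procrustes alignment of two embeddings
#'
#' Finds the translation, isotropic scale and orthogonal matrix (rotations
#' and reflections; embedding axis signs are arbitrary) minimizing
#' `||T(Y_src) - Y_ref||_F`, using shared samples as the point
#' correspondences.
#'
#' @param Y_src,Y_ref Embeddings (`lowdim_representation`, fused embedding,
#'   or matrix) with identical dimensions.
#' @return A list with `transform` (an `alignment_transform`: `rotation`,
#'   `scale`, `translation`), `coords` (aligned source), and `residual`
#'   (Frobenius distance to the reference).
#' @export
procrustes_align <- function(Y_src, Y_ref) {
  src <- rep_coords(Y_src); ref <- rep_coords(Y_ref)
  if (!all(dim(src) == dim(ref))) {
    stop_fusedr("Embeddings must share dimensions.", "shape")
  }
  pr <- vegan::procrustes(X = ref, Y = src, scale = TRUE, symmetric = FALSE)
  # vegan returns Yrot in the centered reference frame; shift back by the
  # reference centroid (its `translation` applies to raw source coordinates)
  aligned <- pr$Yrot +
    matrix(colMeans(ref), nrow(ref), ncol(ref), byrow = TRUE)
  dimnames(aligned) <- dimnames(ref)
  transform <- structure(
    list(rotation = pr$rotation, scale = pr$scale,
         translation = as.numeric(pr$translation)),
    class = "alignment_transform"
  )
  list(transform = transform, coords = aligned,
       residual = sqrt(sum((aligned - ref)^2)))
}

#' @export
print.alignment_transform <- function(x, ...) {
  cat(sprintf("<alignment_transform> d=%d, scale=%.4g\n",
              nrow(x$rotation), x$scale))
  invisible(x)
}

#' Structural fusion of embeddings
#'
#' Procrustes-aligns every embedding to the first in the list (the shared
#' samples are the correspondences), then combines the aligned embeddings by
#' the element-wise mean or by concatenation.
#'
#' @param Ys List of embeddings with a shared sample count (and shared `d`
#'   for `rule = "mean"`).
#' @param rule `"mean"` or `"concatenate"`.
#' @param strategy_name Optional label.
#' @return A `fused_representation` of kind `"embedding"`.
#' @export
structural_fuse <- function(Ys, rule = c("mean", "concatenate"),
                            strategy_name = NULL) {
  rule <- match.arg(rule)
  mats <- reps_as_matrices(Ys)
  ref <- mats[[1]]
  aligned <- c(list(ref), map(mats[-1], function(m) {
    if (!all(dim(m) == dim(ref)) && rule == "mean") {
      stop_fusedr("'mean' requires equal embedding dimensions.", "shape")
    }
    procrustes_align(m, ref)$coords
  }))
  out <- if (rule == "mean") Reduce(`+`, aligned) / length(aligned)
         else do.call(cbind, aligned)
  rownames(out) <- rownames(ref)
  new_fused(out, "embedding", strategy_name,
            provenance = list(rule = rule, fusion = "structural",
                              inputs = length(mats)))
}
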