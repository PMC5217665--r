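#' Bagged decision-tree ensemble
#'
#' The classifier used throughout the package (for decision representations
#' and for scoring fused representations): an ensemble of `n_trees` decision
#' trees, each grown on a bootstrap sample of the training rows and a random
#' subset of `subsample_fraction` of the feature space. Prediction is the
#' majority-voting rule realized as the fraction of trees voting class 1, so
#' scores are usable for ROC ranking.
#'
#' @param x Numeric matrix or data frame of training features.
#' @param y 0/1 labels (no `NA`).
#' @param n_trees Number of trees (default 100).
#' @param subsample_fraction Fraction of features drawn (without replacement)
#'   for each tree (default 0.66).
#' @param seed Integer seed; the same seed reproduces the identical ensemble.
#' @return A `bagged_trees` model.
#' @export
bagged_trees <- function(x, y, n_trees = 100, subsample_fraction = 0.66,
                         seed = 1) {
  x <- rep_coords(x)
  y <- as.integer(y)
  check_binary_labels(y)
  if (anyNA(y)) stop_fusedr("Training labels must be observed.", "degenerate_label")
  n <- nrow(x); p <- ncol(x)
  nfeat <- max(1L, ceiling(subsample_fraction * p))
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(p))
  yf <- factor(y, levels = c(0, 1))
  ctrl <- rpart::rpart.control(cp = 0, xval = 0, minsplit = 4, minbucket = 2,
                               maxdepth = 12)
  trees <- vector("list", n_trees)
  feats <- vector("list", n_trees)
  withr::with_seed(seed, {
    for (b in seq_len(n_trees)) {
      rows <- sample.int(n, n, replace = TRUE)
      cols <- sort(sample.int(p, nfeat))
      dat <- df[rows, cols, drop = FALSE]
      dat$.y <- yf[rows]
      trees[[b]] <- rpart::rpart(.y ~ ., data = dat, method = "class",
                                 control = ctrl)
      feats[[b]] <- cols
    }
  })
  structure(list(trees = trees, features = feats, p = p, n_trees = n_trees,
                 subsample_fraction = subsample_fraction, seed = seed),
            class = "bagged_trees")
}

#' Predict class-1 vote fractions from a bagged ensemble
#'
#' @param object A [bagged_trees()] model.
#' @param newdata Numeric matrix or data frame with the training feature count.
#' @param ... Unused.
#' @return Vote fractions in \[0,1\], one per row of `newdata`.
#' @export
predict.bagged_trees <- function(object, newdata, ...) {
  newdata <- rep_coords(newdata)
  if (ncol(newdata) != object$p) {
    stop_fusedr("`newdata` feature count differs from training.", "shape")
  }
  df <- as.data.frame(newdata)
  names(df) <- paste0("f", seq_len(object$p))
  votes <- matrix(0, nrow(df), object$n_trees)
  for (b in seq_len(object$n_trees)) {
    cls <- predict(object$trees[[b]], df[, object$features[[b]], drop = FALSE],
                   type = "class")
    votes[, b] <- as.numeric(cls == "1")
  }
  rowMeans(votes)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation via midranks: the probability that a random
#' positive is scored above a random negative, ties counting 1/2.
#'
#' @param scores Numeric scores (higher = more class-1).
#' @param labels 0/1 labels of the same length.
#' @return AUC in \[0,1\].
#' @export
compute_auc <- function(scores, labels) {
  keep <- !is.na(labels) & !is.na(scores)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop_fusedr("AUC undefined: only one class present.", "undefined_auc")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Partition groups into `folds` folds, class-stratified where possible:
# groups are stratified by their majority label, shuffled within stratum and
# dealt round-robin, so no group ever spans train and test.
group_folds <- function(groups, labels, folds, seed) {
  gl <- unique(groups)
  if (length(gl) < folds) {
    stop_fusedr("Fewer groups than folds.", "fold")
  }
  gclass <- vapply(gl, function(g) {
    y <- labels[groups == g & !is.na(labels)]
    if (length(y) == 0) return(-1)
    as.numeric(mean(y) >= 0.5)
  }, 0)
  gfold <- integer(length(gl))
  withr::with_seed(seed, {
    offset <- 0L
    for (cls in unique(gclass)) {
      idx <- sample(which(gclass == cls))
      gfold[idx] <- 1L + (offset + seq_along(idx) - 1L) %% folds
      offset <- offset + length(idx)
    }
  })
  gfold[match(groups, gl)]
}

#' Repeated grouped cross-validation with pooled AUC
#'
#' The evaluation harness: per repeat, groups (patients) are randomly
#' partitioned into `folds` folds (class-stratified at the group level where
#' possible); each fold is scored once by a model trained on the remaining
#' folds; all out-of-fold scores are pooled into one AUC per repeat.
#'
#' @param x Feature matrix (samples x features), or `NULL` when `fold_fun`
#'   computes scores itself.
#' @param labels 0/1 labels (`NA`-labeled samples are excluded from CV).
#' @param groups Group/patient IDs (default: one group per sample).
#' @param folds,repeats CV geometry (defaults 3 and 25).
#' @param seed Master seed; per-repeat sub-seeds are derived from it.
#' @param fold_fun Optional `function(train_idx, test_idx, seed)` returning
#'   scores for `test_idx`; defaults to training a [bagged_trees()] model on
#'   `x[train_idx, ]`.
#' @param n_trees,subsample_fraction Classifier settings for the default
#'   `fold_fun`.
#' @param strategy_name Label stored in the result.
#' @return An `evaluation_result` with one pooled AUC per repeat.
#' @export
repeated_grouped_cv <- function(x = NULL, labels, groups = NULL, folds = 3,
                                repeats = 25, seed = 1, fold_fun = NULL,
                                n_trees = 100, subsample_fraction = 0.66,
                                strategy_name = "features") {
  labels <- as.integer(labels)
  n <- length(labels)
  if (is.null(groups)) groups <- as.character(seq_len(n))
  if (is.null(fold_fun)) {
    if (is.null(x)) stop_fusedr("Provide `x` or a `fold_fun`.", "parameter")
    x <- rep_coords(x)
    fold_fun <- function(train_idx, test_idx, fold_seed) {
      fit <- bagged_trees(x[train_idx, , drop = FALSE], labels[train_idx],
                          n_trees, subsample_fraction, seed = fold_seed)
      predict(fit, x[test_idx, , drop = FALSE])
    }
  }
  lab_i <- which(!is.na(labels))
  rep_seeds <- withr::with_seed(seed, sample.int(2^31 - 2, repeats))
  aucs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fid <- group_folds(groups[lab_i], labels[lab_i], folds, rep_seeds[r])
    scores <- rep(NA_real_, length(lab_i))
    for (f in seq_len(folds)) {
      tr <- lab_i[fid != f]
      te <- lab_i[fid == f]
      scores[fid == f] <- fold_fun(tr, te, rep_seeds[r] %% 2^20 + f)
    }
    aucs[r] <- compute_auc(scores, labels[lab_i])
  }
  new_evaluation_result(aucs, strategy_name, seed)
}

new_evaluation_result <- function(aucs, strategy_name, seed) {
  structure(list(auc_per_repeat = aucs, mean = mean(aucs), sd = sd(aucs),
                 strategy_name = strategy_name, seed = seed),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> %s: AUC %.3f +/- %.3f over %d repeats\n",
              x$strategy_name, x$mean, x$sd, length(x$auc_per_repeat)))
  invisible(x)
}

#' Kruskal-Wallis test across strategy AUC vectors
#'
#' Rank-based one-way comparison (tie-corrected H, chi-square p with
#' `groups - 1` df) of the per-repeat AUC distributions of two or more
#' strategies; the null is that all AUC populations share one median.
#'
#' @param auc_groups A named list of numeric vectors (or of
#'   `evaluation_result`s).
#' @return A list with `H`, `p`, and `df`.
#' @export
kruskal_wallis <- function(auc_groups) {
  auc_groups <- as_auc_list(auc_groups)
  if (length(auc_groups) < 2 || any(lengths(auc_groups) < 2)) {
    stop_fusedr("Need >= 2 groups with >= 2 values each.", "input")
  }
  values <- unlist(auc_groups, use.names = FALSE)
  g <- factor(rep(names(auc_groups), lengths(auc_groups)))
  if (length(unique(values)) == 1) {
    return(list(H = 0, p = 1, df = length(auc_groups) - 1))
  }
  kt <- kruskal.test(values, g)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Dunn's post-hoc pairwise comparisons with Bonferroni adjustment
#'
#' Follow-up to [kruskal_wallis()]: z-statistics on differences of mean ranks
#' (with tie correction), two-sided p, Bonferroni-adjusted across all pairs,
#' flagged at `alpha`.
#'
#' @inheritParams kruskal_wallis
#' @param method Currently only `"dunn_bonferroni"`.
#' @param alpha Significance level for the `significant` flag.
#' @return A tibble with one row per strategy pair: `group1`, `group2`, `z`,
#'   `p`, `p_adj`, `significant`.
#' @export
pairwise_compare <- function(auc_groups, method = "dunn_bonferroni",
                             alpha = 0.05) {
  method <- match.arg(method)
  auc_groups <- as_auc_list(auc_groups)
  if (length(auc_groups) < 2 || any(lengths(auc_groups) < 2)) {
    stop_fusedr("Need >= 2 groups with >= 2 values each.", "input")
  }
  values <- unlist(auc_groups, use.names = FALSE)
  g <- rep(names(auc_groups), lengths(auc_groups))
  N <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  nms <- names(auc_groups)
  pairs <- utils::combn(nms, 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(var_base * (1 / ns[[a]] + 1 / ns[[b]]))
    z[j] <- if (se > 0) (mean_ranks[[a]] - mean_ranks[[b]]) / se else 0
    p[j] <- 2 * pnorm(-abs(z[j]))
  }
  p_adj <- p.adjust(p, method = "bonferroni")
  tibble(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
         p_adj = p_adj, significant = p_adj < alpha)
}

#' Compare several evaluated strategies
#'
#' Convenience wrapper running [kruskal_wallis()] and [pairwise_compare()] on
#' a set of `evaluation_result`s.
#'
#' @param results A named list of `evaluation_result`s (or AUC vectors).
#' @param alpha Significance level for the pairwise flags.
#' @return A list with `auc` (long tibble of per-repeat AUCs), `kruskal`
#'   (list `H`, `p`, `df`) and `pairwise` (tibble).
#' @export
compare_strategies <- function(results, alpha = 0.05) {
  groups <- as_auc_list(results)
  long <- bind_rows(imap(groups, function(v, nm) {
    tibble(strategy = nm, rep = seq_along(v), auc = v)
  }))
  list(auc = long,
       kruskal = kruskal_wallis(groups),
       pairwise = pairwise_compare(groups, alpha = alpha))
}

as_auc_list <- function(x) {
  if (inherits(x, "evaluation_result")) x <- list(x)
  out <- map(x, function(g) {
    if (inherits(g, "evaluation_result")) g$auc_per_repeat else as.numeric(g)
  })
  if (is.null(names(out)) || any(names(out) == "")) {
    nms <- map(x, function(g) if (inherits(g, "evaluation_result")) g$strategy_name else NA)
    names(out) <- ifelse(is.na(unlist(nms)),
                         paste0("group", seq_along(out)), unlist(nms))
  }
  out
}
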