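#' Tidy an evaluation result
#'
#' @param x An `evaluation_result`.
#' @param ... Unused.
#' @return A tibble with columns `strategy`, `rep`, `auc`.
#' @export
tidy.evaluation_result <- function(x, ...) {
  tibble(strategy = x$strategy_name, rep = seq_along(x$auc_per_repeat),
         auc = x$auc_per_repeat)
}

#' One-row summary of an evaluation result
#'
#' @param x An `evaluation_result`.
#' @param ... Unused.
#' @return A tibble with `strategy`, `mean_auc`, `sd_auc`, `repeats`.
#' @export
glance.evaluation_result <- function(x, ...) {
  tibble(strategy = x$strategy_name, mean_auc = x$mean, sd_auc = x$sd,
         repeats = length(x$auc_per_repeat))
}

#' @export
tidy.strategy_run <- function(x, ...) tidy(x$evaluation)

#' @export
glance.strategy_run <- function(x, ...) {
  out <- glance(x$evaluation)
  w <- x$fused$provenance$modality_weights
  if (!is.null(w)) out$weights <- paste(round(w, 3), collapse = "/")
  out
}

#' Tidy a fused representation
#'
#' @param x A `fused_representation`.
#' @param ... Unused.
#' @return A tibble: `sample_id` plus one column per fused dimension.
#' @export
tidy.fused_representation <- function(x, ...) {
  m <- x$values
  colnames(m) <- paste0("dim", seq_len(ncol(m)))
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  tibble(sample_id = ids, as_tibble(m))
}

#' Boxplot of per-repeat AUC distributions
#'
#' @param object An `evaluation_result`, or a named list of them (or the
#'   output of [compare_strategies()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evaluation_result <- function(object, ...) {
  plot_auc_distributions(list(object))
}

#' @rdname autoplot.evaluation_result
#' @export
plot_auc_distributions <- function(object, ...) {
  long <- if (is.data.frame(object)) {
    object
  } else if (is.list(object) && is.data.frame(object$auc)) {
    object$auc
  } else {
    groups <- as_auc_list(object)
    bind_rows(imap(groups, function(v, nm) {
      tibble(strategy = nm, rep = seq_along(v), auc = v)
    }))
  }
  ggplot(long, aes(x = .data$strategy, y = .data$auc)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    labs(x = NULL, y = "AUC (pooled per CV repeat)") +
    theme_minimal()
}

#' Scatter plot of the first two fused dimensions
#'
#' @param object A `fused_representation`.
#' @param labels Optional 0/1 labels used to color points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fused_representation <- function(object, labels = NULL, ...) {
  tb <- tidy(object)
  if (ncol(object$values) == 1) {
    tb$dim2 <- 0
  }
  if (!is.null(labels)) tb$class <- factor(labels)
  p <- ggplot(tb, aes(x = .data$dim1, y = .data$dim2)) + theme_minimal() +
    labs(x = "fused dim 1",
         y = if (ncol(object$values) == 1) NULL else "fused dim 2")
  if (!is.null(labels)) p + geom_point(aes(color = .data$class), size = 2)
  else p + geom_point(size = 2)
}
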