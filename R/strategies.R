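#' Preset multimodal fusion strategies
#'
#' The four published strategy presets wired from the package's modules:
#'
#' * `DFS-DD` — decision representation per modality (bagged-tree
#'   probabilities), direct fusion by probabilistic AND; supervised.
#' * `DFS-EC` — feature-perturbed PCA ensembles per modality, pairwise
#'   distances as co-association matrices, element-wise median combination,
#'   embedding of the combined matrix; unsupervised/unweighted.
#' * `DFS-KC` — Gaussian kernel per modality, modality weights learned on a
#'   simplex grid, semi-supervised co-association matrix, multi-kernel
#'   embedding; weighted, semi-supervised.
#' * `DFS-ES` — locally linear embedding per modality, Procrustes structural
#'   fusion (mean); unsupervised/unweighted.
#'
#' @param name One of `"DFS-DD"`, `"DFS-EC"`, `"DFS-KC"`, `"DFS-ES"`.
#' @param ... Named overrides merged shallowly into the preset's top-level
#'   fields (e.g. `d = 3`, `resampling = list(n = 10)`,
#'   `fusion = list(rule = "binary_and")`).
#' @return A `strategy_config`.
#' @export
strategy_preset <- function(name, ...) {
  cfg <- switch(
    name,
    "DFS-DD" = list(
      name = name, supervised = TRUE,
      representation = list(kind = "decision", folds = 3),
      resampling = NULL,
      weighting = list(type = "unweighted"),
      fusion = list(type = "direct", rule = "product_and"),
      d = 1
    ),
    "DFS-EC" = list(
      name = name, supervised = FALSE,
      representation = list(kind = "pca"),
      resampling = list(mode = "features", n = 25, subset_frac = 0.5,
                        replace = TRUE),
      weighting = list(type = "unweighted"),
      fusion = list(type = "coassociation", delta = "distance",
                    combine = "median"),
      d = 5
    ),
    "DFS-KC" = list(
      name = name, supervised = TRUE,
      representation = list(kind = "kernel", family = "gaussian",
                            sigma = "median", sigma_scale = 0.75),
      resampling = NULL,
      weighting = list(type = "weighted", objective = "fisher",
                       grid_step = 0.25, semi_supervised = TRUE,
                       supervision = 0.25),
      fusion = list(type = "multikernel", ridge = NULL),
      d = 2
    ),
    "DFS-ES" = list(
      name = name, supervised = FALSE,
      representation = list(kind = "lle", k = 10),
      resampling = NULL,
      weighting = list(type = "unweighted"),
      fusion = list(type = "structural", rule = "mean"),
      d = 5
    ),
    stop_fusedr(sprintf("Unknown strategy '%s'.", name), "config")
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]] <- modifyList(cfg[[nm]], dots[[nm]])
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "strategy_config")
}

#' @export
print.strategy_config <- function(x, ...) {
  cat(sprintf("<strategy_config> %s: %s representation, %s fusion (%s)%s\n",
              x$name, x$representation$kind, x$fusion$type,
              x$weighting$type,
              if (!is.null(x$resampling))
                sprintf(", resampling %s n=%d", x$resampling$mode,
                        x$resampling$n)
              else ""))
  invisible(x)
}

#' List the available preset strategies
#' @return Character vector of preset names.
#' @export
available_strategies <- function() c("DFS-DD", "DFS-EC", "DFS-KC", "DFS-ES")

# Build the fused representation for a dataset under a config, transductively
# over all N samples. `labels` is the label view the pipeline may read: in
# cross-validation it has the test fold masked to NA, so no supervised step
# can see test labels.
build_fused <- function(dataset, config, labels, seed = 1) {
  mods <- dataset$modalities
  d <- config$d
  out <- switch(
    config$fusion$type,
    direct = {
      decs <- imap(mods, function(m, nm) {
        compute_decisions(m, labels, folds = config$representation$folds,
                          seed = seed + which(names(mods) == nm),
                          modality_name = nm)
      })
      if (identical(config$fusion$rule, "binary_and")) {
        decs <- map(decs, function(dd) { dd$scores <- as.numeric(dd$scores >= 0.5); dd })
      }
      decision_and(unname(decs))
    },
    coassociation = {
      rs <- config$resampling
      Ws <- list()
      for (mi in seq_along(mods)) {
        m <- mods[[mi]]
        dm <- min(d, nrow(m) - 1, ncol(m))
        if (is.null(rs) || rs$n == 1) {
          reps <- list(fit_pca(m, dm))
        } else {
          reps <- generate_weak_representations(
            m, fit_pca, mode = rs$mode, n = rs$n, seed = seed + 1000 * mi,
            subset_size = max(dm, ceiling(rs$subset_frac * ncol(m))),
            replace = rs$replace %||% TRUE, d = dm)
        }
        Ws <- c(Ws, map(reps, build_coassociation,
                        delta = config$fusion$delta))
      }
      What <- combine_coassociation(Ws, rule = config$fusion$combine)
      coassociation_embed(What, d, strategy_name = config$name)
    },
    multikernel = {
      kerns <- imap(mods, function(m, nm) {
        sigma <- config$representation$sigma
        scl <- config$representation$sigma_scale %||% 1
        if (identical(sigma, "median") && scl != 1) {
          sigma <- scl * median_distance(m)
        }
        compute_kernel(m, family = config$representation$family,
                       sigma = sigma, modality_name = nm)
      })
      kerns <- unname(kerns)
      w <- if (identical(config$weighting$type, "weighted") &&
               length(kerns) > 1) {
        learn_modality_weights(kerns, labels,
                               objective = config$weighting$objective,
                               grid_step = config$weighting$grid_step,
                               d = d, seed = seed)
      } else rep(1 / length(kerns), length(kerns))
      What <- if (isTRUE(config$weighting$semi_supervised)) {
        semisupervised_coassociation(
          kerns, labels, weights = as.numeric(w),
          supervision = config$weighting$supervision %||% 0.5)
      } else {
        ksum <- Reduce(`+`, map2(map(kerns, "matrix"), as.numeric(w), `*`))
        new_coassociation(pmax(ksum, 0), "affinity", source = "kernel")
      }
      fr <- multikernel_embed(kerns, What, d, weights = as.numeric(w),
                              ridge = config$fusion$ridge,
                              strategy_name = config$name)
      fr$provenance$modality_weights <- as.numeric(w)
      fr
    },
    structural = {
      embeds <- imap(mods, function(m, nm) {
        dm <- min(d, config$representation$k - 1)
        fit_lle(m, d = dm, k = config$representation$k)
      })
      structural_fuse(unname(embeds), rule = config$fusion$rule,
                      strategy_name = config$name)
    },
    stop_fusedr(sprintf("Unknown fusion type '%s'.", config$fusion$type),
                "config")
  )
  out$strategy_name <- config$name
  out
}

#' Run a fusion strategy under repeated grouped cross-validation
#'
#' Executes the full pipeline of a [strategy_preset()] on a validated
#' dataset. The fused representation is constructed transductively over all
#' N samples, but every supervised step (decision cross-fits, weight
#' learning, semi-supervised co-association) only ever sees a label view
#' with the current test fold masked to `NA`; the bagged-tree classifier is
#' then trained on the training rows of the fused result and scored on the
#' test rows, pooling one AUC per repeat. Unsupervised strategies (DFS-EC,
#' DFS-ES) read no labels at all, so their fused representation is computed
#' once and shared across folds.
#'
#' @param dataset A `multimodal_dataset`.
#' @param config A `strategy_config` (or preset name).
#' @param folds,repeats Cross-validation geometry (defaults 3 and 25).
#' @param seed Master seed: fixes fold draws, every representation seed and
#'   every classifier seed.
#' @param n_trees,subsample_fraction Classifier settings.
#' @param poison_test_labels Audit switch: scrambles each fold's test labels
#'   before they are handed to the pipeline. Because the pipeline masks test
#'   labels, the output must be bit-identical with the switch on or off.
#' @return A `strategy_run`: list with `fused` (full-data
#'   `fused_representation`), `evaluation` (`evaluation_result`), `config`,
#'   `seed`.
#' @export
run_strategy <- function(dataset, config, folds = 3, repeats = 25, seed = 1,
                         n_trees = 100, subsample_fraction = 0.66,
                         poison_test_labels = FALSE) {
  if (is.character(config)) config <- strategy_preset(config)
  if (!inherits(config, "strategy_config")) {
    stop_fusedr("`config` must be a strategy_config or preset name.", "config")
  }
  labels <- dataset$labels
  if (config$supervised) {
    fold_fun <- function(tr, te, fold_seed) {
      labs <- labels
      if (poison_test_labels) {
        labs[te] <- withr::with_seed(fold_seed + 7L,
                                     sample(c(0L, 1L), length(te), TRUE))
      }
      labs[te] <- NA_integer_   # masked view: test labels unreadable below
      fused <- build_fused(dataset, config, labs, seed = fold_seed)
      fit <- bagged_trees(fused$values[tr, , drop = FALSE], labels[tr],
                          n_trees, subsample_fraction, seed = fold_seed)
      predict(fit, fused$values[te, , drop = FALSE])
    }
    evaluation <- repeated_grouped_cv(
      x = NULL, labels = labels, groups = dataset$groups, folds = folds,
      repeats = repeats, seed = seed, fold_fun = fold_fun,
      strategy_name = config$name)
  } else {
    fused_cv <- build_fused(dataset, config, rep(NA_integer_, dataset$N),
                            seed = seed)
    evaluation <- repeated_grouped_cv(
      x = fused_cv$values, labels = labels, groups = dataset$groups,
      folds = folds, repeats = repeats, seed = seed, n_trees = n_trees,
      subsample_fraction = subsample_fraction, strategy_name = config$name)
  }
  fused <- build_fused(dataset, config, labels, seed = seed)
  structure(list(fused = fused, evaluation = evaluation, config = config,
                 seed = seed),
            class = "strategy_run")
}

#' @export
print.strategy_run <- function(x, ...) {
  cat(sprintf("<strategy_run> %s\n", x$config$name))
  print(x$evaluation)
  invisible(x)
}
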