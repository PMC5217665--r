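#' Bootstrap sample-index multisets
#'
#' Draws `n` bootstrap replicates of `N` sample indices (uniform, with
#' replacement), the "perturbing the samples" route to generating weak
#' representations.
#'
#' @param N Number of samples (>= 2).
#' @param n Number of replicates (>= 1).
#' @param seed Integer seed; fully determines every draw.
#' @return A list of `n` integer vectors of length `N`.
#' @export
bootstrap_samples <- function(N, n, seed = 1) {
  if (N < 2 || n < 1) stop_fusedr("Need N >= 2 and n >= 1.", "parameter")
  withr::with_seed(seed, {
    map(seq_len(n), function(i) sample.int(N, N, replace = TRUE))
  })
}

#' Bootstrap feature-index multisets
#'
#' Draws `n` replicates of `subset_size` feature indices, with replacement by
#' default ("perturbing the features"). `replace = FALSE` with
#' `subset_size = P` degenerates to the identity feature set.
#'
#' @param P Number of features.
#' @param n Number of replicates.
#' @param subset_size Features drawn per replicate (>= 1).
#' @param seed Integer seed.
#' @param replace Draw with replacement (default `TRUE`).
#' @return A list of `n` integer vectors of length `subset_size`.
#' @export
perturb_features <- function(P, n, subset_size, seed = 1, replace = TRUE) {
  if (subset_size < 1) stop_fusedr("`subset_size` must be >= 1.", "parameter")
  if (!replace && subset_size > P) {
    stop_fusedr("`subset_size` cannot exceed P without replacement.", "parameter")
  }
  withr::with_seed(seed, {
    map(seq_len(n), function(i) {
      idx <- sample.int(P, subset_size, replace = replace)
      if (!replace) sort(idx) else idx
    })
  })
}

#' Parameter settings for parameter-perturbed ensembles
#'
#' One representation per parameter value ("perturbing the parameters"), order
#' preserved; duplicated values are collapsed with a warning.
#'
#' @param param_name Name of the parameter being varied (e.g. `"k"`).
#' @param values Non-empty vector of values.
#' @return A list of single-entry named lists, one per distinct value.
#' @export
parameter_grid <- function(param_name, values) {
  if (length(values) == 0) stop_fusedr("`values` must be non-empty.", "parameter")
  if (anyDuplicated(values)) {
    warn("Duplicate parameter values collapsed.")
    values <- unique(values)
  }
  map(values, function(v) setNames(list(v), param_name))
}

#' Generate an ensemble of weak representations
#'
#' Produces `n` representations of one modality by perturbing samples,
#' features, or a parameter of the base representation operator. Provenance
#' (the perturbation of each replicate) is attached as the
#' `"perturbations"` attribute.
#'
#' For `mode = "samples"`, a low-dimensional representation built on a
#' bootstrap replicate only covers the samples drawn; the returned coordinate
#' matrix is re-expressed over all N rows with `NA` for absent samples, and
#' co-association combination later takes per-entry medians over the
#' replicates where a pair is observed.
#'
#' @param x Numeric matrix (samples x features).
#' @param base_op A representation function taking the (perturbed) matrix
#'   first, e.g. `fit_pca`, `fit_lle`, `compute_kernel`, or a composition
#'   such as `function(m, ...) graph_embed(build_affinity(m), d = 5)`.
#' @param mode `"features"`, `"samples"`, or `"parameters"`.
#' @param n Number of replicates.
#' @param seed Integer seed.
#' @param subset_size Features per replicate for `mode = "features"`
#'   (default `ceiling(P / 2)`).
#' @param replace Feature draws with replacement (default `TRUE`).
#' @param param_name,param_values Parameter swept for `mode = "parameters"`
#'   (then `n` is taken from `length(param_values)`).
#' @param ... Further fixed arguments to `base_op`.
#' @return A list of `n` representations with a `"perturbations"` attribute.
#' @export
generate_weak_representations <- function(x, base_op,
                                          mode = c("features", "samples",
                                                   "parameters"),
                                          n = 25, seed = 1,
                                          subset_size = NULL, replace = TRUE,
                                          param_name = NULL,
                                          param_values = NULL, ...) {
  mode <- match.arg(mode)
  x <- rep_coords(x)
  N <- nrow(x); P <- ncol(x)
  run_replicate <- function(i, expr) {
    tryCatch(expr, error = function(e) {
      stop_fusedr(sprintf("Replicate %d failed: %s", i, conditionMessage(e)),
                  "replicate")
    })
  }
  if (mode == "features") {
    if (is.null(subset_size)) subset_size <- ceiling(P / 2)
    pert <- perturb_features(P, n, subset_size, seed, replace)
    reps <- imap(pert, function(idx, i) {
      xi <- x[, idx, drop = FALSE]
      colnames(xi) <- make.unique(colnames(xi))
      run_replicate(i, base_op(xi, ...))
    })
  } else if (mode == "samples") {
    pert <- bootstrap_samples(N, n, seed)
    reps <- imap(pert, function(idx, i) {
      uni <- sort(unique(idx))
      r <- run_replicate(i, base_op(x[uni, , drop = FALSE], ...))
      expand_to_all_samples(r, uni, N, rownames(x))
    })
  } else {
    if (is.null(param_values) || is.null(param_name)) {
      stop_fusedr("mode='parameters' needs `param_name` and `param_values`.",
                  "parameter")
    }
    pert <- parameter_grid(param_name, param_values)
    reps <- imap(pert, function(ps, i) {
      run_replicate(i, do.call(base_op, c(list(x), ps, list(...))))
    })
  }
  attr(reps, "perturbations") <- pert
  attr(reps, "mode") <- mode
  attr(reps, "seed") <- seed
  reps
}

# re-express a representation built on a subset of rows over all N rows,
# filling absent samples with NA (resolved at co-association combination)
expand_to_all_samples <- function(rep, idx, N, ids) {
  if (inherits(rep, "lowdim_representation")) {
    full <- matrix(NA_real_, N, ncol(rep$coords))
    full[idx, ] <- rep$coords
    rownames(full) <- ids
    rep$coords <- full
  } else if (inherits(rep, "kernel_representation")) {
    full <- matrix(NA_real_, N, N, dimnames = list(ids, ids))
    full[idx, idx] <- rep$matrix
    rep$matrix <- full
  } else if (is.matrix(rep)) {
    full <- matrix(NA_real_, N, ncol(rep))
    full[idx, ] <- rep
    rownames(full) <- ids
    rep <- full
  }
  rep
}

#' Serialize perturbation manifests
#'
#' Writes the replicate-to-indices map of a weak-representation ensemble as a
#' delimited table for audit.
#'
#' @param reps Output of [generate_weak_representations()].
#' @param path Output file (TSV).
#' @return The manifest tibble, invisibly.
#' @export
write_perturbation_manifest <- function(reps, path) {
  pert <- attr(reps, "perturbations")
  tab <- bind_rows(imap(pert, function(p, i) {
    if (is.list(p)) {
      tibble(replicate = i, kind = "parameter",
             value = paste(names(p), unlist(p), sep = "=", collapse = ";"))
    } else {
      tibble(replicate = i, kind = attr(reps, "mode"),
             value = paste(p, collapse = ","))
    }
  }))
  readr::write_tsv(tab, path)
  invisible(tab)
}
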