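#' Assemble and validate a multimodal dataset
#'
#' Aligns per-modality feature tables with a label table into a single
#' validated dataset object shared by every downstream stage. Samples are
#' matched by ID across all modalities (inner join); samples missing from any
#' modality are dropped with a warning. The internal sample order is
#' lexicographic by sample ID and is fixed here, so every N x N matrix built
#' later (kernels, co-association matrices) shares one indexing.
#'
#' @param modalities A named list of data frames (or numeric matrices with row
#'   names). Data frames must carry the sample ID in `id_col`; every other
#'   column must be numeric and is taken as a feature.
#' @param labels A data frame with the sample ID column, a binary label column
#'   (`label_col`, values 0/1, `NA` = unlabeled), and optionally a group /
#'   patient column (`group_col`). May also be a named vector of 0/1.
#' @param id_col,label_col,group_col Column names in the input tables.
#' @return An object of class `multimodal_dataset`: a list with `modalities`
#'   (named list of numeric matrices, row names = sample IDs), `sample_ids`,
#'   `labels` (integer 0/1 with `NA` for unlabeled), `groups` (character),
#'   `N`, `M`.
#' @examples
#' m1 <- data.frame(sample_id = c("a", "b", "c"), f1 = 1:3, f2 = 4:6)
#' m2 <- data.frame(sample_id = c("b", "c", "d"), g1 = c(0.1, 0.2, 0.3))
#' lab <- data.frame(sample_id = c("a", "b", "c", "d"), label = c(0, 1, 0, 1))
#' ds <- multimodal_dataset(list(x = m1, y = m2), lab)
#' ds$N  # 2: only b and c occur in every table
#' @export
multimodal_dataset <- function(modalities, labels,
                               id_col = "sample_id", label_col = "label",
                               group_col = "group") {
  if (!is.list(modalities) || length(modalities) == 0) {
    stop_fusedr("`modalities` must be a non-empty list of tables.", "validation")
  }
  if (is.null(names(modalities)) || any(names(modalities) == "")) {
    names(modalities) <- paste0("modality", seq_along(modalities))
  }
  mats <- imap(modalities, function(tab, nm) as_feature_matrix(tab, nm, id_col))

  lab_tab <- as_label_table(labels, id_col, label_col, group_col)

  ids <- Reduce(intersect, c(map(mats, rownames), list(lab_tab$sample_id)))
  if (length(ids) == 0) {
    stop_fusedr("No sample IDs are shared by all modality and label tables.",
                "alignment")
  }
  ids <- sort(ids)
  n_all <- max(vapply(mats, nrow, 0L), nrow(lab_tab))
  if (length(ids) < n_all) {
    warn(sprintf("Dropped %d sample(s) missing from at least one table; %d retained.",
                 n_all - length(ids), length(ids)))
  }

  mats <- map(mats, function(m) m[ids, , drop = FALSE])
  lab_tab <- lab_tab[match(ids, lab_tab$sample_id), ]

  lab <- lab_tab$label
  observed <- lab[!is.na(lab)]
  if (!all(observed %in% c(0, 1))) {
    stop_fusedr("Labels must be 0/1 (NA allowed for unlabeled samples).", "label")
  }
  if (length(unique(observed)) < 2) {
    stop_fusedr("Both classes must be present among labeled samples.", "label")
  }
  walk(mats, function(m) {
    if (!all(is.finite(m))) {
      stop_fusedr("Non-finite feature values after parsing.", "validation")
    }
  })

  structure(
    list(
      modalities = mats,
      sample_ids = ids,
      labels = as.integer(lab),
      groups = as.character(lab_tab$group),
      N = length(ids),
      M = length(mats)
    ),
    class = "multimodal_dataset"
  )
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat(sprintf("<multimodal_dataset> %d samples, %d modalities\n", x$N, x$M))
  for (nm in names(x$modalities)) {
    cat(sprintf("  %s: %d features\n", nm, ncol(x$modalities[[nm]])))
  }
  nlab <- sum(!is.na(x$labels))
  cat(sprintf("  labels: %d labeled (%d positive), %d unlabeled; %d groups\n",
              nlab, sum(x$labels == 1, na.rm = TRUE), x$N - nlab,
              length(unique(x$groups))))
  invisible(x)
}

#' Validate raw tables into a dataset
#'
#' Thin wrapper over [multimodal_dataset()] kept as the canonical entry point
#' for file-based workflows: reads nothing itself, just validates and aligns.
#'
#' @inheritParams multimodal_dataset
#' @return A `multimodal_dataset`.
#' @export
validate_dataset <- function(modalities, labels, id_col = "sample_id",
                             label_col = "label", group_col = "group") {
  multimodal_dataset(modalities, labels, id_col, label_col, group_col)
}

# Coerce one modality table to a numeric matrix with sample-ID row names.
as_feature_matrix <- function(tab, modality_name, id_col) {
  if (is.matrix(tab)) {
    if (is.null(rownames(tab))) {
      stop_fusedr(sprintf("Matrix modality '%s' needs sample IDs as row names.",
                          modality_name), "validation")
    }
    m <- tab
    storage.mode(m) <- "double"
  } else {
    tab <- as.data.frame(tab)
    if (!id_col %in% names(tab)) {
      stop_fusedr(sprintf("Modality '%s' lacks ID column '%s'.",
                          modality_name, id_col), "validation")
    }
    feats <- setdiff(names(tab), id_col)
    if (length(feats) < 1) {
      stop_fusedr(sprintf("Modality '%s' has no feature columns.", modality_name),
                  "validation")
    }
    bad <- feats[!vapply(tab[feats], is.numeric, TRUE)]
    if (length(bad) > 0) {
      stop_fusedr(sprintf("Non-numeric feature column(s) in '%s': %s.",
                          modality_name, paste(bad, collapse = ", ")), "parse")
    }
    m <- as.matrix(tab[feats])
    rownames(m) <- as.character(tab[[id_col]])
  }
  if (anyDuplicated(rownames(m))) {
    stop_fusedr(sprintf("Duplicate sample IDs in modality '%s'.", modality_name),
                "id")
  }
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)) ||
      any(colnames(m) == "")) {
    stop_fusedr(sprintf("Modality '%s' needs unique, non-empty feature names.",
                        modality_name), "validation")
  }
  attr(m, "modality_name") <- modality_name
  m
}

as_label_table <- function(labels, id_col, label_col, group_col) {
  if (is.atomic(labels) && !is.null(names(labels))) {
    labels <- data.frame(sample_id = names(labels), label = as.numeric(labels))
    id_col <- "sample_id"; label_col <- "label"; group_col <- "group"
  }
  labels <- as.data.frame(labels)
  if (!id_col %in% names(labels) || !label_col %in% names(labels)) {
    stop_fusedr(sprintf("Label table needs columns '%s' and '%s'.",
                        id_col, label_col), "validation")
  }
  if (anyDuplicated(labels[[id_col]])) {
    stop_fusedr("Duplicate sample IDs in label table.", "id")
  }
  grp <- if (group_col %in% names(labels)) as.character(labels[[group_col]])
         else as.character(labels[[id_col]])
  data.frame(
    sample_id = as.character(labels[[id_col]]),
    label = as.numeric(labels[[label_col]]),
    group = grp,
    stringsAsFactors = FALSE
  )
}

#' @export
as_tibble.multimodal_dataset <- function(x, ...) {
  wide <- do.call(cbind, unname(imap(x$modalities, function(m, nm) {
    colnames(m) <- paste(nm, colnames(m), sep = ".")
    m
  })))
  tibble(sample_id = x$sample_ids, label = x$labels, group = x$groups,
         as_tibble(wide))
}

# labeled-sample helpers used across modules
labeled_idx <- function(dataset) which(!is.na(dataset$labels))

check_binary_labels <- function(y) {
  y <- y[!is.na(y)]
  if (length(unique(y)) < 2) {
    stop_fusedr("Need both classes among labeled samples.", "degenerate_label")
  }
  invisible(TRUE)
}
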