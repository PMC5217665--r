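#' Read a modality feature table
#'
#' Reads a delimited (comma or tab, auto-detected) table with a header row,
#' first column = sample ID, remaining columns numeric features.
#'
#' @param path File path.
#' @return A tibble whose first column holds sample IDs.
#' @export
read_modality_table <- function(path) {
  if (!file.exists(path)) {
    stop_fusedr(sprintf("File not found: %s", path), "io")
  }
  delim <- detect_delim(path)
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  if (ncol(tab) < 2) stop_fusedr("Need an ID column plus >= 1 feature.", "parse")
  if (any(names(tab) == "") || anyNA(names(tab)) ||
      any(grepl("^\\.\\.\\.[0-9]+$", names(tab)))) {
    stop_fusedr(sprintf("Empty column name in %s.", path), "parse")
  }
  ids <- tab[[1]]
  if (anyDuplicated(ids)) {
    stop_fusedr(sprintf("Duplicate sample ID '%s' in %s.",
                        ids[anyDuplicated(ids)], path), "id")
  }
  out <- tab
  for (j in 2:ncol(tab)) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    bad <- which(is.na(v) & !is.na(tab[[j]]) & tab[[j]] != "NA")
    if (length(bad) > 0) {
      stop_fusedr(sprintf("Non-numeric value '%s' at row %d, column '%s' of %s.",
                          tab[[j]][bad[1]], bad[1], names(tab)[j], path),
                  "parse")
    }
    out[[j]] <- v
  }
  out
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Write a modality feature table
#'
#' @param x Numeric matrix with row names, or a data frame whose first
#'   column is the sample ID.
#' @param path Output path (`.tsv` extension writes tabs, otherwise commas).
#' @param id_col Name for the ID column when `x` is a matrix.
#' @return `path`, invisibly.
#' @export
write_modality_table <- function(x, path, id_col = "sample_id") {
  if (is.matrix(x)) {
    x <- as_tibble(x, rownames = id_col)
  }
  if (grepl("\\.tsv$", path)) readr::write_tsv(x, path)
  else readr::write_csv(x, path)
  invisible(path)
}

#' Read a label/group table
#'
#' @param path Delimited file with columns `sample_id`, `label` (0/1 or
#'   empty/NA for unlabeled) and optionally `group`.
#' @return A tibble.
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) stop_fusedr(sprintf("File not found: %s", path), "io")
  tab <- readr::read_delim(path, delim = detect_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "label") %in% names(tab))) {
    stop_fusedr("Label table needs 'sample_id' and 'label' columns.", "parse")
  }
  tab$sample_id <- as.character(tab$sample_id)
  tab$label <- suppressWarnings(as.numeric(tab$label))
  tab
}

#' Read a dataset from per-modality files plus a label file
#'
#' @param modality_paths Named character vector/list of modality file paths.
#' @param label_path Label/group file path.
#' @return A `multimodal_dataset`.
#' @export
read_dataset <- function(modality_paths, label_path) {
  mods <- map(as.list(modality_paths), read_modality_table)
  mods <- map(mods, function(tb) { names(tb)[1] <- "sample_id"; tb })
  multimodal_dataset(mods, read_label_table(label_path))
}

#' Write a dataset as modality CSVs plus a label CSV
#'
#' @param dataset A `multimodal_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (nm in names(dataset$modalities)) {
    p <- file.path(dir, paste0("modality_", nm, ".csv"))
    write_modality_table(dataset$modalities[[nm]], p)
    paths[nm] <- p
  }
  lp <- file.path(dir, "labels.csv")
  readr::write_csv(tibble(sample_id = dataset$sample_ids,
                          label = dataset$labels,
                          group = dataset$groups), lp)
  paths["labels"] <- lp
  invisible(paths)
}

#' Write a fused representation keyed by sample ID
#'
#' @param fused A `fused_representation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fused <- function(fused, path) {
  m <- fused$values
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%04d", seq_len(nrow(m)))
  colnames(m) <- paste0("dim", seq_len(ncol(m)))
  write_modality_table(m, path)
}

cli_config_keys <- c("data", "strategy", "strategies", "cv", "seed",
                     "overrides", "simulate")

#' Read and validate a run configuration file
#'
#' YAML configuration driving the command-line interface; the schema is
#' validated before any computation and unknown keys are reported
#' exhaustively in one message.
#'
#' @param path YAML file.
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_fusedr(sprintf("File not found: %s", path), "io")
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), cli_config_keys)
  if (length(unknown) > 0) {
    stop_fusedr(sprintf("Invalid config key(s): %s.",
                        paste(unknown, collapse = ", ")), "config")
  }
  if (!is.null(cfg$data)) {
    if (is.null(cfg$data$modalities) || is.null(cfg$data$labels)) {
      stop_fusedr("Config 'data' needs 'modalities' and 'labels'.", "config")
    }
    missing <- Filter(Negate(file.exists),
                      c(unlist(cfg$data$modalities), cfg$data$labels))
    if (length(missing) > 0) {
      stop_fusedr(sprintf("Missing input file(s): %s.",
                          paste(missing, collapse = ", ")), "io")
    }
  }
  cfg
}
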