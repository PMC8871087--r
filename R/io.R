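# Dataset I/O and the flat CSV dialect shared by all tools.
#
# Canonical table layout: `sample_id`, integer `label` (0 = majority/normal,
# 1..C-1 = disease classes), then marker columns in a fixed order.  The
# column order is authoritative: the template entropies of a row depend on
# it, so it is recorded on the table and in serialised models.

#' Read a labelled marker dataset from CSV
#'
#' Expects a header with `sample_id`, `label` and at least one marker column;
#' marker columns keep the file's order, which is recorded in the
#' `"marker_order"` attribute.  Labels must be consecutive integers starting
#' at 0 (0 = majority/normal class).
#'
#' @param path Path to a CSV file (UTF-8, `.` decimal, header mandatory).
#'
#' @return A data.frame with columns `sample_id` (character), `label`
#'   (integer) and numeric marker columns.
#' @export
read_marker_dataset <- function(path) {
  if (!file.exists(path))
    stop("dataset file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("dataset is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  marker_cols <- setdiff(names(df), required)
  if (length(marker_cols) < 1L)
    stop("dataset has no marker columns", call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id values: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "), call. = FALSE)
  for (cn in marker_cols) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))) &
                     !is.na(df[[cn]]))
      stop("non-numeric marker value in column '", cn, "', row ",
           if (length(bad)) bad[1L] else "?", call. = FALSE)
    }
  }
  lab <- df$label
  if (!is.numeric(lab) || any(lab != floor(lab)) || anyNA(lab))
    stop("labels must be integers", call. = FALSE)
  lab <- as.integer(lab)
  classes <- sort(unique(lab))
  if (!identical(classes, seq.int(0L, max(lab))))
    stop("labels must be consecutive integers starting at 0; found {",
         paste(classes, collapse = ", "), "}", call. = FALSE)
  df$label <- lab
  df <- df[, c(required, marker_cols)]
  attr(df, "marker_order") <- marker_cols
  df
}

#' Write a labelled marker dataset to CSV
#'
#' Inverse of [read_marker_dataset()]; round-trips losslessly (up to numeric
#' printing precision of 15 significant digits).
#'
#' @param dataset A labelled marker table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_marker_dataset <- function(dataset, path) {
  utils::write.csv(format_num_df(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

format_num_df <- function(df) {
  for (cn in names(df))
    if (is.double(df[[cn]]))
      df[[cn]] <- formatC(df[[cn]], format = "g", digits = 15)
  df
}

#' Extract the marker matrix from a labelled table
#'
#' @param dataset A labelled marker table (`sample_id`, `label`, markers).
#' @return Numeric matrix, one row per sample, marker columns in table order.
#' @export
marker_matrix <- function(dataset) {
  cols <- setdiff(names(dataset), c("sample_id", "label"))
  if (length(cols) < 1L)
    stop("no marker columns in dataset", call. = FALSE)
  x <- as.matrix(dataset[, cols, drop = FALSE])
  if (!is.numeric(x))
    stop("marker columns must be numeric", call. = FALSE)
  rownames(x) <- dataset$sample_id
  x
}

#' Serialise a fitted model to JSON
#'
#' Stores hyperparameters, cost matrix, standardiser statistics, priors and
#' the marker column order.  The training matrix is referenced by file path
#' and MD5 hash when `train_path` is given, otherwise embedded inline.
#'
#' @param model A fitted [csknn()] model.
#' @param path Output JSON path.
#' @param train_path Optional path of the training CSV to reference instead
#'   of embedding the training matrix.
#' @return `path`, invisibly.
#' @export
save_csknn <- function(model, path, train_path = NULL) {
  stopifnot(inherits(model, "csknn"))
  doc <- list(
    package = "csknn", version = "0.1.0",
    k = model$k, m_smooth = model$m_smooth,
    priors = as.list(stats::setNames(model$priors, model$classes)),
    cost_matrix = list(mode = model$cost_matrix$mode,
                       costs = model$cost_matrix$costs),
    standardizer = list(center = model$center, scale = model$scale),
    marker_order = model$marker_order,
    classes = model$classes
  )
  if (is.null(train_path)) {
    doc$train <- list(features = model$x, labels = model$y)
  } else {
    doc$train <- list(path = train_path,
                      md5 = unname(tools::md5sum(train_path)))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model serialised by [save_csknn()]
#'
#' @param path JSON path.
#' @return A fitted `csknn` model.
#' @export
load_csknn <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$train$features))
    stop("model references external training data (", doc$train$path,
         "); re-fit with csknn() after loading that file", call. = FALSE)
  model <- list(
    x = as.matrix(doc$train$features), y = as.integer(doc$train$labels),
    k = as.integer(doc$k), m_smooth = doc$m_smooth,
    priors = unlist(doc$priors, use.names = FALSE),
    cost_matrix = new_cost_matrix(as.matrix(doc$cost_matrix$costs),
                                  doc$cost_matrix$mode),
    center = unlist(doc$standardizer$center),
    scale = unlist(doc$standardizer$scale),
    marker_order = doc$marker_order,
    classes = as.integer(doc$classes)
  )
  model$class_counts <- tabulate(model$y + 1L, nbins = length(model$classes))
  class(model) <- "csknn"
  model
}
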