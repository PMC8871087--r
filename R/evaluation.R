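# Evaluation: confusion-matrix metrics, ROC/AUC by dichotomisation, and the
# jackknife / stratified k-fold experiment harnesses.

#' Confusion matrix
#'
#' @param true,predicted Integer label vectors (0-based), equal length.
#' @param n_classes Number of classes; defaults to `max(labels) + 1`.
#'
#' @return A `n_classes x n_classes` integer matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(true, predicted, n_classes = NULL) {
  true <- as.integer(true)
  predicted <- as.integer(predicted)
  if (length(true) != length(predicted))
    stop("label vectors have different lengths", call. = FALSE)
  if (is.null(n_classes)) n_classes <- max(true, predicted) + 1L
  if (any(true < 0L | true >= n_classes | predicted < 0L |
            predicted >= n_classes))
    stop("label outside 0..", n_classes - 1L, call. = FALSE)
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = as.character(0:(n_classes - 1L)),
                               predicted = as.character(0:(n_classes - 1L))))
  for (i in seq_along(true))
    cm[true[i] + 1L, predicted[i] + 1L] <- cm[true[i] + 1L,
                                              predicted[i] + 1L] + 1L
  cm
}

#' Classification metrics from a confusion matrix
#'
#' Per-class precision, recall and F1 are computed one-vs-rest.  Per-class
#' accuracy is the within-class fraction correct (identical to recall), and
#' the headline `Acc` is their unweighted mean over classes — i.e. balanced
#' accuracy.  Plain (micro) accuracy, the overall fraction correct, is also
#' always reported: on data where one class holds ~90% of the samples the
#' two can differ a lot, and published single "accuracy" figures rarely say
#' which they are.  The single precision/recall/F1 figures are macro
#' averages; `macro_f1` is the mean of per-class F1 while
#' `f1_of_macro` is the harmonic mean of macro-precision and macro-recall
#' (both are reported, labelled).  Zero-denominator ratios are reported as 0
#' with a warning.
#'
#' @param cm Confusion matrix from [confusion_matrix()] (rows = true).
#'
#' @return An object of class `"metrics_report"`: a list with
#'   `confusion`, `per_class` (data.frame of accuracy/precision/recall/F1),
#'   `acc_macro`, `accuracy_micro`, `macro_precision`, `macro_recall`,
#'   `macro_f1`, `f1_of_macro`.
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (sum(cm) == 0L)
    stop("empty confusion matrix", call. = FALSE)
  C <- nrow(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  undefined <- 0L
  safe_div <- function(num, den) {
    bad <- den == 0
    undefined <<- undefined + sum(bad)
    ifelse(bad, 0, num / den)
  }
  recall <- safe_div(tp, tp + fn)     # == per-class accuracy Acc_i
  precision <- safe_div(tp, tp + fp)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  if (undefined > 0L)
    warning(undefined, " undefined ratio(s) (zero denominator) reported ",
            "as 0", call. = FALSE)
  per_class <- data.frame(class = 0:(C - 1L), n = rowSums(cm),
                          accuracy = recall, precision = precision,
                          recall = recall, f1 = f1)
  mp <- mean(precision)
  mr <- mean(recall)
  structure(list(
    confusion = cm,
    per_class = per_class,
    acc_macro = mean(recall),
    accuracy_micro = sum(tp) / sum(cm),
    macro_precision = mp,
    macro_recall = mr,
    macro_f1 = mean(f1),
    f1_of_macro = if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(x$confusion)
  cat(sprintf("\nAcc (macro, mean per-class accuracy): %.4f\n", x$acc_macro))
  cat(sprintf("accuracy (micro, fraction correct):   %.4f\n",
              x$accuracy_micro))
  cat(sprintf("macro precision %.4f  macro recall %.4f  macro F1 %.4f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  if (!is.null(x$auc))
    cat(sprintf("AUC (%s): %.4f\n", x$auc_scheme, x$auc))
  invisible(x)
}

#' ROC curve and AUC by dichotomisation
#'
#' Collapses the multi-class problem to a binary one and computes the
#' trapezoidal area under the empirical ROC curve.  Tied scores are grouped
#' before integration, which makes the trapezoid equal the midpoint
#' (Mann-Whitney) convention.  The default `cancer_vs_normal` scheme pools
#' classes 1..C-1 as positives scored by `1 - p(0|x)`; `one_vs_rest_macro`
#' averages the per-class one-vs-rest AUCs.
#'
#' @param scores Queries x classes matrix of per-class scores (probabilities
#'   from [predict.csknn()], or negated expected costs).
#' @param true Integer true labels (0-based).
#' @param scheme `"cancer_vs_normal"` or `"one_vs_rest_macro"`.
#'
#' @return A list with `auc` and (for `cancer_vs_normal`) `curve`, a
#'   data.frame of `fpr`, `tpr`, `threshold`.
#' @export
roc_auc <- function(scores, true, scheme = c("cancer_vs_normal",
                                             "one_vs_rest_macro")) {
  scheme <- match.arg(scheme)
  scores <- as.matrix(scores)
  true <- as.integer(true)
  if (nrow(scores) != length(true))
    stop("scores and labels disagree in length", call. = FALSE)
  if (scheme == "cancer_vs_normal") {
    pos <- true > 0L
    if (all(pos) || !any(pos))
      stop("ROC undefined: only one class present in the truth",
           call. = FALSE)
    binary_roc(1 - scores[, 1L], pos)
  } else {
    aucs <- vapply(seq_len(ncol(scores)), function(j) {
      pos <- true == (j - 1L)
      if (all(pos) || !any(pos))
        stop("ROC undefined for class ", j - 1L, ": one-class truth",
             call. = FALSE)
      binary_roc(scores[, j], pos)$auc
    }, numeric(1))
    list(auc = mean(aucs), per_class_auc = aucs)
  }
}

# empirical ROC with tie grouping + trapezoidal AUC
binary_roc <- function(score, positive) {
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  y <- positive[o]
  # cumulative counts at each distinct threshold (ties grouped)
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]
  fp <- cumsum(!y)[last]
  tpr <- c(0, tp / sum(positive))
  fpr <- c(0, fp / sum(!positive))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(auc = auc,
       curve = data.frame(fpr = fpr, tpr = tpr,
                          threshold = c(Inf, s[last])))
}

# run one evaluation protocol and assemble the report
assemble_report <- function(true, label, prob) {
  n_classes <- ncol(prob)
  rep <- classification_metrics(confusion_matrix(true, label, n_classes))
  roc <- roc_auc(prob, true, "cancer_vs_normal")
  rep$auc <- roc$auc
  rep$auc_scheme <- "cancer_vs_normal"
  rep$roc_curve <- roc$curve
  rep$prob <- prob
  rep$true <- true
  rep$predicted <- label
  rep
}

#' Jackknife (leave-one-out) evaluation
#'
#' For every sample: refit the standardiser, priors and (ratio-mode) cost
#' matrix on the remaining n - 1 samples, predict the held-out sample, and
#' pool all n predictions into one confusion matrix and ROC.  Fully
#' deterministic — there is no randomness anywhere in the loop.
#'
#' @param x Feature matrix or labelled marker table.
#' @param y Integer labels (ignored when `x` is a labelled table).
#' @param k Neighbour count.
#' @param m_smooth m-estimation strength (0 = plain frequencies).
#' @param cost `"ratio"`, `"uniform"` or a `"cost_matrix"` (see [csknn()]).
#'   `"uniform"` with `m_smooth = 0` is classical majority-vote KNN.
#'
#' @return A `"metrics_report"` with `auc` and `roc_curve` attached.
#' @export
jackknife_evaluate <- function(x, y = NULL, k = 5L, m_smooth = 1,
                               cost = "ratio") {
  if (is.data.frame(x) && "label" %in% names(x)) {
    y <- x$label
    x <- marker_matrix(x)
  }
  x <- as.matrix(x)
  y <- as.integer(y)
  n <- nrow(x)
  counts_all <- tabulate(y + 1L, nbins = max(y) + 1L)
  if (any(counts_all < 2L))
    warning("class(es) with a single sample: their held-out prediction is ",
            "fitted without any same-class training row", call. = FALSE)
  n_classes <- max(y) + 1L
  label <- integer(n)
  prob <- matrix(0, n, n_classes)
  for (i in seq_len(n)) {
    pr <- fit_predict(x[-i, , drop = FALSE], y[-i],
                      x[i, , drop = FALSE], k, m_smooth, cost, n_classes)
    label[i] <- pr$label
    prob[i, ] <- pr$prob
  }
  assemble_report(y, label, prob)
}

#' Stratified k-fold evaluation
#'
#' Same leakage-safe refitting as [jackknife_evaluate()], but over
#' stratified folds; predictions from all folds are pooled into one report.
#' Deterministic given `seed`.
#'
#' @inheritParams jackknife_evaluate
#' @param folds Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @export
kfold_evaluate <- function(x, y = NULL, folds = 5L, seed = 1L, k = 5L,
                           m_smooth = 1, cost = "ratio") {
  if (is.data.frame(x) && "label" %in% names(x)) {
    y <- x$label
    x <- marker_matrix(x)
  }
  x <- as.matrix(x)
  y <- as.integer(y)
  n_classes <- max(y) + 1L
  fold <- make_stratified_folds(y, folds, seed)
  label <- integer(length(y))
  prob <- matrix(0, length(y), n_classes)
  for (f in seq_len(folds)) {
    te <- fold == f
    pr <- fit_predict(x[!te, , drop = FALSE], y[!te],
                      x[te, , drop = FALSE], k, m_smooth, cost, n_classes)
    label[te] <- pr$label
    prob[te, ] <- pr$prob
  }
  assemble_report(y, label, prob)
}

#' Compare feature sets under one protocol
#'
#' Runs the same evaluation protocol on up to three feature matrices built
#' from a labelled panel: the original markers, the 2-column entropy set
#' (ApEn + SaEn), and the combined matrix (markers plus both entropies).
#' Entropies are computed once on the raw marker rows; standardisation of
#' whichever matrix is evaluated happens inside the protocol, per split.
#'
#' @param dataset Labelled marker table.
#' @param sets Subset of `c("original", "entropy_only", "combined")`.
#' @param protocol `"jackknife"` or `"kfold"`.
#' @param folds,seed k-fold parameters (ignored for jackknife).
#' @param k,m_smooth,cost Classifier settings (see [csknn()]).
#' @param params Entropy parameters for the ApEn/SaEn columns.
#'
#' @return A list with `reports` (one `"metrics_report"` per set) and
#'   `comparison`, a data.frame with one metric per row and one column per
#'   feature set.
#' @export
feature_set_experiment <- function(dataset,
                                   sets = c("original", "entropy_only",
                                            "combined"),
                                   protocol = c("jackknife", "kfold"),
                                   folds = 5L, seed = 1L, k = 5L,
                                   m_smooth = 1, cost = "ratio",
                                   params = entropy_params()) {
  sets <- match.arg(sets, c("original", "entropy_only", "combined"),
                    several.ok = TRUE)
  protocol <- match.arg(protocol)
  y <- dataset$label
  markers <- marker_matrix(dataset)
  ent <- entropy_features(dataset, params, which = c("ApEn", "SaEn"),
                          undefined = "cap")
  ent_m <- as.matrix(ent[, c("ApEn", "SaEn")])
  if (anyNA(ent_m) || any(is.infinite(ent_m)))
    stop("entropy features contain degenerate values; inspect the panel",
         call. = FALSE)
  mats <- list(original = markers, entropy_only = ent_m,
               combined = cbind(markers, ent_m))
  run <- function(m) {
    if (protocol == "jackknife")
      jackknife_evaluate(m, y, k = k, m_smooth = m_smooth, cost = cost)
    else
      kfold_evaluate(m, y, folds = folds, seed = seed, k = k,
                     m_smooth = m_smooth, cost = cost)
  }
  reports <- lapply(mats[sets], run)
  metric_rows <- c("acc_macro", "accuracy_micro", "macro_precision",
                   "macro_recall", "macro_f1", "auc")
  comparison <- data.frame(
    metric = metric_rows,
    sapply(reports, function(r) unlist(r[metric_rows]), simplify = TRUE),
    check.names = FALSE)
  list(reports = reports, comparison = comparison)
}

#' Write a metrics report to disk
#'
#' Emits `<stem>_confusion.csv`, `<stem>_per_class.csv`,
#' `<stem>_roc.csv` (curve points, if present) and `<stem>_report.json`
#' (the full report).
#'
#' @param report A `"metrics_report"`.
#' @param stem Output path stem (directory must exist).
#' @return The JSON path, invisibly.
#' @export
write_metrics_report <- function(report, stem) {
  stopifnot(inherits(report, "metrics_report"))
  utils::write.csv(as.data.frame(report$confusion),
                   paste0(stem, "_confusion.csv"))
  utils::write.csv(report$per_class, paste0(stem, "_per_class.csv"),
                   row.names = FALSE)
  if (!is.null(report$roc_curve))
    utils::write.csv(report$roc_curve, paste0(stem, "_roc.csv"),
                     row.names = FALSE)
  json_path <- paste0(stem, "_report.json")
  keep <- c("acc_macro", "accuracy_micro", "macro_precision", "macro_recall",
            "macro_f1", "f1_of_macro", "auc")
  doc <- report[intersect(keep, names(report))]
  doc$confusion <- report$confusion
  doc$per_class <- report$per_class
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(json_path)
}
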