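# Cost-sensitive k-nearest-neighbour classifier.
#
# Prediction pipeline: z-standardise with training statistics, find the k
# nearest training rows by Euclidean distance, estimate class probabilities
# from the neighbour counts with m-estimation shrinkage towards the training
# priors, then assign the class with minimum expected misclassification cost
# L(i|x) = sum_j p(j|x) C(i,j).

#' Fit a cost-sensitive KNN model
#'
#' Stores the standardised training matrix, labels, priors and cost matrix.
#' All statistics (standardiser, priors, ratio-mode costs) come from the
#' training data only, so the model is leakage-safe when fitted inside a
#' resampling loop.
#'
#' @param x Numeric training matrix (rows = samples) or a labelled marker
#'   table (`sample_id`, `label`, markers), in which case `y` is taken from
#'   its `label` column.
#' @param y Integer class labels, 0-based (0 = majority/normal).  Ignored
#'   when `x` is a labelled table.
#' @param k Neighbour count, `1 <= k <= nrow(x)`.
#' @param m_smooth Non-negative m-estimation strength in `[0, 100]`; 0
#'   disables smoothing (raw neighbour frequencies), large values shrink the
#'   probabilities towards the training priors.
#' @param cost `"ratio"` (imbalance-ratio costs from the training counts),
#'   `"uniform"`, or a `"cost_matrix"` object.
#'
#' @return An object of class `"csknn"`.
#' @seealso [predict.csknn()], [build_cost_matrix()]
#' @export
#' @examples
#' panel <- simulate_panel(sim_config(class_sizes = c(60, 15, 15), seed = 1))
#' fit <- csknn(panel, k = 5, m_smooth = 1)
#' table(predict(fit, marker_matrix(panel))$label, panel$label)
csknn <- function(x, y = NULL, k = 5L, m_smooth = 1, cost = "ratio") {
  marker_order <- NULL
  if (is.data.frame(x) && all(c("label") %in% names(x))) {
    y <- x$label
    marker_order <- setdiff(names(x), c("sample_id", "label"))
    x <- marker_matrix(x)
  }
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) != length(y))
    stop("x and y dimensions disagree", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values in training data", call. = FALSE)
  classes <- 0:max(y)
  if (min(y) < 0L)
    stop("labels must be >= 0", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > nrow(x))
    stop("k must be between 1 and the number of training rows", call. = FALSE)
  if (!is.numeric(m_smooth) || m_smooth < 0 || m_smooth > 100)
    stop("m_smooth must be in [0, 100]", call. = FALSE)
  counts <- tabulate(y + 1L, nbins = length(classes))
  if (any(counts == 0L))
    stop("every class 0..max(label) needs at least one training sample",
         call. = FALSE)
  cm <- resolve_cost(cost, counts)
  if (cm$n_classes != length(classes))
    stop("cost matrix has ", cm$n_classes, " classes but labels imply ",
         length(classes), call. = FALSE)
  std <- zscore_standardize(x)
  structure(list(x = std$train, y = y, k = k, m_smooth = m_smooth,
                 priors = counts / sum(counts), class_counts = counts,
                 cost_matrix = cm, center = std$center, scale = std$scale,
                 marker_order = marker_order, classes = classes,
                 metric = "euclidean"),
            class = "csknn")
}

resolve_cost <- function(cost, counts) {
  if (inherits(cost, "cost_matrix")) return(cost)
  if (identical(cost, "ratio")) return(build_cost_matrix(counts))
  if (identical(cost, "uniform")) return(uniform_cost_matrix(length(counts)))
  stop("`cost` must be \"ratio\", \"uniform\" or a cost_matrix object",
       call. = FALSE)
}

#' @export
print.csknn <- function(x, ...) {
  cat("Cost-sensitive KNN model\n")
  cat("  training samples:", nrow(x$x), " features:", ncol(x$x), "\n")
  cat("  class counts:", paste(x$class_counts, collapse = "/"), "\n")
  cat("  k =", x$k, " m_smooth =", x$m_smooth,
      " cost mode:", x$cost_matrix$mode, "\n")
  invisible(x)
}

# Euclidean distances from one query to every training row; computed
# directly (not via the quadratic expansion) so duplicated rows give exactly
# equal distances and the index tie-break is reliable.
query_distances <- function(train_t, query) {
  sqrt(colSums((train_t - query)^2))
}

#' Nearest training neighbours of a query
#'
#' Euclidean distances in the model's standardised feature space; ties at
#' the k-th distance are broken by training-row index (lower index wins), so
#' the result is deterministic.
#'
#' @param model A fitted [csknn()] model.
#' @param query Numeric vector on the raw feature scale (standardised
#'   internally with the model's training statistics).
#' @param k Number of neighbours; defaults to the model's k.
#'
#' @return A list with `index`, `label` and `distance`, each of length `k`,
#'   ordered by increasing distance.
#' @export
nearest_neighbors <- function(model, query, k = model$k) {
  stopifnot(inherits(model, "csknn"))
  query <- as.numeric(query)
  if (length(query) != ncol(model$x))
    stop("query has ", length(query), " features; model expects ",
         ncol(model$x), call. = FALSE)
  q <- (query - model$center) / model$scale
  d <- query_distances(t(model$x), q)
  o <- order(d)[seq_len(k)]  # stable: equal distances keep index order
  list(index = o, label = model$y[o], distance = d[o])
}

#' m-estimation class probabilities from neighbour labels
#'
#' Shrinks the raw neighbour frequency k_j / k towards the prior b_j:
#' `p(j|x) = (k / (k + m)) * k_j / k + (m / (k + m)) * b_j`.
#' At m = 0 this is the plain relative frequency; as m grows the estimate
#' approaches the prior.  The probabilities sum to 1 algebraically.
#'
#' @param neighbor_labels Integer vector of the k neighbours' labels
#'   (0-based).
#' @param k Neighbour count (defaults to `length(neighbor_labels)`).
#' @param m_smooth Non-negative smoothing strength.
#' @param priors Per-class prior probabilities, class 0 first, summing to 1.
#'
#' @return A list with `prob` (per-class probabilities) and
#'   `neighbor_counts` (the k_j).
#' @export
#' @examples
#' class_probabilities(c(0, 0, 0, 1, 2), m_smooth = 5,
#'                     priors = c(0.8, 0.1, 0.1))
class_probabilities <- function(neighbor_labels, k = length(neighbor_labels),
                                m_smooth = 0, priors) {
  if (m_smooth < 0) stop("m_smooth must be >= 0", call. = FALSE)
  if (abs(sum(priors) - 1) > 1e-8)
    stop("priors must sum to 1", call. = FALSE)
  kj <- tabulate(as.integer(neighbor_labels) + 1L, nbins = length(priors))
  w <- k / (k + m_smooth)
  list(prob = w * kj / k + (1 - w) * priors, neighbor_counts = kj)
}

#' Expected misclassification costs
#'
#' `L(i|x) = sum_j p(j|x) * C(j, i)`: the probability-weighted cost of
#' calling sample x class i, where `C(j, i)` is the cost of classifying a
#' true-class-j sample as class i (rows = true class, see
#' [build_cost_matrix()]).  The predicted class is the argmin; since the
#' diagonal is zero, a class with probability 1 has zero expected cost.
#'
#' @param probs Per-class probabilities (numeric vector, or the list
#'   returned by [class_probabilities()]).
#' @param cm A `"cost_matrix"` object.
#'
#' @return Numeric vector of per-class expected costs.
#' @export
#' @examples
#' expected_costs(c(0.9, 0.05, 0.05), serum_cost_matrix())
expected_costs <- function(probs, cm) {
  p <- if (is.list(probs)) probs$prob else as.numeric(probs)
  stopifnot(inherits(cm, "cost_matrix"))
  if (length(p) != cm$n_classes)
    stop("probability vector length does not match cost matrix", call. = FALSE)
  unname(colSums(cm$costs * p))
}

# argmin of expected cost; ties toward the class with more training
# samples, then the lower label index
pick_label <- function(L, class_counts) {
  order(L, -class_counts, seq_along(L))[1L] - 1L
}

#' Predict classes, probabilities and expected costs
#'
#' @param object A fitted [csknn()] model.
#' @param newdata Numeric matrix of queries on the raw feature scale (one
#'   row per query), or a labelled marker table.
#' @param ... Unused.
#'
#' @return A list of class `"csknn_prediction"`: `label` (integer vector),
#'   `prob` (queries x classes probability matrix) and `cost` (queries x
#'   classes expected-cost matrix).
#' @export
predict.csknn <- function(object, newdata, ...) {
  if (is.data.frame(newdata) && "label" %in% names(newdata))
    newdata <- marker_matrix(newdata)
  q <- as.matrix(newdata)
  if (ncol(q) != ncol(object$x))
    stop("newdata has ", ncol(q), " features; model expects ",
         ncol(object$x), call. = FALSE)
  q <- sweep(sweep(q, 2L, object$center), 2L, object$scale, "/")
  nb <- ordered_neighbor_labels(object$x, q, object$y, object$k)
  predict_from_neighbors(nb, object$k, object$m_smooth, object$priors,
                         object$cost_matrix, object$class_counts)
}

# ntest x kmax matrix of neighbour labels (0-based), nearest first
ordered_neighbor_labels <- function(train_std, test_std, train_y, kmax) {
  tt <- t(train_std)
  out <- matrix(0L, nrow(test_std), kmax)
  for (i in seq_len(nrow(test_std))) {
    d <- query_distances(tt, test_std[i, ])
    out[i, ] <- train_y[order(d)[seq_len(kmax)]]
  }
  out
}

predict_from_neighbors <- function(neighbor_labels, k, m_smooth, priors,
                                   cm, class_counts) {
  nq <- nrow(neighbor_labels)
  C <- length(priors)
  prob <- matrix(0, nq, C, dimnames = list(NULL, as.character(0:(C - 1L))))
  cost <- prob
  label <- integer(nq)
  for (i in seq_len(nq)) {
    pe <- class_probabilities(neighbor_labels[i, seq_len(k)], k, m_smooth,
                              priors)
    L <- expected_costs(pe, cm)
    prob[i, ] <- pe$prob
    cost[i, ] <- L
    label[i] <- pick_label(L, class_counts)
  }
  structure(list(label = label, prob = prob, cost = cost),
            class = "csknn_prediction")
}

# fit on (train_x, train_y), predict test_x; used by every resampling loop.
# n_classes fixes the full class space so a split that loses a class still
# yields full-length probability vectors (the lost class keeps prior 0 and a
# count floor of 1 inside the ratio cost matrix).
fit_predict <- function(train_x, train_y, test_x, k, m_smooth, cost,
                        n_classes = max(train_y) + 1L) {
  std <- zscore_standardize(train_x, test_x)
  counts <- tabulate(train_y + 1L, nbins = n_classes)
  cm <- resolve_cost(cost, pmax(counts, 1L))
  nb <- ordered_neighbor_labels(std$train, std$apply, train_y, k)
  predict_from_neighbors(nb, k, m_smooth, counts / sum(counts), cm, counts)
}

# stratified fold assignment: within each class, shuffled round-robin
make_stratified_folds <- function(y, folds, seed) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  small <- tabulate(y + 1L) < folds
  if (any(small))
    warning("class(es) ", paste(which(small) - 1L, collapse = ", "),
            " have fewer samples than folds; some folds miss them",
            call. = FALSE)
  fold
}

# mean of per-class F1 (zero-denominator classes contribute 0)
macro_f1 <- function(true, pred, n_classes) {
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true))
    cm[true[i] + 1L, pred[i] + 1L] <- cm[true[i] + 1L, pred[i] + 1L] + 1L
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  mean(f1)
}

# shared CV scoring engine for select_k / select_m: returns folds x
# n_settings score matrix; `score_fun(true, pred)` maps fold predictions to
# one number.  Neighbour ranking is computed once per fold at kmax and
# reused for every setting.
cv_scores <- function(x, y, settings, folds, seed, score_fun, kmax,
                      predict_setting) {
  fold <- make_stratified_folds(y, folds, seed)
  scores <- matrix(NA_real_, folds, length(settings))
  for (f in seq_len(folds)) {
    te <- fold == f
    std <- zscore_standardize(x[!te, , drop = FALSE], x[te, , drop = FALSE])
    train_y <- y[!te]
    counts <- tabulate(train_y + 1L, nbins = max(y) + 1L)
    nb <- ordered_neighbor_labels(std$train, std$apply, train_y,
                                  min(kmax, nrow(std$train)))
    for (s in seq_along(settings)) {
      pred <- predict_setting(settings[[s]], nb, counts)
      scores[f, s] <- score_fun(y[te], pred)
    }
  }
  scores
}

# "maximum accuracy and minimum variance" compromise: among settings whose
# mean score is within one standard error of the best mean, take the one
# with the smallest variance (ties -> first, i.e. smallest k / m)
select_by_compromise <- function(scores) {
  mu <- colMeans(scores)
  v <- apply(scores, 2L, stats::var)
  best <- which.max(mu)
  se <- stats::sd(scores[, best]) / sqrt(nrow(scores))
  candidate <- which(mu >= mu[best] - se)
  chosen <- candidate[which.min(v[candidate])]
  list(index = chosen, mean = mu, var = v)
}

#' Select the neighbour count k by cross-validation
#'
#' Stratified k-fold cross-validation over a grid of k values.  For each k
#' the mean and variance of the fold accuracies are computed; the chosen k
#' has the minimum variance among all k whose mean accuracy is within one
#' standard error of the best mean ("maximum accuracy and minimum variance"
#' made explicit).  Standardiser, priors and ratio costs are refitted inside
#' every fold.  Deterministic given `seed`.
#'
#' @param x Numeric feature matrix or labelled marker table.
#' @param y Integer labels (ignored when `x` is a labelled table).
#' @param k_grid Integer vector of candidate k values.  Default `1:30`.
#' @param folds Number of cross-validation folds.  Default 10.
#' @param seed Integer seed for the fold assignment.
#' @param m_smooth,cost Passed to the classifier (see [csknn()]).
#'
#' @return A list with `k` (chosen value) and `table` (data.frame of k,
#'   mean_accuracy, var_accuracy).
#' @export
select_k <- function(x, y = NULL, k_grid = 1:30, folds = 10L, seed = 1L,
                     m_smooth = 1, cost = "ratio") {
  if (is.data.frame(x) && "label" %in% names(x)) {
    y <- x$label
    x <- marker_matrix(x)
  }
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(k_grid) < 1L || any(k_grid < 1L))
    stop("k_grid must contain integers >= 1", call. = FALSE)
  scores <- cv_scores(
    x, y, as.list(k_grid), folds, seed,
    score_fun = function(true, pred) mean(true == pred),
    kmax = max(k_grid),
    predict_setting = function(k, nb, counts) {
      k <- min(k, ncol(nb))
      cm <- resolve_cost(cost, pmax(counts, 1L))
      predict_from_neighbors(nb, k, m_smooth, counts / sum(counts), cm,
                             counts)$label
    })
  sel <- select_by_compromise(scores)
  list(k = k_grid[sel$index],
       table = data.frame(k = k_grid, mean_accuracy = sel$mean,
                          var_accuracy = sel$var))
}

#' Select the smoothing strength m by cross-validation
#'
#' Same protocol as [select_k()] but over a (default logarithmic) grid of
#' m-estimation strengths, scored by macro-F1: overall accuracy is
#' insensitive to minority classes, which smoothing exists to protect.
#'
#' @inheritParams select_k
#' @param m_grid Numeric candidate smoothing strengths within
#'   `[0.01, 100]`.  Default `c(0.01, 0.1, 1, 10, 100)`.
#' @param k Neighbour count used while scoring m.
#'
#' @return A list with `m_smooth` (chosen value) and `table` (data.frame of
#'   m, mean_macro_f1, var_macro_f1).
#' @export
select_m <- function(x, y = NULL, m_grid = c(0.01, 0.1, 1, 10, 100),
                     folds = 10L, seed = 1L, k = 5L, cost = "ratio") {
  if (is.data.frame(x) && "label" %in% names(x)) {
    y <- x$label
    x <- marker_matrix(x)
  }
  m_grid <- sort(unique(as.numeric(m_grid)))
  if (length(m_grid) < 1L || any(m_grid < 0) || any(m_grid > 100))
    stop("m_grid values must lie in [0, 100]", call. = FALSE)
  n_classes <- max(y) + 1L
  scores <- cv_scores(
    x, y, as.list(m_grid), folds, seed,
    score_fun = function(true, pred) macro_f1(true, pred, n_classes),
    kmax = k,
    predict_setting = function(m, nb, counts) {
      cm <- resolve_cost(cost, pmax(counts, 1L))
      predict_from_neighbors(nb, min(k, ncol(nb)), m, counts / sum(counts),
                             cm, counts)$label
    })
  sel <- select_by_compromise(scores)
  list(m_smooth = m_grid[sel$index],
       table = data.frame(m = m_grid, mean_macro_f1 = sel$mean,
                          var_macro_f1 = sel$var))
}
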