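# Entropy measures of a per-sample marker sequence.
#
# A sample's ordered vector of P marker values is treated as a sequence
# u(1..n); ApEn/SaEn/FuzzyEn quantify its regularity via m-length template
# matching under the tolerance r * SD(u), InfoEn the spread of its value
# proportions.  All four are computed on raw (un-standardised) values, so
# each is invariant to a common positive rescaling of that sample.

#' Entropy parameters
#'
#' Bundle of the tunable parameters shared by the entropy measures.
#'
#' @param m_embed Positive integer embedding dimension (template length).
#'   Default 2.
#' @param r Positive similarity tolerance coefficient; the match threshold is
#'   `r * sd(u)` per sequence.  Default 0.25.
#' @param p_fuzzy Positive exponent of the fuzzy membership function
#'   `exp(-d^p_fuzzy / (r * sd))`.  Default 2.
#' @param log_base Logarithm base for [info_entropy()].  Default 2 (bits).
#'
#' @return A list of class `"entropy_params"`.
#' @export
#' @examples
#' entropy_params(m_embed = 2, r = 0.25)
entropy_params <- function(m_embed = 2L, r = 0.25, p_fuzzy = 2, log_base = 2) {
  m_embed <- as.integer(m_embed)
  if (length(m_embed) != 1L || is.na(m_embed) || m_embed < 1L)
    stop("`m_embed` must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0 || r > 1)
    stop("`r` must be a single number in (0, 1]", call. = FALSE)
  if (!is.numeric(p_fuzzy) || length(p_fuzzy) != 1L || p_fuzzy <= 0)
    stop("`p_fuzzy` must be a single positive number", call. = FALSE)
  if (!is.numeric(log_base) || length(log_base) != 1L || log_base <= 1)
    stop("`log_base` must be a single number > 1", call. = FALSE)
  structure(list(m_embed = m_embed, r = r, p_fuzzy = p_fuzzy,
                 log_base = log_base),
            class = "entropy_params")
}

# validate a sequence for template-based entropies; returns numeric vector
check_sequence <- function(seq, m_embed, what) {
  seq <- as.numeric(seq)
  n <- length(seq)
  if (anyNA(seq))
    stop(what, ": sequence contains missing values", call. = FALSE)
  if (n < m_embed + 2L)
    stop(what, ": sequence length ", n, " is too short for embedding ",
         "dimension ", m_embed, " (need at least ", m_embed + 2L, ")",
         call. = FALSE)
  if (stats::sd(seq) == 0)
    stop(what, ": degenerate sequence (all values equal, SD = 0); the ",
         "tolerance r * SD is zero and no template can match",
         call. = FALSE)
  seq
}

# Chebyshev distance matrix between the m-length templates of u.
# Templates are rows of the (n - m + 1) x m embedding matrix.
template_distances <- function(u, m) {
  n <- length(u)
  nt <- n - m + 1L
  d <- matrix(0, nt, nt)
  for (k in seq_len(m)) {
    col <- u[k:(k + nt - 1L)]
    d <- pmax(d, abs(outer(col, col, "-")))
  }
  d
}

#' Approximate entropy of a sequence
#'
#' Regularity statistic `ApEn(n, m, r) = phi^m(r) - phi^(m+1)(r)` where
#' `phi^m` is the mean over templates of `log` of the fraction of templates
#' within Chebyshev distance `r * sd(u)`.  Counts include the self-match
#' (every count is at least 1, so the logarithm is always defined).  Larger
#' values mean a more irregular sequence: templates similar at length m are
#' less likely to remain similar at length m + 1.
#'
#' @param seq Numeric vector, the marker sequence u(1..n).
#' @param params An [entropy_params()] object.
#' @param trace If `TRUE`, attach the intermediate template distances and
#'   match ratios as the `"trace"` attribute (for debugging and testing).
#'
#' @return A single finite number.
#' @seealso [sample_entropy()], [fuzzy_entropy()]
#' @export
#' @examples
#' set.seed(1)
#' approximate_entropy(runif(39), entropy_params())
approximate_entropy <- function(seq, params = entropy_params(),
                                trace = FALSE) {
  u <- check_sequence(seq, params$m_embed, "approximate_entropy")
  tol <- params$r * stats::sd(u)
  phi <- function(m) {
    d <- template_distances(u, m)
    ratios <- rowMeans(d < tol)  # self-match included: diagonal is 0 < tol
    list(phi = mean(log(ratios)), d = d, ratios = ratios)
  }
  lo <- phi(params$m_embed)
  hi <- phi(params$m_embed + 1L)
  out <- lo$phi - hi$phi
  if (trace)
    attr(out, "trace") <- list(distances = lo$d, match_ratios = lo$ratios,
                               phi = c(lo$phi, hi$phi))
  out
}

#' Sample entropy of a sequence
#'
#' `SaEn(n, m, r) = -log(C^(m+1) / C^m)` where `C^m` is the mean fraction of
#' template pairs (self-matches excluded) within Chebyshev distance
#' `r * sd(u)`.  Both levels use the same n - m templates, the standard
#' sample-entropy convention, so the ratio compares identical pair sets.
#' Unlike approximate entropy there is no self-match bias, and the value does
#' not depend systematically on the sequence length.
#'
#' @inheritParams approximate_entropy
#'
#' @return A non-negative number, or `Inf` when no template pair matches at
#'   level m + 1 (the conditional probability is zero; flagged, not an error).
#' @export
#' @examples
#' set.seed(1)
#' sample_entropy(runif(39), entropy_params())
sample_entropy <- function(seq, params = entropy_params(), trace = FALSE) {
  u <- check_sequence(seq, params$m_embed, "sample_entropy")
  m <- params$m_embed
  tol <- params$r * stats::sd(u)
  nt <- length(u) - m  # templates used at BOTH levels
  count_level <- function(mm) {
    d <- template_distances(u, mm)[seq_len(nt), seq_len(nt), drop = FALSE]
    diag(d) <- Inf  # exclude self-matches
    mean(rowSums(d < tol)) / (nt - 1L)
  }
  b <- count_level(m)
  a <- count_level(m + 1L)
  out <- if (a == 0) Inf else -log(a / b)
  if (trace) attr(out, "trace") <- list(C_m = b, C_m1 = a)
  out
}

#' Fuzzy entropy of a sequence
#'
#' Like sample entropy but with a continuous membership function instead of a
#' hard threshold: templates are baseline-removed (each template minus its own
#' mean), and each pair contributes `exp(-d^p_fuzzy / (r * sd(u)))` where d is
#' the Chebyshev distance between the centred templates.  Memberships are
#' strictly positive, so the result is finite for every non-degenerate input.
#'
#' @inheritParams approximate_entropy
#'
#' @return A single finite number, `log(phi^m) - log(phi^(m+1))`.
#' @export
#' @examples
#' set.seed(1)
#' fuzzy_entropy(runif(39), entropy_params())
fuzzy_entropy <- function(seq, params = entropy_params(), trace = FALSE) {
  u <- check_sequence(seq, params$m_embed, "fuzzy_entropy")
  tol <- params$r * stats::sd(u)
  phi <- function(m) {
    n <- length(u)
    nt <- n - m + 1L
    emb <- sapply(seq_len(m), function(k) u[k:(k + nt - 1L)])
    emb <- emb - rowMeans(emb)  # remove each template's own baseline
    d <- matrix(0, nt, nt)
    for (k in seq_len(m)) d <- pmax(d, abs(outer(emb[, k], emb[, k], "-")))
    mu <- exp(-(d^params$p_fuzzy) / tol)
    diag(mu) <- 0  # j != i
    list(phi = mean(rowSums(mu) / (nt - 1L)), mu = mu)
  }
  lo <- phi(params$m_embed)
  hi <- phi(params$m_embed + 1L)
  out <- log(lo$phi) - log(hi$phi)
  if (trace)
    attr(out, "trace") <- list(memberships = lo$mu,
                               phi = c(lo$phi, hi$phi))
  out
}

#' Information entropy of a sequence
#'
#' Shannon entropy of the sequence's value proportions: with
#' `p_i = u(i) / sum(u)`, returns `-sum(p_i * log(p_i))` in base `log_base`
#' (bits by default).  Marker values are concentrations and must be strictly
#' positive.  Bounded above by `log_base(n)`, attained exactly when all
#' values are equal; near-uniform positive panels sit just under the ceiling.
#'
#' @inheritParams approximate_entropy
#'
#' @return A number in `[0, log(n, log_base)]`.
#' @export
#' @examples
#' info_entropy(rep(1, 39))  # log2(39)
info_entropy <- function(seq, params = entropy_params()) {
  u <- as.numeric(seq)
  if (length(u) < 1L || anyNA(u))
    stop("info_entropy: need a non-empty sequence without missing values",
         call. = FALSE)
  if (any(u <= 0))
    stop("info_entropy: all values must be strictly positive ",
         "(marker concentrations); found ", sum(u <= 0),
         " non-positive value(s)", call. = FALSE)
  p <- u / sum(u)
  -sum(p * log(p, base = params$log_base))
}

#' Entropy feature columns for a whole dataset
#'
#' Treats each sample row as a sequence (in the dataset's fixed marker column
#' order) and computes the requested entropy measures on the raw marker
#' values.  Samples that trigger a degenerate branch (zero-SD sequence, or no
#' sample-entropy match at level m + 1) receive `NA`/`Inf` flags and are
#' reported via a warning, never dropped.
#'
#' @param dataset A labelled marker table as returned by
#'   [read_marker_dataset()] or [simulate_panel()]: columns `sample_id`,
#'   `label`, then marker columns in order.
#' @param params An [entropy_params()] object.
#' @param which Character subset of `c("ApEn", "SaEn", "FuzzyEn", "InfoEn")`.
#' @param undefined How to treat an undefined sample entropy (no template
#'   pair matches at level m + 1).  `"flag"` (default) keeps the `Inf` flag;
#'   `"cap"` substitutes `log(nt * (nt - 1) / 2)` with `nt = n - m_embed`,
#'   the largest value estimable from that sequence (the conditional
#'   probability cannot be resolved below one pair in `nt * (nt - 1) / 2`),
#'   so the column stays finite for classifiers.  Degenerate sequences
#'   (SD = 0) are always flagged `NA`.
#'
#' @return A data.frame with `sample_id` and one column per requested
#'   entropy, one row per sample (same order as `dataset`).  The number of
#'   flagged/capped values is in the `"n_flagged"` attribute.
#' @export
#' @examples
#' panel <- simulate_panel(sim_config(class_sizes = c(30, 10, 10), seed = 1))
#' head(entropy_features(panel, which = c("ApEn", "SaEn")))
entropy_features <- function(dataset, params = entropy_params(),
                             which = c("ApEn", "SaEn", "FuzzyEn", "InfoEn"),
                             undefined = c("flag", "cap")) {
  which <- match.arg(which, c("ApEn", "SaEn", "FuzzyEn", "InfoEn"),
                     several.ok = TRUE)
  undefined <- match.arg(undefined)
  x <- marker_matrix(dataset)
  funs <- list(ApEn = approximate_entropy, SaEn = sample_entropy,
               FuzzyEn = fuzzy_entropy, InfoEn = info_entropy)
  out <- data.frame(sample_id = dataset$sample_id,
                    stringsAsFactors = FALSE)
  n_flagged <- 0L
  for (w in which) {
    vals <- apply(x, 1L, function(u) {
      tryCatch({
        v <- funs[[w]](u, params)
        if (w == "SaEn" && is.infinite(v) && undefined == "cap")
          v <- saen_cap(u, params)
        as.numeric(v)
      }, error = function(e) NA_real_)
    })
    n_flagged <- n_flagged + sum(is.na(vals) | is.infinite(vals))
    out[[w]] <- vals
  }
  if (n_flagged > 0L)
    warning(n_flagged, " entropy value(s) flagged as degenerate/undefined ",
            "(NA or Inf); rows are kept", call. = FALSE)
  attr(out, "n_flagged") <- n_flagged
  out
}

# largest SaEn estimable from a sequence with nt templates per level: the
# conditional probability cannot be resolved below one unordered pair
saen_cap <- function(u, params) {
  nt <- length(u) - params$m_embed
  log(nt * (nt - 1) / 2)
}

#' Column-wise z-standardisation with training-only statistics
#'
#' Estimates per-column mean and SD on `train` ONLY and applies them to both
#' `train` and `apply` — the leakage-safe contract used inside the jackknife
#' and cross-validation harnesses.  Zero-variance training columns pass
#' through unchanged (scale 1) with a warning.
#'
#' @param train Numeric matrix of training rows (>= 2 rows).
#' @param apply Numeric matrix to transform with the training statistics;
#'   defaults to `train`.
#'
#' @return A list with elements `train`, `apply` (standardised matrices),
#'   `center` and `scale` (the per-column statistics).
#' @export
#' @examples
#' s <- zscore_standardize(matrix(rnorm(20), 5))
#' colMeans(s$train)  # ~ 0
zscore_standardize <- function(train, apply = train) {
  train <- as.matrix(train)
  apply <- as.matrix(apply)
  if (nrow(train) < 2L || ncol(train) < 1L)
    stop("zscore_standardize: need a training matrix with >= 2 rows",
         call. = FALSE)
  if (ncol(apply) != ncol(train))
    stop("zscore_standardize: column count mismatch", call. = FALSE)
  ctr <- colMeans(train)
  scl <- matrixcolsds(train)
  zero <- scl == 0
  if (any(zero)) {
    warning("zscore_standardize: ", sum(zero), " zero-variance column(s) ",
            "pass through unscaled", call. = FALSE)
    scl[zero] <- 1
  }
  list(train = sweep(sweep(train, 2L, ctr), 2L, scl, "/"),
       apply = sweep(sweep(apply, 2L, ctr), 2L, scl, "/"),
       center = ctr, scale = scl)
}

# fast per-column sample SDs
matrixcolsds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  v <- (colSums(x * x) - n * mu * mu) / (n - 1)
  sqrt(pmax(v, 0))
}
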