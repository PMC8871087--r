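test_that("ratio-mode costs follow the imbalance-ratio rule", {
  cm <- build_cost_matrix(c(799, 44, 54))
  # true minority predicted as the majority: full count ratio
  expect_equal(cm$costs["1", "0"], 799 / 44, tolerance = 1e-12)  # 18.159
  expect_equal(cm$costs["2", "0"], 799 / 54, tolerance = 1e-12)  # 14.796
  # smaller-to-larger minority direction uses the ratio, reverse uses 1
  expect_equal(cm$costs["1", "2"], 54 / 44, tolerance = 1e-12)   # 1.227
  expect_equal(cm$costs["2", "1"], 1)
  # majority mistaken for a minority always costs 1
  expect_equal(unname(cm$costs["0", c("1", "2")]), c(1, 1))
  expect_equal(unname(diag(cm$costs)), c(0, 0, 0))

  balanced <- build_cost_matrix(c(100, 100))
  expect_equal(unname(balanced$costs), rbind(c(0, 1), c(1, 0)))
})

test_that("the published fixed cost matrix is shipped verbatim", {
  cm <- serum_cost_matrix()
  expect_equal(unname(cm$costs),
               rbind(c(0, 1, 1), c(9, 0, 1.3), c(7, 1, 0)))
  expect_identical(cm$mode, "fixed")
})

test_that("cost-matrix validation rejects malformed inputs", {
  expect_error(build_cost_matrix(c(10, 0, 5)), "positive")
  expect_error(build_cost_matrix(c(10, -2)), "positive")
  expect_error(build_cost_matrix(mode = "fixed"), "fixed_costs")
  expect_error(
    build_cost_matrix(mode = "fixed",
                      fixed_costs = rbind(c(1, 1), c(1, 0))), "diagonal")
  expect_error(
    build_cost_matrix(mode = "fixed",
                      fixed_costs = rbind(c(0, -1), c(1, 0))), "off-diagonal")
})

test_that("m-estimation interpolates between frequencies and priors", {
  # m = 0: plain relative frequency k_j / k
  p0 <- class_probabilities(c(0, 0, 0, 1, 1), m_smooth = 0,
                            priors = c(0.2, 0.8))
  expect_equal(p0$prob, c(0.6, 0.4))
  expect_equal(p0$neighbor_counts, c(3L, 2L))
  # direct evaluation: k = 5, k_j = 3, m = 5, b_j = 0.1 -> 0.35
  p5 <- class_probabilities(c(0, 0, 0, 1, 2), m_smooth = 5,
                            priors = c(0.1, 0.4, 0.5))
  expect_equal(p5$prob[1L], (5 / 10) * 0.6 + (5 / 10) * 0.1)
  # m -> infinity: probabilities collapse to the priors
  pr <- c(0.05, 0.25, 0.7)
  pinf <- class_probabilities(c(0, 0, 0, 0, 0), m_smooth = 1e6, priors = pr)
  expect_equal(pinf$prob, pr, tolerance = 1e-4)
})

test_that("m-estimation probabilities always sum to 1", {
  set.seed(21)
  for (i in 1:200) {
    C <- sample(2:5, 1L)
    k <- sample(1:15, 1L)
    labels <- sample(0:(C - 1L), k, replace = TRUE)
    pr <- as.numeric(rmultinom(1L, 1000L, rep(1, C))) / 1000
    m <- runif(1L, 0, 100)
    p <- class_probabilities(labels, k, m, pr)$prob
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
})

test_that("expected cost is the probability-weighted column sum", {
  cm <- serum_cost_matrix()
  # certain class has zero cost, others positive (zero diagonal)
  L <- expected_costs(c(0, 0, 1), cm)
  expect_equal(L[3L], 0)
  expect_true(all(L[1:2] > 0))
  # hand evaluation, p = (0.9, 0.05, 0.05): argmin is the normal class
  L <- expected_costs(c(0.9, 0.05, 0.05), cm)
  expect_equal(L, c(0.05 * 9 + 0.05 * 7,
                    0.9 * 1 + 0.05 * 1,
                    0.9 * 1 + 0.05 * 1.3), tolerance = 1e-12)
  expect_equal(which.min(L), 1L)
  # uniform off-diagonal costs: L(i) = 1 - p(i), argmin L = argmax p
  u <- uniform_cost_matrix(3L)
  p <- c(0.2, 0.5, 0.3)
  expect_equal(expected_costs(p, u), 1 - p, tolerance = 1e-12)
})

make_toy_model <- function(n = 60L, seed = 13, k = 3L, m_smooth = 0,
                           cost = "uniform") {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n, 0), ncol = 2L),
             matrix(rnorm(n, 2), ncol = 2L),
             matrix(rnorm(n / 2, 4), ncol = 2L))
  y <- rep(0:2, c(n / 2, n / 2, n / 4))
  csknn(x, y, k = k, m_smooth = m_smooth, cost = cost)
}

test_that("nearest neighbours are exact and deterministically tied", {
  model <- make_toy_model()
  # query equal to a training row at k = 1: that row, distance 0
  raw <- sweep(sweep(model$x, 2L, model$scale, "*"), 2L, -model$center)
  nb <- nearest_neighbors(model, raw[7L, ], k = 1L)
  expect_equal(nb$index, 7L)
  expect_equal(nb$distance, 0)
  # brute-force agreement on random queries
  set.seed(31)
  for (i in 1:40) {
    q <- rnorm(2L, 1, 2)
    qs <- (q - model$center) / model$scale
    d <- sqrt(colSums((t(model$x) - qs)^2))
    expect_equal(nearest_neighbors(model, q, k = 5L)$index,
                 order(d)[1:5])
  }
  # duplicated training rows at identical distance: lower index wins
  x <- rbind(c(0, 0), c(1, 1), c(1, 1), c(3, 3))
  dup <- csknn(x, c(0L, 1L, 1L, 0L), k = 2L, cost = "uniform")
  nb <- nearest_neighbors(dup, c(1, 1), k = 3L)
  expect_equal(nb$index[1:2], c(2L, 3L))
})

test_that("uniform costs with m = 0 reduce to majority-vote KNN", {
  model <- make_toy_model(n = 80L, k = 5L)
  set.seed(17)
  queries <- matrix(rnorm(400, 1.5, 2), ncol = 2L)
  pred <- predict(model, queries)
  raw_train <- sweep(sweep(model$x, 2L, model$scale, "*"), 2L,
                     -model$center)
  for (i in seq_len(nrow(queries)))
    expect_identical(pred$label[i],
                     oracle_knn(model$x, model$y,
                                (queries[i, ] - model$center) / model$scale,
                                5L))
})

test_that("one-hot neighbourhoods give degenerate probabilities and costs", {
  x <- rbind(matrix(0, 5L, 2L) + rnorm(10, sd = 0.01),
             matrix(5, 5L, 2L) + rnorm(10, sd = 0.01),
             matrix(10, 5L, 2L) + rnorm(10, sd = 0.01))
  y <- rep(0:2, each = 5L)
  model <- csknn(x, y, k = 5L, m_smooth = 0, cost = serum_cost_matrix())
  pred <- predict(model, rbind(c(0, 0)))
  expect_equal(pred$prob[1L, ], c("0" = 1, "1" = 0, "2" = 0))
  expect_identical(pred$label, 0L)
  expect_equal(unname(pred$cost[1L, ]), c(0, 1, 1))
})

test_that("raising miss-the-minority costs never adds class-0 predictions", {
  set.seed(41)
  n0 <- 60L
  x <- rbind(matrix(rnorm(n0 * 2L, 0), ncol = 2L),
             matrix(rnorm(24L, 1.2), ncol = 2L),
             matrix(rnorm(24L, -1.2), ncol = 2L))
  y <- rep(0:2, c(n0, 12L, 12L))
  queries <- matrix(rnorm(120L, 0, 1.3), ncol = 2L)  # borderline region
  scale_cost <- function(f) {
    costs <- rbind(c(0, 1, 1), c(f, 0, 1), c(f, 1, 0))
    build_cost_matrix(mode = "fixed", fixed_costs = costs)
  }
  n_zero_prev <- Inf
  prev_label <- NULL
  for (f in c(1, 2, 5, 10, 20)) {
    model <- csknn(x, y, k = 5L, m_smooth = 1, cost = scale_cost(f))
    lab <- predict(model, queries)$label
    n_zero <- sum(lab == 0L)
    expect_lte(n_zero, n_zero_prev)
    if (!is.null(prev_label))  # no query ever moves back TO class 0
      expect_true(all(!(prev_label != 0L & lab == 0L)))
    n_zero_prev <- n_zero
    prev_label <- lab
  }
})

test_that("model fitting validates its invariants", {
  x <- matrix(rnorm(20), 10L)
  y <- rep(0:1, 5L)
  expect_error(csknn(x, y, k = 11L), "k must be")
  expect_error(csknn(x, y, m_smooth = 101), "m_smooth")
  expect_error(csknn(x, c(y[-1L], 3L)), "at least one")
  fit <- csknn(x, y, k = 3L)
  expect_equal(sum(fit$priors), 1)
  expect_error(predict(fit, matrix(0, 1L, 3L)), "features")
})

test_that("select_k follows the accuracy/variance compromise and is stable", {
  set.seed(99)
  x <- rbind(matrix(rnorm(240, 0), ncol = 2L),
             matrix(rnorm(240, 2), ncol = 2L))
  y <- rep(0:1, each = 120L)
  flip <- sample(240L, 36L)
  y[flip] <- 1L - y[flip]  # label noise: k = 1 memorises it

  single <- select_k(x, y, k_grid = 7L, folds = 5L, seed = 2L)
  expect_equal(single$k, 7L)

  sel1 <- select_k(x, y, k_grid = c(1L, 3L, 5L, 7L, 9L), folds = 5L,
                   seed = 1L, m_smooth = 0, cost = "uniform")
  sel2 <- select_k(x, y, k_grid = c(1L, 3L, 5L, 7L, 9L), folds = 5L,
                   seed = 1L, m_smooth = 0, cost = "uniform")
  expect_identical(sel1, sel2)
  expect_gt(sel1$k, 1L)
  expect_named(sel1$table, c("k", "mean_accuracy", "var_accuracy"))
})

test_that("select_m scores a grid by macro-F1 and is deterministic", {
  panel <- simulate_panel(sim_config(class_sizes = c(120, 12, 12), seed = 5))
  single <- select_m(panel, m_grid = 2.5, folds = 5L, seed = 1L, k = 3L)
  expect_equal(single$m_smooth, 2.5)
  s1 <- select_m(panel, m_grid = c(0.01, 1, 10), folds = 5L, seed = 3L,
                 k = 3L)
  s2 <- select_m(panel, m_grid = c(0.01, 1, 10), folds = 5L, seed = 3L,
                 k = 3L)
  expect_identical(s1, s2)
  expect_true(s1$m_smooth %in% c(0.01, 1, 10))
  expect_error(select_m(panel, m_grid = c(1, 200)), "\\[0, 100\\]")
})

test_that("predictions carry no randomness", {
  model <- make_toy_model(n = 40L, k = 4L, m_smooth = 2, cost = "ratio")
  set.seed(1); q <- matrix(rnorm(40, 1, 2), ncol = 2L)
  set.seed(123); p1 <- predict(model, q)
  set.seed(999); p2 <- predict(model, q)
  expect_identical(p1, p2)
})
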