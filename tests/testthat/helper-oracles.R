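# Independent brute-force oracles: literal, loop-based transcriptions of the
# defining formulas, kept deliberately naive and separate from the package's
# vectorised implementations.

oracle_apen <- function(u, m = 2L, r = 0.25) {
  n <- length(u)
  tol <- r * sd(u)
  phi <- function(mm) {
    nt <- n - mm + 1L
    logC <- numeric(nt)
    for (i in seq_len(nt)) {
      count <- 0L
      for (j in seq_len(nt)) {         # j ranges over ALL templates (self in)
        dij <- 0
        for (k in 0:(mm - 1L))
          dij <- max(dij, abs(u[i + k] - u[j + k]))
        if (dij < tol) count <- count + 1L
      }
      logC[i] <- log(count / nt)
    }
    mean(logC)
  }
  phi(m) - phi(m + 1L)
}

oracle_saen <- function(u, m = 2L, r = 0.25) {
  n <- length(u)
  tol <- r * sd(u)
  level <- function(mm) {
    nt <- n - m                         # same template count at both levels
    acc <- 0
    for (i in seq_len(nt)) {
      count <- 0L
      for (j in seq_len(nt)) {
        if (j == i) next                # self-match excluded
        dij <- 0
        for (k in 0:(mm - 1L))
          dij <- max(dij, abs(u[i + k] - u[j + k]))
        if (dij < tol) count <- count + 1L
      }
      acc <- acc + count / (nt - 1L)
    }
    acc / nt
  }
  a <- level(m + 1L)
  b <- level(m)
  if (a == 0) Inf else -log(a / b)
}

oracle_fuzen <- function(u, m = 2L, r = 0.25, p_fuzzy = 2) {
  n <- length(u)
  tol <- r * sd(u)
  phi <- function(mm) {
    nt <- n - mm + 1L
    total <- 0
    for (i in seq_len(nt)) {
      xi <- u[i:(i + mm - 1L)] - mean(u[i:(i + mm - 1L)])
      inner <- 0
      for (j in seq_len(nt)) {
        if (j == i) next
        xj <- u[j:(j + mm - 1L)] - mean(u[j:(j + mm - 1L)])
        dij <- max(abs(xi - xj))
        inner <- inner + exp(-(dij^p_fuzzy) / tol)
      }
      total <- total + inner / (nt - 1L)
    }
    total / nt
  }
  log(phi(m)) - log(phi(m + 1L))
}

# plain majority-vote KNN with the package's documented tie rules:
# neighbour ties at the k-th distance by training index, vote ties toward
# the larger training class then the lower label
oracle_knn <- function(train, y, query, k) {
  d <- numeric(nrow(train))
  for (i in seq_len(nrow(train)))
    d[i] <- sqrt(sum((train[i, ] - query)^2))
  nb <- y[order(d)[seq_len(k)]]
  counts <- tabulate(y + 1L, nbins = max(y) + 1L)
  votes <- tabulate(nb + 1L, nbins = max(y) + 1L)
  order(-votes, -counts, seq_along(votes))[1L] - 1L
}

# all-pairs Mann-Whitney AUC with midpoint tie handling
oracle_auc_pairs <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# deterministic "random" test sequences with enough repeats for template
# matches to occur at both embedding levels
random_sequences <- function(n_seq, n_range = 10:50, seed = 4242) {
  set.seed(seed)
  lapply(seq_len(n_seq), function(i) {
    n <- sample(n_range, 1L)
    # half smooth-ish (rounded walks, abundant matches), half plain noise
    if (i %% 2L == 0L) round(cumsum(rnorm(n)), 1L) else runif(n)
  })
}
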