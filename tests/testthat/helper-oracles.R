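# Independent naive re-implementations of every metric, written as explicit
# scalar loops so they share no code path with the package internals, plus
# small fixture builders. All expected values in the tests are computed (or
# hand-derived) through these.

naive_cosine <- function(u, v) {
  num <- 0; su <- 0; sv <- 0
  for (i in seq_along(u)) {
    num <- num + u[i] * v[i]
    su <- su + u[i]^2
    sv <- sv + v[i]^2
  }
  1 - num / (sqrt(su) * sqrt(sv))
}

naive_correlation <- function(u, v) {
  n <- length(u)
  mu <- sum(u) / n; mv <- sum(v) / n
  num <- 0; du <- 0; dv <- 0
  for (i in seq_len(n)) {
    num <- num + (u[i] - mu) * (v[i] - mv)
    du <- du + (u[i] - mu)^2
    dv <- dv + (v[i] - mv)^2
  }
  1 - num / sqrt(du * dv)
}

naive_euclidean <- function(u, v) {
  s <- 0
  for (i in seq_along(u)) s <- s + (u[i] - v[i])^2
  sqrt(s)
}

naive_minkowski3 <- function(u, v) {
  s <- 0
  for (i in seq_along(u)) s <- s + abs(u[i] - v[i])^3
  s^(1 / 3)
}

naive_mahalanobis <- function(u, v, inv) {
  d <- u - v
  q <- 0
  for (i in seq_along(d)) for (j in seq_along(d)) {
    q <- q + d[i] * inv[i, j] * d[j]
  }
  sqrt(max(q, 0))
}

naive_metric <- function(u, v, kind, inv = NULL) {
  switch(kind,
         cosine = naive_cosine(u, v),
         correlation = naive_correlation(u, v),
         euclidean = naive_euclidean(u, v),
         minkowski3 = naive_minkowski3(u, v),
         mahalanobis = naive_mahalanobis(u, v, inv))
}

# Double-loop oracle over all unordered pairs of a norms table.
naive_pair_values <- function(table, kind, inv = NULL) {
  X <- table$ratings
  n <- nrow(X)
  keys <- rownames(X)
  out <- vector("list", n * (n - 1) / 2)
  t <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    t <- t + 1L
    wa <- min(keys[i], keys[j]); wb <- max(keys[i], keys[j])
    out[[t]] <- data.frame(word_a = wa, word_b = wb,
                           distance = naive_metric(X[i, ], X[j, ], kind, inv),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# A small norms table of strictly positive random ratings (no zero or
# constant vectors, so every metric is defined).
rand_table <- function(n, seed = 1) {
  withr::with_seed(seed, {
    ratings <- matrix(stats::runif(n * 11, 0.2, 5), n, 11)
    norms_table(sprintf("t%04d", seq_len(n)), ratings, source = "test")
  })
}

rand_vec <- function() stats::runif(11, 0.2, 5)
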