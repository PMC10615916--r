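#' Default covariance template for synthetic norms
#'
#' Block structure qualitatively mirroring the intercorrelations of real
#' sensorimotor ratings (things that can be touched can usually be seen):
#' 0.5 within the six perceptual dimensions, 0.4 within the five action
#' dimensions, 0.2 across blocks, unit diagonal.
#'
#' @return Symmetric positive-definite 11x11 matrix with dimension names.
#' @export
default_covariance_template <- function() {
  S <- matrix(0.2, 11, 11)
  S[1:6, 1:6] <- 0.5
  S[7:11, 7:11] <- 0.4
  diag(S) <- 1
  dimnames(S) <- list(sm_dimensions(), sm_dimensions())
  S
}

#' Generate a synthetic norms table with known covariance structure
#'
#' Draws latent vectors from a multivariate normal with the template
#' covariance, shifts them to the middle of the rating scale, and clips into
#' \[0, 5\] (latent-Gaussian-then-clip: the simplest mechanism that produces
#' the required inter-dimension correlations; the mild clipping distortion
#' is acceptable for testing). Words are labelled `w00001`, `w00002`, ...
#' Deterministic under `seed`.
#'
#' @param n_words Number of concepts (at least 2).
#' @param covariance 11x11 symmetric positive-semi-definite latent
#'   covariance; default [default_covariance_template()].
#' @param center Latent mean mapped to the rating scale (default 2.5, the
#'   scale midpoint).
#' @param scale Multiplier applied to the latent draws before shifting
#'   (default 1, i.e. unit latent SD per dimension under the default
#'   template).
#' @param seed Integer seed.
#' @return A [norms_table()].
#' @export
generate_norms_fixture <- function(n_words, covariance = default_covariance_template(),
                                   center = 2.5, scale = 1, seed = 1L) {
  if (n_words < 2L) {
    smd_error("smd_spec_error", "n_words must be at least 2")
  }
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(covariance, t(covariance))) ||
      nrow(covariance) != 11L ||
      min(eigen(covariance, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8) {
    smd_error("smd_spec_error",
              "covariance must be a symmetric positive-semi-definite 11x11 matrix")
  }
  latent <- withr::with_seed(seed,
    MASS::mvrnorm(n_words, mu = rep(0, 11), Sigma = covariance))
  latent <- matrix(latent, nrow = n_words)
  ratings <- pmin(pmax(center + scale * latent, 0), 5)
  norms_table(sprintf("w%05d", seq_len(n_words)), ratings,
              source = sprintf("synthetic(seed=%d)", seed))
}

# Map a linear pair index t in 1..n(n-1)/2 to the unordered pair (i, j),
# i < j, enumerated with i ascending.
unrank_pair <- function(t, n) {
  cum <- function(k) k * n - k * (k + 1) / 2  # pairs with first element <= k
  i <- floor(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * (t - 1))) / 2) + 1
  i <- max(i, 1L)
  while (i > 1 && cum(i - 1) >= t) i <- i - 1
  while (t > cum(i)) i <- i + 1
  j <- i + (t - cum(i - 1))
  c(i, j)
}

#' Generate a synthetic similarity benchmark with known ground truth
#'
#' Samples unordered word pairs from the table without replacement and sets
#' each human score to `link(1 - cosine_distance) + noise`, with Gaussian
#' noise of standard deviation `noise_sd`. The generative parameters (and
#' the noiseless signal values) are recorded as attributes so recovery
#' tests can apply the closed-form attenuation prediction
#' \eqn{|r_{obs}| = sd_{signal} / \sqrt{sd_{signal}^2 + noise\_sd^2}}.
#'
#' @param table A [norms_table()] with at least 2 words.
#' @param n_pairs Number of pairs to sample (at most `pair_count(n)`).
#' @param noise_sd Standard deviation of the additive score noise
#'   (non-negative; 0 gives a perfect monotone benchmark with r = -1
#'   against cosine distance under the identity link).
#' @param link Monotone-increasing function mapping cosine similarity in
#'   \[0, 1\] to the score scale (default identity).
#' @param seed Integer seed.
#' @return A [benchmark_table()] named `"synthetic"` with attributes
#'   `noise_sd`, `signal` (noiseless link values) and `signal_sd`.
#' @export
generate_benchmark_fixture <- function(table, n_pairs, noise_sd = 0.5,
                                       link = identity, seed = 1L) {
  stopifnot(inherits(table, "norms_table"))
  if (noise_sd < 0) smd_error("smd_spec_error", "noise_sd must be >= 0")
  n <- n_concepts(table)
  if (n < 2L) {
    smd_error("smd_insufficient_data", "need at least 2 words")
  }
  pc <- pair_count(n)
  if (n_pairs < 1L || n_pairs > pc) {
    smd_error("smd_spec_error",
              sprintf("n_pairs must be in [1, %.0f]", pc))
  }
  keys <- rownames(table$ratings)
  out <- withr::with_seed(seed, {
    idx <- sample(pc, n_pairs)
    noise <- stats::rnorm(n_pairs, 0, noise_sd)
    list(idx = idx, noise = noise)
  })
  ij <- t(vapply(out$idx, unrank_pair, numeric(2), n = n))
  sim <- vapply(seq_len(n_pairs), function(r) {
    1 - cosine_distance(table$ratings[ij[r, 1L], ],
                        table$ratings[ij[r, 2L], ])
  }, numeric(1))
  signal <- link(sim)
  bench <- benchmark_table(keys[ij[, 1L]], keys[ij[, 2L]],
                           signal + out$noise, name = "synthetic")
  attr(bench, "noise_sd") <- noise_sd
  attr(bench, "signal") <- signal
  attr(bench, "signal_sd") <- stats::sd(signal)
  bench
}

#' Closed-form attenuation of a noiseless correlation
#'
#' With additive independent noise of standard deviation `noise_sd` on one
#' variable, a perfect correlation attenuates to
#' `sd_signal / sqrt(sd_signal^2 + noise_sd^2)`.
#'
#' @param signal_sd Standard deviation of the noiseless signal.
#' @param noise_sd Standard deviation of the added noise.
#' @return Predicted absolute correlation.
#' @export
attenuated_r <- function(signal_sd, noise_sd) {
  signal_sd / sqrt(signal_sd^2 + noise_sd^2)
}
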