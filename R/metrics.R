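#' Specify a distance metric
#'
#' Five metrics over 11-dimensional sensorimotor rating vectors are
#' supported. Cosine distance is the principal measure; correlation,
#' Euclidean, Minkowski-3 and Mahalanobis distances are alternatives.
#' Mahalanobis requires a covariance context (see [estimate_covariance()]),
#' which whitens the dimensions' intercorrelational structure.
#'
#' @param kind One of `"cosine"`, `"correlation"`, `"euclidean"`,
#'   `"minkowski3"`, `"mahalanobis"`.
#' @param context A `covariance_context`, required iff `kind` is
#'   `"mahalanobis"`.
#' @return An object of class `metric_spec`.
#' @export
metric_spec <- function(kind = c("cosine", "correlation", "euclidean",
                                 "minkowski3", "mahalanobis"),
                        context = NULL) {
  kind <- match.arg(kind)
  if (kind == "mahalanobis") {
    if (is.null(context) || !inherits(context, "covariance_context")) {
      smd_error("smd_spec_error",
                "mahalanobis distance requires a covariance_context")
    }
  }
  structure(list(kind = kind, context = context), class = "metric_spec")
}

metric_kinds <- function() {
  c("cosine", "correlation", "euclidean", "minkowski3", "mahalanobis")
}

check_ratings_pair <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != 11L || length(v) != 11L) {
    smd_error("smd_validation_error", "rating vectors must have length 11")
  }
  if (any(!is.finite(u)) || any(!is.finite(v))) {
    smd_error("smd_validation_error", "rating vectors must be finite")
  }
  list(u = u, v = v)
}

#' Cosine distance between two sensorimotor vectors
#'
#' One minus the cosine of the angle between the two rating vectors:
#' \deqn{d(u, v) = 1 - \frac{u \cdot v}{\|u\| \, \|v\|}.}
#' For non-negative ratings the distance lies in \[0, 1\]: 0 for identical or
#' positively proportional profiles, 1 for profiles with no shared dimension.
#' An all-zero vector has no direction and is an error, not a sentinel.
#'
#' @param u,v Numeric vectors of 11 ratings.
#' @return Cosine distance.
#' @export
#' @examples
#' cosine_distance(c(5, rep(0, 10)), c(5, 5, rep(0, 9)))
cosine_distance <- function(u, v) {
  p <- check_ratings_pair(u, v)
  nu <- sqrt(sum(p$u^2)); nv <- sqrt(sum(p$v^2))
  if (nu == 0 || nv == 0) {
    smd_error("smd_zero_vector",
              "cosine distance is undefined for an all-zero vector")
  }
  d <- 1 - sum(p$u * p$v) / (nu * nv)
  d <- max(d, 0)
  if (all(p$u >= 0) && all(p$v >= 0)) d <- min(d, 1)
  d
}

#' Distance between two sensorimotor vectors under a chosen metric
#'
#' Dispatches on `spec$kind`: cosine (see [cosine_distance()]); correlation
#' (1 minus the Pearson correlation of the two 11-value sequences);
#' Euclidean (L2 norm of the difference); Minkowski-3
#' (\eqn{(\sum |u_i - v_i|^3)^{1/3}}); Mahalanobis
#' (\eqn{\sqrt{(u-v)^\top \Sigma^{+} (u-v)}} with the context's
#' pseudo-inverse covariance). All are symmetric and zero for identical
#' vectors.
#'
#' @param u,v Numeric vectors of 11 ratings.
#' @param spec A [metric_spec()].
#' @return The distance.
#' @export
metric_distance <- function(u, v, spec = metric_spec("cosine")) {
  stopifnot(inherits(spec, "metric_spec"))
  p <- check_ratings_pair(u, v)
  switch(spec$kind,
    cosine = cosine_distance(p$u, p$v),
    correlation = {
      if (stats::sd(p$u) == 0 || stats::sd(p$v) == 0) {
        smd_error("smd_constant_vector",
                  "correlation distance is undefined for a constant vector")
      }
      1 - stats::cor(p$u, p$v)
    },
    euclidean = sqrt(sum((p$u - p$v)^2)),
    minkowski3 = sum(abs(p$u - p$v)^3)^(1 / 3),
    mahalanobis = {
      dlt <- p$u - p$v
      sqrt(max(0, drop(crossprod(dlt, spec$context$inverse %*% dlt))))
    })
}

#' Estimate the dimension covariance of a norms table
#'
#' Computes the 11x11 covariance of the rating dimensions across all
#' concepts (dimensions as variables, concepts as observations, unbiased
#' n-1 denominator) and its Moore--Penrose pseudo-inverse. The pseudo-inverse
#' equals the plain inverse when the covariance is well conditioned and
#' remains defined when a dimension is (nearly) linearly dependent on others.
#'
#' @param table A [norms_table()] with at least 2 concepts (more rows than
#'   dimensions preferred).
#' @return An object of class `covariance_context` with elements `matrix`,
#'   `inverse` and `source_n`.
#' @export
estimate_covariance <- function(table) {
  stopifnot(inherits(table, "norms_table"))
  X <- table$ratings
  if (nrow(X) < 2L) {
    smd_error("smd_insufficient_data",
              "need at least 2 concepts to estimate a covariance")
  }
  S <- stats::cov(X)
  structure(list(matrix = S, inverse = MASS::ginv(S), source_n = nrow(X)),
            class = "covariance_context")
}

#' @export
print.covariance_context <- function(x, ...) {
  cat(sprintf("<covariance_context> 11x11, estimated from %d concepts\n",
              x$source_n))
  invisible(x)
}

#' Identity covariance context
#'
#' With the identity covariance, Mahalanobis distance reduces to Euclidean;
#' mostly useful for testing and as a neutral default.
#'
#' @return A `covariance_context`.
#' @export
identity_covariance <- function() {
  structure(list(matrix = diag(11), inverse = diag(11), source_n = 0L),
            class = "covariance_context")
}

# Resolve a metric name string (possibly needing a covariance estimated from
# the table) into a metric_spec. Used by the CLI and convenience wrappers.
resolve_metric <- function(name, table = NULL) {
  if (inherits(name, "metric_spec")) return(name)
  if (!is.character(name) || !(name %in% metric_kinds())) {
    smd_error("smd_spec_error",
              sprintf("unknown metric '%s' (use one of: %s)",
                      as.character(name)[1L],
                      paste(metric_kinds(), collapse = ", ")))
  }
  if (name == "mahalanobis") {
    if (is.null(table)) {
      smd_error("smd_spec_error",
                "mahalanobis needs a norms table to estimate the covariance")
    }
    return(metric_spec("mahalanobis", estimate_covariance(table)))
  }
  metric_spec(name)
}

# Row transforms shared by the streaming pair scan and neighbour search.
# cosine/correlation rows become unit vectors whose dot product is the
# (centred) cosine; mahalanobis rows are whitened so Euclidean geometry
# applies afterwards.
transform_rows <- function(X, kind, context = NULL) {
  keys <- rownames(X)
  switch(kind,
    cosine = {
      nrm <- sqrt(rowSums(X^2))
      z <- which(nrm == 0)
      if (length(z) > 0L) {
        smd_error("smd_zero_vector",
                  sprintf("all-zero rating vector for '%s' (cosine undefined)",
                          keys[z[1L]]),
                  key = keys[z[1L]])
      }
      X / nrm
    },
    correlation = {
      Xc <- X - rowMeans(X)
      nrm <- sqrt(rowSums(Xc^2))
      z <- which(nrm == 0)
      if (length(z) > 0L) {
        smd_error("smd_constant_vector",
                  sprintf("constant rating vector for '%s' (correlation undefined)",
                          keys[z[1L]]),
                  key = keys[z[1L]])
      }
      Xc / nrm
    },
    euclidean = X,
    minkowski3 = X,
    mahalanobis = {
      e <- eigen(context$inverse, symmetric = TRUE)
      W <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), length(e$values))
      Y <- X %*% W
      rownames(Y) <- keys
      Y
    })
}

# Distances from transformed row i-block to transformed row j-block.
# Returns a length(ii) x length(jj) matrix.
cross_distances <- function(Xt, ii, jj, kind) {
  A <- Xt[ii, , drop = FALSE]
  B <- Xt[jj, , drop = FALSE]
  if (kind %in% c("cosine", "correlation")) {
    D <- 1 - tcrossprod(A, B)
    D[D < 0] <- 0
    if (kind == "cosine") D[D > 1 & D < 1 + 1e-12] <- 1
    return(D)
  }
  if (kind %in% c("euclidean", "mahalanobis")) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    d2[d2 < 0] <- 0
    return(sqrt(d2))
  }
  # minkowski3: no cross-product identity; loop over the (small) i-block
  D <- matrix(0, nrow(A), nrow(B))
  for (r in seq_len(nrow(A))) {
    D[r, ] <- rowSums(abs(sweep(B, 2L, A[r, ]))^3)^(1 / 3)
  }
  D
}
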