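#' Sammon stress of a 2-D layout
#'
#' \deqn{E = \frac{1}{\sum_{i<j} d^*_{ij}} \sum_{i<j}
#'   \frac{(d^*_{ij} - d_{ij})^2}{d^*_{ij}}}
#' where \eqn{d^*_{ij}} are the input distances and \eqn{d_{ij}} the
#' Euclidean distances between layout coordinates. Invariant under rigid
#' motions (rotation, translation, reflection) of the layout.
#'
#' @param d Input distances: a `dist` or a symmetric matrix.
#' @param coords Numeric matrix of layout coordinates (one row per point).
#' @return The stress value (non-negative).
#' @export
sammon_stress <- function(d, coords) {
  D <- as.matrix(d)
  up <- upper.tri(D)
  dstar <- D[up]
  if (any(dstar <= 0)) {
    smd_error("smd_domain_error", "input distances must be positive")
  }
  dy <- as.matrix(stats::dist(coords))[up]
  sum((dstar - dy)^2 / dstar) / sum(dstar)
}

pairwise_matrix <- function(table, keys, spec) {
  X <- table$ratings[keys, , drop = FALSE]
  Xt <- transform_rows(X, spec$kind, spec$context)
  D <- cross_distances(Xt, seq_along(keys), seq_along(keys), spec$kind)
  diag(D) <- 0
  dimnames(D) <- list(keys, keys)
  (D + t(D)) / 2
}

#' 2-D Sammon-mapping layout of selected concepts
#'
#' Arranges the chosen concepts in the plane so that layout Euclidean
#' distances approximate their pairwise sensorimotor distances, by
#' minimising the Sammon stress (see [sammon_stress()]) with gradient
#' descent and a backtracking line search: a step is only accepted if it
#' lowers the stress, so the stress trace is non-increasing. The initial
#' configuration is classical scaling (eigendecomposition of the doubly
#' centred squared-distance matrix) when it yields two usable axes,
#' otherwise a seeded random configuration; identical inputs and seed give
#' identical layouts. Exact-zero input distances are perturbed to 1e-9.
#'
#' @param table A [norms_table()].
#' @param words At least 3 words present in the table.
#' @param spec Metric spec or name (default cosine).
#' @param seed Integer seed for the random fallback initialisation.
#' @param max_iter Maximum accepted descent iterations.
#' @param tol Stop when the relative stress improvement falls below this.
#' @param init `"classical"` (default) or `"random"`.
#' @return An object of class `sammon_layout`: `words`, `coords` (n x 2,
#'   rownames = keys), `stress`, `stress_trace`, `seed`, `iterations`,
#'   `metric`.
#' @export
sammon_layout <- function(table, words, spec = metric_spec("cosine"),
                          seed = 1L, max_iter = 500L, tol = 1e-9,
                          init = c("classical", "random")) {
  stopifnot(inherits(table, "norms_table"))
  spec <- resolve_metric(spec, table)
  init <- match.arg(init)
  keys <- normalize_word(words)
  if (length(keys) < 3L) {
    smd_error("smd_insufficient_points",
              "need at least 3 words for a 2-D layout")
  }
  if (anyDuplicated(keys)) {
    smd_error("smd_domain_error", "duplicate words in layout request")
  }
  absent <- setdiff(keys, rownames(table$ratings))
  if (length(absent) > 0L) {
    smd_error("smd_not_found",
              sprintf("word not in norms: '%s'", absent[1L]),
              key = absent[1L])
  }
  D <- pairwise_matrix(table, keys, spec)
  D[D == 0] <- 1e-9
  diag(D) <- 0
  n <- length(keys)

  Y <- NULL
  if (init == "classical") {
    Y <- tryCatch(suppressWarnings(stats::cmdscale(D, k = 2)),
                  error = function(e) NULL)
    if (is.null(Y) || ncol(Y) < 2L || anyNA(Y)) Y <- NULL
  }
  if (is.null(Y)) {
    Y <- withr::with_seed(seed,
      matrix(stats::rnorm(n * 2, sd = mean(D[upper.tri(D)])), n, 2))
  }

  up <- upper.tri(D)
  cnorm <- sum(D[up])
  stress_of <- function(Y) {
    dy <- as.matrix(stats::dist(Y))[up]
    sum((D[up] - dy)^2 / D[up]) / cnorm
  }
  gradient <- function(Y) {
    DY <- as.matrix(stats::dist(Y))
    DY[DY < 1e-12] <- 1e-12
    A <- (D - DY) / (D * DY)
    diag(A) <- 0
    (-2 / cnorm) * (rowSums(A) * Y - A %*% Y)
  }

  stress <- stress_of(Y)
  trace <- stress
  alpha <- 0.1 * mean(D[up])
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    G <- gradient(Y)
    gn <- sqrt(sum(G^2))
    if (gn == 0 || stress == 0) break
    step <- alpha / gn
    improved <- FALSE
    for (bt in seq_len(40L)) {
      Ynew <- Y - step * G
      snew <- stress_of(Ynew)
      if (snew < stress) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
    rel <- (stress - snew) / max(stress, .Machine$double.xmin)
    Y <- Ynew
    stress <- snew
    trace <- c(trace, stress)
    iterations <- it
    alpha <- step * gn * 2  # carry the successful scale forward
    if (rel < tol) break
  }

  rownames(Y) <- keys
  colnames(Y) <- c("x", "y")
  structure(list(words = keys, coords = Y, stress = stress,
                 stress_trace = trace, seed = as.integer(seed),
                 iterations = iterations, metric = spec$kind),
            class = "sammon_layout")
}

#' @export
print.sammon_layout <- function(x, ...) {
  cat(sprintf("<sammon_layout> %d points  metric=%s  stress=%.3g  iterations=%d\n",
              nrow(x$coords), x$metric, x$stress, x$iterations))
  invisible(x)
}

#' Write a layout as CSV coordinates plus a JSON sidecar
#'
#' The CSV holds `word`, `x`, `y`; the sidecar records `stress`, `seed`,
#' `iterations` and `metric` so the layout is reproducible and checkable.
#'
#' @param layout A `sammon_layout`.
#' @param path Coordinates CSV path.
#' @param sidecar Optional JSON path (default: `path` with `.json`).
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path, sidecar = NULL) {
  stopifnot(inherits(layout, "sammon_layout"))
  df <- data.frame(word = layout$words,
                   x = layout$coords[, 1L], y = layout$coords[, 2L])
  write_delim_auto(df, path)
  if (is.null(sidecar)) sidecar <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(list(stress = layout$stress, seed = layout$seed,
                            iterations = layout$iterations,
                            metric = layout$metric),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Sensorimotor profile of a concept for polar plotting
#'
#' Returns the 11 ratings labelled and ordered for the conventional polar
#' ("radar") plot: clockwise from the top — auditory, gustatory, haptic,
#' interoceptive, olfactory, visual, foot/leg, hand/arm, head, mouth/throat,
#' torso. This is the same order as [sm_dimensions()], relabelled with the
#' display names.
#'
#' @param table A [norms_table()].
#' @param word Word label (any case).
#' @return An object of class `profile_export`: `word` (key) and `values`
#'   (named numeric, display-label order).
#' @export
profile_export <- function(table, word) {
  v <- get_vector(table, word)
  structure(list(word = attr(v, "key"),
                 values = stats::setNames(as.numeric(v),
                                          sm_dimensions("display"))),
            class = "profile_export")
}

#' @export
print.profile_export <- function(x, ...) {
  cat(sprintf("<profile_export> '%s'\n", x$word))
  print(round(x$values, 3))
  invisible(x)
}

#' Map a profile back to the canonical rating vector
#'
#' Inverse of [profile_export()]: relabels the display-order values with the
#' canonical dimension names (the two orders coincide; only labels change).
#'
#' @param profile A `profile_export`.
#' @return Named numeric vector of 11 ratings in canonical order.
#' @export
profile_to_ratings <- function(profile) {
  stopifnot(inherits(profile, "profile_export"))
  stats::setNames(as.numeric(profile$values), sm_dimensions())
}

#' Write one or more profiles to CSV
#'
#' One row per word: `word`, then 11 columns in polar-plot order.
#'
#' @param table A [norms_table()].
#' @param words Character vector of words.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(table, words, path) {
  profs <- lapply(words, function(w) profile_export(table, w))
  vals <- do.call(rbind, lapply(profs, function(p) p$values))
  df <- data.frame(word = vapply(profs, function(p) p$word, character(1)),
                   vals, check.names = FALSE, row.names = NULL)
  names(df) <- c("word", sm_dimensions("display"))
  write_delim_auto(df, path)
  invisible(path)
}
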