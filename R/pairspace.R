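#' Number of unordered concept pairs
#'
#' `n * (n - 1) / 2`, computed in double precision (exact for any realistic
#' vocabulary size; well below 2^53). For the 39,707-concept published norms
#' this is 788,303,071 pairs.
#'
#' @param n Non-negative concept count.
#' @return The unordered pair count.
#' @export
#' @examples
#' pair_count(39707)
pair_count <- function(n) {
  n <- as.numeric(n)
  if (length(n) != 1L || !is.finite(n) || n < 0 || n != floor(n)) {
    smd_error("smd_domain_error", "n must be a single non-negative integer")
  }
  n * (n - 1) / 2
}

# Histogram breaks per metric. Cosine uses fixed width .01 on [0,1]; the
# other metrics use 100 equal bins from 0 to an a-priori upper bound implied
# by the [0,5] rating scale, so a single streaming pass suffices and counts
# always sum to the pair count.
metric_breaks <- function(kind, context = NULL) {
  upper <- switch(kind,
    cosine = 1,
    correlation = 2,
    euclidean = sqrt(11 * 25),
    minkowski3 = (11 * 125)^(1 / 3),
    mahalanobis = {
      lam <- max(eigen(context$inverse, symmetric = TRUE,
                       only.values = TRUE)$values, 0)
      sqrt(lam * 11 * 25) + 1e-9
    })
  seq(0, upper, length.out = 101L)
}

order_pair_keys <- function(ka, kb) {
  swap <- ka > kb
  wa <- ifelse(swap, kb, ka)
  wb <- ifelse(swap, ka, kb)
  list(word_a = wa, word_b = wb)
}

empty_pairs <- function() {
  data.frame(word_a = character(), word_b = character(),
             distance = numeric(), stringsAsFactors = FALSE)
}

# Keep the k most extreme pairs after merging a block's candidates into the
# retained set. Ties break lexicographically on (word_a, word_b).
merge_extremes <- function(current, candidate, k, largest) {
  all <- rbind(current, candidate)
  if (nrow(all) == 0L) return(all)
  o <- if (largest) {
    order(-all$distance, all$word_a, all$word_b)
  } else {
    order(all$distance, all$word_a, all$word_b)
  }
  utils::head(all[o, , drop = FALSE], k)
}

#' Streaming summary of all unordered pair distances
#'
#' Scans the `n(n-1)/2` unordered concept pairs in blocks of `chunk_size`
#' rows, accumulating compensated running moments, bounded lists of the
#' `top_k` smallest and largest pairs, and a fixed-bin histogram — without
#' ever materialising the full pair matrix (the published norms yield ~788
#' million pairs). Self-pairs are excluded. The result is independent of
#' `chunk_size`.
#'
#' The reported `sd` uses the population (divide-by-N) convention, so a
#' single-pair table reports `sd = 0`.
#'
#' @param table A [norms_table()] with at least 2 concepts.
#' @param spec A [metric_spec()] or metric name.
#' @param top_k How many extreme pairs to retain at each end (default 100).
#' @param chunk_size Rows per streaming block.
#' @return An object of class `distance_summary` with elements `metric`,
#'   `n_concepts`, `n_pairs`, `mean`, `sd`, `min_pairs`, `max_pairs` (data
#'   frames `word_a`, `word_b`, `distance`) and `histogram`
#'   (`breaks`, `counts`).
#' @export
summarize_distances <- function(table, spec = metric_spec("cosine"),
                                top_k = 100L, chunk_size = 512L) {
  stopifnot(inherits(table, "norms_table"))
  spec <- resolve_metric(spec, table)
  if (top_k < 1L) smd_error("smd_domain_error", "top_k must be >= 1")
  if (chunk_size < 1L) smd_error("smd_domain_error", "chunk_size must be >= 1")
  X <- table$ratings
  n <- nrow(X)
  if (n < 2L) {
    smd_error("smd_insufficient_data",
              "need at least 2 concepts to summarise pair distances")
  }
  keys <- rownames(X)
  Xt <- transform_rows(X, spec$kind, spec$context)
  breaks <- metric_breaks(spec$kind, spec$context)
  counts <- integer(length(breaks) - 1L)
  sum_acc <- c(0, 0)
  sq_acc <- c(0, 0)
  n_pairs <- 0
  mins <- empty_pairs()
  maxs <- empty_pairs()

  starts <- seq.int(1L, n - 1L, by = chunk_size)
  for (a in starts) {
    b <- min(a + chunk_size - 1L, n - 1L)
    ii <- a:b
    jj <- (a + 1L):n
    D <- cross_distances(Xt, ii, jj, spec$kind)
    ri <- matrix(ii, nrow = length(ii), ncol = length(jj))
    cj <- matrix(jj, nrow = length(ii), ncol = length(jj), byrow = TRUE)
    keep <- cj > ri
    vals <- D[keep]
    i_idx <- ri[keep]
    j_idx <- cj[keep]
    m <- length(vals)
    if (m == 0L) next

    n_pairs <- n_pairs + m
    sum_acc <- kahan_add(sum_acc, sum(vals))
    sq_acc <- kahan_add(sq_acc, sum(vals * vals))
    bins <- .bincode(vals, breaks, include.lowest = TRUE)
    counts <- counts + tabulate(bins, nbins = length(counts))

    kk <- min(top_k, m)
    os <- order(vals)[seq_len(kk)]
    pk <- order_pair_keys(keys[i_idx[os]], keys[j_idx[os]])
    mins <- merge_extremes(mins,
      data.frame(word_a = pk$word_a, word_b = pk$word_b,
                 distance = vals[os], stringsAsFactors = FALSE),
      top_k, largest = FALSE)
    ol <- order(-vals)[seq_len(kk)]
    pk <- order_pair_keys(keys[i_idx[ol]], keys[j_idx[ol]])
    maxs <- merge_extremes(maxs,
      data.frame(word_a = pk$word_a, word_b = pk$word_b,
                 distance = vals[ol], stringsAsFactors = FALSE),
      top_k, largest = TRUE)
  }

  mean_d <- sum_acc[1L] / n_pairs
  var_d <- max(sq_acc[1L] / n_pairs - mean_d^2, 0)
  rownames(mins) <- NULL
  rownames(maxs) <- NULL
  structure(list(metric = spec$kind,
                 n_concepts = n,
                 n_pairs = n_pairs,
                 mean = mean_d,
                 sd = sqrt(var_d),
                 min_pairs = mins,
                 max_pairs = maxs,
                 histogram = list(breaks = breaks, counts = counts),
                 top_k = as.integer(top_k)),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, digits = 4, ...) {
  cat(sprintf("<distance_summary> metric=%s  concepts=%d  pairs=%.0f\n",
              x$metric, x$n_concepts, x$n_pairs))
  cat(sprintf("  mean = %.*f   sd = %.*f\n", digits, x$mean, digits, x$sd))
  if (nrow(x$min_pairs) > 0L) {
    cat(sprintf("  closest pair:  %s-%s  %.4g\n",
                x$min_pairs$word_a[1L], x$min_pairs$word_b[1L],
                x$min_pairs$distance[1L]))
    cat(sprintf("  furthest pair: %s-%s  %.4g\n",
                x$max_pairs$word_a[1L], x$max_pairs$word_b[1L],
                x$max_pairs$distance[1L]))
  }
  invisible(x)
}

#' Extract the k most extreme pairs from a summary
#'
#' @param summary A `distance_summary`.
#' @param which `"smallest"` or `"largest"`.
#' @param k How many pairs; must not exceed the `top_k` retained when the
#'   summary was computed.
#' @return Data frame `word_a`, `word_b`, `distance`, most extreme first;
#'   ties broken lexicographically.
#' @export
extreme_pairs <- function(summary, which = c("smallest", "largest"), k = 10L) {
  stopifnot(inherits(summary, "distance_summary"))
  which <- match.arg(which)
  pool <- if (which == "smallest") summary$min_pairs else summary$max_pairs
  if (k > min(summary$top_k, summary$n_pairs)) {
    smd_error("smd_bounds_error",
              sprintf("k = %d exceeds the %d extreme pairs retained",
                      k, min(summary$top_k, summary$n_pairs)))
  }
  utils::head(pool, k)
}

#' Exact nearest sensorimotor neighbours of a concept
#'
#' Computes the distance from the query to every other concept and returns
#' the `k` closest, ascending, ties broken alphabetically; the query itself
#' is excluded and `k` is capped at `n - 1`.
#'
#' @param table A [norms_table()].
#' @param word Query word (any case).
#' @param k Number of neighbours requested.
#' @param spec A [metric_spec()] or metric name.
#' @return An object of class `neighbour_result` with elements `query`, `k`
#'   and `neighbours` (data frame `word`, `distance`).
#' @export
nearest_neighbours <- function(table, word, k = 5L,
                               spec = metric_spec("cosine")) {
  stopifnot(inherits(table, "norms_table"))
  spec <- resolve_metric(spec, table)
  if (k < 1L) smd_error("smd_domain_error", "k must be >= 1")
  key <- normalize_word(word)
  X <- table$ratings
  qi <- match(key, rownames(X))
  if (is.na(qi)) {
    smd_error("smd_not_found", sprintf("word not in norms: '%s'", key),
              key = key)
  }
  Xt <- transform_rows(X, spec$kind, spec$context)
  d <- drop(cross_distances(Xt, qi, seq_len(nrow(X)), spec$kind))
  keys <- rownames(X)
  d <- d[-qi]
  others <- keys[-qi]
  o <- order(d, others)
  kk <- min(k, length(others))
  structure(list(query = key, k = as.integer(k),
                 neighbours = data.frame(word = others[o][seq_len(kk)],
                                         distance = unname(d[o][seq_len(kk)]),
                                         row.names = NULL,
                                         stringsAsFactors = FALSE)),
            class = "neighbour_result")
}

#' @export
print.neighbour_result <- function(x, ...) {
  cat(sprintf("<neighbour_result> query='%s'  k=%d\n", x$query, x$k))
  print(x$neighbours, row.names = TRUE)
  invisible(x)
}

#' Write a distance summary as a JSON report (plus optional histogram CSV)
#'
#' @param summary A `distance_summary`.
#' @param path Output JSON path.
#' @param hist_path Optional CSV path for `bin_left`, `bin_right`, `count`.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path, hist_path = NULL) {
  stopifnot(inherits(summary, "distance_summary"))
  rep <- list(metric = summary$metric,
              n_concepts = summary$n_concepts,
              n_pairs = summary$n_pairs,
              mean = summary$mean,
              sd = summary$sd,
              min_pairs = summary$min_pairs,
              max_pairs = summary$max_pairs,
              histogram = list(breaks = summary$histogram$breaks,
                               counts = summary$histogram$counts))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(hist_path)) {
    br <- summary$histogram$breaks
    hdf <- data.frame(bin_left = br[-length(br)], bin_right = br[-1L],
                      count = summary$histogram$counts)
    write_delim_auto(hdf, hist_path)
  }
  invisible(path)
}

#' Export all pair distances to a delimited file
#'
#' Writes `word_a`, `word_b`, `distance` rows for every unordered pair; the
#' pair space is streamed in blocks, never held in memory. Intended for
#' moderate tables — the full published norms produce ~788 million rows.
#'
#' @param table A [norms_table()].
#' @param path Output path (`.csv` or `.tsv`).
#' @param spec Metric spec or name.
#' @param chunk_size Rows per streaming block.
#' @return `path`, invisibly.
#' @export
export_pairs <- function(table, path, spec = metric_spec("cosine"),
                         chunk_size = 512L) {
  stopifnot(inherits(table, "norms_table"))
  spec <- resolve_metric(spec, table)
  X <- table$ratings
  n <- nrow(X)
  keys <- rownames(X)
  Xt <- transform_rows(X, spec$kind, spec$context)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  writeLines(paste(c("word_a", "word_b", "distance"), collapse = sep), con)
  starts <- seq.int(1L, n - 1L, by = chunk_size)
  for (a in starts) {
    b <- min(a + chunk_size - 1L, n - 1L)
    ii <- a:b
    jj <- (a + 1L):n
    D <- cross_distances(Xt, ii, jj, spec$kind)
    ri <- matrix(ii, length(ii), length(jj))
    cj <- matrix(jj, length(ii), length(jj), byrow = TRUE)
    keep <- cj > ri
    pk <- order_pair_keys(keys[ri[keep]], keys[cj[keep]])
    writeLines(paste(pk$word_a, pk$word_b,
                     format(D[keep], digits = 15, trim = TRUE,
                            scientific = FALSE),
                     sep = sep), con)
  }
  invisible(path)
}
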