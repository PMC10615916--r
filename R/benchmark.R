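#' Construct a benchmark table of human similarity judgements
#'
#' @param word1,word2 Character vectors of pair members (normalised on
#'   construction).
#' @param human_score Numeric human similarity/relatedness score per pair.
#' @param name Benchmark name (e.g. `"simlex"`).
#' @param predictors Optional data frame of extra predictor columns, one row
#'   per pair (e.g. precomputed WordNet distance, feature overlap, CBOW
#'   distance).
#' @return An object of class `benchmark_table` whose `pairs` data frame has
#'   columns `word1`, `word2`, `human_score`, then any predictors.
#' @export
benchmark_table <- function(word1, word2, human_score, name = "generic",
                            predictors = NULL) {
  w1 <- normalize_word(word1)
  w2 <- normalize_word(word2)
  human_score <- as.numeric(human_score)
  if (length(w1) != length(w2) || length(w1) != length(human_score)) {
    smd_error("smd_validation_error", "pair columns differ in length")
  }
  if (any(!is.finite(human_score))) {
    smd_error("smd_validation_error",
              sprintf("non-finite human score at pair %d",
                      which(!is.finite(human_score))[1L]))
  }
  ukey <- paste(pmin(w1, w2), pmax(w1, w2), sep = "\r")
  dup <- which(duplicated(ukey))
  if (length(dup) > 0L) {
    smd_error("smd_duplicate_pair",
              sprintf("duplicate unordered pair '%s'-'%s' (rows %d and %d)",
                      pmin(w1, w2)[dup[1L]], pmax(w1, w2)[dup[1L]],
                      match(ukey[dup[1L]], ukey), dup[1L]))
  }
  pairs <- data.frame(word1 = w1, word2 = w2, human_score = human_score,
                      stringsAsFactors = FALSE)
  if (!is.null(predictors)) {
    predictors <- as.data.frame(predictors)
    if (nrow(predictors) != nrow(pairs)) {
      smd_error("smd_validation_error",
                "predictor rows differ from pair rows")
    }
    pairs <- cbind(pairs, predictors)
  }
  structure(list(name = name, pairs = pairs), class = "benchmark_table")
}

#' @export
print.benchmark_table <- function(x, ...) {
  extra <- setdiff(names(x$pairs), c("word1", "word2", "human_score"))
  cat(sprintf("<benchmark_table> '%s': %d pairs%s\n", x$name, nrow(x$pairs),
              if (length(extra)) paste0(" + columns: ",
                                        paste(extra, collapse = ", "))
              else ""))
  invisible(x)
}

#' Number of pairs in a benchmark
#' @param bench A `benchmark_table`.
#' @return Integer pair count.
#' @export
n_pairs <- function(bench) {
  stopifnot(inherits(bench, "benchmark_table"))
  nrow(bench$pairs)
}

#' Load a word-pair similarity benchmark
#'
#' Supported dialects: `"simlex"` (tab-separated, columns `word1`, `word2`
#' and `SimLex999`), `"wordsim"` (comma-separated, columns `Word 1`,
#' `Word 2`, `Human (mean)`), `"men"` (space-separated, headerless:
#' word1 word2 score), and `"generic"` (CSV/TSV by extension with header
#' columns `word1`, `word2`, `score`; any further columns are kept as
#' predictor columns).
#'
#' @param path Path to the benchmark file.
#' @param dialect One of `"generic"`, `"simlex"`, `"wordsim"`, `"men"`.
#' @param name Benchmark name; defaults to the dialect.
#' @return A [benchmark_table()].
#' @export
load_benchmark <- function(path, dialect = c("generic", "simlex",
                                             "wordsim", "men"),
                           name = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    smd_error("smd_file_error", sprintf("file not found: %s", path))
  }
  if (is.null(name)) name <- dialect
  parse_fail <- function(i, what) {
    smd_error("smd_parse_error",
              sprintf("malformed row at line %d of %s: %s", i, path, what),
              line = i)
  }
  if (dialect == "men") {
    df <- tryCatch(utils::read.table(path, header = FALSE, sep = "",
                                     stringsAsFactors = FALSE,
                                     fileEncoding = "UTF-8"),
                   error = function(e) parse_fail(NA_integer_,
                                                  conditionMessage(e)))
    if (ncol(df) < 3L) parse_fail(1L, "expected: word1 word2 score")
    sc <- suppressWarnings(as.numeric(df[[3L]]))
    bad <- which(!is.finite(sc))
    if (length(bad) > 0L) parse_fail(bad[1L], "non-numeric score")
    return(benchmark_table(df[[1L]], df[[2L]], sc, name = name))
  }
  df <- if (dialect == "simlex") {
    utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      fileEncoding = "UTF-8")
  } else {
    read_delim_auto(path)
  }
  cols <- switch(dialect,
    simlex = c("word1", "word2", "SimLex999"),
    wordsim = c("Word 1", "Word 2", "Human (mean)"),
    generic = c("word1", "word2", "score"))
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    smd_error("smd_schema_error",
              sprintf("missing column '%s' in %s", missing[1L], path),
              column = missing[1L])
  }
  sc <- suppressWarnings(as.numeric(df[[cols[3L]]]))
  bad <- which(!is.finite(sc))
  if (length(bad) > 0L) parse_fail(bad[1L] + 1L, "non-numeric score")
  preds <- NULL
  if (dialect == "generic") {
    extra <- setdiff(names(df), cols)
    if (length(extra) > 0L) {
      preds <- df[extra]
      preds[] <- lapply(preds, function(v) suppressWarnings(as.numeric(v)))
    }
  }
  benchmark_table(df[[cols[1L]]], df[[cols[2L]]], sc, name = name,
                  predictors = preds)
}

#' Write a benchmark to a generic delimited file
#'
#' Columns `word1`, `word2`, `score`, then any predictor columns; the file
#' round-trips through `load_benchmark(dialect = "generic")`.
#'
#' @param bench A `benchmark_table`.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(bench, path) {
  stopifnot(inherits(bench, "benchmark_table"))
  df <- bench$pairs
  names(df)[names(df) == "human_score"] <- "score"
  write_delim_auto(df, path)
  invisible(path)
}

#' Attach sensorimotor distances to a benchmark
#'
#' Adds a `sensorimotor_distance` column computed from the norms under the
#' chosen metric. Pairs with either word missing from the norms are flagged
#' uncovered (`NA` distance), not dropped; the covered count is recorded in
#' the `coverage` attribute.
#'
#' @param bench A `benchmark_table`.
#' @param table A [norms_table()].
#' @param spec Metric spec or name.
#' @return The benchmark with the distance column; `attr(, "coverage")`
#'   holds the number of covered pairs.
#' @export
attach_distance <- function(bench, table, spec = metric_spec("cosine")) {
  stopifnot(inherits(bench, "benchmark_table"),
            inherits(table, "norms_table"))
  spec <- resolve_metric(spec, table)
  keys <- rownames(table$ratings)
  i1 <- match(bench$pairs$word1, keys)
  i2 <- match(bench$pairs$word2, keys)
  covered <- !is.na(i1) & !is.na(i2)
  d <- rep(NA_real_, nrow(bench$pairs))
  for (r in which(covered)) {
    d[r] <- metric_distance(table$ratings[i1[r], ], table$ratings[i2[r], ],
                            spec)
  }
  bench$pairs$sensorimotor_distance <- d
  attr(bench, "coverage") <- sum(covered)
  bench
}

#' Merge precomputed predictor columns into a benchmark
#'
#' Reads a delimited file with columns `word1`, `word2` and one or more
#' predictor columns (e.g. WordNet distance, feature overlap, CBOW
#' distance) and joins them on the normalised unordered pair. Benchmark
#' pairs absent from the file get `NA`.
#'
#' @param bench A `benchmark_table`.
#' @param path Path to the predictor join file.
#' @return The benchmark with the predictor columns appended.
#' @export
attach_predictors <- function(bench, path) {
  stopifnot(inherits(bench, "benchmark_table"))
  df <- read_delim_auto(path)
  missing <- setdiff(c("word1", "word2"), names(df))
  if (length(missing) > 0L) {
    smd_error("smd_schema_error",
              sprintf("missing column '%s' in %s", missing[1L], path),
              column = missing[1L])
  }
  w1 <- normalize_word(df$word1)
  w2 <- normalize_word(df$word2)
  fkey <- paste(pmin(w1, w2), pmax(w1, w2), sep = "\r")
  bkey <- paste(pmin(bench$pairs$word1, bench$pairs$word2),
                pmax(bench$pairs$word1, bench$pairs$word2), sep = "\r")
  idx <- match(bkey, fkey)
  for (col in setdiff(names(df), c("word1", "word2"))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bench$pairs[[col]] <- v[idx]
  }
  bench
}

#' Zero-order correlation between human scores and a predictor
#'
#' Pearson correlation over the pairs where both the human score and the
#' named column are non-missing (listwise per comparison).
#'
#' @param bench A `benchmark_table`.
#' @param column Predictor column name (e.g. `"sensorimotor_distance"`).
#' @return List with elements `r` and `n`.
#' @export
correlate <- function(bench, column = "sensorimotor_distance") {
  stopifnot(inherits(bench, "benchmark_table"))
  if (!column %in% names(bench$pairs)) {
    smd_error("smd_schema_error", sprintf("no column '%s' in benchmark",
                                          column),
              column = column)
  }
  x <- bench$pairs$human_score
  y <- bench$pairs[[column]]
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3L) {
    smd_error("smd_insufficient_data",
              "need at least 3 jointly covered pairs for a correlation")
  }
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    smd_error("smd_constant_vector",
              "correlation undefined for a constant column")
  }
  list(r = stats::cor(x[ok], y[ok]), n = n)
}

# Quiet OLS R^2 via the pivoted QR in lm.fit (rank-deficient designs are
# handled by dropping aliased columns, with no perfect-fit warnings).
ols_r2 <- function(y, X) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Unique variance of sensorimotor distance in a hierarchical regression
#'
#' Ordinary-least-squares fit of the human score on the step-1 predictor
#' alone, then on step-1 plus sensorimotor distance, on the rows jointly
#' covered by both predictors. Because the models are nested and fit on the
#' same rows, the R-squared increase is non-negative by construction.
#'
#' @param bench A `benchmark_table` with both columns present.
#' @param step1 Name of the step-1 predictor column.
#' @param step2 Name of the step-2 predictor column (default
#'   `"sensorimotor_distance"`).
#' @return List `r2_step1`, `r2_step2`, `delta`, `n`.
#' @export
hierarchical_delta_r2 <- function(bench, step1,
                                  step2 = "sensorimotor_distance") {
  stopifnot(inherits(bench, "benchmark_table"))
  for (col in c(step1, step2)) {
    if (!col %in% names(bench$pairs)) {
      smd_error("smd_schema_error",
                sprintf("no column '%s' in benchmark", col), column = col)
    }
  }
  y <- bench$pairs$human_score
  x1 <- bench$pairs[[step1]]
  x2 <- bench$pairs[[step2]]
  ok <- is.finite(y) & is.finite(x1) & is.finite(x2)
  if (sum(ok) < 4L) {
    smd_error("smd_insufficient_data",
              "need at least 4 jointly covered pairs for the hierarchy")
  }
  y <- y[ok]; x1 <- x1[ok]; x2 <- x2[ok]
  # an exact duplicate of the step-2 column is the well-defined "no unique
  # variance" case (delta = 0); any other perfect collinearity is degenerate
  if (!identical(x1, x2) && stats::sd(x1) > 0 && stats::sd(x2) > 0 &&
      abs(stats::cor(x1, x2)) > 1 - 1e-12) {
    smd_error("smd_degenerate_model",
              "step-1 and step-2 predictors are perfectly collinear")
  }
  r2_1 <- ols_r2(y, cbind(x1))
  r2_2 <- ols_r2(y, cbind(x1, x2))
  delta <- max(r2_2 - r2_1, 0)  # nested fits; guard rounding only
  list(r2_step1 = r2_1, r2_step2 = r2_2, delta = delta, n = length(y))
}

#' Exhaustive best-subset ranking of similarity predictors
#'
#' Fits every non-empty subset of the named predictors by OLS on the rows
#' jointly covered by all of them (so fits are compared on identical data)
#' and ranks the subsets by the Schwarz Bayesian information criterion,
#' which penalises parameter count. Ties in BIC break towards fewer
#' predictors, then lexicographically.
#'
#' @param bench A `benchmark_table`.
#' @param predictors Character vector of at most 12 predictor column names.
#' @return Data frame `subset` (comma-joined names), `k`, `r2`, `bic`,
#'   ranked best (lowest BIC) first, with attribute `n` (rows used).
#' @export
best_subset <- function(bench, predictors) {
  stopifnot(inherits(bench, "benchmark_table"))
  predictors <- unique(as.character(predictors))
  if (length(predictors) < 1L || length(predictors) > 12L) {
    smd_error("smd_domain_error", "need between 1 and 12 predictors")
  }
  for (col in predictors) {
    if (!col %in% names(bench$pairs)) {
      smd_error("smd_schema_error",
                sprintf("no column '%s' in benchmark", col), column = col)
    }
  }
  dat <- bench$pairs[c("human_score", predictors)]
  dat <- dat[stats::complete.cases(dat) &
               rowSums(!is.finite(as.matrix(dat))) == 0, , drop = FALSE]
  if (nrow(dat) < length(predictors) + 2L) {
    smd_error("smd_insufficient_data",
              "too few jointly covered pairs for subset fits")
  }
  p <- length(predictors)
  nr <- nrow(dat)
  y <- dat$human_score
  tss <- sum((y - mean(y))^2)
  rows <- vector("list", 2^p - 1L)
  idx <- 0L
  for (mask in seq_len(2^p - 1L)) {
    members <- predictors[bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L]
    fit <- stats::lm.fit(cbind(1, as.matrix(dat[members])), y)
    rss <- sum(fit$residuals^2)
    # floor the RSS at numerical noise so a saturated (R^2 = 1) fit does not
    # swamp the criterion; the parameter penalty then decides between
    # equally perfect subsets
    rss_f <- max(rss, tss * 1e-12, .Machine$double.xmin)
    bic <- nr * log(rss_f / nr) + (length(members) + 2) * log(nr)
    idx <- idx + 1L
    rows[[idx]] <- data.frame(subset = paste(sort(members), collapse = ","),
                              k = length(members),
                              r2 = 1 - rss / tss,
                              bic = bic,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$bic, out$k, out$subset), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n") <- nrow(dat)
  out
}

#' Load a concreteness rating table
#'
#' Generic delimited file with header columns `word` and `rating` (1--5
#' concreteness scale, e.g. the Brysbaert ratings).
#'
#' @param path Path to the ratings file.
#' @param threshold Split point: words rated below it are abstract, at or
#'   above it concrete (default 3, the scale midpoint).
#' @return An object of class `concreteness_map`.
#' @export
load_concreteness <- function(path, threshold = 3) {
  df <- read_delim_auto(path)
  missing <- setdiff(c("word", "rating"), names(df))
  if (length(missing) > 0L) {
    smd_error("smd_schema_error",
              sprintf("missing column '%s' in %s", missing[1L], path),
              column = missing[1L])
  }
  concreteness_map(df$word, df$rating, threshold = threshold)
}

#' Construct a concreteness map
#'
#' @param words Character vector of words.
#' @param ratings Numeric concreteness ratings (1--5 scale).
#' @param threshold Abstract/concrete split point (default 3).
#' @return An object of class `concreteness_map`.
#' @export
concreteness_map <- function(words, ratings, threshold = 3) {
  keys <- normalize_word(words)
  ratings <- as.numeric(ratings)
  if (any(!is.finite(ratings))) {
    smd_error("smd_validation_error", "concreteness ratings must be finite")
  }
  structure(list(ratings = stats::setNames(ratings, keys),
                 threshold = threshold),
            class = "concreteness_map")
}

#' Split a benchmark by pair concreteness
#'
#' Words rated below the map's threshold are abstract; at or above it,
#' concrete (so a rating of exactly 3.0 is concrete under the default).
#' Pairs are partitioned into abstract--abstract, mixed and
#' concrete--concrete sub-benchmarks; pairs with either word missing from
#' the map go to `unsplit`.
#'
#' @param bench A `benchmark_table`.
#' @param cmap A [concreteness_map()].
#' @return List of benchmark tables `abstract`, `mixed`, `concrete`,
#'   `unsplit`, plus `sizes` (named integer vector).
#' @export
concreteness_split <- function(bench, cmap) {
  stopifnot(inherits(bench, "benchmark_table"),
            inherits(cmap, "concreteness_map"))
  r1 <- cmap$ratings[bench$pairs$word1]
  r2 <- cmap$ratings[bench$pairs$word2]
  known <- !is.na(r1) & !is.na(r2)
  conc1 <- r1 >= cmap$threshold
  conc2 <- r2 >= cmap$threshold
  grp <- rep("unsplit", nrow(bench$pairs))
  grp[known & !conc1 & !conc2] <- "abstract"
  grp[known & (conc1 != conc2)] <- "mixed"
  grp[known & conc1 & conc2] <- "concrete"
  take <- function(g) {
    sub <- bench
    sub$pairs <- bench$pairs[grp == g, , drop = FALSE]
    rownames(sub$pairs) <- NULL
    sub$name <- paste(bench$name, g, sep = ":")
    attr(sub, "coverage") <- sum(is.finite(sub$pairs$sensorimotor_distance))
    sub
  }
  out <- list(abstract = take("abstract"), mixed = take("mixed"),
              concrete = take("concrete"), unsplit = take("unsplit"))
  out$sizes <- vapply(out[1:4], n_pairs, integer(1))
  out
}

#' Full benchmark evaluation report
#'
#' Composes the validation pipeline: attach sensorimotor distances, report
#' coverage, zero-order correlations for the distance and every predictor
#' column, hierarchical incremental R-squared with each predictor at step 1
#' and sensorimotor distance at step 2, an exhaustive best-subset ranking,
#' and (when a concreteness map is supplied) per-split correlations.
#'
#' @param bench A `benchmark_table`.
#' @param table A [norms_table()].
#' @param spec Metric spec or name.
#' @param predictors Character vector of predictor columns already on the
#'   benchmark (e.g. after [attach_predictors()]); may be empty.
#' @param cmap Optional [concreteness_map()].
#' @return An object of class `eval_report`.
#' @export
evaluate_benchmark <- function(bench, table, spec = metric_spec("cosine"),
                               predictors = character(), cmap = NULL) {
  bench <- attach_distance(bench, table, spec)
  cols <- c("sensorimotor_distance", predictors)
  correlations <- lapply(stats::setNames(cols, cols), function(col) {
    tryCatch(correlate(bench, col), smd_error = function(e) NULL)
  })
  delta <- lapply(stats::setNames(predictors, predictors), function(p) {
    tryCatch(hierarchical_delta_r2(bench, p), smd_error = function(e) NULL)
  })
  subsets <- if (length(cols) > 1L) {
    tryCatch(best_subset(bench, cols), smd_error = function(e) NULL)
  } else NULL
  splits <- NULL
  if (!is.null(cmap)) {
    parts <- concreteness_split(bench, cmap)
    splits <- list(sizes = parts$sizes,
                   correlations = lapply(parts[c("abstract", "mixed",
                                                 "concrete")], function(s) {
                     tryCatch(correlate(s, "sensorimotor_distance"),
                              smd_error = function(e) NULL)
                   }))
  }
  structure(list(name = bench$name,
                 n = n_pairs(bench),
                 coverage = attr(bench, "coverage"),
                 correlations = correlations,
                 delta_r2 = delta,
                 best_subset = subsets,
                 splits = splits,
                 benchmark = bench),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> '%s': %d pairs, %d covered by the norms\n",
              x$name, x$n, x$coverage))
  for (col in names(x$correlations)) {
    co <- x$correlations[[col]]
    if (!is.null(co)) {
      cat(sprintf("  r(human, %s) = %+.3f  (n = %d)\n", col, co$r, co$n))
    }
  }
  for (p in names(x$delta_r2)) {
    d <- x$delta_r2[[p]]
    if (!is.null(d)) {
      cat(sprintf("  step1 %s: R2 %.3f -> %.3f  (delta = %.3f, n = %d)\n",
                  p, d$r2_step1, d$r2_step2, d$delta, d$n))
    }
  }
  if (!is.null(x$best_subset)) {
    cat(sprintf("  best subset: {%s}  R2 = %.3f  BIC = %.1f\n",
                x$best_subset$subset[1L], x$best_subset$r2[1L],
                x$best_subset$bic[1L]))
  }
  if (!is.null(x$splits)) {
    cat(sprintf("  concreteness split sizes: %s\n",
                paste(sprintf("%s=%d", names(x$splits$sizes),
                              x$splits$sizes), collapse = " ")))
  }
  invisible(x)
}

#' Serialise an evaluation report to JSON
#'
#' @param report An `eval_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  out <- report[c("name", "n", "coverage", "correlations", "delta_r2")]
  if (!is.null(report$best_subset)) out$best_subset <- report$best_subset
  if (!is.null(report$splits)) out$splits <- report$splits
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
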