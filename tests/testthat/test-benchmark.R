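write_generic_bench <- function(df, ext = ".csv") {
  path <- tempfile(fileext = ext)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("generic benchmark files load with predictors and reject duplicates", {
  df <- data.frame(word1 = sprintf("left%02d", 1:10),
                   word2 = sprintf("right%02d", 1:10),
                   score = seq(0.5, 5, by = 0.5),
                   wordnet_distance = stats::runif(10))
  path <- write_generic_bench(df)
  on.exit(unlink(path))
  bench <- load_benchmark(path, "generic")
  expect_equal(n_pairs(bench), 10L)
  expect_true("wordnet_distance" %in% names(bench$pairs))

  # unordered duplicate, even reversed and case-flipped
  df_dup <- rbind(df[1:3, ],
                  data.frame(word1 = "RIGHT02", word2 = "Left02",
                             score = 1, wordnet_distance = 0.1))
  p2 <- write_generic_bench(df_dup)
  on.exit(unlink(p2), add = TRUE)
  expect_error(load_benchmark(p2, "generic"), class = "smd_duplicate_pair")

  df_bad <- df
  df_bad$score <- as.character(df_bad$score)
  df_bad$score[4] <- "often"
  p3 <- write_generic_bench(df_bad)
  on.exit(unlink(p3), add = TRUE)
  expect_error(load_benchmark(p3, "generic"), class = "smd_parse_error")
})

test_that("the simlex, wordsim and men dialects parse their layouts", {
  simlex <- tempfile(fileext = ".txt")
  writeLines(c("word1\tword2\tPOS\tSimLex999",
               "old\tnew\tA\t1.58", "smart\tintelligent\tA\t9.2"), simlex)
  on.exit(unlink(simlex))
  b <- load_benchmark(simlex, "simlex")
  expect_equal(n_pairs(b), 2L)
  expect_equal(b$pairs$human_score, c(1.58, 9.2))

  wordsim <- tempfile(fileext = ".csv")
  writeLines(c("Word 1,Word 2,Human (mean)",
               "love,sex,6.77", "tiger,cat,7.35"), wordsim)
  on.exit(unlink(wordsim), add = TRUE)
  b <- load_benchmark(wordsim, "wordsim")
  expect_equal(b$pairs$word1, c("love", "tiger"))
  expect_equal(b$pairs$human_score, c(6.77, 7.35))

  men <- tempfile(fileext = ".txt")
  writeLines(c("sun sunlight 50.0", "automobile car 48.0"), men)
  on.exit(unlink(men), add = TRUE)
  b <- load_benchmark(men, "men")
  expect_equal(b$pairs$word2, c("sunlight", "car"))
  expect_equal(b$pairs$human_score, c(50, 48))
})

test_that("attach_distance reports coverage and keeps uncovered pairs", {
  tab <- rand_table(20, seed = 81)
  keys <- rownames(tab$ratings)
  bench <- benchmark_table(keys[1:5], keys[6:10], 1:5)
  bench <- attach_distance(bench, tab)
  expect_equal(attr(bench, "coverage"), 5L)
  expect_equal(bench$pairs$sensorimotor_distance,
               vapply(1:5, function(r) naive_cosine(tab$ratings[keys[r], ],
                                                    tab$ratings[keys[r + 5], ]),
                      numeric(1)), tolerance = 1e-10)

  bench2 <- benchmark_table(c(keys[1:4], "unknown word"), keys[6:10], 1:5)
  bench2 <- attach_distance(bench2, tab)
  expect_equal(attr(bench2, "coverage"), 4L)
  expect_equal(n_pairs(bench2), 5L)  # flagged, not dropped
  expect_true(is.na(bench2$pairs$sensorimotor_distance[5]))
})

test_that("correlations behave as Pearson r on jointly covered pairs", {
  tab <- rand_table(30, seed = 82)
  bench <- attach_distance(generate_benchmark_fixture(tab, 50, noise_sd = 0.2,
                                                      seed = 9), tab)
  bench$pairs$self <- bench$pairs$human_score
  bench$pairs$negself <- -bench$pairs$human_score
  expect_equal(correlate(bench, "self")$r, 1, tolerance = 1e-12)
  expect_equal(correlate(bench, "negself")$r, -1, tolerance = 1e-12)
  # invariant to strictly increasing linear rescaling
  r0 <- correlate(bench, "sensorimotor_distance")$r
  bench$pairs$human_score <- 3 + 12 * bench$pairs$human_score
  expect_equal(correlate(bench, "sensorimotor_distance")$r, r0,
               tolerance = 1e-12)
  bench$pairs$flat <- 1
  expect_error(correlate(bench, "flat"), class = "smd_constant_vector")
  expect_error(correlate(bench, "nothere"), class = "smd_schema_error")
})

test_that("hierarchical R2 matches a normal-equations oracle and is monotone", {
  tab <- rand_table(40, seed = 83)
  bench <- attach_distance(generate_benchmark_fixture(tab, 20, noise_sd = 0.3,
                                                      seed = 10), tab)
  bench$pairs$other <- withr::with_seed(11, stats::runif(20))
  res <- hierarchical_delta_r2(bench, "other")
  # independent solve via the normal equations
  y <- bench$pairs$human_score
  r2_of <- function(Xcols) {
    X <- cbind(1, as.matrix(Xcols))
    beta <- solve(crossprod(X), crossprod(X, y))
    fit <- X %*% beta
    1 - sum((y - fit)^2) / sum((y - mean(y))^2)
  }
  expect_equal(res$r2_step1, r2_of(bench$pairs["other"]), tolerance = 1e-10)
  expect_equal(res$r2_step2,
               r2_of(bench$pairs[c("other", "sensorimotor_distance")]),
               tolerance = 1e-10)
  expect_equal(res$delta, res$r2_step2 - res$r2_step1, tolerance = 1e-10)
  expect_gte(res$delta, 0)

  # duplicated predictor explains no unique variance
  bench$pairs$copy <- bench$pairs$sensorimotor_distance
  expect_equal(hierarchical_delta_r2(bench, "copy")$delta, 0,
               tolerance = 1e-10)

  # forced decomposition: human score is exactly minus the distance
  bench2 <- bench
  bench2$pairs$human_score <- -bench2$pairs$sensorimotor_distance
  res2 <- hierarchical_delta_r2(bench2, "other")
  expect_equal(res2$r2_step2, 1, tolerance = 1e-10)
  expect_equal(res2$delta, 1 - res2$r2_step1, tolerance = 1e-10)

  # perfectly collinear predictors are degenerate
  bench$pairs$double <- 2 * bench$pairs$sensorimotor_distance
  expect_error(hierarchical_delta_r2(bench, "double"),
               class = "smd_degenerate_model")
})

test_that("ΔR² is non-negative for every step-1 predictor on random data", {
  tab <- rand_table(60, seed = 84)
  bench <- attach_distance(generate_benchmark_fixture(tab, 120,
                                                      noise_sd = 0.4,
                                                      seed = 12), tab)
  preds <- withr::with_seed(13, {
    data.frame(p1 = stats::runif(120), p2 = stats::rnorm(120),
               p3 = bench$pairs$human_score + stats::rnorm(120, 0, 0.5))
  })
  bench$pairs <- cbind(bench$pairs, preds)
  for (p in c("p1", "p2", "p3")) {
    expect_gte(hierarchical_delta_r2(bench, p)$delta, 0)
  }
})

test_that("best-subset search enumerates 2^p - 1 models and ranks sensibly", {
  tab <- rand_table(80, seed = 85)
  bench <- attach_distance(generate_benchmark_fixture(tab, 500,
                                                      noise_sd = 0.02,
                                                      seed = 14), tab)
  bench$pairs$perfect <- bench$pairs$human_score        # collinear with y
  bench$pairs$noise <- withr::with_seed(15, stats::rnorm(500))
  res <- best_subset(bench, c("sensorimotor_distance", "perfect", "noise"))
  expect_equal(nrow(res), 2^3 - 1)
  expect_identical(res$subset[1], "perfect")
  expect_equal(res$r2[res$subset == "perfect"], 1, tolerance = 1e-12)

  # a pure-noise predictor never improves the best subset's criterion rank
  res2 <- best_subset(bench, c("sensorimotor_distance", "noise"))
  expect_identical(res2$subset[1], "sensorimotor_distance")
  expect_error(best_subset(bench, character(0)), class = "smd_domain_error")
})

test_that("concreteness splits follow the strict-below-3 rule", {
  cmap <- concreteness_map(c("idea", "faith", "rock", "hammer", "edge"),
                           c(2.1, 2.9, 4.8, 4.9, 3.0))
  bench <- benchmark_table(c("idea", "rock", "edge", "idea", "idea"),
                           c("faith", "hammer", "faith", "rock", "mystery"),
                           c(5, 4, 3, 2, 1))
  parts <- concreteness_split(bench, cmap)
  expect_equal(unname(parts$sizes),
               c(1L, 2L, 1L, 1L))  # abstract, mixed, concrete, unsplit
  expect_equal(parts$abstract$pairs$word1, "idea")   # 2.1 & 2.9 both < 3
  # 3.0 is concrete by the >= 3 rule, so edge-faith is mixed
  expect_true("edge" %in% parts$mixed$pairs$word1)
  expect_equal(parts$concrete$pairs$word2, "hammer")
  expect_equal(parts$unsplit$pairs$word2, "mystery")
  expect_equal(sum(parts$sizes), n_pairs(bench))
})

test_that("predictor join files merge on the normalised unordered pair", {
  tab <- rand_table(10, seed = 86)
  keys <- rownames(tab$ratings)
  bench <- benchmark_table(keys[1:4], keys[5:8], c(1, 2, 3, 4))
  join <- data.frame(word1 = c(toupper(keys[5]), keys[2]),
                     word2 = c(keys[1], keys[6]),
                     cbow_distance = c(0.9, 0.7))
  path <- write_generic_bench(join)
  on.exit(unlink(path))
  bench <- attach_predictors(bench, path)
  expect_equal(bench$pairs$cbow_distance, c(0.9, 0.7, NA, NA))
})

test_that("the full evaluation report composes coverage, ΔR² and splits", {
  tab <- rand_table(50, seed = 87)
  bench <- generate_benchmark_fixture(tab, 200, noise_sd = 0.05, seed = 16)
  bench$pairs$alt <- withr::with_seed(17,
    -bench$pairs$human_score + stats::rnorm(200, 0, 0.3))
  cmap <- concreteness_map(rownames(tab$ratings),
                           withr::with_seed(18, stats::runif(50, 1, 5)))
  rep <- evaluate_benchmark(bench, tab, predictors = "alt", cmap = cmap)
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$coverage, 200L)
  expect_lt(rep$correlations$sensorimotor_distance$r, 0)
  expect_gte(rep$delta_r2$alt$delta, 0)
  expect_equal(sum(rep$splits$sizes), 200L)
  expect_equal(nrow(rep$best_subset), 3L)
  out <- withr::local_tempfile(fileext = ".json")
  write_report(rep, out)
  parsed <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(parsed$coverage, 200L)
})
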