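#' Canonical sensorimotor dimensions
#'
#' The 11 dimensions of sensorimotor experience, in the fixed canonical order
#' used throughout the package: six perceptual modalities (auditory,
#' gustatory, haptic, interoceptive, olfactory, visual) followed by five
#' action effectors (foot/leg, hand/arm, head, mouth/throat, torso). This is
#' also the clockwise-from-the-top order of the polar profile plots.
#'
#' @param style `"canonical"` for machine-friendly names (`foot_leg`, ...),
#'   `"display"` for the conventional slashed labels (`foot/leg`, ...).
#' @return Character vector of length 11.
#' @export
#' @examples
#' sm_dimensions()
sm_dimensions <- function(style = c("canonical", "display")) {
  style <- match.arg(style)
  canonical <- c("auditory", "gustatory", "haptic", "interoceptive",
                 "olfactory", "visual", "foot_leg", "hand_arm", "head",
                 "mouth_throat", "torso")
  if (style == "canonical") return(canonical)
  c("auditory", "gustatory", "haptic", "interoceptive", "olfactory", "visual",
    "foot/leg", "hand/arm", "head", "mouth/throat", "torso")
}

#' Normalise a word label into a lookup key
#'
#' Keys are case-folded and whitespace-normalised so that the upper-case
#' labels used by the published norms and the lower-case labels used by
#' similarity benchmarks map to the same entry. Multi-word items are kept
#' verbatim apart from whitespace collapsing; there is no tokenisation.
#'
#' @param label Character vector of word labels.
#' @return Character vector of normalised keys (lower case, trimmed, internal
#'   whitespace runs collapsed to single spaces).
#' @export
#' @examples
#' normalize_word("CYAN")
#' normalize_word("  soap   opera ")
normalize_word <- function(label) {
  if (!is.character(label)) label <- as.character(label)
  key <- tolower(trimws(label))
  key <- gsub("[[:space:]]+", " ", key)
  if (length(key) == 0L || any(is.na(key)) || any(!nzchar(key))) {
    smd_error("smd_invalid_word", "word label is empty after trimming")
  }
  key
}

#' Column map for a norms file
#'
#' Describes which file columns hold the word label and the 11 mean ratings,
#' the latter matched positionally to [sm_dimensions()] order.
#'
#' @param word_column Name of the word-label column.
#' @param rating_columns Character vector of 11 distinct column names, ordered
#'   as [sm_dimensions()].
#' @return An object of class `column_map`.
#' @seealso [lancaster_column_map()] for the default targeting the published
#'   norms header.
#' @export
column_map <- function(word_column, rating_columns) {
  if (length(word_column) != 1L || !nzchar(word_column)) {
    smd_error("smd_spec_error", "word_column must be a single column name")
  }
  rating_columns <- as.character(rating_columns)
  if (length(rating_columns) != 11L || anyDuplicated(rating_columns)) {
    smd_error("smd_spec_error",
              "rating_columns must be 11 distinct column names")
  }
  structure(list(word_column = word_column,
                 rating_columns = stats::setNames(rating_columns,
                                                  sm_dimensions())),
            class = "column_map")
}

#' Default column map for the published sensorimotor norms
#'
#' Matches the header of the Lancaster Sensorimotor Norms item-level CSV
#' (mean ratings per dimension). Override with [column_map()] for files with
#' a different schema.
#'
#' @return A `column_map`.
#' @export
lancaster_column_map <- function() {
  column_map("Word",
             c("Auditory.mean", "Gustatory.mean", "Haptic.mean",
               "Interoceptive.mean", "Olfactory.mean", "Visual.mean",
               "Foot_leg.mean", "Hand_arm.mean", "Head.mean",
               "Mouth.mean", "Torso.mean"))
}

#' Construct a norms table from words and a rating matrix
#'
#' The central container: one row per concept, 11 columns of mean sensorimotor
#' ratings in canonical dimension order, keyed by normalised word. Ratings
#' must be finite and within the 0--5 rating scale; duplicate keys are a hard
#' error, since silent overwrites would corrupt pair statistics.
#'
#' @param words Character vector of display labels (one per row).
#' @param ratings Numeric matrix with `length(words)` rows and 11 columns.
#' @param source Provenance string recorded on the table.
#' @return An object of class `norms_table`.
#' @export
norms_table <- function(words, ratings, source = "in-memory") {
  ratings <- as.matrix(ratings)
  storage.mode(ratings) <- "double"
  if (ncol(ratings) != 11L) {
    smd_error("smd_validation_error", "ratings must have 11 columns")
  }
  if (nrow(ratings) != length(words)) {
    smd_error("smd_validation_error",
              "words and ratings row count differ")
  }
  bad <- which(!is.finite(ratings) | ratings < 0 | ratings > 5,
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    smd_error("smd_validation_error",
              sprintf("rating out of [0,5] or non-numeric at row %d, dimension %s",
                      bad[1L, 1L], sm_dimensions()[bad[1L, 2L]]),
              row = bad[1L, 1L], column = sm_dimensions()[bad[1L, 2L]])
  }
  keys <- normalize_word(words)
  dup <- which(duplicated(keys))
  if (length(dup) > 0L) {
    first <- match(keys[dup[1L]], keys)
    smd_error("smd_duplicate_word",
              sprintf("duplicate word key '%s' (rows %d and %d)",
                      keys[dup[1L]], first, dup[1L]),
              key = keys[dup[1L]], rows = c(first, dup[1L]))
  }
  dimnames(ratings) <- list(keys, sm_dimensions())
  structure(list(ratings = ratings,
                 words = stats::setNames(as.character(words), keys),
                 source = source),
            class = "norms_table")
}

#' @export
print.norms_table <- function(x, ...) {
  cat(sprintf("<norms_table> %d concepts x 11 sensorimotor dimensions\n",
              nrow(x$ratings)))
  cat(sprintf("  source: %s\n", x$source))
  invisible(x)
}

#' Number of concepts in a norms table
#' @param table A `norms_table`.
#' @return Integer concept count.
#' @export
n_concepts <- function(table) {
  stopifnot(inherits(table, "norms_table"))
  nrow(table$ratings)
}

#' Load a sensorimotor norms table from a delimited file
#'
#' Reads a CSV or TSV (chosen by extension) with a header row, maps columns
#' through `map`, validates every rating against the 0--5 scale, and keys the
#' rows by normalised word. Row numbers in error messages count the header as
#' line 1.
#'
#' @param path Path to the norms file.
#' @param map A [column_map()]; defaults to the published norms header.
#' @return A [norms_table()] with `source` set to `path`.
#' @export
load_norms <- function(path, map = lancaster_column_map()) {
  df <- read_delim_auto(path)
  needed <- c(map$word_column, unname(map$rating_columns))
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    smd_error("smd_schema_error",
              sprintf("missing column '%s' in %s", missing[1L], path),
              column = missing[1L])
  }
  n <- nrow(df)
  ratings <- matrix(NA_real_, n, 11L)
  for (d in seq_len(11L)) {
    col <- map$rating_columns[[d]]
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v) | v < 0 | v > 5)
    if (length(bad) > 0L) {
      smd_error("smd_validation_error",
                sprintf("invalid rating in column '%s', file row %d (must be a number in [0,5])",
                        col, bad[1L] + 1L),
                row = bad[1L] + 1L, column = col)
    }
    ratings[, d] <- v
  }
  words <- as.character(df[[map$word_column]])
  keys <- normalize_word(words)
  dup <- which(duplicated(keys))
  if (length(dup) > 0L) {
    first <- match(keys[dup[1L]], keys)
    smd_error("smd_duplicate_word",
              sprintf("duplicate word key '%s' at file rows %d and %d",
                      keys[dup[1L]], first + 1L, dup[1L] + 1L),
              key = keys[dup[1L]], rows = c(first + 1L, dup[1L] + 1L))
  }
  norms_table(words, ratings, source = path)
}

#' Look up one concept's sensorimotor vector
#'
#' Lookup goes through [normalize_word()], so `"CYAN"` and `"cyan"` retrieve
#' the same entry.
#'
#' @param table A `norms_table`.
#' @param word Word label (any case).
#' @return Named numeric vector of 11 ratings in canonical dimension order,
#'   with attributes `word` (display label) and `key`.
#' @export
get_vector <- function(table, word) {
  stopifnot(inherits(table, "norms_table"))
  key <- normalize_word(word)
  if (length(key) != 1L) smd_error("smd_invalid_word", "one word at a time")
  i <- match(key, rownames(table$ratings))
  if (is.na(i)) {
    smd_error("smd_not_found", sprintf("word not in norms: '%s'", key),
              key = key)
  }
  v <- table$ratings[i, ]
  attr(v, "word") <- unname(table$words[[key]])
  attr(v, "key") <- key
  v
}

#' Write a norms table to a delimited file
#'
#' Emits the default published-norms schema ([lancaster_column_map()]), so
#' the file round-trips through [load_norms()] unchanged.
#'
#' @param table A `norms_table`.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_norms <- function(table, path) {
  stopifnot(inherits(table, "norms_table"))
  map <- lancaster_column_map()
  df <- data.frame(unname(table$words), table$ratings,
                   check.names = FALSE, row.names = NULL)
  names(df) <- c(map$word_column, unname(map$rating_columns))
  write_delim_auto(df, path)
  invisible(path)
}
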