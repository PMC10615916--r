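# Internal helpers: classed error conditions and delimited-file reading.

smd_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "smd_error")))
}

# CSV vs TSV chosen by file extension; header row required, UTF-8.
read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    smd_error("smd_file_error", sprintf("file not found: %s", path))
  }
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", fileEncoding = "UTF-8")
}

write_delim_auto <- function(df, path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
}

# Kahan-compensated accumulator for streaming sums.
kahan_add <- function(acc, x) {
  y <- x - acc[2L]
  t <- acc[1L] + y
  acc[2L] <- (t - acc[1L]) - y
  acc[1L] <- t
  acc
}
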