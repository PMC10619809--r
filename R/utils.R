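# Small shared utilities.

# Write a tibble as CSV with a '#'-prefixed metadata header block
# (key=value lines). Readers that skip comment lines parse it as plain CSV.
write_csv_meta <- function(x, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta) && length(meta))
    writeLines(paste0("# ", names(meta), "=", unname(meta)), con)
  write.csv(x, con, row.names = FALSE)
  invisible(path)
}

read_csv_meta <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Deterministic 32-bit sub-seed derived from a base seed and a stream label.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(paste0(stream)) * seq_along(utf8ToInt(paste0(stream))))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}
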