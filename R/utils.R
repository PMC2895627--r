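`%||%` <- function(a, b) if (is.null(a)) b else a

# Trapezoid integral over an ordered grid.
.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Deterministic 32-bit substream derivation (Lehmer-style mix). Keeps every
# derived seed in [1, 2^31 - 2] so set.seed() always accepts it, and stays
# exact in double arithmetic (products < 2^53).
derive_seed <- function(seed, k) {
  m <- 2147483647
  s <- ((seed %% m) * 48271 + (k %% m) * 30269 + 12345) %% m
  as.integer(if (s == 0) 1 else s)
}

.write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  list_cols <- vapply(df, is.list, logical(1))
  for (j in which(list_cols)) {
    df[[j]] <- vapply(df[[j]], function(x) {
      if (length(x) == 0 || all(is.na(x))) "." else paste(x, collapse = ",")
    }, character(1))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  invisible(path)
}

.read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, na.strings = ".",
             stringsAsFactors = FALSE, check.names = FALSE, comment.char = "")
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
.msgf <- function(fmt, ...) message(sprintf(fmt, ...))
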