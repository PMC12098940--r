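# Internal helpers: error signalling, identifier quoting, chunk arithmetic.

abort_scsql <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("scsql_error_", class), "scsql_error"), ...)
}

# Double-quote an identifier for SQL (quotes embedded quotes by doubling).
qid <- function(x) {
  paste0('"', gsub('"', '""', x, fixed = TRUE), '"')
}

# Split 1..n into consecutive blocks of at most `size` (last block may be short).
split_blocks <- function(n, size) {
  if (n == 0L) return(list())
  starts <- seq.int(1L, n, by = size)
  lapply(starts, function(s) seq.int(s, min(s + size - 1L, n)))
}

`%||%` <- rlang::`%||%`

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# paste0 treats zero-length inputs as ""; these ids must be empty at n = 0.
make_ids <- function(prefix, n) {
  if (n == 0L) character(0) else paste0(prefix, seq_len(n))
}
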