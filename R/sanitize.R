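#' Sanitize a column or gene name for use as a database identifier
#'
#' Gene symbols routinely contain characters that are not legal in bare SQL
#' identifiers (`HLA-A`, `MT.CO1`). Every character outside `[A-Za-z0-9_]`
#' is replaced with an underscore; a leading digit gets an underscore
#' prefix; collisions with already-assigned names are resolved by appending
#' the smallest integer suffix `_1`, `_2`, ... not yet taken. The mapping is
#' deterministic given the name and the set of taken names, and leaves
#' already-safe unique names untouched.
#'
#' @param name raw name (non-empty string).
#' @param taken character vector of sanitized names already assigned within
#'   the same table.
#' @return the sanitized identifier (character scalar).
#' @examples
#' sanitize_identifier("HLA-A")          # "HLA_A"
#' sanitize_identifier("MT.CO1", "MT_CO1") # "MT_CO1_1"
#' @export
sanitize_identifier <- function(name, taken = character()) {
  if (!is_scalar_string(name) || !nzchar(name)) {
    abort_scsql("identifier must be a non-empty string", "invalid_identifier")
  }
  safe <- gsub("[^A-Za-z0-9_]", "_", name)
  if (grepl("^[0-9]", safe)) safe <- paste0("_", safe)
  if (!safe %in% taken) return(safe)
  i <- 1L
  while (paste0(safe, "_", i) %in% taken) i <- i + 1L
  paste0(safe, "_", i)
}

# Sanitize a vector of names in source order, resolving collisions
# deterministically. Returns a tibble(original, sanitized, ordinal).
sanitize_names <- function(names, table_name) {
  sanitized <- character(length(names))
  taken <- character(0)
  for (i in seq_along(names)) {
    sanitized[i] <- sanitize_identifier(names[i], taken)
    taken <- c(taken, sanitized[i])
  }
  tibble::tibble(
    table_name = table_name,
    original = as.character(names),
    sanitized = sanitized,
    ordinal = seq_along(names)
  )
}
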