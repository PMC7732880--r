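# Internal helpers shared across modules.

# Deterministic child seeds: a single run seed fans out to per-stage /
# per-round seeds via a fixed counter scheme, so partial re-runs reproduce.
child_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(counter))
  as.integer((as.double(seed) * 1000L + as.double(counter)) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Radix order: locale-independent tie-breaking on names.
order_desc_by_value_then_name <- function(values, names) {
  order(-values, names, method = "radix")
}

stop_ts <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_prob <- function(x, open = TRUE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
}

# Stable JSON used for all serialized reports: fixed key order (insertion
# order of the R lists), unboxed scalars, full double precision.
write_stable_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

# Cheap order-sensitive checksum for index sets (split-fixity bookkeeping).
index_checksum <- function(idx) {
  idx <- as.double(sort(as.integer(idx)))
  sprintf("%d:%.0f:%.0f", length(idx), sum(idx),
          sum(idx * seq_along(idx)) %% 1e12)
}
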