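`%||%` <- function(a, b) if (is.null(a)) b else a

# pairwise log(exp(x) + exp(y)) without underflow; x, y same length
log_add <- function(x, y) {
  m <- pmax(x, y)
  # both -Inf: log(0 + 0) = -Inf, avoid NaN from -Inf - -Inf
  out <- m + log1p(exp(pmin(x, y) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# deterministic hash of an R object (used to stamp outputs with the config)
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), tf)
  unname(tools::md5sum(tf))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
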