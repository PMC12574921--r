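# Internal helpers shared across modules.

# Scalar type checks kept tiny and explicit; user-facing errors name the
# offending argument so CLI and interactive use read the same.
is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == trunc(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_count <- function(x, name, min = 1) {
  if (!is_count(x, min = min)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "lisnet_config_error")
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is_number(x) && (if (strict) x > min else x >= min)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number %s %s.",
                  name, if (strict) ">" else ">=", format(min)),
          class = "lisnet_config_error")
  }
  as.numeric(x)
}

check_seed <- function(seed) {
  if (!is_number(seed) || seed != trunc(seed)) {
    abort("`seed` must be a single integer.", class = "lisnet_config_error")
  }
  as.integer(seed %% .Machine$integer.max)
}

# Deterministic per-object sub-seed: mixes a base seed with a string key so
# generators can draw independent, reproducible streams per pair/fly/model.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(paste(key, collapse = "\r")) *
             (seq_along(utf8ToInt(paste(key, collapse = "\r"))) %% 61 + 1))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 12582917) %%
               2147483587)
}

# Canonical unordered pair key, used for prediction caching and file naming.
pair_key <- function(a, b) {
  paste(sort(c(a, b)), collapse = "__")
}
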