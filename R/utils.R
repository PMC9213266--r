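## Internal helpers: argument checking, error classes, hashing.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Error conditions carry a class so the CLI can map them to exit codes:
## parameter errors -> 2, data/structural errors -> 3.
abort_param <- function(msg) {
  stop(errorCondition(msg, class = c("aslbs_parameter_error", "aslbs_error")))
}

abort_data <- function(msg) {
  stop(errorCondition(msg, class = c("aslbs_data_error", "aslbs_error")))
}

check_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    abort_param(sprintf("`%s` must be a single finite %s number, got %s",
                        name, if (strict) "positive" else "non-negative",
                        paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_same_dim <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b))) {
    abort_data(sprintf("%s must share one shape (%s vs %s)", what,
                       paste(dim(a), collapse = "x"),
                       paste(dim(b), collapse = "x")))
  }
  invisible(TRUE)
}

## FNV-1a 32-bit hash of a character scalar; used to stamp reports with a
## configuration fingerprint without an external digest dependency.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    ## xor on the low byte only (b < 256); keeps h in double to dodge the
    ## 32-bit signed-integer range of bitwXor
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    ## 32-bit modular multiply by the FNV prime 16777619, split into 16-bit
    ## halves so intermediates stay below 2^53 (exact in double arithmetic)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## Canonical JSON for hashing/round-trip: sorted names, fixed precision.
canonical_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}
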