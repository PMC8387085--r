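# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' @noRd
is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
}

# Row-major scan key (origin top-left): used wherever deterministic ordering
# of pixels or components is required. r, c are 1-based matrix indices.
scan_key <- function(r, c, width) (r - 1) * width + (c - 1)

# Polygon area by the shoelace formula; x, y are vertex coordinates in order.
shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Pad a matrix with a ring of `value`; used before the distance transform so
# that outside-image counts as background.
pad_matrix <- function(m, value = 0) {
  out <- matrix(value, nrow(m) + 2L, ncol(m) + 2L)
  out[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  out
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream; seed = NULL leaves the RNG alone.
with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
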