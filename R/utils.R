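#' @keywords internal
#' @import data.table
#' @importFrom jsonlite write_json read_json toJSON
#' @importFrom stats sd var rnorm runif qt pt dbinom aggregate setNames quantile fft dist
#' @importFrom utils read.delim read.table
"_PACKAGE"

## Input validation helpers.  All user-facing errors are classed so tests
## can match on condition class rather than message text.

stop_invalid <- function(msg, class = "trfcomp_invalid_argument") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    stop_invalid(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0)
    stop_invalid(sprintf("`%s` must be >= 0", name))
  if (integerish && abs(x - round(x)) > 1e-8)
    stop_invalid(sprintf("`%s` must be an integer", name))
  invisible(x)
}

check_no_na <- function(x, name) {
  if (anyNA(x) || any(!is.finite(x)))
    stop_invalid(sprintf("`%s` contains NA/NaN/Inf values", name))
  invisible(x)
}

## 32-bit xor on doubles in [0, 2^32) via 16-bit halves (base bitwXor only
## accepts values representable as R integers).
xor32 <- function(a, b) {
  bitwXor(a %% 65536, b %% 65536) +
    65536 * bitwXor(a %/% 65536, b %/% 65536)
}

fnv1a32 <- function(bytes) {
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

## Deterministic child-seed derivation: a 32-bit FNV-1a hash of the parent
## seed and a stage tag, folded into [0, 2^31).  Keeps every derived seed a
## valid R integer and decorrelates stages sharing a global seed.
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  as.integer(fnv1a32(utf8ToInt(tag)) %% 2147483647)
}

## FNV-1a hash of a string, hex-encoded; used for config fingerprints in
## run manifests (cheap, dependency-free, not cryptographic).
fnv1a_hex <- function(x) {
  h <- fnv1a32(utf8ToInt(x))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
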