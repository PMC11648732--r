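# Internal helpers: deterministic sub-seed derivation, canonical JSON
# serialization (so byte-equality of configs is meaningful), content hashing,
# and scoped RNG handling.

#' Derive a reproducible sub-seed from a master seed and a key
#'
#' Independent pseudo-random streams (per site, per round, per case) are keyed
#' by hashing the master seed together with string labels, so that simulated
#' sites running in one process behave like isolated processes with their own
#' generators. The result is a valid 32-bit, non-negative R seed.
#'
#' @param seed integer master seed.
#' @param ... further atomic keys (site ids, round indices, ...).
#' @return a single integer seed in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "|")
  hex <- fnv1a64(charToRaw(key))
  # take the low 31 bits of the 64-bit hash
  low <- substr(hex, 9, 16)
  val <- strtoi(substr(low, 2, 8), base = 16L) # 28 bits, always < 2^31
  d1 <- strtoi(substr(low, 1, 1), base = 16L)
  as.integer((val + d1 * 2^28) %% .Machine$integer.max)
}

# Evaluate `expr` with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Canonical JSON: recursively sort names, fixed number formatting. Used
# wherever byte-equality of a serialized object is part of the contract.
canonical_json <- function(x) {
  canon <- function(v) {
    if (is.list(v)) {
      if (!is.null(names(v)) && length(v)) v <- v[order(names(v))]
      lapply(v, canon)
    } else v
  }
  jsonlite::toJSON(canon(x), auto_unbox = TRUE, digits = I(12), null = "null")
}

#' Content digest of an R object
#'
#' A deterministic 64-bit FNV-1a digest over a canonical serialization.
#' Used for model-configuration hashes, checkpoint integrity and dataset
#' digests.
#'
#' @param x an R object. Atomic vectors, arrays and (nested) lists are
#'   serialized canonically; other objects via `serialize()`.
#' @return a 16-character hex string.
#' @export
object_digest <- function(x) {
  raw <- serialize(x, NULL, version = 2, xdr = TRUE)
  # drop the serialization header (R version stamps) so the digest depends
  # only on content
  fnv1a64(raw[-seq_len(14)])
}

# stopifnot with a clearer message
abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
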