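abort_input <- function(msg) stop(msg, call. = FALSE)

check_number <- function(x, name, min = -Inf, strict = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    abort_input(sprintf("`%s` must be a single number", name))
  if (finite && !is.finite(x))
    abort_input(sprintf("`%s` must be finite", name))
  ok <- if (strict) x > min else x >= min
  if (!ok)
    abort_input(sprintf("`%s` must be %s %s", name, if (strict) ">" else ">=", min))
  invisible(x)
}

#' Content hash of a configuration object
#'
#' Deterministic 31-bit polynomial hash over the canonical JSON
#' serialization of `x` (keys in the order defined by the constructors,
#' doubles at full precision). Used to freeze scenarios and to key sweep
#' cells for resumption; not a cryptographic hash.
#'
#' @param x A list-like configuration object.
#' @return A character scalar (hex digits).
#' @export
config_hash <- function(x) {
  json <- jsonlite::toJSON(unclass_deep(x), auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(as.character(json)))
  h <- 0
  m <- 2147483647  # 2^31 - 1
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", as.integer(h))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else {
    x
  }
}

# seeds for replicate substreams: deterministic given the master seed,
# 32-bit safe, distinct with overwhelming probability
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  )
  set.seed(as.integer(master_seed))
  sample.int(2147483646L, n)
}
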