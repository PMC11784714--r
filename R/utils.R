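# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a context label
#'
#' Child seeds keep every stage of the pipeline independently reproducible:
#' the same master seed and the same context string always map to the same
#' 31-bit integer seed, and distinct contexts map to (practically) distinct
#' seeds.
#'
#' @param seed Integer master seed.
#' @param ... Context labels (stage name, comparison name, fold index, ...).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  s <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Polynomial rolling hash of a serialized R object, as a hex string; used to
# fingerprint run configurations in the manifest.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Column-wise standardization; zero-variance columns are centred and left
# with unit divisor so they standardize to an all-zero column.
standardize_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

standardize_apply <- function(x, std) {
  sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
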