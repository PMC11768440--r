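# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-stage / per-evaluation seed derivation from a master seed.
# Linear congruential step keeps everything inside the 32-bit signed range.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + 7919 * as.double(index)) %% 2147483647)
}

stop_dustrisk <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

check_numeric_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_dustrisk("%s must be a numeric matrix", what)
  if (anyNA(x)) stop_dustrisk("%s contains missing values", what)
  invisible(x)
}

# Pairwise Euclidean distances as a dense symmetric matrix.
dist_matrix <- function(x) as.matrix(stats::dist(x))

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
}
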