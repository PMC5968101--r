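# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_irritmap <- function(msg, class) {
  rlang::abort(msg, class = c(class, "irritmap_error"))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_irritmap(sprintf("`%s` must be a single finite number.", name),
                  "irritmap_config_error")
  }
  if (positive && x <= 0) {
    stop_irritmap(sprintf("`%s` must be > 0.", name), "irritmap_config_error")
  }
  invisible(x)
}

# Row-wise vector norms of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m^2))

# Draw a reproducible sub-seed stream from a master seed (keeps values
# well inside 32-bit integer range).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
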