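# Internal helpers shared across modules.

# Deterministic 32-bit sub-seed derived from a master seed and an index,
# so each participant (or fold, or draw block) gets its own RNG stream.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(index) * 16807) %% 2147483647
  as.integer((x * 69621) %% 2147483629) + 1L
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stop_config <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_config("`%s` must be a probability in [0, 1]", name)
  }
  invisible(x)
}

check_marginal <- function(p, name, tol = 1e-9) {
  check_prob(unname(p), name)
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    stop_config("`%s` must be a named probability vector", name)
  }
  if (abs(sum(p) - 1) > tol) {
    stop_config("`%s` must sum to 1 (got %.12f)", name, sum(p))
  }
  invisible(p)
}

# Sample categories from a named marginal.
sample_marginal <- function(n, marginal) {
  if (n == 0L) return(character(0))
  sample(names(marginal), n, replace = TRUE, prob = unname(marginal))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
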