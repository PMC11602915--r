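#' @importFrom rlang %||% abort warn .data
#' @importFrom stats median quantile qnorm pnorm plogis rnorm runif rbinom
#'   rpois rlnorm cor sd weighted.mean setNames integrate
#' @importFrom utils head
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so seeded generation never perturbs the
# global stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-city seed derived from the scenario seed; kept inside
# 32-bit integer range.
derive_seed <- function(seed, index, offset = 0L) {
  as.integer((as.double(seed) + 7919 * index + 104729 * offset) %% 2147483629)
}

assert_scalar_number <- function(x, field, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("invalid configuration: `%s` must be a single number in [%s, %s]",
                  field, format(lower), format(upper)),
          class = "urbanpoverty_config_error")
  }
  invisible(x)
}

assert_range <- function(x, field, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 2L || anyNA(x) || x[1] > x[2] ||
      x[1] < lower || x[2] > upper) {
    abort(sprintf("invalid configuration: `%s` must be a non-decreasing [min, max] pair within [%s, %s]",
                  field, format(lower), format(upper)),
          class = "urbanpoverty_config_error")
  }
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
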