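#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif prcomp aov anova qtukey pf var sd
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG seed without disturbing the caller's stream.
# seed = NULL means "use the current stream" (non-reproducible).
with_rng_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Deterministic per-stage sub-seed derivation so that a pipeline run can be
# reproduced by composing the stage functions by hand with the same seeds.
# Offsets: 1 = clustering, 2 = head init, 3 = epoch shuffling, 4 = reduction.
derive_seed <- function(base, round, offset) {
  if (is.null(base)) return(NULL)
  (as.integer(base) + 1009L * as.integer(round) + as.integer(offset)) %% 2147483647L
}

# round() uses banker's rounding on .5 ties; printed tables use half-up.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_input <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_input(sprintf("`%s` must be a single finite number in [%s, %s]",
                       name, format(lower), format(upper)))
  }
  invisible(x)
}

MATURITY_STAGES <- c("unripe", "ripe", "overripe")
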