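#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# Deterministic sub-seed fan-out; keeps results < 2^31 so set.seed() accepts them.
sub_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 9176 + 1) %% 2147483629)
}

# Half-up rounding to integers (round() is banker's; map classes on the
# 0-1000 suitability scale must be stable across platforms).
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
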