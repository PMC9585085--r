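# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library calls never perturb user randomness.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed: keeps derived seeds strictly below 2^31.
derive_seed <- function(seed, index) {
  (as.integer(seed) * 48271 + as.integer(index) * 1009) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

SIDES <- c("left", "right")

side_to_int <- function(side) {
  out <- match(side, SIDES)
  if (anyNA(out[!is.na(side)])) {
    stop("sides must be 'left' or 'right'", call. = FALSE)
  }
  out
}

other_side <- function(side) SIDES[3L - side_to_int(side)]

assert_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}
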