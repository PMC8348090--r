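# Internal helpers shared across modules.

BEHAVIORS <- c("bite", "chew", "chew_bite")
FORAGE_SPECIES <- c("alfalfa", "tall_fescue")
FORAGE_HEIGHTS <- c("tall", "short")
SAMPLE_RATE <- 22050L
INT16_MIN <- -32768L
INT16_MAX <- 32767L

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards. All randomised operations in the
# package route through this so that a seed argument fully determines the
# result without clobbering the session RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and an index, staying inside the
# 32-bit signed range R requires of set.seed().
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}

clip_int16 <- function(x) {
  x <- round(x)
  x[x > INT16_MAX] <- INT16_MAX
  x[x < INT16_MIN] <- INT16_MIN
  as.integer(x)
}

match_enum <- function(value, choices, what) {
  if (length(value) != 1L || !value %in% choices) {
    stop(sprintf("`%s` must be one of: %s", what,
                 paste(choices, collapse = ", ")), call. = FALSE)
  }
  value
}
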