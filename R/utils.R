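# Internal helpers: seeded substreams and small validators.

# Large prime below 2^31 used to fold substream names into the seed space.
.SEED_MOD <- 2147480009

#' Derive a reproducible substream seed from a global seed and a stream name
#'
#' A single user-facing seed is fanned out to named substreams (one per
#' stochastic stage), so adding a new stage never shifts the random stream
#' of an existing one.
#'
#' @param seed integer global seed.
#' @param name character scalar naming the substream.
#' @return An integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name),
            length(name) == 1L)
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% .SEED_MOD
  as.integer((abs(as.numeric(seed)) * 48611 + h) %% .SEED_MOD)
}

# Evaluate expr under a local RNG state seeded with `seed`; the ambient
# .Random.seed is restored afterwards so callers are unaffected.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_validation <- function(...) {
  stop(structure(class = c("phosphoscreen_validation_error", "error",
                           "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Polynomial rolling hash of a character scalar, reported as hex; used for
# the run manifest's config fingerprint (stability, not cryptography).
config_hash <- function(x) {
  stopifnot(is_string(x))
  h <- 5381
  for (ch in utf8ToInt(x)) h <- (h * 127 + ch) %% .SEED_MOD
  sprintf("%08x", as.integer(h))
}
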