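#' Derive a child seed from a master seed and a stream label
#'
#' All stochastic components of the package draw from independent streams
#' derived from one master seed, keyed by a component label (and optionally an
#' index), so that e.g. adding traits to a simulation does not perturb the
#' genotype draws.  The derivation is a plain 31-bit polynomial string hash —
#' deterministic across platforms and always below 2^31.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the stream, e.g.
#'   `child_seed(1, "traits", 3)`.
#' @return a single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' child_seed(42, "panel") != child_seed(42, "traits")
#' @export
child_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Run `expr` with the RNG seeded from a child stream, restoring the caller's
# RNG state afterwards so package internals never disturb user-level draws.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
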