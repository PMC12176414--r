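# Reproducible sub-seeding. Every randomized step in the protocol draws its
# randomness under a child seed derived deterministically from a master seed
# and the step's coordinates, so replicates and variants are reproducible
# independently and in any order.

.SEED_MOD <- 2147483647  # 2^31 - 1; keeps every derived seed a valid R integer

#' Derive a child seed from a master seed and step coordinates
#'
#' Mixes the master seed with any number of integer or character components
#' by a multiplicative congruential fold, yielding a deterministic seed
#' below 2^31. Identical inputs always yield the identical child seed.
#'
#' @param seed Integer master seed.
#' @param ... Coordinates of the randomized step (integers or strings),
#'   e.g. \code{childSeed(s, "rep", 7)}.
#' @return A single integer seed in [1, 2^31 - 1].
#' @examples
#' childSeed(42, "rep", 3)
#' @export
childSeed <- function(seed, ...) {
  h <- as.numeric(seed) %% .SEED_MOD
  for (part in list(...)) {
    codes <- if (is.character(part)) utf8ToInt(paste(part, collapse = "/"))
             else as.numeric(part)
    for (x in codes) {
      # 48271 is a classic MINSTD multiplier; products stay exact in doubles
      h <- (h * 48271 + (x %% .SEED_MOD) * 7919 + 17) %% .SEED_MOD
    }
  }
  as.integer(h + 1)
}

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates \code{expr}, and restores the caller's RNG
#' state, so seeded package internals never disturb user randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
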