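# Seed plumbing: one master seed per run, expanded into per-stage child
# seeds so that adding a sample never perturbs another sample's draws.

#' Derive a stable child seed from a master seed and stage labels
#'
#' A polynomial rolling hash over the master seed and an arbitrary number of
#' string labels (stage name, unit id, sample id, ...). Stable across
#' sessions and platforms; the result is a positive 31-bit integer suitable
#' for `set.seed()`.
#'
#' @param master integer master seed.
#' @param ... character labels identifying the stage.
#' @return a single integer in `[1, 2^31 - 2]`
#' @examples
#' childSeed(42, "hierarchy")
#' childSeed(42, "reads", "unit1", "cell3")
#' @export
childSeed <- function(master, ...) {
  labels <- as.character(unlist(list(...)))
  key <- paste(c(format(as.integer(master)), labels), collapse = "\x1f")
  bytes <- utf8ToInt(key)
  mod <- 2147483587  # largest prime < 2^31 - 1
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% mod
  as.integer(h + 1)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# A NULL seed means "use the current stream".
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}
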