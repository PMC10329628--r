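# Seed plumbing: all randomness in the package flows from a master seed via
# named substreams, so stages (anatomy / attachments / forces / visibility /
# net-init / split) can be reproduced independently.

#' Derive a substream seed from a master seed and a stream name
#'
#' @param master integer master seed.
#' @param name character scalar naming the stream.
#' @return an integer seed in [0, 2^31).
#' @export
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(master) * 48271 + h * 16807) %% 2147483647)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so callers' RNG state is untouched.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
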