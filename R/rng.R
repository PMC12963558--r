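# Local seeding: run code under a fixed seed without disturbing the caller's
# RNG stream, and derive independent sub-seeds from one top-level seed so a
# whole synthetic study is reproducible from a single integer.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a deterministic sub-seed
#'
#' Mixes a parent seed with a string tag via a small multiplicative hash,
#' returning an integer in `[0, 2^31 - 2]`. Used to give every recording,
#' rest segment and questionnaire of a study its own reproducible stream
#' from one top-level seed (e.g. tag `"rec/S03/HM"`).
#'
#' @param seed parent integer seed.
#' @param tag character tag naming the consumer.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, tag) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}
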