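#' Derive a stage-specific RNG seed from a global seed
#'
#' All stochastic stages of the pipeline draw their randomness from a single
#' user-supplied seed. Each stage (and, within a stage, each entity such as a
#' contig or an implanted locus) receives its own substream seed obtained by
#' stable string hashing of \code{(seed, stage, id)}, so that results are
#' reproducible independently of call order.
#'
#' @param seed integer; the global seed.
#' @param stage character scalar naming the stage (e.g. \code{"genome"}).
#' @param id optional character/numeric entity identifier within the stage.
#' @return An integer in \code{[0, 2^31 - 2]}, suitable for \code{set.seed()}.
#' @export
split_seed <- function(seed, stage, id = "") {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  key <- paste0(stage, "\r", paste(id, collapse = ","))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(key)) {
    # Horner update; products stay < 2^53 so double arithmetic is exact
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# interval overlap length for 0-based half-open intervals; 0 when disjoint
overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# external (1-based inclusive) <-> internal (0-based half-open)
to_external <- function(start, end) list(start = start + 1L, end = end)
to_internal <- function(start, end) list(start = start - 1L, end = end)

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic stream evaluation: run expr with a local RNG state
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
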