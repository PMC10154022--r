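#' Counter-based random substreams
#'
#' Every random quantity in the simulation is a pure function of
#' (root seed, person id, stream id, counter), evaluated through a keyed
#' SplitMix64 hash. This gives each simulated person a reproducible private
#' substream, so that the same person's natural history is bit-identical
#' across scenarios and across population sizes (the common-random-numbers
#' contract), without any dependence on R's global RNG state.
#'
#' Stream ids used by the package: 0 other-cause mortality, 1 frailty,
#' 2 lesion count, 3 per-lesion draws (blocks of 8), 4 exam draws
#' (blocks of 64 per exam: slot 0 is the person-level draw, slots 1+j the
#' per-lesion draws).
#'
#' @param seed root seed (non-negative integer-valued scalar).
#' @param person person id (positive integer-valued scalar).
#' @param stream stream id (non-negative integer-valued scalar).
#' @param counters vector of non-negative counters.
#' @return numeric vector of uniforms in (0, 1), one per counter.
#' @examples
#' rng_uniforms(1, 1, 0, 0:4)
#' @export
rng_uniforms <- function(seed, person, stream, counters) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0,
            is.numeric(person), length(person) == 1L, person >= 1,
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  cpp_uniforms(as.double(seed), as.double(person), as.double(stream),
               as.double(counters))
}

#' Per-person random stream object
#'
#' A small stateful handle over [rng_uniforms()] used by the single-exam
#' operations. `$unif(stream, counters)` returns stateless uniforms;
#' `$exam_block()` returns the 64 uniforms for the next exam event and
#' advances the exam counter, mirroring the draw protocol of the compiled
#' replay engine.
#'
#' @param seed root seed.
#' @param person person id.
#' @return an environment of class `crc_rng`.
#' @export
crc_rng <- function(seed, person = 1L) {
  e <- new.env(parent = emptyenv())
  e$seed <- seed
  e$person <- person
  e$exam_counter <- 0L
  e$unif <- function(stream, counters) rng_uniforms(seed, person, stream, counters)
  e$exam_block <- function() {
    base <- e$exam_counter * 64
    e$exam_counter <- e$exam_counter + 1L
    rng_uniforms(seed, person, 4, base + 0:63)
  }
  class(e) <- "crc_rng"
  e
}
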