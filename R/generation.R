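#' Draw per-type mutation counts for one generation
#'
#' The number of events of each type in a generation is Poisson with mean
#' `mu_type * start_size`, all four counts independent, and all based on
#' the genome size at the start of the generation (not on mid-generation
#' sizes). By Poisson additivity the total count is Poisson with mean
#' `mu_total * start_size`.
#'
#' @param rates a [mutation_rates] object.
#' @param start_size genome size at the start of the generation, bp, `>= 1`.
#' @return Named integer vector of counts
#'   (`small_insertion`, `small_deletion`, `large_deletion`, `duplication`).
#' @export
draw_mutation_counts <- function(rates, start_size) {
  stopifnot(inherits(rates, "mutation_rates"), start_size >= 1)
  counts <- stats::rpois(4L, start_size * c(rates$mu_ins, rates$mu_sdel,
                                            rates$mu_ldel, rates$mu_dup))
  names(counts) <- EVENT_TYPES
  counts
}

#' Simulate one generation (one replication) of a genome
#'
#' Draws the per-type Poisson event counts, applies the events one by one
#' in a uniformly random order -- each event acting on the size left by the
#' previous one, with rearrangement sizes drawn at application time against
#' the current, mid-generation size -- and finally rewires a size-0 outcome
#' to size 1, so that the generational chain on positive sizes has no
#' absorbing state.
#'
#' @param start_size genome size at the start of the generation, bp, `>= 1`.
#' @param rates a [mutation_rates] object.
#' @param indels an [indel_model].
#' @param rearr a [rearrangement_model].
#' @param record_events if `TRUE`, return the full typed event log.
#' @return A list of class `"generation_outcome"`: `start_size`,
#'   `end_size` (>= 1), `counts_by_type`, and (if recorded) `events`, a
#'   `data.frame` with one row per event (`event_type`, `size_change`,
#'   `pre_size`, `post_size`) in the order applied.
#' @examples
#' set.seed(1)
#' one_generation(4e6, mutation_rates(), indel_model(),
#'                rearrangement_model("uniform"))$end_size
#' @export
one_generation <- function(start_size, rates, indels, rearr,
                           record_events = TRUE) {
  stopifnot(start_size >= 1)
  counts <- draw_mutation_counts(rates, start_size)
  n <- sum(counts)
  types <- rep.int(seq_len(4L), counts)
  if (n > 1L) types <- types[sample.int(n)]   # uniform random order
  s <- start_size
  if (record_events && n > 0L) {
    pre <- post <- numeric(n)
    for (i in seq_len(n)) {
      pre[i] <- s
      s <- apply_mutation_size(s, types[i], indels, rearr)
      post[i] <- s
    }
    events <- data.frame(event_type = EVENT_TYPES[types],
                         size_change = post - pre,
                         pre_size = pre, post_size = post)
  } else {
    for (i in seq_len(n)) s <- apply_mutation_size(s, types[i], indels, rearr)
    events <- if (record_events)
      data.frame(event_type = character(), size_change = numeric(),
                 pre_size = numeric(), post_size = numeric())
  }
  structure(list(start_size = start_size,
                 end_size = max(1, s),
                 counts_by_type = counts,
                 events = events),
            class = "generation_outcome")
}
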