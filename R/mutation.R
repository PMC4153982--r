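#' Apply a single mutation to a genome size
#'
#' Implements the transition rules of the one-mutation kernel on genome
#' sizes:
#'
#' * small insertions add a draw from the insertion size law (this is the
#'   only way to escape size 0);
#' * small deletions remove a draw from the deletion size law, floored at 0
#'   (all transitions below 0 are rewired to 0);
#' * duplications add a rearrangement-size draw (1..s for the uniform law);
#' * large deletions remove a rearrangement-size draw, so under the uniform
#'   law the final size is uniform on `0:(s-1)`.
#'
#' At size 0, small deletions, duplications and large deletions leave the
#' genome at 0.
#'
#' @param current_size genome size before the mutation, bp, `>= 0`.
#' @param event_type one of `"small_insertion"`, `"small_deletion"`,
#'   `"large_deletion"`, `"duplication"`.
#' @param indels an [indel_model].
#' @param rearr a [rearrangement_model].
#' @return A one-row `data.frame` (a `MutationEvent` record) with columns
#'   `event_type`, `size_change`, `pre_size`, `post_size`.
#' @examples
#' set.seed(1)
#' apply_mutation(4e6, "large_deletion", indel_model(),
#'                rearrangement_model("uniform"))
#' @export
apply_mutation <- function(current_size, event_type, indels, rearr) {
  stopifnot(current_size >= 0)
  event_type <- match.arg(event_type, EVENT_TYPES)
  post <- apply_mutation_size(current_size, match(event_type, EVENT_TYPES),
                              indels, rearr)
  data.frame(event_type = event_type,
             size_change = post - current_size,
             pre_size = current_size,
             post_size = post)
}

# hot-path scalar version: type code 1 ins, 2 sdel, 3 ldel, 4 dup
apply_mutation_size <- function(s, type, indels, rearr) {
  if (type == 1L)
    return(s + sample_indel_size(indels$l_ins, indels$p_ins))
  if (type == 2L)
    return(max(0, s - sample_indel_size(indels$l_sdel, indels$p_sdel)))
  if (s == 0) return(0)                # rearrangements cannot act on nothing
  d <- sample_rearrangement_size(rearr, s)
  if (type == 3L) s - d else s + d
}
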