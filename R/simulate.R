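# Internal single-line engine shared by run_line() and run_until_floor().
#
# Generations without any mutation leave the size unchanged, and with
# per-bp rates around 1e-8 the vast majority of generations are empty, so
# by default the engine draws the geometric gap to the next event-bearing
# generation in O(1) (`skip_empty = TRUE`) instead of looping generation by
# generation. Within an event-bearing generation the total event count is
# drawn from the Poisson law conditioned on being >= 1 and the types from
# the conditional type distribution, which is distributionally identical to
# four independent per-type Poisson draws (Poisson thinning); the naive
# per-generation path is kept for equivalence checks.
sim_line_engine <- function(s0, max_gens, floor_size, rates, indels, rearr,
                            record_sizes = FALSE, record_events = FALSE,
                            skip_empty = TRUE) {
  mu <- rates$mu_total
  prob <- rates$prob
  mus <- c(rates$mu_ins, rates$mu_sdel, rates$mu_ldel, rates$mu_dup)
  kind <- switch(rearr$kind, uniform = 1L, truncated_lognormal = 2L,
                 empirical_table = 3L)
  if (kind == 2L) { ml <- rearr$meanlog; sl <- rearr$sdlog }
  # uniform indel laws dodge per-draw prob-vector overhead
  ins_unif <- all(indels$p_ins == indels$p_ins[1])
  del_unif <- all(indels$p_sdel == indels$p_sdel[1])
  l_ins <- indels$l_ins; l_sdel <- indels$l_sdel
  p_ins <- indels$p_ins; p_sdel <- indels$p_sdel

  s <- s0
  gen <- 0
  n_by_type <- integer(4L)
  size_sum <- numeric(4L)
  sizes <- if (record_sizes) c(s0, numeric(max_gens)) else NULL
  ev <- if (record_events) vector("list", 64L) else NULL
  n_ev_chunks <- 0L
  hit_floor <- FALSE
  floor_gen <- NA_integer_

  check_floor <- !is.null(floor_size)
  while (gen < max_gens) {
    lam <- mu * s
    if (skip_empty) {
      p <- -expm1(-lam)
      if (p <= 0) {                      # no events can ever occur again
        if (record_sizes) sizes[(gen + 2L):(max_gens + 1L)] <- s
        gen <- max_gens
        break
      }
      gap <- stats::rgeom(1L, p)
      if (gen + gap >= max_gens) {
        if (record_sizes && gen < max_gens)
          sizes[(gen + 2L):(max_gens + 1L)] <- s
        gen <- max_gens
        break
      }
      if (record_sizes && gap > 0L)
        sizes[(gen + 2L):(gen + gap + 1L)] <- s
      gen <- gen + gap + 1L
      n <- stats::qpois(stats::runif(1L, exp(-lam), 1), lam)  # total | >= 1
      types <- if (n == 1L) sample.int(4L, 1L, prob = prob) else
        sample.int(4L, n, replace = TRUE, prob = prob)
    } else {
      gen <- gen + 1L
      counts <- stats::rpois(4L, mus * s)
      n <- sum(counts)
      if (n == 0L) {
        if (record_sizes) sizes[gen + 1L] <- s
        next
      }
      types <- rep.int(seq_len(4L), counts)
      if (n > 1L) types <- types[sample.int(n)]
    }

    if (record_events) { pre_v <- post_v <- numeric(n) }
    for (i in seq_len(n)) {
      ty <- types[i]
      if (record_events) pre_v[i] <- s
      if (ty == 1L) {
        d <- if (ins_unif) sample.int(l_ins, 1L) else
          sample.int(l_ins, 1L, prob = p_ins)
        s_new <- s + d
      } else if (ty == 2L) {
        d <- if (del_unif) sample.int(l_sdel, 1L) else
          sample.int(l_sdel, 1L, prob = p_sdel)
        s_new <- max(0, s - d)
      } else if (s == 0) {
        s_new <- 0
      } else {
        if (kind == 1L) {
          d <- ceiling(stats::runif(1L) * s)
        } else if (kind == 2L) {
          fmax <- stats::plnorm(s + 0.5, ml, sl)
          if (fmax < 1e-12)
            stop("truncated lognormal: acceptance probability below 1e-12 ",
                 "at size ", s)
          d <- min(max(1, round(stats::qlnorm(stats::runif(1L, 0, fmax),
                                              ml, sl))), s)
        } else {
          d <- sample_rearrangement_size(rearr, s)
        }
        s_new <- if (ty == 3L) s - d else s + d
      }
      n_by_type[ty] <- n_by_type[ty] + 1L
      size_sum[ty] <- size_sum[ty] + abs(s_new - s)
      s <- s_new
      if (record_events) post_v[i] <- s
    }
    if (s < 1) s <- 1                     # end-of-generation rewiring
    if (record_sizes) sizes[gen + 1L] <- s
    if (record_events) {
      n_ev_chunks <- n_ev_chunks + 1L
      if (n_ev_chunks > length(ev)) ev <- c(ev, vector("list", length(ev)))
      ev[[n_ev_chunks]] <- data.frame(
        generation = gen, event_index = seq_len(n),
        event_type = EVENT_TYPES[types],
        size_change = post_v - pre_v, pre_size = pre_v, post_size = post_v)
    }
    if (check_floor && s < floor_size) {
      hit_floor <- TRUE
      floor_gen <- gen
      break
    }
  }

  list(final_size = s, generations_run = gen,
       sizes = if (record_sizes) sizes[seq_len(gen + 1L)],
       event_log = if (record_events) {
         if (n_ev_chunks > 0L) do.call(rbind, ev[seq_len(n_ev_chunks)])
         else data.frame(generation = integer(), event_index = integer(),
                         event_type = character(), size_change = numeric(),
                         pre_size = numeric(), post_size = numeric())
       },
       n_by_type = stats::setNames(n_by_type, EVENT_TYPES),
       size_sum_by_type = stats::setNames(size_sum, EVENT_TYPES),
       hit_floor = hit_floor, floor_generation = floor_gen)
}

#' Simulate one mutation-accumulation line
#'
#' Propagates a single genome through repeated single-individual
#' bottlenecks, one [one_generation()]-equivalent replication per
#' generation, with no selection.
#'
#' @param initial_size starting genome size, bp, `>= 1`.
#' @param generations number of generations to simulate, `>= 0`.
#' @param rates a [mutation_rates] object.
#' @param indels an [indel_model].
#' @param rearr a [rearrangement_model].
#' @param floor optional size threshold (bp): the line stops at the first
#'   generation whose end-of-generation size is below `floor`.
#' @param record_sizes keep the full per-generation size trajectory.
#' @param record_events keep the full typed event log.
#' @param skip_empty jump over mutation-free generations in O(1) (the
#'   default); `FALSE` forces the naive per-generation loop, which samples
#'   from the identical distribution.
#' @param line_id identifier stored in the result.
#' @return An object of class `"line_trajectory"`: `line_id`, `sizes`
#'   (length `generations_run + 1`, starting at `initial_size`; present if
#'   recorded), `event_log` (if recorded; columns `generation`,
#'   `event_index`, `event_type`, `size_change`, `pre_size`, `post_size`),
#'   `final_size`, per-type event counts and summed absolute event sizes,
#'   `stop_reason` (`"completed"` or `"hit_floor"`), and `floor_generation`.
#' @examples
#' set.seed(1)
#' tr <- run_line(4e6, 200, mutation_rates(), indel_model(),
#'                rearrangement_model("uniform"))
#' tr$final_size
#' @export
run_line <- function(initial_size, generations, rates, indels, rearr,
                     floor = NULL, record_sizes = TRUE,
                     record_events = FALSE, skip_empty = TRUE,
                     line_id = 1L) {
  stopifnot(initial_size >= 1, generations >= 0)
  if (!is.null(floor) && floor >= initial_size)
    stop("floor must be below initial_size")
  out <- sim_line_engine(initial_size, generations, floor, rates, indels,
                         rearr, record_sizes = record_sizes,
                         record_events = record_events,
                         skip_empty = skip_empty)
  structure(list(line_id = line_id,
                 initial_size = initial_size,
                 generations = generations,
                 generations_run = out$generations_run,
                 sizes = out$sizes,
                 event_log = out$event_log,
                 final_size = out$final_size,
                 n_by_type = out$n_by_type,
                 size_sum_by_type = out$size_sum_by_type,
                 stop_reason = if (out$hit_floor) "hit_floor" else "completed",
                 floor_generation = out$floor_generation),
            class = "line_trajectory")
}

#' Run a mutation-accumulation experiment
#'
#' Simulates `n_lines` independent lines (sequential draws from one RNG
#' stream; a fixed `seed` makes the whole experiment reproducible) and
#' summarizes them: the fraction of lines whose final size is strictly
#' below the initial size, the median signed size change, and per-type
#' event-count and event-size summaries in the style of an observed
#' mutation-accumulation polymorphism table.
#'
#' @inheritParams run_line
#' @param n_lines number of independent lines, `>= 1`.
#' @param seed optional integer seed, applied with [set.seed()] on entry.
#' @param keep_trajectories keep each line's per-generation sizes
#'   (memory: `n_lines * (generations + 1)` doubles).
#' @param keep_event_logs keep each line's full event log; per-type count
#'   and mean-size accumulators are always kept.
#' @return An object of class `"ma_experiment"`: `final_sizes`,
#'   `fraction_shrunk`, `median_size_change`, matrices `n_events` and
#'   `mean_event_size` (`n_lines` x 4, the latter `NA` for lines without
#'   events of a type), the event-summary table of [summarize_events()],
#'   and the configuration used.
#' @examples
#' set.seed(1)
#' ex <- run_experiment(200, 4e6, 1000, mutation_rates(), indel_model(),
#'                      rearrangement_model("uniform"))
#' ex$fraction_shrunk
#' @export
run_experiment <- function(n_lines, initial_size, generations, rates, indels,
                           rearr, seed = NULL, keep_trajectories = FALSE,
                           keep_event_logs = FALSE, skip_empty = TRUE) {
  stopifnot(n_lines >= 1)
  if (!is.null(seed)) set.seed(seed)
  final_sizes <- numeric(n_lines)
  n_events <- matrix(0L, n_lines, 4L, dimnames = list(NULL, EVENT_TYPES))
  size_sums <- matrix(0, n_lines, 4L, dimnames = list(NULL, EVENT_TYPES))
  trajectories <- if (keep_trajectories) vector("list", n_lines)
  event_logs <- if (keep_event_logs) vector("list", n_lines)
  for (i in seq_len(n_lines)) {
    out <- sim_line_engine(initial_size, generations, NULL, rates, indels,
                           rearr, record_sizes = keep_trajectories,
                           record_events = keep_event_logs,
                           skip_empty = skip_empty)
    final_sizes[i] <- out$final_size
    n_events[i, ] <- out$n_by_type
    size_sums[i, ] <- out$size_sum_by_type
    if (keep_trajectories) trajectories[[i]] <- out$sizes
    if (keep_event_logs) event_logs[[i]] <- out$event_log
  }
  mean_event_size <- size_sums / n_events       # NaN where a type never hit
  mean_event_size[n_events == 0L] <- NA_real_
  res <- structure(list(
    n_lines = n_lines, initial_size = initial_size,
    generations = generations,
    final_sizes = final_sizes,
    fraction_shrunk = mean(final_sizes < initial_size),
    median_size_change = stats::median(final_sizes) - initial_size,
    n_events = n_events,
    mean_event_size = mean_event_size,
    trajectories = trajectories,
    event_logs = event_logs,
    rates = rates, indels = indels, rearr = rearr, seed = seed),
    class = "ma_experiment")
  res$event_summary <- summarize_events(res)
  res
}

#' @export
print.ma_experiment <- function(x, ...) {
  cat(sprintf("Mutation-accumulation experiment: %d lines x %d generations, start %g bp\n",
              x$n_lines, x$generations, x$initial_size))
  cat(sprintf("  fraction of lines shrunk : %.4f\n", x$fraction_shrunk))
  cat(sprintf("  median size change       : %+.4g bp\n", x$median_size_change))
  cat("  per-type event summary (medians over lines; spread as MAD / SD):\n")
  print(x$event_summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Summarize the mutation events observed in a set of lines
#'
#' For each mutation type, reports the median across lines of the per-line
#' event count and the median across lines of the per-line mean absolute
#' event size. Lines without events of a type contribute a count of 0 but
#' are excluded from that type's size summary (their per-line mean is
#' undefined). Because "spread" of such medians admits several conventions,
#' both the median absolute deviation and the standard deviation across
#' lines are reported. A pooled per-event size median (all events of a type
#' across all lines pooled before taking the median) is available with
#' `pooled = TRUE`.
#'
#' @param x an `"ma_experiment"` or a list of `"line_trajectory"` objects.
#' @param pooled also report the pooled median absolute event size,
#'   weighting every event equally (requires per-line size sums only for
#'   `FALSE`; for `TRUE`, `x` must carry event logs).
#' @return A `data.frame` with one row per event type.
#' @export
summarize_events <- function(x, pooled = FALSE) {
  if (inherits(x, "ma_experiment")) {
    n_events <- x$n_events
    mean_size <- x$mean_event_size
    logs <- x$event_logs
  } else if (is.list(x) && length(x) > 0 &&
             inherits(x[[1]], "line_trajectory")) {
    n_events <- do.call(rbind, lapply(x, `[[`, "n_by_type"))
    size_sums <- do.call(rbind, lapply(x, `[[`, "size_sum_by_type"))
    mean_size <- size_sums / n_events
    mean_size[n_events == 0L] <- NA_real_
    logs <- lapply(x, `[[`, "event_log")
  } else stop("x must be an ma_experiment or a list of line_trajectory")
  if (nrow(n_events) == 0) stop("no lines to summarize")
  out <- data.frame(
    event_type = EVENT_TYPES,
    median_n_events = apply(n_events, 2, stats::median),
    mad_n_events = apply(n_events, 2, stats::mad),
    sd_n_events = apply(n_events, 2, stats::sd),
    median_event_size = apply(mean_size, 2, stats::median, na.rm = TRUE),
    mad_event_size = apply(mean_size, 2, stats::mad, na.rm = TRUE),
    sd_event_size = apply(mean_size, 2, stats::sd, na.rm = TRUE))
  if (pooled) {
    if (is.null(logs) || any(vapply(logs, is.null, logical(1))))
      stop("pooled = TRUE requires event logs (keep_event_logs/record_events)")
    all_ev <- do.call(rbind, logs)
    out$pooled_median_event_size <- vapply(EVENT_TYPES, function(ty)
      stats::median(abs(all_ev$size_change[all_ev$event_type == ty])),
      numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Propagate lines until genome size falls below a floor
#'
#' Runs independent mutation-accumulation lines until each first reaches a
#' size strictly below `floor` (or until `max_generations`). Mutation-free
#' generations are skipped in O(1), so horizons of hundreds of thousands of
#' generations are fast.
#'
#' @inheritParams run_experiment
#' @param floor size threshold in bp; must be `< initial_size`.
#' @param max_generations give up after this many generations; such lines
#'   report `crossing_generation = max_generations` and `crossed = FALSE`.
#' @return A `data.frame` with columns `line_id`, `crossing_generation`
#'   (first generation with end-of-generation size below `floor`),
#'   `crossed`, and `final_size`.
#' @examples
#' set.seed(1)
#' fl <- run_until_floor(5, 1e5, 1e3, 1e6, mutation_rates(), indel_model(),
#'                       rearrangement_model("uniform"))
#' range(fl$crossing_generation)
#' @export
run_until_floor <- function(n_lines, initial_size, floor, max_generations,
                            rates, indels, rearr, seed = NULL) {
  stopifnot(n_lines >= 1, max_generations >= 1)
  if (floor >= initial_size) stop("floor must be below initial_size")
  if (!is.null(seed)) set.seed(seed)
  gens <- numeric(n_lines)
  crossed <- logical(n_lines)
  fin <- numeric(n_lines)
  for (i in seq_len(n_lines)) {
    out <- sim_line_engine(initial_size, max_generations, floor, rates,
                           indels, rearr)
    crossed[i] <- out$hit_floor
    gens[i] <- if (out$hit_floor) out$floor_generation else max_generations
    fin[i] <- out$final_size
  }
  data.frame(line_id = seq_len(n_lines), crossing_generation = gens,
             crossed = crossed, final_size = fin)
}

#' Replay a logged event sequence
#'
#' Re-applies the events of a recorded line deterministically (no random
#' draws: each logged `size_change` is applied in order, with mid-course
#' flooring at 0 and end-of-generation rewiring to 1) and returns the
#' reconstructed per-generation sizes. Used to verify that a trajectory is
#' exactly reproduced by its event log.
#'
#' @param trajectory a `"line_trajectory"` with `event_log` recorded.
#' @return Numeric vector of sizes, length `generations_run + 1`.
#' @export
replay_events <- function(trajectory) {
  stopifnot(inherits(trajectory, "line_trajectory"),
            !is.null(trajectory$event_log))
  log <- trajectory$event_log
  gens <- trajectory$generations_run
  sizes <- numeric(gens + 1L)
  sizes[1L] <- trajectory$initial_size
  s <- trajectory$initial_size
  idx <- split(seq_len(nrow(log)), factor(log$generation, levels = seq_len(gens)))
  for (g in seq_len(gens)) {
    for (i in idx[[g]]) {
      s <- max(0, s + log$size_change[i])
    }
    if (s < 1) s <- 1
    sizes[g + 1L] <- s
  }
  sizes
}
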