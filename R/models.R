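#' Per-base-pair mutation rates
#'
#' Bundles the four per-bp, per-generation mutation rates of the model:
#' small insertions, small deletions, large (segmental) deletions and
#' segmental duplications. The total rate `mu_total` is their sum; within a
#' generation the number of events of each type is Poisson with mean
#' `mu_type * s0`, where `s0` is the genome size at the start of the
#' generation.
#'
#' The defaults are the rates measured in mutation-accumulation experiments
#' with enterobacteria (a large-deletion rate of 3.778e-9 per bp per
#' generation, an equal duplication rate, and indel rates twice as large),
#' which are the reference conditions used throughout the package.
#'
#' @param mu_ins small-insertion rate, per bp per generation.
#' @param mu_sdel small-deletion rate, per bp per generation.
#' @param mu_ldel large-deletion rate, per bp per generation.
#' @param mu_dup segmental-duplication rate, per bp per generation.
#' @return An object of class `"mutation_rates"`: a list with the four
#'   rates, `mu_total`, and `prob`, the conditional type distribution
#'   `mu_type / mu_total` (all zero rates leave `prob` as `NA`).
#' @examples
#' r <- mutation_rates()
#' r$mu_total
#' @export
mutation_rates <- function(mu_ins = 7.556e-9, mu_sdel = 7.556e-9,
                           mu_ldel = 3.778e-9, mu_dup = 3.778e-9) {
  mus <- c(mu_ins = mu_ins, mu_sdel = mu_sdel, mu_ldel = mu_ldel,
           mu_dup = mu_dup)
  if (any(!is.finite(mus)) || any(mus < 0))
    stop("mutation rates must be finite and >= 0")
  mu_total <- sum(mus)
  structure(list(mu_ins = mu_ins, mu_sdel = mu_sdel, mu_ldel = mu_ldel,
                 mu_dup = mu_dup, mu_total = mu_total,
                 prob = if (mu_total > 0) unname(mus) / mu_total
                        else rep(NA_real_, 4)),
            class = "mutation_rates")
}

#' @export
print.mutation_rates <- function(x, ...) {
  cat("Per-bp mutation rates (per generation):\n")
  cat(sprintf("  small insertions : %.4g\n", x$mu_ins))
  cat(sprintf("  small deletions  : %.4g\n", x$mu_sdel))
  cat(sprintf("  large deletions  : %.4g\n", x$mu_ldel))
  cat(sprintf("  duplications     : %.4g\n", x$mu_dup))
  cat(sprintf("  total            : %.4g\n", x$mu_total))
  invisible(x)
}

# canonical event-type codes used throughout the package
EVENT_TYPES <- c("small_insertion", "small_deletion", "large_deletion",
                 "duplication")

#' Size law of small insertions and deletions
#'
#' Indels add or remove a bounded number of base pairs, drawn from a
#' distribution that does not depend on the current genome size. The default
#' is uniform on 1..40 bp for both insertions and deletions, the law used in
#' the reference mutation-accumulation setup; arbitrary probability vectors
#' over 1..`l_ins` (resp. 1..`l_sdel`) may be supplied instead.
#'
#' @param l_ins maximum insertion size, bp.
#' @param l_sdel maximum small-deletion size, bp.
#' @param p_ins optional probability vector over sizes `1:l_ins`
#'   (default uniform).
#' @param p_sdel optional probability vector over sizes `1:l_sdel`
#'   (default uniform).
#' @return An object of class `"indel_model"`.
#' @export
indel_model <- function(l_ins = 40L, l_sdel = 40L, p_ins = NULL,
                        p_sdel = NULL) {
  l_ins <- as.integer(l_ins); l_sdel <- as.integer(l_sdel)
  if (l_ins < 1L || l_sdel < 1L) stop("indel size bounds must be >= 1")
  norm_p <- function(p, l, what) {
    if (is.null(p)) return(rep(1 / l, l))
    if (length(p) != l || any(p < 0))
      stop(sprintf("%s must be a nonnegative vector of length %d", what, l))
    s <- sum(p)
    if (abs(s - 1) > 1e-12) {
      if (s <= 0) stop(sprintf("%s must have positive mass", what))
      p <- p / s
    }
    p
  }
  structure(list(l_ins = l_ins, l_sdel = l_sdel,
                 p_ins = norm_p(p_ins, l_ins, "p_ins"),
                 p_sdel = norm_p(p_sdel, l_sdel, "p_sdel")),
            class = "indel_model")
}

#' Size law of duplications and large deletions
#'
#' Rearrangement sizes scale with the genome. Three laws are supported:
#'
#' * `"uniform"`: the event size is uniform on `1:s`, where `s` is the
#'   current genome size (equivalently, the two breakpoints are uniform
#'   along the chromosome). This makes gains and losses exactly
#'   multiplicative.
#' * `"truncated_lognormal"`: sizes follow a fixed lognormal law,
#'   redrawn while they exceed the current genome size. The defaults
#'   (`meanlog = 10.1214`, `sdlog = 2.5602`, natural-log scale) come from a
#'   lognormal fit to experimentally verified rearrangements in
#'   *Escherichia coli* and *Salmonella enterica* cultures.
#' * `"empirical_table"`: sizes are drawn from a user-supplied size/weight
#'   table, truncated at the current genome size and renormalized.
#'
#' @param kind one of `"uniform"`, `"truncated_lognormal"`,
#'   `"empirical_table"`.
#' @param meanlog,sdlog lognormal parameters, natural-log scale
#'   (truncated_lognormal only); `sdlog` must be positive.
#' @param table two-column `data.frame` (`size`, `weight`) or named numeric
#'   vector of weights with sizes as names (empirical_table only).
#' @return An object of class `"rearrangement_model"`.
#' @examples
#' rearrangement_model("uniform")
#' rearrangement_model("truncated_lognormal")
#' @export
rearrangement_model <- function(kind = c("uniform", "truncated_lognormal",
                                         "empirical_table"),
                                meanlog = 10.1214, sdlog = 2.5602,
                                table = NULL) {
  kind <- match.arg(kind)
  obj <- list(kind = kind)
  if (kind == "truncated_lognormal") {
    if (!is.finite(meanlog) || !is.finite(sdlog) || sdlog <= 0)
      stop("truncated_lognormal requires finite meanlog and sdlog > 0")
    obj$meanlog <- meanlog
    obj$sdlog <- sdlog
  } else if (kind == "empirical_table") {
    if (is.null(table)) stop("empirical_table requires a size/weight table")
    if (is.data.frame(table)) {
      sz <- table[[1]]; w <- table[[2]]
    } else {
      sz <- as.numeric(names(table)); w <- as.numeric(table)
    }
    if (anyNA(sz) || any(sz < 1) || any(sz != round(sz)))
      stop("table sizes must be positive integers")
    if (any(w < 0) || sum(w) <= 0) stop("table weights must be >= 0, not all 0")
    o <- order(sz)
    obj$size <- as.numeric(sz[o])
    obj$weight <- w[o] / sum(w)
  }
  structure(obj, class = "rearrangement_model")
}

#' @export
print.rearrangement_model <- function(x, ...) {
  cat("Rearrangement size law:", x$kind, "\n")
  if (x$kind == "truncated_lognormal")
    cat(sprintf("  meanlog = %.4f, sdlog = %.4f (natural log scale)\n",
                x$meanlog, x$sdlog))
  if (x$kind == "empirical_table")
    cat(sprintf("  %d support points, sizes %g..%g bp\n",
                length(x$size), min(x$size), max(x$size)))
  invisible(x)
}

#' Draw mutation types conditional on a mutation having occurred
#'
#' Given the four per-bp rates, any single mutation is of type `type` with
#' probability `mu_type / mu_total`, independent of the genome size.
#'
#' @param rates a [mutation_rates] object with `mu_total > 0`.
#' @param n number of draws.
#' @return Character vector of event types (one of `"small_insertion"`,
#'   `"small_deletion"`, `"large_deletion"`, `"duplication"`).
#' @examples
#' set.seed(1)
#' table(sample_event_type(mutation_rates(), 1000))
#' @export
sample_event_type <- function(rates, n = 1L) {
  stopifnot(inherits(rates, "mutation_rates"))
  if (rates$mu_total <= 0)
    stop("all rates are zero: the conditional type distribution is undefined")
  EVENT_TYPES[sample.int(4L, n, replace = TRUE, prob = rates$prob)]
}

#' Draw rearrangement (duplication / large-deletion) sizes
#'
#' For the uniform law the size is an integer uniform on `1:current_size`.
#' For the truncated lognormal, the event size is the lognormal law
#' conditioned on not exceeding the current genome size; draws are
#' integerized by rounding to the nearest bp (clamped to a minimum of 1 bp)
#' before the truncation test, and sampled by inversion of the conditional
#' CDF, which is distributionally identical to redrawing until the size
#' fits. For an empirical table, weights are truncated at `current_size`
#' and renormalized.
#'
#' @param model a [rearrangement_model].
#' @param current_size current genome size in bp, `>= 1`. Callers must
#'   handle the zero-size state before calling (rearrangements leave an
#'   empty genome unchanged).
#' @param n number of draws.
#' @return Numeric vector of event sizes in bp, each in `1:current_size`.
#' @export
sample_rearrangement_size <- function(model, current_size, n = 1L) {
  stopifnot(inherits(model, "rearrangement_model"))
  if (current_size < 1)
    stop("current_size must be >= 1 (the size-0 state has its own rules)")
  switch(model$kind,
    uniform = ceiling(stats::runif(n) * current_size),
    truncated_lognormal = {
      fmax <- stats::plnorm(current_size + 0.5, model$meanlog, model$sdlog)
      if (fmax < 1e-12)
        stop("truncated lognormal: acceptance probability below 1e-12 at ",
             "current_size = ", current_size)
      x <- stats::qlnorm(stats::runif(n, 0, fmax), model$meanlog, model$sdlog)
      pmin(pmax(1, round(x)), current_size)
    },
    empirical_table = {
      keep <- model$size <= current_size
      if (!any(keep))
        stop("empirical table has no mass at or below current_size = ",
             current_size)
      sz <- model$size[keep]
      w <- model$weight[keep]
      sz[sample.int(length(sz), n, replace = TRUE, prob = w)]
    })
}

# single indel size draw; p is the probability vector over 1..l
sample_indel_size <- function(l, p, n = 1L) {
  sample.int(l, n, replace = TRUE, prob = p)
}

# exact conditional pmf of the integerized truncated lognormal over 1..s
# (law of max(1, round(X)) given round(X) <= s, X ~ lognormal)
trunc_lnorm_pmf <- function(s, meanlog, sdlog) {
  s <- as.integer(s)
  hi <- stats::plnorm(seq_len(s) + 0.5, meanlog, sdlog)
  lo <- c(0, hi[-s])
  p <- hi - lo
  tot <- hi[s]
  if (tot < 1e-300) stop("no lognormal mass at or below ", s)
  p / tot
}
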