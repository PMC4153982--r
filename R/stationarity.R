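# Drift analysis of the size chain and finite-window kernel numerics.
#
# The convergence condition for the generational chain is expressed through
# per-type asymptotic drifts: the expected change of f(size) caused by one
# mutation of each type, in the limit of large genomes, for a positive
# increasing scaling function f. For uniform rearrangements the natural
# scale is f = log (drifts -1 for deletions, 2 log 2 - 1 for duplications,
# 0 for indels); for the truncated lognormal the natural scale is the
# identity (drifts +/- the complete-lognormal mean, +/- the mean indel
# size). The chain converges to a unique stationary distribution when
# sum(mu_type * delta_type) < 0.

resolve_scaling <- function(f) {
  if (is.character(f)) {
    f <- match.arg(f, c("log", "identity"))
    return(list(name = f, fn = if (f == "log") log else identity))
  }
  if (is.function(f)) return(list(name = "custom", fn = f))
  stop("f must be \"log\", \"identity\", or a function")
}

# E[f(S')] for one uniform-law rearrangement at size s, exact.
# log: deletions use sum_{j=0}^{s-1} log j with log 0 := 0, i.e. lgamma(s);
# duplications use sum_{j=s+1}^{2s} log j = lgamma(2s+1) - lgamma(s+1).
unif_rearr_Ef <- function(s, type, scal) {
  if (scal$name == "log") {
    if (type == "large_deletion") return(lgamma(s) / s)
    return((lgamma(2 * s + 1) - lgamma(s + 1)) / s)
  }
  if (scal$name == "identity") {
    if (type == "large_deletion") return((s - 1) / 2)
    return(s + (s + 1) / 2)
  }
  if (s > 1e7)
    stop("custom scaling with uniform rearrangements: exact sum limited to ",
         "s <= 1e7")
  j <- if (type == "large_deletion") 0:(s - 1) else (s + 1):(2 * s)
  v <- scal$fn(j)
  v[j == 0] <- 0
  mean(v)
}

#' Expected one-mutation change of a scaled genome size
#'
#' Computes `E[f(S') - f(s)]` exactly for a single mutation of the given
#' type starting from size `s`, where `S'` is the size after the mutation.
#' For `f = log`, the convention `log 0 = 0` is used for the transition to
#' the empty genome. Uniform-rearrangement sums are evaluated in closed
#' form via the log-gamma function, so sizes up to 1e9 and beyond are
#' exact; truncated-lognormal deletions/duplications under the identity
#' scale use the closed-form conditional mean of the lognormal law.
#'
#' @param s starting size, bp, `>= 1` (the size-0 boundary state has its
#'   own transition rules and no defined drift).
#' @param event_type one of `"small_insertion"`, `"small_deletion"`,
#'   `"large_deletion"`, `"duplication"`.
#' @param indels an [indel_model].
#' @param rearr a [rearrangement_model].
#' @param f scaling function: `"log"` (default), `"identity"`, or a
#'   positive increasing function (exact summation, sizes up to 1e7).
#' @param n_mc Monte-Carlo sample size used only where no exact path
#'   exists (lognormal rearrangements under a non-identity scale).
#' @return The drift value, in units of `f`.
#' @examples
#' expected_scaled_jump(2, "large_deletion", indel_model(),
#'                      rearrangement_model("uniform"))   # -log(2)
#' @export
expected_scaled_jump <- function(s, event_type, indels, rearr, f = "log",
                                 n_mc = 200000L) {
  stopifnot(s >= 1)
  event_type <- match.arg(event_type, EVENT_TYPES)
  scal <- resolve_scaling(f)
  f0 <- if (scal$name == "log") log(s) else scal$fn(s)

  if (event_type == "small_insertion") {
    v <- scal$fn(s + seq_len(indels$l_ins))
    return(sum(indels$p_ins * v) - f0)
  }
  if (event_type == "small_deletion") {
    j <- pmax(0, s - seq_len(indels$l_sdel))
    v <- scal$fn(j)
    v[j == 0] <- 0
    return(sum(indels$p_sdel * v) - f0)
  }

  # rearrangements
  if (rearr$kind == "uniform")
    return(unif_rearr_Ef(s, event_type, scal) - f0)
  if (rearr$kind == "empirical_table") {
    keep <- rearr$size <= s
    if (!any(keep)) stop("empirical table has no mass at or below s")
    d <- rearr$size[keep]
    w <- rearr$weight[keep] / sum(rearr$weight[keep])
    j <- if (event_type == "large_deletion") s - d else s + d
    v <- scal$fn(j)
    v[j == 0] <- 0
    return(sum(w * v) - f0)
  }
  # truncated lognormal
  if (scal$name == "identity") {
    m <- truncated_lognormal_mean(s, rearr$meanlog, rearr$sdlog)
    return(if (event_type == "large_deletion") -m else m)
  }
  if (s <= 1e6) {                      # exact sum over the integer law
    p <- trunc_lnorm_pmf(s, rearr$meanlog, rearr$sdlog)
    d <- seq_len(s)
    j <- if (event_type == "large_deletion") s - d else s + d
    v <- scal$fn(j)
    v[j == 0] <- 0
    return(sum(p * v) - f0)
  }
  d <- sample_rearrangement_size(rearr, s, n_mc)
  j <- if (event_type == "large_deletion") s - d else s + d
  v <- scal$fn(j)
  v[j == 0] <- 0
  mean(v) - f0
}

#' Closed-form asymptotic drifts, where known
#'
#' Large-size limits of [expected_scaled_jump()]: for uniform
#' rearrangements under the log scale, `(-1, 2 log 2 - 1)` for deletions
#' and duplications and 0 for indels; for truncated-lognormal
#' rearrangements under the identity scale, minus/plus the
#' complete-lognormal mean `exp(meanlog + sdlog^2/2)` and minus/plus the
#' mean indel size.
#'
#' @inheritParams expected_scaled_jump
#' @return Named vector of drifts
#'   (`small_insertion`, `small_deletion`, `large_deletion`,
#'   `duplication`), in units of `f`.
#' @export
asymptotic_deltas <- function(indels, rearr, f = "log") {
  scal <- resolve_scaling(f)
  if (rearr$kind == "uniform" && scal$name == "log")
    return(stats::setNames(c(0, 0, -1, 2 * log(2) - 1), EVENT_TYPES))
  if (scal$name == "identity") {
    mean_ins <- sum(indels$p_ins * seq_len(indels$l_ins))
    mean_sdel <- sum(indels$p_sdel * seq_len(indels$l_sdel))
    m <- switch(rearr$kind,
      truncated_lognormal = exp(rearr$meanlog + rearr$sdlog^2 / 2),
      empirical_table = sum(rearr$weight * rearr$size),
      uniform = stop("uniform rearrangements have no finite drift under ",
                     "the identity scale; use f = \"log\""))
    return(stats::setNames(c(mean_ins, -mean_sdel, -m, m), EVENT_TYPES))
  }
  if (scal$name == "log" &&
      rearr$kind %in% c("truncated_lognormal", "empirical_table"))
    return(stats::setNames(c(0, 0, 0, 0), EVENT_TYPES))  # bounded jumps
  stop("no closed-form asymptotic drift for this model/scaling; use ",
       "estimate_asymptotic_deltas()")
}

#' Estimate asymptotic per-type drifts on a size grid
#'
#' Evaluates [expected_scaled_jump()] for each mutation type along an
#' increasing grid of sizes and checks for a plateau: the type's drift has
#' converged when the change between the two largest grid sizes is within
#' `rel_tol` relatively (or `abs_tol` absolutely, which matters for drifts
#' converging to 0). Non-converged types are flagged and make downstream
#' condition checks refuse to conclude.
#'
#' @inheritParams expected_scaled_jump
#' @param size_grid increasing vector of sizes; the default spans 1e3 to
#'   1e12 (heavy-tailed laws like the reference lognormal need sizes far
#'   beyond the genomic range before their conditional mean plateaus).
#' @param rel_tol,abs_tol plateau tolerances.
#' @return An object of class `"drift_estimate"`: `deltas` (named vector,
#'   taken at the largest grid size), `converged` (named logical),
#'   `values` (grid x type matrix), `scaling_name`, `size_grid`.
#' @examples
#' estimate_asymptotic_deltas(indel_model(),
#'                            rearrangement_model("uniform"))$deltas
#' @export
estimate_asymptotic_deltas <- function(indels, rearr, f = "log",
                                       size_grid = 10^(3:12),
                                       rel_tol = 1e-3, abs_tol = 1e-6) {
  stopifnot(length(size_grid) >= 2, !is.unsorted(size_grid),
            all(size_grid >= 1))
  scal <- resolve_scaling(f)
  vals <- sapply(EVENT_TYPES, function(ty)
    vapply(size_grid, function(s)
      expected_scaled_jump(s, ty, indels, rearr, f = f), numeric(1)))
  n <- length(size_grid)
  last <- vals[n, ]
  prev <- vals[n - 1, ]
  converged <- abs(last - prev) <= pmax(rel_tol * abs(last), abs_tol)
  structure(list(deltas = last, converged = converged, values = vals,
                 scaling_name = scal$name, size_grid = size_grid),
            class = "drift_estimate")
}

#' @export
print.drift_estimate <- function(x, ...) {
  cat(sprintf("Asymptotic per-type drifts (scale: %s):\n", x$scaling_name))
  for (ty in EVENT_TYPES)
    cat(sprintf("  %-16s %.6g%s\n", ty, x$deltas[[ty]],
                if (x$converged[[ty]]) "" else "  [not converged]"))
  invisible(x)
}

#' Check the stationary-distribution condition
#'
#' The generational size chain has a unique asymptotic stationary
#' distribution when the rate-weighted sum of the per-type asymptotic
#' drifts is negative:
#' `mu_ldel d_ldel + mu_dup d_dup + mu_ins d_ins + mu_sdel d_sdel < 0`.
#' For uniform rearrangements under the log scale this reduces to
#' `(2 log 2 - 1) mu_dup < mu_ldel`. A net drift of zero (as for the
#' truncated lognormal under the identity scale with symmetric rates)
#' gives no verdict, and drifts that have not plateaued make the check
#' refuse to conclude.
#'
#' @param rates a [mutation_rates] object.
#' @param deltas a `"drift_estimate"` (from
#'   [estimate_asymptotic_deltas()]) or a named drift vector such as
#'   [asymptotic_deltas()] returns.
#' @param zero_tol relative tolerance below which the net drift is treated
#'   as zero (scaled by `sum(mu * |delta|)`).
#' @return A list: `net_drift` (in units of `f` per bp per generation) and
#'   `verdict`, one of `"converges"`, `"not_guaranteed"`,
#'   `"inconclusive"`.
#' @examples
#' stationarity_condition(mutation_rates(),
#'   asymptotic_deltas(indel_model(), rearrangement_model("uniform")))
#' @export
stationarity_condition <- function(rates, deltas, zero_tol = 1e-9) {
  stopifnot(inherits(rates, "mutation_rates"))
  if (inherits(deltas, "drift_estimate")) {
    conv <- all(deltas$converged)
    d <- deltas$deltas
  } else {
    conv <- TRUE
    d <- deltas
  }
  d <- d[EVENT_TYPES]
  if (anyNA(d)) stop("deltas must be named with the four event types")
  mus <- c(rates$mu_ins, rates$mu_sdel, rates$mu_ldel, rates$mu_dup)
  net <- sum(mus * d)
  scale <- sum(mus * abs(d))
  verdict <- if (!conv) "inconclusive"
    else if (scale == 0 || abs(net) <= zero_tol * scale) "inconclusive"
    else if (net < 0) "converges"
    else "not_guaranteed"
  list(net_drift = net, verdict = verdict)
}

#' Finite-window one-mutation transition matrix
#'
#' Builds the transition kernel of a single mutation on the states
#' `0:s_max` as a sparse row-stochastic matrix: each row mixes the four
#' type-conditional kernels with weights `mu_type / mu_total`. Mass that
#' would land above `s_max` is recorded per row as `leaked`, never
#' redistributed. Row 0 encodes the boundary rules: only small insertions
#' leave the empty state.
#'
#' @param s_max window upper bound (states `0:s_max`), `>= 2`.
#' @param rates a [mutation_rates] with `mu_total > 0`.
#' @param indels an [indel_model].
#' @param rearr a [rearrangement_model].
#' @return An object of class `"truncated_chain"`: `P` (sparse
#'   `(s_max+1) x (s_max+1)` matrix, rows/cols labelled by size), `states`,
#'   `leaked` (per-row probability beyond the window), `kind = "m1"`.
#' @export
build_m1 <- function(s_max, rates, indels, rearr) {
  stopifnot(s_max >= 2)
  if (rates$mu_total <= 0) stop("mu_total must be > 0")
  s_max <- as.integer(s_max)
  w <- rates$prob                      # ins, sdel, ldel, dup
  ii <- jj <- xx <- vector("list", s_max + 1L)

  # row 0: small insertions escape; all other types stay
  d_ins <- seq_len(indels$l_ins)
  keep <- d_ins <= s_max
  ii[[1]] <- c(rep.int(0L, sum(keep)), 0L)
  jj[[1]] <- c(d_ins[keep], 0L)
  xx[[1]] <- c(w[1] * indels$p_ins[keep], w[2] + w[3] + w[4])

  d_sdel <- seq_len(indels$l_sdel)
  for (i in seq_len(s_max)) {
    # insertions
    j_ins <- i + d_ins
    k_ins <- j_ins <= s_max
    # small deletions (floored at 0)
    j_sdel <- pmax(0L, i - d_sdel)
    # rearrangement size law at size i
    if (rearr$kind == "uniform") {
      d_r <- seq_len(i)
      p_r <- rep.int(1 / i, i)
    } else if (rearr$kind == "truncated_lognormal") {
      d_r <- seq_len(i)
      p_r <- trunc_lnorm_pmf(i, rearr$meanlog, rearr$sdlog)
    } else {
      keep_t <- rearr$size <= i
      if (!any(keep_t))
        stop("empirical table has no mass at or below ", i,
             "; enlarge the table or the window")
      d_r <- as.integer(rearr$size[keep_t])
      p_r <- rearr$weight[keep_t] / sum(rearr$weight[keep_t])
    }
    j_dup <- i + d_r
    k_dup <- j_dup <= s_max
    ii[[i + 1L]] <- rep.int(i, sum(k_ins) + length(d_sdel) + length(d_r) +
                              sum(k_dup))
    jj[[i + 1L]] <- c(j_ins[k_ins], j_sdel, i - d_r, j_dup[k_dup])
    xx[[i + 1L]] <- c(w[1] * indels$p_ins[k_ins], w[2] * indels$p_sdel,
                      w[3] * p_r, w[4] * p_r[k_dup])
  }
  P <- Matrix::sparseMatrix(i = unlist(ii) + 1L, j = unlist(jj) + 1L,
                            x = unlist(xx),
                            dims = c(s_max + 1L, s_max + 1L),
                            dimnames = list(0:s_max, 0:s_max))
  leaked <- 1 - Matrix::rowSums(P)
  leaked[leaked < 0] <- 0              # guard rounding
  structure(list(P = P, states = 0:s_max, leaked = unname(leaked),
                 kind = "m1", rates = rates),
            class = "truncated_chain")
}

#' Finite-window one-generation transition matrix
#'
#' Builds the generational kernel on `1:s_max` by mixing powers of the
#' one-mutation kernel with Poisson weights: row `i` is
#' `sum_n Pois(n; mu_total * i) * (row i of M1^n)`, summed up to the
#' `1 - tail` Poisson quantile, with the end-of-generation state-0 mass
#' rewired to state 1. Powers are applied row-wise (vector times sparse
#' matrix), never materializing `M1^n`. Each row's `leaked` collects the
#' window leak plus the truncated Poisson tail.
#'
#' @inheritParams build_m1
#' @param tail Poisson tail mass cut per row.
#' @param m1 optionally, a precomputed `build_m1(s_max, ...)` chain.
#' @return An object of class `"truncated_chain"` with dense `P`
#'   (`s_max x s_max`, rows/cols labelled `1:s_max`), `leaked`,
#'   `kind = "mg"`.
#' @export
build_mg <- function(s_max, rates, indels, rearr, tail = 1e-12, m1 = NULL) {
  s_max <- as.integer(s_max)
  if (is.null(m1)) m1 <- build_m1(s_max, rates, indels, rearr)
  stopifnot(inherits(m1, "truncated_chain"), m1$kind == "m1",
            nrow(m1$P) == s_max + 1L)
  P1 <- m1$P
  mu <- rates$mu_total
  P <- matrix(0, s_max, s_max, dimnames = list(1:s_max, 1:s_max))
  leaked <- numeric(s_max)
  for (i in seq_len(s_max)) {
    lam <- mu * i
    nmax <- stats::qpois(tail, lam, lower.tail = FALSE)
    wts <- stats::dpois(0:nmax, lam)
    v <- numeric(s_max + 1L)
    v[i + 1L] <- 1
    acc <- wts[1L] * v
    for (n in seq_len(nmax)) {
      v <- as.numeric(v %*% P1)
      acc <- acc + wts[n + 1L] * v
    }
    acc[2L] <- acc[2L] + acc[1L]       # rewire final size 0 to 1
    P[i, ] <- acc[-1L]
    leaked[i] <- max(0, 1 - sum(acc[-1L]))
  }
  structure(list(P = P, states = 1:s_max, leaked = leaked, kind = "mg",
                 rates = rates),
            class = "truncated_chain")
}

#' @export
print.truncated_chain <- function(x, ...) {
  cat(sprintf("Truncated %s chain on %d states (%d..%d)\n",
              if (x$kind == "m1") "one-mutation" else "one-generation",
              length(x$states), min(x$states), max(x$states)))
  cat(sprintf("  max row leak: %.3g, mean row leak: %.3g\n",
              max(x$leaked), mean(x$leaked)))
  invisible(x)
}

#' Stationary distribution of a truncated chain
#'
#' Renormalizes the rows over the window (requiring the per-row leak to be
#' below `leak_tol`) and power-iterates `pi <- pi P` until the total
#' variation distance between successive iterates falls below `tol`. The
#' geometric decay of the returned TV trajectory is the finite-window echo
#' of the Doeblin-type convergence bound of the full chain.
#'
#' @param chain a `"truncated_chain"` (typically from [build_mg()]).
#' @param tol convergence threshold on the successive-iterate TV distance.
#' @param max_iter iteration cap; non-convergence is an error.
#' @param leak_tol maximum admissible *stationary-weighted* leak
#'   `sum(pi_i * leaked_i)`. Rows near the window top always leak under
#'   truncation, but in shrink-biased regimes (the only regimes with a
#'   stationary law) they carry exponentially little stationary mass; a
#'   large weighted leak signals a window too narrow for the regime.
#' @param start optional starting distribution over the window states
#'   (default uniform).
#' @return A list: `pi` (named stationary probabilities), `n_iter`,
#'   `tv_trace` (TV distance per iteration), `residual`
#'   (`||pi P - pi||_TV`), `weighted_leak`.
#' @export
stationary_distribution <- function(chain, tol = 1e-10, max_iter = 50000L,
                                    leak_tol = 0.01, start = NULL) {
  stopifnot(inherits(chain, "truncated_chain"))
  P <- chain$P
  rs <- if (inherits(P, "sparseMatrix")) Matrix::rowSums(P) else rowSums(P)
  P <- P / rs                           # renormalize over the window
  n <- nrow(P)
  x <- if (is.null(start)) rep(1 / n, n) else {
    stopifnot(length(start) == n, all(start >= 0), sum(start) > 0)
    start / sum(start)
  }
  tv_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    x_new <- as.numeric(x %*% P)
    x_new <- x_new / sum(x_new)
    tv <- 0.5 * sum(abs(x_new - x))
    tv_trace[it] <- tv
    x <- x_new
    if (tv < tol) {
      res <- 0.5 * sum(abs(as.numeric(x %*% P) - x))
      wleak <- sum(x * chain$leaked)
      if (wleak > leak_tol)
        stop(sprintf("stationary-weighted leak %.3g exceeds leak_tol = %g; enlarge the window",
                     wleak, leak_tol))
      return(list(pi = stats::setNames(x, chain$states), n_iter = it,
                  tv_trace = tv_trace, residual = res,
                  weighted_leak = wleak))
    }
  }
  stop(sprintf("power iteration did not reach tol = %g in %d iterations (last TV = %.3g)",
               tol, max_iter, tv_trace[max_iter]))
}
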