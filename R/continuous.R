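# Continuous duplication/deletion approximation.
#
# For large genomes, indels are negligible and the duplication/deletion
# process is multiplicative: each mutation multiplies the (real-valued)
# size by a factor uniform on [0,1] (deletion) or [1,2] (duplication), so
# the log size performs a random walk with i.i.d. jumps J. One generation
# mixes n-mutation walks with Poisson(n; (mu_ldel + mu_dup) * s0) weights.

#' Moments of the log-scale jump of a single rearrangement
#'
#' The multiplier of a deletion is uniform on \[0,1\] and of a duplication
#' uniform on \[1,2\]; conditioning on the event type having rates
#' `mu_ldel`, `mu_dup` gives the per-mutation log jump `J` with
#' `E[J] = -mu_ldel/(mu_ldel+mu_dup) + (2 log 2 - 1) mu_dup/(mu_ldel+mu_dup)`
#' and
#' `E[J^2] = 2 (mu_ldel + (1 - log 2)^2 mu_dup) / (mu_ldel + mu_dup)`.
#'
#' @param mu_ldel,mu_dup per-bp rates of large deletions and duplications;
#'   their sum must be positive.
#' @return A list of class `"jump_moments"`: `mean_J`, `second_moment_J`,
#'   `sd_J` (all dimensionless, natural-log scale).
#' @examples
#' jump_moments(1e-9, 0)$mean_J       # pure deletion: -1
#' jump_moments(0, 1e-9)$mean_J       # pure duplication: 2*log(2) - 1
#' @export
jump_moments <- function(mu_ldel, mu_dup) {
  stopifnot(mu_ldel >= 0, mu_dup >= 0)
  tot <- mu_ldel + mu_dup
  if (tot <= 0) stop("mu_ldel + mu_dup must be > 0")
  m1 <- (-mu_ldel + (2 * log(2) - 1) * mu_dup) / tot
  m2 <- 2 * (mu_ldel + (1 - log(2))^2 * mu_dup) / tot
  structure(list(mean_J = m1, second_moment_J = m2,
                 sd_J = sqrt(m2 - m1^2)),
            class = "jump_moments")
}

# drift and dispersion coefficients of the one-generation log size
drift_A <- function(mu_ldel, mu_dup) mu_ldel - (2 * log(2) - 1) * mu_dup
disp_B <- function(mu_ldel, mu_dup)
  sqrt(2 * (log(2) - 1)^2 * mu_dup + 2 * mu_ldel)

#' Mean and standard deviation of log genome size after one generation
#'
#' Under the continuous duplication/deletion approximation, mixing the
#' n-mutation log walks with Poisson(n; (mu_ldel+mu_dup) s0) weights gives
#' `E[log S_f] = log s0 - A s0` and `sd[log S_f] = B sqrt(s0)`, with
#' `A = mu_ldel - (2 log 2 - 1) mu_dup` and
#' `B = sqrt(2 (log 2 - 1)^2 mu_dup + 2 mu_ldel)`.
#'
#' @param s0 starting size(s), bp, `> 0` (vectorized).
#' @inheritParams jump_moments
#' @return A list with vectors `mean` and `sd` (natural-log scale), plus
#'   the coefficients `A` and `B`.
#' @export
generation_log_moments <- function(s0, mu_ldel, mu_dup) {
  stopifnot(all(s0 > 0), mu_ldel >= 0, mu_dup >= 0)
  A <- drift_A(mu_ldel, mu_dup)
  B <- disp_B(mu_ldel, mu_dup)
  list(mean = log(s0) - A * s0, sd = B * sqrt(s0), A = A, B = B)
}

#' One-generation quantile-bound curve Q_k
#'
#' `Q_k(s0) = exp(log s0 - A s0 + k B sqrt(s0))` is the exponential of the
#' mean of log size after one generation plus `k` standard deviations; by
#' Cantelli's inequality at least `1 - 1/(1+k^2)` of the offspring of a
#' genome of size `s0` lie at or below `Q_k(s0)`.
#'
#' @param s0 starting size(s), bp, `> 0` (vectorized).
#' @param k bound order, `>= 1`.
#' @inheritParams jump_moments
#' @return Numeric vector of bounds, bp.
#' @export
q_curve <- function(s0, k, mu_ldel, mu_dup) {
  stopifnot(all(s0 > 0), k >= 1)
  A <- drift_A(mu_ldel, mu_dup)
  B <- disp_B(mu_ldel, mu_dup)
  exp(log(s0) - A * s0 + k * B * sqrt(s0))
}

#' Closed-form quantile bounds of the continuous approximation
#'
#' When the shrinkage condition `(2 log 2 - 1) mu_dup < mu_ldel` holds
#' (`A > 0`), the bound curve [q_curve()] has a maximum at
#' `s0_max = 1/A + k^2 B^2 / (8 A^2) (1 + sqrt(1 + 16 A / (k^2 B^2)))`
#' (the root of `A u^2 - (k B / 2) u - 1 = 0` in `u = sqrt(s0)`) and a
#' unique fixed point `s_fixed = k^2 B^2 / A^2 >= s0_max`. `s_max_tilde =
#' Q_k(s0_max)` bounds the `1 - 1/(1+k^2)` quantile of the size after one
#' generation for *any* starting size, and sizes above `s_fixed` shrink
#' below `s_fixed` with at least that probability in one generation.
#'
#' @param k bound order, `>= 1`.
#' @inheritParams jump_moments
#' @return An object of class `"continuous_bounds"`: `A`, `B`, `k`,
#'   `s0_max`, `s_fixed`, `s_max_tilde`, `cantelli_prob`, and `q_at`, the
#'   bound curve as a function of `s0`.
#' @examples
#' b <- continuous_bounds(1, 1e-6, 1e-6)
#' b$s_fixed        # about 5.81 / mu
#' @export
continuous_bounds <- function(k, mu_ldel, mu_dup) {
  stopifnot(k >= 1, mu_ldel >= 0, mu_dup >= 0)
  A <- drift_A(mu_ldel, mu_dup)
  B <- disp_B(mu_ldel, mu_dup)
  if (A <= 0)
    stop("bounds require (2 log 2 - 1) * mu_dup < mu_ldel (A > 0); ",
         "with A <= 0 the bound curve grows without maximum")
  s0_max <- 1 / A + k^2 * B^2 / (8 * A^2) *
    (1 + sqrt(1 + 16 * A / (k^2 * B^2)))
  s_fixed <- k^2 * B^2 / A^2
  q_at <- function(s0) q_curve(s0, k, mu_ldel, mu_dup)
  structure(list(A = A, B = B, k = k,
                 s0_max = s0_max, s_fixed = s_fixed,
                 s_max_tilde = q_at(s0_max),
                 cantelli_prob = cantelli_quantile_bound(k),
                 q_at = q_at),
            class = "continuous_bounds")
}

#' @export
print.continuous_bounds <- function(x, ...) {
  cat(sprintf("Continuous-approximation bounds (k = %g):\n", x$k))
  cat(sprintf("  A = %.6g per bp, B = %.6g per sqrt(bp)\n", x$A, x$B))
  cat(sprintf("  s0_max  = %.6g bp (maximizer of Q_k)\n", x$s0_max))
  cat(sprintf("  s_fixed = %.6g bp (fixed point of Q_k)\n", x$s_fixed))
  cat(sprintf("  s_max~  = %.6g bp; at least %.3f of offspring below it\n",
              x$s_max_tilde, x$cantelli_prob))
  invisible(x)
}

#' Guaranteed quantile mass of the k-th order bound
#'
#' By Cantelli's (one-sided Chebyshev) inequality, the probability that the
#' post-generation size lies at or below the k-th order bound is at least
#' `1 - 1/(1 + k^2)`: 0.5 for `k = 1`, 0.8 for `k = 2`.
#'
#' @param k bound order, `>= 1`.
#' @return Probability `1 - 1/(1 + k^2)`.
#' @export
cantelli_quantile_bound <- function(k) {
  if (any(k < 1)) stop("k must be >= 1")
  1 - 1 / (1 + k^2)
}

#' Simulate the continuous duplication/deletion generation process
#'
#' Monte-Carlo draws of the final size of one generation of the continuous
#' approximation: the number of deletions and duplications are Poisson with
#' means `mu_ldel * s0` and `mu_dup * s0`, and each event multiplies the
#' size by a factor uniform on \[0,1\] (deletion) or \[1,2\] (duplication).
#' Serves as the internal stochastic oracle for the closed-form moments and
#' the Cantelli bound checks.
#'
#' @param s0 starting size, bp, `> 0`.
#' @inheritParams jump_moments
#' @param n number of replicate generations.
#' @return Numeric vector of `n` final sizes (positive reals).
#' @export
sim_continuous_generation <- function(s0, mu_ldel, mu_dup, n = 10000L) {
  stopifnot(s0 > 0, n >= 1)
  n_del <- stats::rpois(n, mu_ldel * s0)
  n_dup <- stats::rpois(n, mu_dup * s0)
  log_s <- rep(log(s0), n)
  tot_del <- sum(n_del)
  if (tot_del > 0) {
    jumps <- log(stats::runif(tot_del))
    log_s <- log_s + rowsum_by_count(jumps, n_del, n)
  }
  tot_dup <- sum(n_dup)
  if (tot_dup > 0) {
    jumps <- log(1 + stats::runif(tot_dup))
    log_s <- log_s + rowsum_by_count(jumps, n_dup, n)
  }
  exp(log_s)
}

# sum `values` in groups whose sizes are given by `counts` (length n)
rowsum_by_count <- function(values, counts, n) {
  idx <- rep.int(seq_len(n), counts)
  out <- numeric(n)
  agg <- rowsum(values, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Simulate the continuous multiplicative walk after n mutations
#'
#' Draws `n_rep` realizations of the size after exactly `n_mut`
#' rearrangements (each a deletion with probability
#' `mu_ldel/(mu_ldel+mu_dup)`, else a duplication) in the continuous
#' approximation. Oracle for the n-mutation moment identities.
#'
#' @param s0 starting size, `> 0`.
#' @param n_mut number of mutations.
#' @inheritParams jump_moments
#' @param n_rep number of replicates.
#' @return Numeric vector of `n_rep` sizes.
#' @export
sim_continuous_walk <- function(s0, n_mut, mu_ldel, mu_dup, n_rep = 10000L) {
  stopifnot(s0 > 0, n_mut >= 0)
  tot <- mu_ldel + mu_dup
  if (tot <= 0) stop("mu_ldel + mu_dup must be > 0")
  if (n_mut == 0) return(rep(s0, n_rep))
  is_del <- stats::runif(n_rep * n_mut) < mu_ldel / tot
  lam <- ifelse(is_del, stats::runif(n_rep * n_mut),
                1 + stats::runif(n_rep * n_mut))
  exp(log(s0) + colSums(matrix(log(lam), n_mut, n_rep)))
}
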