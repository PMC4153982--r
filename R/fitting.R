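#' Fit a lognormal law to observed rearrangement sizes
#'
#' Maximum-likelihood lognormal fit: `meanlog` is the mean of the natural
#' logs of the sizes and `sdlog` the population (divisor `n`) standard
#' deviation of the logs. Base-10 equivalents are reported alongside
#' (divide by `log(10)`). The empirical CDF of the input is returned for
#' plotting against the fitted distribution function.
#'
#' @param sizes positive event sizes in bp, at least 3.
#' @return An object of class `"lognormal_fit"`: `meanlog`, `sdlog`,
#'   `n_obs`, `log10_meanlog`, `log10_sdlog`, `ecdf`.
#' @examples
#' set.seed(1)
#' fit_lognormal(round(rlnorm(200, 10.1214, 2.5602)) + 1)
#' @export
fit_lognormal <- function(sizes) {
  sizes <- as.numeric(sizes)
  if (length(sizes) < 3) stop("need at least 3 observations")
  if (anyNA(sizes) || any(sizes < 1))
    stop("all sizes must be >= 1 bp (nonpositive sizes have no log)")
  lx <- log(sizes)
  meanlog <- mean(lx)
  sdlog <- sqrt(mean((lx - meanlog)^2))
  if (sdlog <= 0)
    stop("degenerate sample: all sizes identical, sdlog would be 0")
  structure(list(meanlog = meanlog, sdlog = sdlog, n_obs = length(sizes),
                 log10_meanlog = meanlog / log(10),
                 log10_sdlog = sdlog / log(10),
                 ecdf = stats::ecdf(sizes)),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("Lognormal fit to %d event sizes:\n", x$n_obs))
  cat(sprintf("  meanlog = %.4f (natural log)  = %.4f (log10)\n",
              x$meanlog, x$log10_meanlog))
  cat(sprintf("  sdlog   = %.4f (natural log)  = %.4f (log10)\n",
              x$sdlog, x$log10_sdlog))
  invisible(x)
}

#' Mean of a lognormal law truncated from above
#'
#' `E[X | X <= s]` for `X ~ lognormal(meanlog, sdlog)`, in closed form:
#' `exp(meanlog + sdlog^2/2) * Phi((log s - meanlog - sdlog^2)/sdlog) /
#' Phi((log s - meanlog)/sdlog)`. As `s` grows this converges to the
#' complete-lognormal mean `exp(meanlog + sdlog^2/2)`.
#'
#' @param s truncation point(s), bp (vectorized).
#' @param meanlog,sdlog lognormal parameters, natural-log scale.
#' @return Numeric vector of conditional means.
#' @export
truncated_lognormal_mean <- function(s, meanlog, sdlog) {
  stopifnot(all(s > 0), sdlog > 0)
  denom <- stats::plnorm(s, meanlog, sdlog)
  if (any(denom < 1e-12))
    stop("no lognormal mass at or below the smallest truncation point")
  z <- (log(s) - meanlog) / sdlog
  exp(meanlog + sdlog^2 / 2) * stats::pnorm(z - sdlog) / denom
}

#' Expected rearrangement size as a function of genome size
#'
#' Tabulates the mean event size induced by truncating a fixed size law at
#' the current genome size: the truncated-lognormal conditional mean (for
#' the given fit) and, for comparison, the uniform-law mean `(s + 1) / 2`.
#' The lognormal curve flattens at the complete-lognormal mean for large
#' genomes, while the uniform mean keeps growing linearly -- the contrast
#' that drives the difference between the two accumulation regimes.
#'
#' @param fit a `"lognormal_fit"`, or any list with `meanlog` and `sdlog`
#'   elements (e.g. a `rearrangement_model("truncated_lognormal")`).
#' @param sizes_grid positive genome sizes, bp.
#' @return A `data.frame` with columns `genome_size`,
#'   `expected_event_size_lognormal`, `expected_event_size_uniform`.
#' @examples
#' truncated_mean_curve(rearrangement_model("truncated_lognormal"),
#'                      c(1e4, 1e6, 4e6, 1e9))
#' @export
truncated_mean_curve <- function(fit, sizes_grid) {
  stopifnot(all(sizes_grid > 0))
  if (is.null(fit$meanlog) || is.null(fit$sdlog))
    stop("fit must carry meanlog and sdlog")
  data.frame(
    genome_size = sizes_grid,
    expected_event_size_lognormal =
      truncated_lognormal_mean(sizes_grid, fit$meanlog, fit$sdlog),
    expected_event_size_uniform = (sizes_grid + 1) / 2)
}

#' Generate a synthetic rearrangement-size dataset
#'
#' Draws `n` integer event sizes from a lognormal law (rounded to the
#' nearest bp, clamped to a minimum of 1) as a synthetic stand-in for an
#' observed rearrangement-size dataset, and optionally writes them to the
#' plain-text format [read_rearrangement_sizes()] and [fit_lognormal()]
#' consume: one size per line, `#` comments allowed.
#'
#' @param n number of events, `>= 1`.
#' @param meanlog,sdlog lognormal parameters, natural-log scale.
#' @param seed optional integer seed for reproducible fixtures.
#' @param path optional output file path.
#' @return Integer-valued numeric vector of sizes (invisibly if written).
#' @examples
#' sizes <- make_fixture_rearrangements(127, seed = 1)
#' fit_lognormal(sizes)
#' @export
make_fixture_rearrangements <- function(n, meanlog = 10.1214,
                                        sdlog = 2.5602, seed = NULL,
                                        path = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  sizes <- pmax(1, round(stats::rlnorm(n, meanlog, sdlog)))
  if (!is.null(path)) {
    header <- c("# synthetic rearrangement sizes (bp), lognormal draws",
                sprintf("# meanlog = %.6f, sdlog = %.6f, n = %d%s",
                        meanlog, sdlog, n,
                        if (is.null(seed)) "" else sprintf(", seed = %d", seed)))
    writeLines(c(header, format(sizes, scientific = FALSE, trim = TRUE)),
               path)
    return(invisible(sizes))
  }
  sizes
}

#' Read rearrangement sizes from a plain-text file
#'
#' One positive integer size (bp) per line; blank lines and lines starting
#' with `#` are ignored.
#'
#' @param path file path.
#' @return Numeric vector of sizes.
#' @export
read_rearrangement_sizes <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sizes <- suppressWarnings(as.numeric(lines))
  if (anyNA(sizes) || any(sizes < 1) || any(sizes != round(sizes)))
    stop("file must contain one positive integer size per line")
  sizes
}
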