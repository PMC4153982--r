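test_that("one-mutation log drifts match hand-computed and asymptotic values", {
  im <- ref_indels(); ru <- unif_rearr()
  # s = 1: the only deletion target is 0 and log 0 := 0
  expect_equal(expected_scaled_jump(1, "large_deletion", im, ru), 0)
  # s = 2: (log 1)/2 - log 2
  expect_equal(expected_scaled_jump(2, "large_deletion", im, ru), -log(2))
  # large-size limits
  expect_equal(expected_scaled_jump(1e9, "large_deletion", im, ru), -1,
               tolerance = 1e-6)
  expect_equal(expected_scaled_jump(1e9, "duplication", im, ru),
               2 * log(2) - 1, tolerance = 1e-6)
  expect_lt(abs(expected_scaled_jump(1e9, "small_insertion", im, ru)), 1e-6)
  expect_error(expected_scaled_jump(0, "duplication", im, ru), ">= 1")
  # closed log-gamma form equals the brute-force sum at moderate size
  s <- 5000
  brute <- mean(log((s + 1):(2 * s))) - log(s)
  expect_equal(expected_scaled_jump(s, "duplication", im, ru), brute,
               tolerance = 1e-12)
})

test_that("asymptotic drift estimates plateau at the known constants", {
  d <- estimate_asymptotic_deltas(ref_indels(), unif_rearr())
  expect_true(all(d$converged))
  expect_equal(unname(d$deltas[c("large_deletion", "duplication")]),
               c(-1, 2 * log(2) - 1), tolerance = 1e-4)
  expect_lt(max(abs(d$deltas[c("small_insertion", "small_deletion")])), 1e-6)

  # truncated lognormal in natural scale: +/- the complete-lognormal mean
  dl <- estimate_asymptotic_deltas(ref_indels(), lnorm_rearr(),
                                   f = "identity")
  expect_true(all(dl$converged))
  m <- exp(10.1214 + 2.5602^2 / 2)               # ~6.59e5
  expect_equal(unname(dl$deltas[c("large_deletion", "duplication")]),
               c(-m, m), tolerance = 1e-3)
  expect_equal(unname(dl$deltas[c("small_insertion", "small_deletion")]),
               c(20.5, -20.5))
  # numeric estimates agree with the closed-form limits
  expect_equal(dl$deltas, asymptotic_deltas(ref_indels(), lnorm_rearr(),
                                            f = "identity"),
               tolerance = 1e-3)
})

test_that("the convergence condition reproduces the uniform-model inequality", {
  # reference uniform setup: net drift ~ -2.32e-9, converges
  v <- stationarity_condition(ref_rates(),
                              asymptotic_deltas(ref_indels(), unif_rearr()))
  expect_equal(v$verdict, "converges")
  expect_equal(v$net_drift, 3.778e-9 * (2 * log(2) - 2), tolerance = 1e-12)

  # lognormal in natural scale: exact cancellation, no verdict
  vl <- stationarity_condition(ref_rates(),
                               asymptotic_deltas(ref_indels(), lnorm_rearr(),
                                                 f = "identity"))
  expect_equal(vl$verdict, "inconclusive")
  expect_equal(vl$net_drift, 0)

  # boundary: mu_dup / mu_ldel = 1 / (2 log 2 - 1) zeroes the drift
  rb <- mutation_rates(0, 0, 1e-9, 1e-9 / (2 * log(2) - 1))
  vb <- stationarity_condition(rb, asymptotic_deltas(ref_indels(),
                                                     unif_rearr()))
  expect_equal(vb$verdict, "inconclusive")

  # generic condition == Theorem-2 inequality over random rate draws
  set.seed(501)
  d_unif <- asymptotic_deltas(ref_indels(), unif_rearr())
  for (i in 1:100) {
    r <- mutation_rates(stats::runif(1), stats::runif(1), stats::runif(1),
                        stats::runif(1))
    v <- stationarity_condition(r, d_unif)
    expect_equal(v$net_drift, (2 * log(2) - 1) * r$mu_dup - r$mu_ldel,
                 tolerance = 1e-12)
    if (v$verdict != "inconclusive")
      expect_equal(v$verdict == "converges",
                   (2 * log(2) - 1) * r$mu_dup < r$mu_ldel)
  }

  # drift monotone: increasing in mu_dup, decreasing in mu_ldel
  net <- function(ldel, dup)
    stationarity_condition(mutation_rates(1e-9, 1e-9, ldel, dup),
                           d_unif)$net_drift
  expect_gt(net(1e-9, 2e-9), net(1e-9, 1e-9))
  expect_lt(net(2e-9, 1e-9), net(1e-9, 1e-9))

  # non-plateaued drifts refuse to conclude
  d_bad <- estimate_asymptotic_deltas(ref_indels(), lnorm_rearr(),
                                      f = "identity", size_grid = c(1e3, 1e4))
  expect_false(all(d_bad$converged))
  expect_equal(stationarity_condition(ref_rates(), d_bad)$verdict,
               "inconclusive")
})

test_that("the truncated one-mutation kernel is row-stochastic with tracked leak", {
  r <- ref_rates()
  m1 <- build_m1(100, r, ref_indels(), unif_rearr())
  expect_equal(unname(Matrix::rowSums(m1$P) + m1$leaked), rep(1, 101),
               tolerance = 1e-10)
  # row 0: only insertions escape, each size 1..40 with mass (mu_ins/mu)/40
  row0 <- m1$P[1, ]
  expect_equal(unname(row0[1]), (r$mu_total - r$mu_ins) / r$mu_total)
  expect_equal(unname(row0[2:41]),
               rep(r$mu_ins / r$mu_total / 40, 40))
  expect_equal(sum(row0[-(1:41)]), 0)
  # duplication block flat at (mu_dup/mu)/s over s+1..2s (use 2-bp indels
  # so the block is not overlaid by insertion mass)
  m1b <- build_m1(100, r, indel_model(2, 2), unif_rearr())
  s <- 30
  dup_block <- m1b$P[s + 1, (s + 4):(2 * s + 1)]   # j = s+3 .. 2s
  expect_equal(unname(as.numeric(dup_block)),
               rep(r$mu_dup / r$mu_total / s, s - 2))
  expect_error(build_m1(100, mutation_rates(0, 0, 0, 0), ref_indels(),
                        unif_rearr()), "> 0")
})

test_that("the one-generation kernel tends to the identity as rates vanish", {
  r_tiny <- mutation_rates(1e-9, 1e-9, 5e-10, 5e-10)
  mg <- build_mg(30, r_tiny, ref_indels(), unif_rearr())
  expect_true(all(diag(mg$P) > 0.999))
  expect_equal(unname(rowSums(mg$P) + mg$leaked), rep(1, 30),
               tolerance = 1e-9)
})

test_that("a generation-kernel row matches Monte-Carlo of the generation process", {
  r <- mutation_rates(0.01, 0.01, 0.005, 0.005)
  mg <- cached("mg_row_check",
               build_mg(400, r, ref_indels(), unif_rearr()))
  i <- 80
  set.seed(502)
  n <- 200000
  ends <- vapply(seq_len(n), function(j)
    one_generation(i, r, ref_indels(), unif_rearr(),
                   record_events = FALSE)$end_size, numeric(1))
  emp <- tabulate(pmin(ends, 400), 400) / n
  row <- mg$P[i, ]
  # bin into 8-bp cells: the raw per-size TV has a Monte-Carlo noise floor
  # of ~0.015 at this n over a support several hundred sizes wide
  bins <- rep(seq_len(50), each = 8)
  expect_lt(tv_dist(rowsum(emp, bins), rowsum(as.numeric(row), bins)), 0.01)
})

test_that("stationary vectors solve the balance equations", {
  # two-state toy kernel with known closed form: pi = (b, a)/(a+b)
  toy <- structure(list(P = matrix(c(0.7, 0.3, 0.2, 0.8), 2, byrow = TRUE,
                                   dimnames = list(1:2, 1:2)),
                        states = 1:2, leaked = c(0, 0), kind = "mg"),
                   class = "truncated_chain")
  st <- stationary_distribution(toy, tol = 1e-14)
  expect_equal(unname(st$pi), c(0.4, 0.6), tolerance = 1e-8)
  expect_lt(st$residual, 1e-12)

  mg <- scaled_mg(300)
  st1 <- stationary_distribution(mg)
  # stationarity: pi P = pi after renormalization
  expect_lt(st1$residual, 1e-8)
  # independence from the starting distribution
  st2 <- stationary_distribution(mg, start = c(rep(0, 299), 1))
  expect_lt(tv_dist(st1$pi, st2$pi), 1e-8)
  # TV trajectory decays geometrically (Doeblin-type convergence echo)
  tv <- st1$tv_trace
  expect_lt(tv[length(tv)], tv[1] * 1e-6)

  # window self-consistency: enlarging the window barely moves pi
  mg_small <- scaled_mg(240)
  st_small <- stationary_distribution(mg_small)
  p_big <- st1$pi[1:240] / sum(st1$pi[1:240])
  expect_lt(tv_dist(p_big, st_small$pi), 0.01)
})
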