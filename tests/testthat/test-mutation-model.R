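test_that("mutation type draws follow mu_type / mu_total", {
  # degenerate: only large deletions possible
  r <- mutation_rates(0, 0, 1e-9, 0)
  expect_true(all(sample_event_type(r, 50) == "large_deletion"))

  # symmetric rates: each type close to 1/4
  set.seed(101)
  n <- 100000
  tab <- table(sample_event_type(mutation_rates(1, 1, 1, 1), n)) / n
  expect_true(all(abs(tab - 0.25) < 3 * sqrt(0.25 * 0.75 / n)))

  # reference rates: large deletions are 1/6 of mutations
  f_ldel <- mean(sample_event_type(ref_rates(), n) == "large_deletion")
  expect_lt(abs(f_ldel - 1 / 6), 3 * sqrt((1 / 6) * (5 / 6) / n))

  expect_error(sample_event_type(mutation_rates(0, 0, 0, 0)), "undefined")
})

test_that("rate and model constructors validate their inputs", {
  expect_error(mutation_rates(-1, 0, 0, 0), ">= 0")
  expect_equal(mutation_rates(1, 2, 3, 4)$mu_total, 10)
  expect_error(indel_model(0), ">= 1")
  expect_error(indel_model(p_ins = c(0.5, 0.5)), "length 40")
  expect_error(rearrangement_model("truncated_lognormal", sdlog = 0), "sdlog")
  expect_error(rearrangement_model("empirical_table"), "table")
  expect_error(rearrangement_model("empirical_table",
                                   table = data.frame(size = 1.5, w = 1)),
               "positive integers")
})

test_that("uniform rearrangement sizes are uniform on 1..current_size", {
  expect_equal(sample_rearrangement_size(unif_rearr(), 1, 20), rep(1, 20))

  set.seed(102)
  n <- 100000
  s <- 4e6
  x <- sample_rearrangement_size(unif_rearr(), s, n)
  expect_true(all(x >= 1 & x <= s))
  # closed-form mean of the discrete uniform, 3 sigma
  expect_lt(abs(mean(x) - (s + 1) / 2), 3 * (s / sqrt(12)) / sqrt(n))

  # flatness at fixed small size: chi-square GoF not rejected at alpha 1e-3
  y <- sample_rearrangement_size(unif_rearr(), 50, n)
  expect_gt(stats::chisq.test(tabulate(y, 50))$p.value, 0.001)
})

test_that("truncated lognormal sizes match the conditional law", {
  set.seed(103)
  n <- 100000
  s <- 4e6
  m <- lnorm_rearr()
  x <- sample_rearrangement_size(m, s, n)
  expect_true(all(x >= 1 & x <= s))
  # oracle: numerically integrated conditional mean of the truncated density
  oracle <- stats::integrate(function(t) t * stats::dlnorm(t, m$meanlog, m$sdlog),
                             0, s + 0.5, rel.tol = 1e-10)$value /
    stats::plnorm(s + 0.5, m$meanlog, m$sdlog)
  expect_lt(abs(mean(x) - oracle), 3 * stats::sd(x) / sqrt(n) + 0.5)

  # no mass below the truncation point: refuse instead of looping forever
  far <- rearrangement_model("truncated_lognormal", meanlog = 40, sdlog = 1)
  expect_error(sample_rearrangement_size(far, 10), "1e-12")
  expect_error(sample_rearrangement_size(m, 0), ">= 1")
})

test_that("empirical table sizes truncate and renormalize", {
  m <- rearrangement_model("empirical_table",
                           table = data.frame(size = c(5, 50, 500),
                                              weight = c(1, 1, 2)))
  set.seed(104)
  x <- sample_rearrangement_size(m, 100, 5000)
  expect_true(all(x %in% c(5, 50)))
  expect_lt(abs(mean(x == 5) - 0.5), 3 * sqrt(0.25 / 5000))
  expect_error(sample_rearrangement_size(m, 3), "no mass")
})

test_that("apply_mutation respects the boundary rules", {
  im <- ref_indels(); ru <- unif_rearr()
  # empty genome: rearrangements and small deletions do nothing
  for (ty in c("duplication", "large_deletion", "small_deletion"))
    expect_equal(apply_mutation(0, ty, im, ru)$post_size, 0)
  expect_gte(apply_mutation(0, "small_insertion", im, ru)$post_size, 1)

  # small deletion larger than the genome floors at 0
  im9 <- indel_model(l_sdel = 9, p_sdel = c(rep(0, 8), 1))
  expect_equal(apply_mutation(5, "small_deletion", im9, ru)$post_size, 0)

  # size-1 genome: a uniform large deletion can only empty it
  expect_equal(apply_mutation(1, "large_deletion", im, ru)$post_size, 0)

  ev <- apply_mutation(4e6, "duplication", im, ru)
  expect_true(ev$size_change >= 1 && ev$size_change <= ev$pre_size)
  expect_equal(ev$post_size, ev$pre_size + ev$size_change)
})

test_that("mutations never produce negative sizes and only insertions escape 0", {
  set.seed(105)
  im <- indel_model(l_ins = 5, l_sdel = 5)
  ru <- unif_rearr()
  for (i in 1:300) {
    s <- sample(c(0, 1, 2, 7, 1000), 1)
    ty <- sample(c("small_insertion", "small_deletion",
                   "large_deletion", "duplication"), 1)
    ev <- apply_mutation(s, ty, im, ru)
    expect_gte(ev$post_size, 0)
    if (s == 0 && ty != "small_insertion") expect_equal(ev$post_size, 0)
  }
})

test_that("symmetric indels have zero expected size change above the bound", {
  im <- ref_indels()
  d_ins <- expected_scaled_jump(100, "small_insertion", im, unif_rearr(),
                                f = "identity")
  d_sdel <- expected_scaled_jump(100, "small_deletion", im, unif_rearr(),
                                 f = "identity")
  expect_equal(d_ins, 20.5)
  expect_equal(d_ins + d_sdel, 0)
})
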