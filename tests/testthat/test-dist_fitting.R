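test_that("histograms tabulate occurrence counts with totals", {
  fd <- freq_distribution(c(1, 1, 2, 9))
  expect_equal(fd$m, c(1L, 2L, 9L))
  expect_equal(fd$freq, c(2, 1, 1))
  expect_equal(fd$M, 4)
  expect_equal(fd$J, 9L)
  expect_equal(fd$total_events, 13)
  expect_equal(freq_distribution(5)$m, 5L)
  expect_error(freq_distribution(numeric(0)), "empty")
  expect_error(freq_distribution(c(1, 0)), "positive")
})

test_that("the three relation histograms agree with hand enumeration and duality", {
  ds <- make_toy_dataset()  # tu1: FLs {A},{A,B}; tu2: FL {A}
  f1 <- fls_per_tu(ds)
  expect_equal(f1$m, c(1L, 2L)); expect_equal(f1$freq, c(1, 1))
  f2 <- tus_per_fl(ds)
  expect_equal(f2$m, c(1L, 2L)); expect_equal(f2$freq, c(1, 1))
  f3 <- svs_per_tu(ds)
  expect_equal(f3$m, c(1L, 2L)); expect_equal(f3$freq, c(1, 1))
  # double-counting identity on random data
  set.seed(13)
  for (i in 1:5) {
    ds <- random_small_dataset(6L)
    if (all(ds$tus$class == "unannotated")) next
    expect_equal(fls_per_tu(ds)$total_events, tus_per_fl(ds)$total_events)
  }
})

test_that("GDP pmf matches closed forms, normalizes, and decreases", {
  expect_equal(gdp_pmf(1:2, k = 1, b = 0, J = 2), c(0.8, 0.2))
  # infinite-support standard Pareto at k = 1: f(1) = 6 / pi^2
  expect_equal(gdp_pmf(1, k = 1, b = 0, J = Inf), 6 / pi^2,
               tolerance = 1e-10)
  # finite-sum normalizer against an independent zeta implementation
  skip_if_not_installed("pracma")
  for (k in 1:3)
    expect_equal(1 / gdp_norm_const(k, 0, Inf), pracma::zeta(k + 1),
                 tolerance = 1e-8)
  set.seed(17)
  for (i in 1:200) {
    k <- runif(1, 0.05, 5); b <- runif(1, -0.9, 10)
    J <- sample(1:500, 1L)
    f <- gdp_pmf(seq_len(J), k, b, J)
    expect_lt(abs(sum(f) - 1), 1e-12)
    if (J > 1L) expect_true(all(diff(f) < 0))
  }
  expect_error(gdp_pmf(1, k = 0, b = 0, J = 5), "k")
  expect_error(gdp_pmf(1, k = 1, b = -1, J = 5), "b")
  expect_error(gdp_pmf(6, k = 1, b = 0, J = 5), "1..J")
})

test_that("exponential fit recovers noiseless parameters and rejects flat data", {
  m <- 1:9
  fd <- freq_dist_from_counts(m, 1000 * exp(-0.5 * m))
  fit <- fit_exponential(fd)
  expect_equal(fit$a, 1000, tolerance = 1e-6)
  expect_equal(fit$b, 0.5, tolerance = 1e-6)
  flat <- freq_dist_from_counts(1:6, rep(50, 6))
  expect_error(fit_exponential(flat), "boundary")
})

test_that("exponential rate is recovered within 3 SE from sampled counts", {
  set.seed(2010)
  draws <- 1L + stats::rgeom(20000L, 1 - exp(-0.5))  # discretized exp, b=0.5
  fit <- fit_exponential(freq_distribution(draws), method = "mle")
  expect_lt(abs(fit$b - 0.5), 3 * fit$se_b)
})

test_that("GDP fit recovers noiseless parameters including heavy-shift tails", {
  m <- 1:50
  fd <- freq_dist_from_counts(m, 10000 * gdp_pmf(m, 1, 0, 50))
  fit <- fit_gdp(fd, fix_b_zero = TRUE)
  expect_equal(fit$k, 1, tolerance = 1e-6)
  expect_equal(fit$k + 1, 2, tolerance = 1e-6)  # Zipf-Lotka slope
  # published-magnitude tail parameters, refit from the exact curve
  m2 <- 10:73
  fd2 <- freq_dist_from_counts(m2, 5000 * gdp_pmf(m2, 4.16, 8.75, 73))
  fit2 <- fit_gdp(fd2, m_range = c(10, 73))
  expect_equal(fit2$k, 4.16, tolerance = 1e-4)
  expect_equal(fit2$b, 8.75, tolerance = 1e-4)
  # stored normalization honors the truncation invariant
  expect_lt(abs(sum(fit2$C / (seq_len(fit2$J) + fit2$b)^(fit2$k + 1)) - 1),
            1e-12)
})

test_that("standard-Pareto shape is recovered within 10 percent from samples", {
  draws <- sample_gdp(50000L, k = 1, b = 0, J = 1000L, seed = 7)
  fit <- fit_gdp(freq_distribution(draws), fix_b_zero = TRUE,
                 method = "mle")
  expect_lt(abs(fit$k - 1), 0.1)
})

test_that("mixture fit splits regimes, recovers parameters, and normalizes", {
  sv <- list(s = 0.9, exp_b = 0.5, gdp_k = 4.16, gdp_b = 8.75,
             breakpoint = 10L, J = 73L)
  draws <- sample_sv_mixture(20000L, sv, seed = 2010)
  fd <- freq_distribution(draws)
  fit <- fit_mixture(fd, breakpoint = 10, method = "mle")
  expect_lt(abs(fit$s - 0.9), 0.05)
  expect_lt(abs(fit$comp1$b - 0.5), 3 * fit$comp1$se_b)
  expect_lt(abs(fit$comp2$k - 4.16) / 4.16, 0.15)
  pmf <- mixture_pmf(fit)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  # wholly exponential data with the breakpoint at J: tail flagged absent
  m <- 1:9
  body <- freq_dist_from_counts(m, round(5000 * exp(-0.5 * m)))
  only <- fit_mixture(body, breakpoint = 9)
  expect_null(only$comp2)
  expect_equal(only$s, sum(body$freq[body$m < 9]) / body$M)
  expect_equal(sum(mixture_pmf(only)), 1, tolerance = 1e-12)
  rep_ <- mixture_report(only)
  expect_true(all(is.na(rep_$estimate[rep_$component == "P2"])))
  expect_error(fit_mixture(body, breakpoint = 1), "breakpoint")
  expect_error(fit_mixture(body, breakpoint = 99), "breakpoint")
})

test_that("descriptive rows reproduce ratio, singleton and skewness conventions", {
  fd <- fixture_histogram(total_events = 23640, total_objects = 20928,
                          n1 = 18575, J = 9)
  row <- describe_relation(fd)
  expect_equal(round(row$ratio, 2), 1.13)
  expect_equal(round(row$p1, 1), 88.8)
  expect_equal(row$n1, 18575)
  all1 <- describe_relation(freq_distribution(rep(1, 10)))
  expect_equal(all1$p1, 100)
  expect_equal(all1$skewness, 0)
  small <- describe_relation(freq_dist_from_counts(c(1, 4), c(2, 1)))
  expect_equal(small$ratio, 2)
  expect_equal(small$n1, 2)
  expect_equal(small$p1, 100 * 2 / 3, tolerance = 1e-10)
  # n1 recovery on random inputs
  set.seed(3)
  for (i in 1:10) {
    v <- sample(1:6, 40, replace = TRUE)
    expect_equal(describe_relation(freq_distribution(v))$n1, sum(v == 1))
  }
})
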