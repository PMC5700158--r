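test_that("product-form law reduces to the negative binomial without feedback", {
  set.seed(101)
  for (i in 1:12) {
    cc <- runif(1, 0.5, 80); d <- runif(1, 0.5, 3); p <- runif(1, 0.1, 0.95)
    d1 <- steady_state_distribution(constant_rf(cc), p, d)
    d2 <- negative_binomial_pmf(cc, d, p)
    len <- min(length(d1$probs), length(d2$probs))
    expect_lt(max(abs(log(d1$probs[1:len]) - log(d2$probs[1:len]))), 1e-12)
    expect_lt(abs(sum(d1$probs) + d1$truncation_mass - 1), 1e-10)
    expect_lt(d1$truncation_mass, 1e-10)
  }
})

test_that("closed-form negative binomial pmf values", {
  # size c/d = 1 is geometric q p^n; p_0 = q^{c/d}; direct value at n = 2
  g <- negative_binomial_pmf(1, 1, 0.5)
  expect_equal(g$probs[1:4], 0.5 * 0.5^(0:3))
  expect_equal(negative_binomial_pmf(3.7, 2, 0.8)$probs[1],
               0.2^(3.7 / 2))
  expect_equal(negative_binomial_pmf(3, 1, 0.6)$probs[3], 0.13824)
})

test_that("degenerate and truncated cases are handled explicitly", {
  pt <- steady_state_distribution(constant_rf(0), 0.5, 1)
  expect_equal(pt$probs, 1)
  expect_equal(distribution_moments(pt), list(mean_n = 0, var_n = 0))
  expect_error(steady_state_distribution(constant_rf(5), 0.9999, 1,
                                         n_max = 2000),
               "n_max")
})

test_that("moments match closed forms", {
  g <- negative_binomial_pmf(1, 1, 0.5)       # geometric, p = 0.5
  m <- distribution_moments(g)
  expect_equal(m$mean_n, 1, tolerance = 1e-9)
  expect_equal(m$var_n, 2, tolerance = 1e-9)
  nb <- negative_binomial_pmf(2, 1, 0.5)      # size 2: mean 2, var 4
  m2 <- distribution_moments(nb)
  expect_equal(m2$mean_n, 2, tolerance = 1e-9)
  expect_equal(m2$var_n, 4, tolerance = 1e-9)
  # product-form mean equals (c/d)(p/q) for constant c
  d3 <- steady_state_distribution(constant_rf(5), 0.5, 1)
  expect_equal(distribution_moments(d3)$mean_n, 5, tolerance = 1e-9)
})

test_that("feedback coefficient: sign law and the decomposition identity", {
  # constant c has eta_f = 0
  d0 <- steady_state_distribution(constant_rf(6), 0.6, 1)
  expect_lt(abs(feedback_coefficient_exact(d0, constant_rf(6))), 1e-12)
  # increasing c (linear activation form) has eta_f > 0
  rf_up <- linear_activation_rf(3, 50, 80, 2)
  dup <- steady_state_distribution(rf_up, 0.5, 1)
  expect_gt(feedback_coefficient_exact(dup, rf_up), 0)
  # negative-feedback Hill: eta_f equals eta - 1/(q<n>) to 1e-10
  rf_dn <- hill_regulatory_function(50, 100, 5, 2)
  ddn <- steady_state_distribution(rf_dn, 0.7, 1)
  ef <- feedback_coefficient_exact(ddn, rf_dn)
  mom <- distribution_moments(ddn)
  expect_lt(ef, 0)
  expect_lt(abs(ef - (mom$var_n / mom$mean_n^2 -
                        1 / (0.3 * mom$mean_n))), 1e-10)
})

test_that("noise decomposition identities hold exactly for analytic laws", {
  set.seed(102)
  for (i in 1:15) {
    s <- runif(1, 10, 300); r <- runif(1, 0, 10)
    p <- runif(1, 0.2, 0.9); h <- sample(1:4, 1); a <- runif(1, 1, 800)
    rf <- if (i %% 2) hill_regulatory_function(a, s, r, h)
          else linear_inactivation_rf(a, runif(1, 0.5, 50), s, r)
    bp <- list(p = p, q = 1 - p, lam = 30)
    dist <- steady_state_distribution(rf, p, 1)
    dec <- decompose_noise(dist, rf, bp, d = 1, v = 30)
    expect_lt(abs(dec$eta - dec$feedback_free - dec$eta_f), 1e-10)
    expect_lt(abs(dec$poisson_term + dec$mrna_term - dec$feedback_free),
              1e-10)
    expect_gt(dec$eta, 0)
    expect_lt(dec$eta_f, 0)
    expect_true(is.na(dec$eta_s))
  }
  # no feedback: eta = 1/(q<n>) exactly and eta_f = 0
  rf0 <- constant_rf(5)
  dec0 <- decompose_noise(steady_state_distribution(rf0, 0.5, 1), rf0,
                          list(p = 0.5, q = 0.5, lam = 30), 1, 30)
  expect_lt(abs(dec0$eta_f), 1e-12)
  expect_equal(dec0$eta, dec0$feedback_free, tolerance = 1e-10)
  # positive feedback exceeds the feedback-free noise
  rfp <- linear_activation_rf(2, 100, 60, 1)
  decp <- decompose_noise(steady_state_distribution(rfp, 0.5, 1), rfp,
                          list(p = 0.5, q = 0.5, lam = 30), 1, 30)
  expect_gt(decp$eta_f, 0)
  expect_gt(decp$eta, decp$feedback_free)
})

test_that("steep negative feedback can push noise below the Poisson level", {
  rf <- hill_regulatory_function(100, 280, 1, 4)
  dist <- steady_state_distribution(rf, 0.25, 1)
  mom <- distribution_moments(dist)
  expect_lt(mom$var_n / mom$mean_n^2, 1 / (2 * mom$mean_n))
  expect_gt(hill_steepness(100, 280, 1, 4), 1)   # requires alpha > d
})

test_that("noise bounds and efficiency algebra", {
  b <- noise_bounds_negative(q = 0.4, mean_n = 10, alpha = 1 * 0.4 / 0.6,
                             p = 0.6, d = 1)
  # alpha p/(d q) = 1: lower = upper/2, efficiency cap 1/2
  expect_equal(b$lower, b$upper / 2)
  expect_equal(b$efficiency_cap, 0.5)
  expect_warning(b0 <- noise_bounds_negative(0.4, 10, 0, 0.6, 1), "alpha")
  expect_equal(b0$lower, b0$upper)
  expect_equal(b0$efficiency_cap, 0)
  expect_equal(efficiency(eta = 0.31, eta_f = -0.18), 0.18 / 0.49)
  expect_lt(abs(efficiency(0.49 - 0.18, -0.18) - 0.367), 5e-4)
  expect_equal(efficiency(1, -1e-9), 1e-9 / (1 + 1e-9))
  expect_error(efficiency(0.5, 0.1), "negative feedback")
  expect_error(efficiency(-1, -0.1), "eta > 0")
})

test_that("exponential tail decay at rate q in the bursty regime", {
  # c/d = 1 makes the tail ratio exactly p at every n
  for (p in c(0.99, 0.5)) {
    dist <- negative_binomial_pmf(1, 1, p)
    dev <- if (p == 0.5) suppressWarnings(tail_decay_check(dist, 1 - p))
           else tail_decay_check(dist, 1 - p)
    expect_lt(dev, 0.05 * (1 - p))
  }
  # saturated Hill tail approaches the same limiting ratio
  rf <- hill_regulatory_function(1e4, 5, 1, 2)
  dist <- steady_state_distribution(rf, 0.99, 1)
  expect_lt(tail_decay_check(dist, 0.01), 0.05 * 0.01)
  expect_warning(tail_decay_check(negative_binomial_pmf(1, 1, 0.5), 0.5),
                 "p/q")
})

test_that("distribution serialization round-trips through TSV", {
  dist <- negative_binomial_pmf(4, 1, 0.5)
  path <- tempfile(fileext = ".tsv")
  write_distribution(dist, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$n, dist$n)
  expect_equal(back$probability, dist$probs, tolerance = 1e-12)
  rep <- decomposition_report(decompose_noise(dist, constant_rf(4),
                                              list(p = 0.5, q = 0.5,
                                                   lam = 30), 1, 30))
  expect_true(all(c("eta", "poisson_term", "mrna_term", "feedback_free",
                    "eta_f", "eta_s", "mean_n", "var_n", "mrna_mean") %in%
                    names(rep)))
})
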