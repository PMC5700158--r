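test_that("effective transcription rate is the switching-weighted average", {
  # equal weights give the midpoint; b_n = 0 gives the fully active rate
  cir <- gene_circuit(s = 10, r = 2, u = 1, v = 1, d = 1,
                      switching = switching_spec("constant", a = 3, b = 3))
  expect_equal(effective_transcription_rate(cir, 0:5), rep(6, 6))
  cir2 <- gene_circuit(s = 10, r = 2, u = 1, v = 1, d = 1,
                       switching = list(a_fn = function(n) rep(5, length(n)),
                                        b_fn = function(n) rep(0, length(n))))
  expect_equal(effective_transcription_rate(cir2, 7), 10)
  # a_n = n, b_n = 6: direct arithmetic at n = 4
  cir3 <- gene_circuit(s = 100, r = 10, u = 1, v = 1, d = 1,
                       switching = switching_spec("linear_activation",
                                                  a = 0, k = 1, b = 6))
  expect_equal(effective_transcription_rate(cir3, 4), 46)
  # zero total switching rate is an explicit error naming n
  cir4 <- gene_circuit(s = 1, r = 1, u = 1, v = 1, d = 1,
                       switching = switching_spec("linear_activation",
                                                  a = 0, k = 1, b = 0))
  expect_error(effective_transcription_rate(cir4, 0), "n = 0")
})

test_that("effective rate is bracketed by r and s for random circuits", {
  set.seed(11)
  for (i in 1:20) {
    s <- runif(1, 0, 50); r <- runif(1, 0, 50)
    form <- sample(c("constant", "linear_activation",
                     "linear_inactivation", "hill"), 1)
    sw <- switching_spec(form, a = runif(1, 0.1, 100), b = runif(1, 0.1, 100),
                         k = runif(1, 0, 5), h = sample(1:4, 1))
    cir <- gene_circuit(s, r, 1, 1, 1, sw)
    cn <- effective_transcription_rate(cir, 0:200)
    expect_true(all(cn >= min(r, s) - 1e-12 & cn <= max(r, s) + 1e-12))
  }
})

test_that("burst parameters satisfy p + q = 1 and p/q = u/v", {
  bp <- burst_parameters(1, 1, 1)
  expect_identical(bp$p + bp$q, 1)
  expect_equal(c(bp$p, bp$q, bp$lam), c(0.5, 0.5, 1))
  bp2 <- burst_parameters(99, 1, 1)
  expect_equal(c(bp2$p, bp2$q), c(0.99, 0.01))
  bp3 <- burst_parameters(1, 30, 1)
  expect_equal(bp3$q, 30 / 31)
  expect_equal(bp3$lam, 30)
  set.seed(4)
  for (i in 1:10) {
    u <- runif(1, 0.01, 100); v <- runif(1, 0.01, 100)
    bp <- burst_parameters(u, v, 1)
    expect_identical(bp$p + bp$q, 1)
    expect_equal(bp$p / bp$q, u / v)
  }
  expect_error(burst_parameters(0, 1, 1), "positive")
})

test_that("generalized Hill function and its topology declaration", {
  expect_equal(hill_regulatory_function(1, 5, 5, 2)$c_fn(0:10), rep(5, 11))
  expect_identical(hill_regulatory_function(1, 5, 5, 2)$declared_topology,
                   "none")
  expect_equal(hill_regulatory_function(1, 10, 0, 1)$c_fn(1), 5)
  expect_equal(hill_regulatory_function(8, 10, 2, 3)$c_fn(2), 6)
  rf <- hill_regulatory_function(100, 10, 1, 2)
  expect_equal(rf$c_fn(0), 10)
  expect_lt(rf$c_fn(1e6), 1 + 1e-6)
  expect_identical(rf$declared_topology, "negative")
  expect_identical(hill_regulatory_function(100, 1, 10, 2)$declared_topology,
                   "positive")
  expect_error(hill_regulatory_function(0, 1, 1, 1), "a")
  expect_error(hill_regulatory_function(1, 1, 1, 0.5), "h")
})

test_that("hill steepness matches the brute-force derivative maximum", {
  expect_equal(hill_steepness(4, 10, 2, 1), 2)
  expect_equal(hill_steepness(7, 3, 3, 2), 0)
  set.seed(21)
  for (h in c(1, 2, 3, 4)) {
    for (rep in 1:3) {
      a <- runif(1, 0.5, 500); s <- runif(1, 10, 200); r <- runif(1, 0, 9)
      alpha <- hill_steepness(a, s, r, h)
      if (h == 1) {
        # |c'| is maximal at x = 0 for h = 1
        expect_equal(alpha, (s - r) / a)
      } else {
        x <- exp(seq(log(1e-3), log(1e5), length.out = 2e5))
        grid_max <- max(h * a * (s - r) * x^(h - 1) / (a + x^h)^2)
        expect_equal(alpha, grid_max, tolerance = 1e-6)
      }
    }
  }
})

test_that("topology classification is monotonicity with a floating guard", {
  expect_identical(classify_topology(constant_rf(4)), "none")
  expect_identical(classify_topology(hill_regulatory_function(50, 9, 1, 2)),
                   "negative")
  expect_identical(classify_topology(linear_activation_rf(1, 6, 100, 10)),
                   "positive")
  # additive floating noise far below tolerance must not produce a call
  jitter_rf <- regulatory_function(function(x)
    5 + 5e-14 * sin(x), "unknown", s = 5, r = 5)
  expect_identical(classify_topology(jitter_rf), "none")
  vshape <- regulatory_function(function(x) abs(x - 50) + 1, "unknown")
  expect_identical(classify_topology(vshape, 200), "non-monotone")
  # constructor-declared topology agrees with the numeric classification
  set.seed(31)
  for (i in 1:15) {
    a <- runif(1, 1, 500); s <- runif(1, 0, 100); r <- runif(1, 0, 100)
    h <- sample(1:4, 1)
    rf <- hill_regulatory_function(a, s, r, h)
    expect_identical(classify_topology(rf), rf$declared_topology)
  }
})

test_that("circuits are constructible from JSON config blocks", {
  cfg <- list(s = 100, r = 5, u = 70, v = 30, d = 1,
              switching = list(form = "hill", a = 200, h = 2))
  cir <- circuit_from_config(cfg)
  expect_s3_class(cir, "gene_circuit")
  expect_equal(effective_transcription_rate(cir, 0), 100)
  rf <- as_regulatory_function(cir)
  expect_identical(rf$declared_topology, "negative")
  # the four switching families from file
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(s = 10, r = 1, u = 30, v = 30, d = 1,
                            switching = list(form = "linear_inactivation",
                                             a = 50, b = 2, k = 1)),
                       path, auto_unbox = TRUE)
  cir2 <- circuit_from_config(path)
  expect_equal(cir2$b_fn(10), 12)
  expect_identical(as_regulatory_function(cir2)$declared_topology, "negative")
  expect_error(circuit_from_config(list(s = 1, r = 1, u = 1, v = 1, d = 1,
                                        bogus = 2)), "bogus")
  expect_error(circuit_from_config(list(s = 1, u = 1, v = 1, d = 1)),
               "missing")
})
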