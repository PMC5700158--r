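test_that("moment estimates are the sample mean and unbiased variance", {
  expect_equal(estimate_moments(single_cell_dataset(c(2, 2, 2, 2))),
               list(mean_hat = 2, var_hat = 0))
  expect_equal(estimate_moments(single_cell_dataset(0:3)),
               list(mean_hat = 1.5, var_hat = 5 / 3))
  expect_error(estimate_moments(single_cell_dataset(3)), "two cells")
  expect_error(single_cell_dataset(c(-1, 2)), "non-negative")
  # CLT-scale agreement with the negative binomial truth
  dist <- negative_binomial_pmf(2, 1, 0.5)
  ds <- sample_cells(dist, 1e5, seed = 41)
  se <- sqrt(4 / 1e5)
  expect_lt(abs(estimate_moments(ds)$mean_hat - 2), 3 * se)
})

test_that("tail decay-rate estimation recovers q", {
  # geometric data: the fitted per-copy ratio gives q almost exactly
  g <- negative_binomial_pmf(1, 1, 0.95)
  ds <- sample_cells(g, 1e4, seed = 42)
  fit <- estimate_decay_rate(ds)
  expect_lt(abs(fit$q_hat - 0.05), 0.1 * 0.05)
  expect_gt(fit$r_squared, 0.8)
  expect_true(fit$decreasing)
  # Hill-feedback law at p = 0.99, 1e5 cells: within 15% of q = 0.01
  cc <- class_negative()
  dist <- steady_state_distribution(cc$rf, cc$p, 1)
  big <- sample_cells(dist, 1e5, seed = 43)
  expect_lt(abs(estimate_decay_rate(big)$q_hat - 0.01), 0.15 * 0.01)
  # too little data is an explicit error
  tiny <- single_cell_dataset(rep(c(5, 6), 10))
  expect_error(estimate_decay_rate(tiny), "window|cells")
})

test_that("decay estimate is equivariant under concentration rescaling", {
  cc <- class_negative()
  dist <- steady_state_distribution(cc$rf, cc$p, 1)
  ds <- sample_cells(dist, 2e4, seed = 44)
  fit_n <- estimate_decay_rate(ds)
  for (V in c(10, 100)) {
    conc <- single_cell_dataset(ds$values / V, is_concentration = TRUE)
    fit_x <- estimate_decay_rate(conc)
    # decay rate scales by V; q_hat * mean is dimensionless and invariant
    expect_lt(abs(fit_x$q_hat * mean(conc$values) /
                    (fit_n$q_hat * mean(ds$values)) - 1), 0.02)
  }
})

test_that("ols tail-fit variant behaves on deep-exponential data", {
  g <- negative_binomial_pmf(1, 1, 0.95)     # geometric: exactly exponential
  ds <- sample_cells(g, 2e4, seed = 45)
  fit <- estimate_decay_rate(ds, method = "ols")
  expect_lt(abs(fit$q_hat - 0.05), 0.15 * 0.05)
  expect_identical(fit$method, "ols")
})

test_that("feedback inference recovers all three topologies", {
  for (topo in c("none", "negative", "positive")) {
    cc <- class_circuit(topo)
    dist <- steady_state_distribution(cc$rf, cc$p, cc$d)
    ef <- feedback_coefficient_exact(dist, cc$rf)
    ds <- sample_cells(dist, 1e4, seed = 50 + match(topo, c("none",
                       "negative", "positive")), label = topo)
    inf <- infer_feedback(ds, B = 200, seed = 60)
    expect_identical(inf$call, topo)
    expect_false(inf$unreliable)
    # plug-in identity holds by construction
    expect_equal(inf$eta_f_hat + inf$feedback_free_hat, inf$eta_hat)
    expect_equal(inf$eta_hat, inf$var_hat / inf$mean_hat^2)
    if (topo != "none")
      expect_lt(abs(inf$eta_f_hat - ef), 4 * inf$se_eta_f)
  }
})

test_that("moderate-burst repressive circuit yields a negative estimate", {
  # outside the q << p regime (p = 0.7) the feedback-free plug-in retains
  # a finite-window bias, so only the sign of the point estimate is
  # asserted here
  rf <- hill_regulatory_function(200, 100, 5, 2)
  dist <- steady_state_distribution(rf, 0.7, 1)
  ds <- sample_cells(dist, 1e4, seed = 55)
  inf <- infer_feedback(ds, B = 100, seed = 56)
  expect_lt(inf$eta_f_hat, 0)
  expect_identical(inf$call, "negative")
})

test_that("estimator consistency: error shrinks with sample size", {
  cc <- class_negative()
  dist <- steady_state_distribution(cc$rf, cc$p, cc$d)
  ef <- feedback_coefficient_exact(dist, cc$rf)
  med_err <- sapply(c(1e3, 1e4, 1e5), function(n) {
    errs <- sapply(1:8, function(i) {
      ds <- sample_cells(dist, n, seed = 700 + 13 * i + n / 1000)
      mom <- estimate_moments(ds)
      fit <- estimate_decay_rate(ds)
      abs(mom$var_hat / mom$mean_hat^2 -
            1 / (fit$q_hat * mom$mean_hat) - ef)
    })
    median(errs)
  })
  expect_lt(med_err[3], med_err[1])
  expect_lt(med_err[2], 2 * med_err[1])  # monotone within noise
})

test_that("panel analysis isolates failures and matches single inference", {
  cc <- class_none()
  dist <- steady_state_distribution(cc$rf, cc$p, cc$d)
  good <- sample_cells(dist, 5000, seed = 71, label = "ok")
  bad <- single_cell_dataset(rep(3, 600), label = "constant")
  panel <- analyze_panel(list(good, bad), B = 50, seed = 5)
  expect_equal(nrow(panel), 2)
  expect_identical(panel$call[1], "none")
  expect_true(is.na(panel$eta_f_hat[2]))
  expect_match(panel$error[2], "constant|undefined")
  single <- infer_feedback(good, B = 50, seed = 5)
  expect_equal(panel$eta_f_hat[1], single$eta_f_hat)
})

test_that("datasets load from one-column and long-format files", {
  path1 <- tempfile(fileext = ".csv")
  writeLines(c("value", "1", "2", "3"), path1)
  d1 <- read_datasets(path1)
  expect_length(d1, 1)
  expect_equal(d1[[1]]$values, c(1, 2, 3))
  path2 <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(condition = rep(c("a", "b"), each = 3),
                                value = 1:6),
                     path2, sep = "\t", quote = FALSE, row.names = FALSE)
  d2 <- read_datasets(path2)
  expect_length(d2, 2)
  expect_identical(d2[[2]]$label, "b")
  expect_equal(d2[[2]]$values, c(4, 5, 6))
})
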