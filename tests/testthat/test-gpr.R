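test_that("SE kernel matches its closed form and is PSD on the training grid", {
  th <- hyperparams(0, 0, log(0.5)) # l = 1, sigma_f = 1, sigma_n = 0.5
  expect_equal(se_kernel(0, 0, th), matrix(1), tolerance = 1e-12)
  expect_equal(se_kernel(0, 1, th), matrix(exp(-0.5)), tolerance = 1e-12)
  # noise only on the diagonal, only for the identical grid
  K <- se_kernel(c(0, 1), c(0, 1), th, include_noise = TRUE)
  expect_equal(diag(K), rep(1 + 0.25, 2), tolerance = 1e-12)
  expect_equal(K[1, 2], exp(-0.5), tolerance = 1e-12)
  expect_equal(se_kernel(c(0, 1), c(0, 1.5), th, include_noise = TRUE)[1, 1],
               1, tolerance = 1e-12)

  set.seed(42)
  for (rep in 1:10) {
    t <- sort(runif(6, 0, 100))
    th2 <- hyperparams(runif(1, -5, -1), runif(1, -1, 0.5), runif(1, -3, -0.5))
    Kn <- se_kernel(t, t, th2, include_noise = TRUE)
    sn2 <- theta_linear(th2)[["sigma_n2"]]
    expect_gte(min(eigen(Kn, symmetric = TRUE, only.values = TRUE)$values),
               sn2 - 1e-10)
  }
  expect_error(se_kernel(c(0, NA), 1, th), class = "phenofill_invalid_input")
})

test_that("log marginal likelihood matches dense-algebra oracles", {
  # n = 1: data-fit term vanishes for y = 0
  th <- hyperparams(-2, log(0.8), log(0.3))
  ts1 <- time_series(0, 0)
  expect_equal(log_marginal_likelihood(ts1, th),
               -0.5 * log(0.8^2 + 0.3^2) - 0.5 * log(2 * pi),
               tolerance = 1e-12)
  # n = 2 toy against explicit 2x2 inverse/determinant
  th2 <- hyperparams(0, 0, log(0.1))
  ts2 <- time_series(c(0, 1), c(1, -1))
  orc <- dense_gp_oracle(c(0, 1), c(1, -1), numeric(0), 0, 0, log(0.1))
  expect_equal(log_marginal_likelihood(ts2, th2), orc$lml, tolerance = 1e-10)
  # random problems
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(3:30, 1)
    t <- sort(runif(n, 0, 500))
    y <- rnorm(n)
    v <- c(runif(1, -5, -1), runif(1, -1, 0.5), runif(1, -2.5, -0.5))
    orc <- dense_gp_oracle(t, y, numeric(0), v[1], v[2], v[3])
    expect_equal(log_marginal_likelihood(time_series(t, y), theta_from_vector(v)),
                 orc$lml, tolerance = 1e-8)
  }
})

test_that("analytic gradient agrees with central finite differences", {
  set.seed(101)
  worst <- 0
  for (rep in 1:30) {
    n <- sample(4:20, 1)
    t <- sort(runif(n, 0, 600))
    y <- rnorm(n)
    th <- hyperparams(runif(1, -5, -1.5), runif(1, -1.5, 0.5), runif(1, -2.5, -0.5))
    ts <- time_series(t, y)
    g <- lml_gradient(ts, th)
    fd <- fd_gradient(ts, th)
    rel <- max(abs(g - fd) / pmax(abs(fd), 1e-6))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-4)
  # zero observations: gradient still matches FD (pure complexity term)
  ts0 <- time_series(c(0, 30, 60, 90), rep(0, 4))
  th0 <- hyperparams(-3, -0.5, -1.5)
  expect_equal(as.numeric(lml_gradient(ts0, th0)), fd_gradient(ts0, th0),
               tolerance = 1e-5)
})

test_that("fit_gpr produces a valid factorization and weight vector", {
  th <- hyperparams(-2.5, log(0.9), log(0.2))
  lin <- theta_linear(th)
  # scalar case: alpha = y / (sf2 + sn2)
  f1 <- fit_gpr(time_series(0, 2), th, min_obs = 1)
  expect_equal(f1$alpha, 2 / (lin[["sigma_f2"]] + lin[["sigma_n2"]]),
               tolerance = 1e-12)
  # n = 50 random series against dense solve
  set.seed(3)
  t <- sort(runif(50, 0, 800)); y <- rnorm(50)
  f <- fit_gpr(time_series(t, y), th)
  orc <- dense_gp_oracle(t, y, numeric(0), th$log_inv_l, th$log_sigma_f,
                         th$log_sigma_n)
  expect_equal(f$alpha, orc$alpha, tolerance = 1e-8)
  # factorization reproduces C
  C <- se_kernel(t, t, th) + diag(lin[["sigma_n2"]], 50)
  expect_equal(crossprod(f$chol_upper), C + diag(f$jitter_used, 50),
               tolerance = 1e-10)
  # determinism
  f2 <- fit_gpr(time_series(t, y), th)
  expect_identical(f$alpha, f2$alpha)
  # insufficient data
  expect_error(fit_gpr(time_series(c(0, 1), c(1, 2)), th),
               class = "phenofill_insufficient_data")
})

test_that("escalating jitter rescues near-singular covariances", {
  th <- hyperparams(0, 0, -20) # near-zero noise
  ts <- time_series(c(0, 1e-8, 1, 2), c(1, 1, 0, 0))
  f <- fit_gpr(ts, th)
  expect_gt(f$jitter_used, 0)
  expect_true(all(is.finite(f$alpha)))
})

test_that("predictive mean and variance match the dense oracle", {
  set.seed(12)
  worst_m <- 0; worst_v <- 0
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    t <- sort(runif(n, 0, 700)); y <- rnorm(n, sin(t / 50), 0.3)
    v <- c(runif(1, -4.5, -2), runif(1, -1, 0.5), runif(1, -2.5, -1))
    th <- theta_from_vector(v)
    ts <- sort(runif(15, -50, 750))
    p <- predict(fit_gpr(time_series(t, y), th), ts)
    orc <- dense_gp_oracle(t, y, ts, v[1], v[2], v[3])
    worst_m <- max(worst_m, max(abs(p$mean - orc$mean)))
    worst_v <- max(worst_v, max(abs(p$sd^2 - orc$var)))
  }
  expect_lt(worst_m, 1e-8)
  expect_lt(worst_v, 1e-8)
})

test_that("noise-free GP interpolates and reverts to the prior far away", {
  th <- hyperparams(log(1 / 20), log(1.5), -20)
  t <- seq(0, 120, by = 15); y <- sin(t / 25)
  fit <- fit_gpr(time_series(t, y), th)
  p <- predict(fit, t)
  expect_equal(p$mean, y, tolerance = 1e-8)
  lin <- theta_linear(th)
  far <- predict(fit, c(-5000, 5000))
  expect_equal(far$mean, c(0, 0), tolerance = 1e-6)
  expect_equal(far$sd^2, rep(lin[["sigma_f2"]] + lin[["sigma_n2"]], 2),
               tolerance = 1e-6)
  # single training point closed form: mean(t*) = y * k(t*,0)/(sf2+sn2)
  th1 <- hyperparams(log(1 / 3), 0, -20)
  f1 <- fit_gpr(time_series(0, 2), th1, min_obs = 1)
  tt <- c(-2, 0, 1, 4)
  expect_equal(predict(f1, tt)$mean, 2 * exp(-tt^2 / (2 * 9)) /
                 (1 + exp(2 * -20)), tolerance = 1e-8)
})

test_that("predictive sd is bounded by the prior and non-negative", {
  set.seed(5)
  th <- hyperparams(-3, -0.3, -1.5)
  lin <- theta_linear(th)
  t <- sort(runif(40, 0, 500)); y <- rnorm(40)
  p <- predict(fit_gpr(time_series(t, y), th), seq(-100, 600, by = 7))
  expect_true(all(p$sd >= 0))
  expect_true(all(p$sd^2 <= lin[["sigma_f2"]] + lin[["sigma_n2"]] + 1e-10))
})
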