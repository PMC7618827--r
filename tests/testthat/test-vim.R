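test_that("theta estimator reproduces the hand-computed example", {
  r <- theta_estimate(phi = c(2, 0), tau = c(1, 0), tau_s = c(0.5, 0.5))
  expect_equal(r$estimate, 0.75)
  expect_equal(r$ic_uncentered, c(1.25, 0.25))
  expect_equal(r$se, sqrt(0.125))
  expect_equal(r$ci, 0.75 + c(-1, 1) * qnorm(0.975) * sqrt(0.125))
})

test_that("cross-form algebraic identity holds to machine precision", {
  set.seed(3)
  for (i in 1:20) {
    n <- 50
    phi <- rnorm(n); tau <- rnorm(n); tau_s <- rnorm(n)
    r <- theta_estimate(phi, tau, tau_s)
    alt <- mean((tau - tau_s) * (2 * phi - tau - tau_s))
    expect_equal(r$estimate, alt)
    # estimating-equation identity: estimate is exactly the mean IC
    expect_identical(r$estimate, mean(r$ic_uncentered))
  }
})

test_that("identical CATE and subset CATE give a degenerate zero estimate", {
  tau <- rnorm(30)
  r <- theta_estimate(rnorm(30), tau, tau)
  expect_equal(r$estimate, 0)
  expect_equal(r$se, 0)
})

test_that("theta estimator validates inputs", {
  expect_error(theta_estimate(1:3, 1:2, 1:3), "equal length")
  expect_error(theta_estimate(c(1, NaN), c(1, 2), c(1, 2)), "NaN")
  expect_error(theta_estimate(1, 1, 1), "two observations")
})

test_that("scalar tau_s yields the VTE estimator", {
  phi <- c(2, 0); tau <- c(1, 0)
  r <- theta_estimate(phi, tau, mean(phi))
  expect_equal(r$estimand, "theta_p")
  expect_equal(r$ic_uncentered, (phi - 1)^2 - (phi - tau)^2)
})

test_that("psi estimator is the exact ratio with the stated IC variance", {
  # proportional uncentered ICs give a zero-variance ratio: psi = 0.75/1.5
  th_s <- tevim:::new_vim_result("theta_s", c(1.25, 0.25))
  th_p <- tevim:::new_vim_result("theta_p", c(2.5, 0.5))
  ps <- psi_estimate(th_s, th_p)
  expect_equal(ps$estimate, 0.5)
  expect_equal(ps$se, 0)

  same <- psi_estimate(th_p, th_p)
  expect_equal(same$estimate, 1)
  expect_equal(same$se, 0)

  # zero importance with a degenerate IC gives psi exactly 0
  th0 <- tevim:::new_vim_result("theta_s", rep(0, 2))
  expect_equal(psi_estimate(th0, th_p)$estimate, 0)
})

test_that("negative and zero VTE are flagged or rejected", {
  phi <- rnorm(20); tau <- rnorm(20)
  th_s <- theta_estimate(phi, tau, tau + 0.1)
  th_neg <- theta_estimate(phi, tau, mean(phi))
  th_neg$estimate <- -0.5
  expect_match(psi_estimate(th_s, th_neg)$flags, "negative-VTE", all = FALSE)
  th_zero <- th_neg; th_zero$estimate <- 0
  expect_error(psi_estimate(th_s, th_zero), "zero")
})

test_that("transformed intervals match the delta method and stay in range", {
  r <- theta_estimate(c(2, 0), c(1, 0), c(0.5, 0.5))
  r$estimate <- 1.0; r$se <- 0.5
  ci <- transformed_ci(r, "log")
  expect_equal(ci$lo, exp(-qnorm(0.975) * 0.5))
  expect_equal(ci$hi, exp(qnorm(0.975) * 0.5))
  expect_gt(ci$lo, 0)

  r$se <- 0
  ci0 <- transformed_ci(r, "log")
  expect_equal(c(ci0$lo, ci0$hi), c(1, 1))

  r$estimate <- -0.1
  bad <- transformed_ci(r, "logit")
  expect_true(is.na(bad$lo))
  expect_match(bad$flag, "domain")

  r$estimate <- 0.3; r$se <- 0.2
  cl <- transformed_ci(r, "logit")
  expect_true(cl$lo > 0 && cl$hi < 1)
})

test_that("VTE estimator is orthogonal to the ATE plug-in at the AIPW value", {
  set.seed(12)
  phi <- rnorm(200, 1); tau <- rnorm(200)
  tau_p_star <- mean(phi)
  base <- theta_estimate(phi, tau, tau_p_star)$estimate
  for (delta in c(0.5, 0.1, 0.01, -0.2)) {
    pert <- theta_estimate(phi, tau, tau_p_star + delta)$estimate
    # first-order term vanishes: the change is exactly delta^2
    expect_equal(pert - base, delta^2)
  }
})

test_that("oracle inputs on DGP 3 recover analytic truths within 3 SEs", {
  d <- generate_dgp(3, 1e5, seed = 101)
  o <- attr(d, "oracle")
  phi <- oracle_phi(d)
  truth <- dgp_truth(3)
  for (s in list(1L, 2L, 4L, 5L)) {
    tau_s <- oracle_tau_s_dgp3(d$x, s)
    r <- theta_estimate(phi, o$tau, tau_s)
    tv <- truth$theta_s[[tevim:::subset_key(s)]]
    expect_lt(abs(r$estimate - tv), 3 * max(r$se, 1e-12) + 1e-8)
  }
})

test_that("population TE-VIMs are monotone in the subset ordering", {
  truth <- dgp_truth(3, subsets = list(1L, c(1L, 2L), c(1L, 2L, 3L), 1:6))
  th <- truth$theta_s
  expect_true(all(diff(th) >= -1e-12))
  expect_equal(unname(th[["1,2,3,4,5,6"]]), truth$theta_p)
})
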