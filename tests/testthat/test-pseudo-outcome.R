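test_that("pseudo-outcome reproduces hand-computed values", {
  # y = mu(a,x): only the regression difference remains
  expect_equal(pseudo_outcome(1, 1, 1, 0.3, 0.7), 0.7)
  # (2 - 1) * 0.6 / 0.24 + 0.5
  expect_equal(pseudo_outcome(2, 1, 1, 0.5, 0.4), 3.0)
  # (1 - 0) * (-0.5) / 0.25 + 0.5
  expect_equal(pseudo_outcome(1, 0, 0.5, 0, 0.5), -1.5)
})

test_that("pseudo-outcome rejects boundary propensities and non-binary A", {
  expect_error(pseudo_outcome(1, 1, 0, 0, 0), "positivity")
  expect_error(pseudo_outcome(1, 1, 0, 0, 1), "positivity")
  expect_error(pseudo_outcome(1, 2, 0, 0, 0.5), "binary")
})

test_that("nuisance fitting honours known propensities and per-arm means", {
  d <- tiny_data()
  nuis <- fit_nuisances(d, learner_spec("mean"), propensity = 0.48)
  ev <- tevim:::eval_nuisances(nuis, d, 1:4)
  expect_equal(ev$pi, rep(0.48, 4))
  expect_equal(ev$mu1, rep(2, 4))
  expect_equal(ev$mu0, rep(0, 4))
  expect_true(nuis$known_propensity)

  expect_error(fit_nuisances(d, learner_spec("mean"), propensity = 1.2),
               "strictly in")
  d1 <- te_data(y = 1:4, a = rep(1, 4), x = matrix(rnorm(4)))
  expect_error(fit_nuisances(d1, learner_spec("mean"), propensity = 0.5),
               "single treatment arm")
})

test_that("fitted propensities are clipped with a warning", {
  set.seed(1)
  n <- 200
  x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "X1"))
  a <- rbinom(n, 1, plogis(6 * x[, 1]))  # near-deterministic assignment
  if (length(unique(a)) < 2) a[1:2] <- c(0, 1)
  d <- te_data(y = rnorm(n), a = a, x = x)
  nuis <- fit_nuisances(d, learner_spec("mean"),
                        propensity_learner = learner_spec("lm"), clip = 0.05)
  expect_warning(nuis$predict_pi(x), "clipping")
  ev <- tevim:::eval_nuisances(nuis, d, 1:n)  # records the fraction silently
  expect_true(all(ev$pi >= 0.05 & ev$pi <= 0.95))
  expect_gt(ev$clip_frac, 0)
})

test_that("AIPW ATE has the estimating-equation form and IC variance", {
  r <- aipw_ate(c(1, 2, 3))
  expect_equal(r$estimate, 2)
  expect_equal(r$se, sqrt(2) / 3)
  expect_equal(mean(r$ic_uncentered), r$estimate)

  rc <- aipw_ate(rep(1.7, 5))
  expect_equal(rc$estimate, 1.7)
  expect_equal(rc$se, 0)

  # two-row randomized design with zero outcome model: difference in means
  phi <- pseudo_outcome(c(1, 0), c(1, 0), 0, 0, 0.5)
  expect_equal(phi, c(2, 0))
  expect_equal(aipw_ate(phi)$estimate, 1)
})

test_that("mean pseudo-outcome with oracle nuisances is unbiased for the ATE", {
  d <- generate_dgp(1, 1e5, seed = 31)
  r <- aipw_ate(oracle_phi(d))
  truth <- dgp_truth(1)
  expect_lt(abs(r$estimate - truth$tau_p), 3 * r$se)
})

test_that("the pseudo-outcome mean is doubly robust", {
  # one nuisance wrong-but-fixed, the other oracle
  d <- generate_dgp(1, 4e4, seed = 77)
  o <- attr(d, "oracle")
  truth <- dgp_truth(1)
  # wrong outcome model (identically zero), oracle propensity
  r1 <- aipw_ate(pseudo_outcome(d$y, d$a, 0, 0, o$pi))
  expect_lt(abs(r1$estimate - truth$tau_p), 4 * r1$se)
  # wrong propensity (constant 0.3), oracle outcome model
  r2 <- aipw_ate(pseudo_outcome(d$y, d$a, o$mu1, o$mu0, 0.3))
  expect_lt(abs(r2$estimate - truth$tau_p), 4 * r2$se)
})

test_that("continuous-treatment pseudo-outcome reduces to the binary form", {
  set.seed(8)
  for (i in 1:100) {
    mu1 <- rnorm(1); mu0 <- rnorm(1); pi <- runif(1, 0.05, 0.95)
    y <- rnorm(1)
    for (a in 0:1) {
      mu_x <- pi * mu1 + (1 - pi) * mu0
      got <- continuous_pseudo_outcome(y, a, mu_x, mu1 - mu0, pi,
                                       pi * (1 - pi))
      expect_equal(got, pseudo_outcome(y, a, mu1, mu0, pi))
    }
  }
})

test_that("continuous pseudo-outcome handles direct evaluations and errors", {
  # noise-free linear outcome returns lambda exactly
  expect_equal(continuous_pseudo_outcome(y = 0.5 + 0.5 * (2 - 1), a = 2,
                                         mu_x = 0.5, lambda_x = 0.5,
                                         pi_x = 1, var_a_x = 4), 0.5)
  expect_equal(continuous_pseudo_outcome(1, 2, 0, 0.5, 1, 4), 0.625)
  expect_error(continuous_pseudo_outcome(1, 1, 0, 0, 0.5, 0), "positive")
})
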