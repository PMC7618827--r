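test_that("generation is reproducible and validates its arguments", {
  d1 <- generate_dgp(1, 100, seed = 9)
  d2 <- generate_dgp(1, 100, seed = 9)
  expect_identical(d1$y, d2$y)
  expect_identical(d1$x, d2$x)
  expect_error(generate_dgp(4, 10), "unknown DGP")
})

test_that("DGP 1 marginals match their stated laws", {
  d <- generate_dgp(1, 1e5, seed = 17)
  expect_true(all(d$x >= -1 & d$x <= 1))
  # E[A] from 2-d Gauss-Legendre quadrature of expit(-0.4 x1 + 0.1 x1 x2)
  gl <- pracma::gaussLegendre(40, -1, 1)
  EA <- sum(outer(gl$w, gl$w) *
              outer(gl$x, gl$x, function(u, v) plogis(-0.4 * u + 0.1 * u * v))) / 4
  mcse <- sqrt(EA * (1 - EA) / d$n)
  expect_lt(abs(mean(d$a) - EA), 3 * mcse)
  # outcome noise has unit variance around its conditional mean
  o <- attr(d, "oracle")
  resid <- d$y - (o$mu0 + d$a * o$tau)
  expect_equal(sd(resid), 1, tolerance = 0.02)
})

test_that("DGP 3 covariance blocks and noise scale are as specified", {
  d <- generate_dgp(3, 1e5, seed = 23)
  C <- cor(d$x)
  expect_equal(C["X1", "X2"], 0.5, tolerance = 0.02)
  expect_equal(C["X3", "X4"], 0.5, tolerance = 0.02)
  expect_equal(C["X5", "X6"], 0.5, tolerance = 0.02)
  expect_lt(abs(C["X2", "X3"]), 0.02)
  expect_equal(apply(d$x, 2, sd), rep(1, 6), tolerance = 0.02,
               ignore_attr = TRUE)
  o <- attr(d, "oracle")
  expect_equal(sd(d$y - (o$mu0 + d$a * o$tau)), sqrt(3), tolerance = 0.02)
  # propensity depends on X5 even though the CATE does not
  expect_gt(abs(cor(o$pi, d$x[, "X5"])), 0.2)
})

test_that("closed-form truths reproduce the printed population values", {
  t1 <- dgp_truth(1)
  expect_equal(round(t1$tau_p, 2), 1.39)
  expect_equal(round(t1$theta_p, 3), 1.003)
  expect_equal(round(unname(t1$theta_s[c("1", "2")]), 2), c(0.32, 0.69))
  expect_equal(round(unname(t1$psi_s[c("1", "2")]), 2), c(0.32, 0.68))

  t2 <- dgp_truth(2)
  expect_equal(round(t2$tau_p, 3), 0.139)
  expect_equal(round(t2$theta_p, 5), 0.01003)
  expect_equal(round(unname(t2$theta_s[c("1", "2")]), 4), c(0.0032, 0.0069))
  expect_equal(round(unname(t2$psi_s[c("1", "2")]), 2), c(0.32, 0.68))

  t3 <- dgp_truth(3)
  expect_equal(t3$theta_p, 8)
  expect_equal(t3$table$loo, c(0.75, 3, 0.75, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(t3$table$koi, c(4, 6.25, 1, 0.25, 0, 0), ignore_attr = TRUE)
})

test_that("truth tables are internally consistent", {
  for (dgp in 1:3) {
    tt <- dgp_truth(dgp)
    expect_equal(tt$psi_s, tt$theta_s / tt$theta_p)
    expect_true(all(tt$theta_s >= -1e-12 & tt$theta_s <= tt$theta_p + 1e-12))
  }
  expect_equal(sum(dgp_truth(3)$table$shapley), dgp_truth(3)$theta_p)
})

test_that("Monte-Carlo oracle corroborates the closed forms", {
  mc1 <- dgp_truth_mc(1, list(1L, 2L, 1:2), draws = 4e5, seed = 19)
  t1 <- dgp_truth(1)
  expect_equal(mc1$tau_p, t1$tau_p, tolerance = 0.01)
  expect_equal(unname(mc1$theta_s[c("1", "2")]),
               unname(t1$theta_s[c("1", "2")]), tolerance = 0.02)
  mc3 <- dgp_truth_mc(3, list(1L, 4L, setdiff(1:6, 2)), draws = 4e5, seed = 19)
  t3 <- dgp_truth(3, subsets = list(1L, 4L, setdiff(1:6, 2)))
  expect_equal(unname(mc3$theta_s), unname(t3$theta_s), tolerance = 0.05)
})

test_that("the study runner aggregates estimates against the truth", {
  lrn <- list(outcome = lm_dgp1(), propensity = lm_prop1(),
              cate = lm_dgp1(), projection = lm_dgp1())
  st <- run_study(1, n = 400, n_reps = 4, algorithms = c("noSS-A", "SS-A"),
                  K = c("SS-A" = 2L), learners = lrn, seed = 33)
  expect_s3_class(st, "te_study")
  s <- st$summary
  expect_setequal(unique(s$algorithm), c("noSS-A", "SS-A"))
  expect_true(all(s$coverage >= 0 & s$coverage <= 1))
  expect_true(all(s$n_reps == 4))
  expect_equal(st$n_failed, 0L)
  expect_true(all(st$ranking$ranking_accuracy >= 0 &
                    st$ranking$ranking_accuracy <= 1))
  # truths attached per estimand
  expect_equal(unique(s$truth[s$estimand == "theta_p"]), dgp_truth(1)$theta_p)
})
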