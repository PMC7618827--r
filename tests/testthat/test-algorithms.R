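# shared small dataset and fast correctly-specified learners
alg_data <- function(n = 600, seed = 3) generate_dgp(1, n, seed = seed)

alg_args <- function() {
  list(outcome_learner = lm_dgp1(), propensity_learner = lm_prop1(),
       cate_learner = lm_dgp1(), projection_learner = lm_dgp1())
}

test_that("noSS pipelines perform the expected number of regression fits", {
  d <- alg_data()
  fa <- do.call(tevim, c(list(d, algorithm = "noSS-A", mode = "loo", seed = 1),
                         alg_args()))
  counts <- table(fa$fit_log$role)
  expect_equal(unname(counts[["outcome"]]), 1L)
  expect_equal(unname(counts[["propensity"]]), 1L)
  expect_equal(sum(grepl("^projection", fa$fit_log$role)), 2L)
  expect_false(any(fa$fit_log$role == "cate"))

  fb <- do.call(tevim, c(list(d, algorithm = "noSS-B", mode = "loo", seed = 1),
                         alg_args()))
  expect_equal(sum(fb$fit_log$role == "cate"), 1L)
})

test_that("SS-A performs O(K) fits and satisfies the cross-fitting contract", {
  d <- alg_data()
  K <- 8L
  fit <- do.call(tevim, c(list(d, algorithm = "SS-A", K = K, mode = "custom",
                               subsets = list(1L), seed = 2), alg_args()))
  expect_equal(sum(fit$fit_log$role == "outcome"), K)
  expect_equal(sum(grepl("^projection", fit$fit_log$role)), K)
  expect_true(check_crossfit(fit))
  # every row's provenance excludes its own fold
  own <- fit$scheme$assignment
  expect_false(any(vapply(seq_len(d$n), function(i)
    own[i] %in% fit$phi$provenance[[i]], logical(1))))
})

test_that("SS-B pairs folds, averages K-1 pseudo-outcomes, costs O(K^2)", {
  d <- alg_data()
  for (K in c(3L, 4L)) {
    fit <- do.call(tevim, c(list(d, algorithm = "SS-B", K = K, mode = "custom",
                                 subsets = list(1L), seed = 4), alg_args()))
    expect_equal(sum(fit$fit_log$role == "outcome"), K * (K - 1L) / 2L)
    expect_equal(sum(fit$fit_log$role == "cate"), K)
    expect_true(check_crossfit(fit))
  }
})

test_that("fold-count preconditions are enforced", {
  d <- alg_data(200)
  expect_error(do.call(tevim, c(list(d, algorithm = "SS-A", K = 1), alg_args())),
               "K >= 2")
  expect_error(do.call(tevim, c(list(d, algorithm = "SS-B", K = 2), alg_args())),
               "K >= 3")
  expect_error(do.call(tevim, c(list(d, algorithm = "noSS-A", K = 3), alg_args())),
               "K = 1")
})

test_that("an outcome independent of treatment and covariates yields null TE-VIMs", {
  set.seed(5)
  n <- 400
  d <- te_data(y = rnorm(n), a = rbinom(n, 1, 0.5),
               x = matrix(rnorm(2 * n), n, 2,
                          dimnames = list(NULL, c("X1", "X2"))))
  fit <- tevim(d, algorithm = "noSS-A", mode = "loo",
               outcome_learner = learner_spec("mean"),
               propensity_learner = learner_spec("mean"),
               projection_learner = learner_spec("mean"), seed = 6)
  # constant learners can represent no heterogeneity at all
  expect_equal(fit$results$theta_p$estimate, 0)
  for (r in fit$results$theta_s) expect_equal(r$estimate, 0)
})

test_that("identical seeds reproduce a run exactly; estimands are coherent", {
  d <- alg_data(400)
  f1 <- do.call(tevim, c(list(d, algorithm = "SS-A", K = 3, seed = 11),
                         alg_args()))
  f2 <- do.call(tevim, c(list(d, algorithm = "SS-A", K = 3, seed = 11),
                         alg_args()))
  expect_equal(as.data.frame(f1), as.data.frame(f2))

  # psi = theta_s / theta_p exactly; estimating-equation identity per result
  for (nm in names(f1$results$theta_s)) {
    th <- f1$results$theta_s[[nm]]
    ps <- f1$results$psi_s[[nm]]
    expect_identical(th$estimate, mean(th$ic_uncentered))
    expect_equal(ps$estimate, th$estimate / f1$results$theta_p$estimate)
  }
  expect_identical(f1$results$ate$estimate, mean(f1$phi$phi))
})

test_that("known propensity bypasses propensity fitting", {
  d <- alg_data(300)
  fit <- tevim(d, algorithm = "noSS-A", propensity = 0.48,
               outcome_learner = lm_dgp1(), projection_learner = lm_dgp1(),
               seed = 3)
  expect_false(any(fit$fit_log$role == "propensity"))
})

test_that("shapley mode attributions sum to the VTE estimate", {
  d <- generate_dgp(3, 500, seed = 41)
  lml <- learner_spec("lm")
  fit <- tevim(d, algorithm = "noSS-A", mode = "shapley",
               outcome_learner = lml, propensity_learner = lml,
               projection_learner = lml, seed = 8)
  tab <- fit$mode_report$table
  expect_equal(sum(tab$estimate), fit$results$theta_p$estimate)
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$se >= 0))
})
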