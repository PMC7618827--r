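#' Replicated simulation study
#'
#' Generates `n_reps` datasets from a benchmark DGP, runs each requested
#' algorithm on every replicate, and aggregates bias, empirical SD, Wald CI
#' coverage and (for DGPs 1-2) the ranking accuracy — the fraction of
#' replicates in which \eqn{\hat\Theta_2 > \hat\Theta_1}, i.e. the second
#' covariate is correctly ranked as the more important. Monte-Carlo standard
#' errors accompany every aggregate. Replicate-level failures are caught and
#' counted; more than 10\% failures aborts the study.
#'
#' @param dgp 1, 2 or 3.
#' @param n sample size per replicate.
#' @param n_reps number of replicates (>= 2).
#' @param algorithms character vector of pipeline names (see [tevim()]).
#' @param K named integer vector/list of fold counts per algorithm, or a
#'   single value; defaults to 1 for noSS pipelines and 8 / 3 for SS-A /
#'   SS-B.
#' @param mode comparison mode passed to [tevim()] (default `"loo"`).
#' @param learners named list with entries `outcome`, `propensity`, `cate`,
#'   `projection` ([learner_spec()]s); a single spec is recycled to all
#'   roles.
#' @param level CI level.
#' @param seed top-level seed; replicate r uses a seed derived from it.
#' @param verbose print a progress line every 25 replicates.
#' @return An object of class `te_study`: list with `summary` (one row per
#'   estimand x algorithm: truth, bias, bias MC-SE, empirical SD, coverage,
#'   coverage MC-SE), `ranking` (per algorithm, DGPs 1-2), `replicates`
#'   (raw per-replicate estimates) and `n_failed`.
#' @export
run_study <- function(dgp, n, n_reps, algorithms = c("noSS-A", "SS-A"),
                      K = NULL, mode = "loo",
                      learners = learner_spec("gam", k = 5),
                      level = 0.95, seed = 1L, verbose = FALSE) {
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (inherits(learners, "learner_spec"))
    learners <- list(outcome = learners, propensity = learners,
                     cate = learners, projection = learners)
  default_K <- c("noSS-A" = 1L, "noSS-B" = 1L, "SS-A" = 8L, "SS-B" = 3L)
  Kmap <- default_K[algorithms]
  if (!is.null(K)) {
    if (is.null(names(K))) Kmap[] <- as.integer(K)
    else Kmap[names(K)] <- as.integer(unlist(K))
  }

  truth <- dgp_truth(dgp)
  p <- truth$p
  subsets <- subsets_for_mode(p, mode)
  keys <- vapply(subsets, subset_key, "")
  truth_theta <- truth$theta_s[keys]
  truth_psi <- truth$psi_s[keys]

  rep_seeds <- derive_seeds(seed, 2L * n_reps)
  rows <- list()
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    d <- generate_dgp(dgp, n, seed = rep_seeds[r])
    for (alg in algorithms) {
      res <- tryCatch(
        tevim(d, algorithm = alg, mode = mode, K = Kmap[[alg]],
              outcome_learner = learners$outcome,
              propensity_learner = learners$propensity,
              cate_learner = learners$cate,
              projection_learner = learners$projection,
              level = level, seed = rep_seeds[n_reps + r]),
        error = function(e) e)
      if (inherits(res, "error")) {
        n_failed <- n_failed + 1L
        if (n_failed > 0.1 * n_reps * length(algorithms))
          stop("more than 10% of replicate runs failed; last error: ",
               conditionMessage(res))
        next
      }
      df <- as.data.frame(res)
      df$rep <- r; df$algorithm <- alg; df$n <- n
      rows[[length(rows) + 1L]] <- df
    }
    if (verbose && r %% 25 == 0) message("replicate ", r, "/", n_reps)
  }
  reps <- do.call(rbind, rows)

  truth_for <- function(estimand, subset) {
    switch(estimand,
           ate = truth$tau_p,
           theta_p = truth$theta_p,
           theta_s = unname(truth_theta[label_to_key(subset)]),
           psi_s = unname(truth_psi[label_to_key(subset)]))
  }
  label_to_key <- function(lab)
    vapply(strsplit(lab, ","), function(v)
      subset_key(match(v, paste0("X", seq_len(p)))), "")

  agg <- do.call(rbind, lapply(
    split(reps, list(reps$estimand, reps$subset, reps$algorithm), drop = TRUE),
    function(g) {
      tv <- truth_for(g$estimand[1], g$subset[1])
      R <- nrow(g)
      cover <- mean(g$ci_lo <= tv & tv <= g$ci_hi)
      data.frame(estimand = g$estimand[1], subset = g$subset[1],
                 algorithm = g$algorithm[1], n = g$n[1], n_reps = R,
                 truth = tv,
                 bias = mean(g$estimate) - tv,
                 bias_mcse = sd(g$estimate) / sqrt(R),
                 sd = sd(g$estimate),
                 mean_se = mean(g$se),
                 coverage = cover,
                 coverage_mcse = sqrt(cover * (1 - cover) / R),
                 stringsAsFactors = FALSE)
    }))
  rownames(agg) <- NULL

  ranking <- NULL
  if (dgp %in% c(1, 2) && mode == "loo") {
    th <- reps[reps$estimand == "theta_s", ]
    ranking <- do.call(rbind, lapply(split(th, th$algorithm), function(g) {
      w <- merge(g[g$subset == "X1", c("rep", "estimate")],
                 g[g$subset == "X2", c("rep", "estimate")], by = "rep")
      acc <- mean(w$estimate.y > w$estimate.x)
      data.frame(algorithm = g$algorithm[1], n = n, n_reps = nrow(w),
                 ranking_accuracy = acc,
                 mcse = sqrt(acc * (1 - acc) / nrow(w)),
                 stringsAsFactors = FALSE)
    }))
    rownames(ranking) <- NULL
  }

  structure(list(dgp = dgp, n = n, n_reps = n_reps, summary = agg,
                 ranking = ranking, replicates = reps, n_failed = n_failed),
            class = "te_study")
}

#' @export
print.te_study <- function(x, ...) {
  cat("Simulation study: DGP", x$dgp, ", n =", x$n, ",", x$n_reps,
      "replicates (", x$n_failed, "failed )\n")
  print(x$summary, digits = 3)
  if (!is.null(x$ranking)) { cat("Ranking accuracy:\n"); print(x$ranking, digits = 3) }
  invisible(x)
}
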