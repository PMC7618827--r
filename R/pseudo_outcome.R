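#' AIPW pseudo-outcome
#'
#' The augmented inverse propensity weighted score
#' \deqn{\varphi(z) = \frac{\{y - \mu(a, x)\}(a - \pi(x))}{\pi(x)\{1 - \pi(x)\}}
#'   + \mu(1, x) - \mu(0, x),}
#' whose conditional mean given \eqn{X = x} equals the CATE \eqn{\tau(x)};
#' it plays the role of the never-observed individual treatment effect and
#' is the regression target of the DR-learner.
#'
#' @param y outcome value(s).
#' @param a treatment value(s) in \{0, 1\}.
#' @param mu1,mu0 outcome regression predictions \eqn{\mu(1,x)}, \eqn{\mu(0,x)}.
#' @param pi propensity score value(s), strictly inside (0, 1). Clipping, if
#'   any, must happen upstream (see [fit_nuisances()]); this function refuses
#'   boundary values.
#' @return Numeric vector of pseudo-outcome values.
#' @examples
#' pseudo_outcome(y = 2, a = 1, mu1 = 1, mu0 = 0.5, pi = 0.4)  # 3
#' @export
pseudo_outcome <- function(y, a, mu1, mu0, pi) {
  if (any(!is.finite(pi)) || any(pi <= 0) || any(pi >= 1))
    stop("positivity violation: propensity scores must lie strictly in (0, 1)")
  if (any(!(a %in% c(0, 1)))) stop("treatment must be binary {0,1}")
  mu_a <- a * mu1 + (1 - a) * mu0
  (y - mu_a) * (a - pi) / (pi * (1 - pi)) + mu1 - mu0
}

#' Pseudo-outcome for a continuous treatment
#'
#' Extends the binary-treatment pseudo-outcome to a continuous exposure via
#' the linear-projection CATE analogue
#' \eqn{\lambda(x) = cov(A, Y | X = x) / var(A | X = x)}:
#' \deqn{[y - \mu(x) - \lambda(x)\{a - \pi(x)\}]
#'   \frac{a - \pi(x)}{var(A | X = x)} + \lambda(x),}
#' with \eqn{\mu(x) = E(Y|X=x)} and \eqn{\pi(x) = E(A|X=x)}. For a binary
#' treatment with \eqn{var(A|X) = \pi(1-\pi)} this reduces exactly to
#' [pseudo_outcome()].
#'
#' @param y outcome value(s).
#' @param a treatment value(s), possibly continuous.
#' @param mu_x conditional mean outcome \eqn{E(Y | X = x)}.
#' @param lambda_x projection coefficient \eqn{\lambda(x)}.
#' @param pi_x conditional mean treatment \eqn{E(A | X = x)}.
#' @param var_a_x conditional treatment variance, strictly positive.
#' @return Numeric vector.
#' @export
continuous_pseudo_outcome <- function(y, a, mu_x, lambda_x, pi_x, var_a_x) {
  if (any(!is.finite(var_a_x)) || any(var_a_x <= 0))
    stop("var(A | X) must be strictly positive")
  resid <- y - mu_x - lambda_x * (a - pi_x)
  resid * (a - pi_x) / var_a_x + lambda_x
}

new_pseudo_outcomes <- function(phi, provenance) {
  stopifnot(length(provenance) == length(phi))
  if (anyNA(phi) || any(!is.finite(phi))) stop("non-finite pseudo-outcomes")
  structure(list(phi = phi, provenance = provenance, n = length(phi)),
            class = "pseudo_outcomes")
}

phi_values <- function(phi) {
  if (inherits(phi, "pseudo_outcomes")) phi$phi else as.numeric(phi)
}

#' @export
print.pseudo_outcomes <- function(x, ...) {
  cat("Pseudo-outcomes: n =", x$n, ", mean =", signif(mean(x$phi), 5),
      ", sd =", signif(sd(x$phi), 5), "\n")
  invisible(x)
}

#' Fit nuisance models (outcome regressions and propensity score)
#'
#' Fits \eqn{\hat\mu(a, \cdot)} and \eqn{\hat\pi(\cdot)} on the rows outside
#' `exclude`, following the T-learner default of two per-arm outcome
#' regressions (a single joint regression with the treatment as a feature is
#' available via `joint_outcome = TRUE`; the two are interchangeable for the
#' DR-learner pipeline). In randomized designs the propensity can be supplied
#' as a known constant (or per-row vector), bypassing propensity fitting
#' entirely. Propensity predictions are clipped to `[clip, 1 - clip]`.
#'
#' @param data a [te_data()] object.
#' @param outcome_learner [learner_spec()] for the outcome regressions.
#' @param propensity_learner [learner_spec()] for the propensity model;
#'   ignored when `propensity` is supplied.
#' @param propensity optional known propensity score: scalar in (0, 1) or a
#'   length-n vector.
#' @param scheme [make_folds()] scheme (defaults to the single-fold scheme).
#' @param exclude fold ids to hold out of training.
#' @param clip clipping bound \eqn{\epsilon} for fitted propensities
#'   (default 0.01); a warning reports the fraction clipped.
#' @param joint_outcome fit one outcome regression with A as a feature
#'   instead of two per-arm regressions.
#' @param seed learner seed.
#' @return An object of class `nuisance_fit` with closures `predict_mu1`,
#'   `predict_mu0`, `predict_pi` and the training-fold record `train_folds`.
#' @export
fit_nuisances <- function(data, outcome_learner,
                          propensity_learner = learner_spec("gam"),
                          propensity = NULL,
                          scheme = make_folds(data$n, 1L),
                          exclude = integer(0),
                          clip = 0.01, joint_outcome = FALSE, seed = 1L) {
  stopifnot(inherits(data, "te_data"))
  train <- which(!(scheme$assignment %in% exclude))
  if (!length(train)) stop("empty training set: all folds excluded")
  a_tr <- data$a[train]
  if (length(unique(a_tr)) < 2L)
    stop("training rows contain a single treatment arm; both arms are required")
  x <- data$x
  seeds <- derive_seeds(seed, 3L)

  if (joint_outcome) {
    xa <- cbind(x, .A = data$a)
    fit_out <- fit_predict_heldout(outcome_learner, xa, data$y, scheme, exclude,
                                   seed = seeds[1L])
    predict_mu1 <- function(newx) predict(fit_out, cbind(newx, .A = 1))
    predict_mu0 <- function(newx) predict(fit_out, cbind(newx, .A = 0))
    fits <- list(outcome = fit_out)
  } else {
    # per-arm regressions: restrict the scheme to each arm's rows
    fit_arm <- function(arm, s) {
      rows <- which(data$a == arm)
      sub <- structure(list(n = length(rows), K = scheme$K,
                            assignment = scheme$assignment[rows],
                            seed = scheme$seed), class = "fold_scheme")
      if (!any(!(sub$assignment %in% exclude)))
        stop("no arm-", arm, " rows outside the excluded folds")
      fit_predict_heldout(outcome_learner, x[rows, , drop = FALSE],
                          data$y[rows], sub, exclude, seed = s)
    }
    fit_mu1 <- fit_arm(1L, seeds[1L])
    fit_mu0 <- fit_arm(0L, seeds[2L])
    predict_mu1 <- function(newx) predict(fit_mu1, newx)
    predict_mu0 <- function(newx) predict(fit_mu0, newx)
    fits <- list(mu1 = fit_mu1, mu0 = fit_mu0)
  }

  if (!is.null(propensity)) {
    if (any(propensity <= 0) || any(propensity >= 1))
      stop("known propensity must lie strictly in (0, 1)")
    if (!length(propensity) %in% c(1L, data$n))
      stop("known propensity must be a scalar or a length-n vector")
    pi_known <- if (length(propensity) == 1L) rep(propensity, data$n) else propensity
    predict_pi <- function(newx, rows = NULL) {
      k <- if (is.null(rows)) rep(mean(pi_known), nrow(as.matrix(newx))) else pi_known[rows]
      structure(k, clip_frac = 0)
    }
    fit_pi <- NULL
  } else {
    fit_pi <- fit_predict_heldout(propensity_learner, x, data$a, scheme, exclude,
                                  binary = TRUE, seed = seeds[3L])
    predict_pi <- function(newx, rows = NULL) {
      p <- predict(fit_pi, newx)
      nclip <- sum(p < clip | p > 1 - clip)
      if (nclip > 0)
        warning(sprintf("propensity clipping: %d of %d predictions (%.1f%%) outside [%g, %g]",
                        nclip, length(p), 100 * nclip / length(p), clip, 1 - clip))
      structure(pmin(pmax(p, clip), 1 - clip), clip_frac = nclip / length(p))
    }
  }

  structure(list(predict_mu1 = predict_mu1, predict_mu0 = predict_mu0,
                 predict_pi = predict_pi,
                 train_folds = setdiff(seq_len(scheme$K), exclude),
                 clip_bounds = c(clip, 1 - clip),
                 known_propensity = !is.null(propensity),
                 fits = fits, fit_pi = fit_pi),
            class = "nuisance_fit")
}

# evaluate a nuisance fit on a row subset, returning phi / mu / pi
eval_nuisances <- function(nuis, data, rows) {
  xr <- data$x[rows, , drop = FALSE]
  mu1 <- nuis$predict_mu1(xr)
  mu0 <- nuis$predict_mu0(xr)
  pi <- suppressWarnings(nuis$predict_pi(xr, rows = rows))
  list(mu1 = mu1, mu0 = mu0, pi = as.numeric(pi),
       clip_frac = attr(pi, "clip_frac"),
       phi = pseudo_outcome(data$y[rows], data$a[rows], mu1, mu0, as.numeric(pi)))
}

#' AIPW estimator of the average treatment effect
#'
#' The sample mean of the pseudo-outcomes, with influence-curve standard
#' error \eqn{\sqrt{n^{-2} \sum_i (\hat\varphi_i - \hat\tau_p)^2}} and a Wald
#' confidence interval.
#'
#' @param phi pseudo-outcome values (numeric vector or the object produced
#'   by the estimation pipelines).
#' @param level confidence level (default 0.95).
#' @return A [vim_result] with `estimand = "ate"`.
#' @export
aipw_ate <- function(phi, level = 0.95) {
  v <- phi_values(phi)
  if (length(v) < 2L) stop("need at least two observations")
  new_vim_result(estimand = "ate", ic_uncentered = v, level = level,
                 subset_label = "")
}

# headroom below 2^31 so per-fold offsets never overflow integer range
derive_seeds <- function(seed, m) {
  withr::with_seed(seed, sample.int(2146000000L, m))
}
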