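#' T-learner CATE evaluations
#'
#' The difference of the two per-arm outcome regressions,
#' \eqn{\hat\tau^{(T)}(x) = \hat\mu(1, x) - \hat\mu(0, x)}, evaluated at the
#' supplied rows.
#'
#' @param nuis a [fit_nuisances()] object.
#' @param x covariate matrix of evaluation rows.
#' @return Numeric vector of CATE evaluations.
#' @export
t_learner <- function(nuis, x) {
  stopifnot(inherits(nuis, "nuisance_fit"))
  nuis$predict_mu1(x) - nuis$predict_mu0(x)
}

#' DR-learner: regress pseudo-outcomes on covariates
#'
#' Second stage of the DR-learner: the estimated pseudo-outcomes are
#' regressed on the covariates, giving a CATE estimator whose complexity is
#' controlled by the chosen learner's regularization. When the fold scheme
#' splits the data (`K > 1`), the cross-fitting contract is enforced: each
#' training row's pseudo-outcome must have been produced by nuisance models
#' whose training folds exclude every evaluation (held-out) fold.
#'
#' @param phi pseudo-outcomes: a `pseudo_outcomes` object (with provenance)
#'   or a bare numeric vector (no provenance check possible; accepted for
#'   single-sample use).
#' @param x covariate matrix (n rows).
#' @param learner [learner_spec()] for the regression.
#' @param scheme [make_folds()] scheme.
#' @param exclude fold ids held out of training (the folds the fit will be
#'   evaluated on).
#' @param seed learner seed.
#' @return A `cf_fit` predictor for \eqn{\hat\tau(\cdot)}.
#' @export
dr_learner <- function(phi, x, learner, scheme = make_folds(nrow(x), 1L),
                       exclude = integer(0), seed = 1L) {
  values <- phi_values(phi)
  if (inherits(phi, "pseudo_outcomes") && scheme$K > 1L && length(exclude)) {
    train <- which(!(scheme$assignment %in% exclude))
    bad <- vapply(phi$provenance[train],
                  function(pr) any(exclude %in% pr), logical(1))
    if (any(bad))
      stop("cross-fitting contract violated: ", sum(bad), " training pseudo-outcome(s) ",
           "were produced by nuisance fits trained on an evaluation fold (",
           paste(exclude, collapse = ","), ")")
  }
  fit_predict_heldout(learner, x, values, scheme, exclude, seed = seed)
}

#' Projection metalearner for subset CATEs
#'
#' Estimates \eqn{\tau_s(x) = E\{\tau(X) | X_{-s} = x_{-s}\}} by regressing
#' initial CATE evaluations on the retained covariates \eqn{X_{-s}}. This is
#' the recommended metalearner for subset CATEs: it handles runtime
#' confounding (where \eqn{Y \not\perp A | X_{-s}}) and keeps
#' \eqn{\hat\tau_s} approximately compatible with \eqn{\hat\tau}. The
#' alternative of regressing pseudo-outcomes directly on \eqn{X_{-s}} is
#' available by passing pseudo-outcome values as `tau_hat`.
#'
#' @param tau_hat per-row CATE evaluations (regression targets).
#' @param x full covariate matrix (n rows).
#' @param s integer indices of the covariates to drop; must be a nonempty
#'   proper subset of the columns. For the full covariate set the subset
#'   CATE is the constant ATE: use [aipw_ate()] and the scalar form of
#'   [theta_estimate()] instead.
#' @param learner [learner_spec()] for the projection regression.
#' @param scheme,exclude,seed as in [dr_learner()].
#' @return A `cf_fit` predictor for \eqn{\hat\tau_s(\cdot)}; its
#'   `predict()` accepts the full covariate matrix and ignores the dropped
#'   columns.
#' @export
project_cate <- function(tau_hat, x, s, learner,
                         scheme = make_folds(nrow(x), 1L),
                         exclude = integer(0), seed = 1L) {
  x <- as.matrix(x)
  p <- ncol(x)
  s <- sort(unique(as.integer(s)))
  if (!length(s)) stop("`s` must be nonempty; for s = {} the subset CATE is tau itself")
  if (length(setdiff(s, seq_len(p))))
    stop("`s` contains indices outside 1..p")
  if (length(s) == p)
    stop("s is the full covariate set: tau_s is the constant ATE; ",
         "use aipw_ate() / the scalar tau_s form of theta_estimate() instead")
  keep <- setdiff(seq_len(p), s)
  xk <- x[, keep, drop = FALSE]
  fit <- fit_predict_heldout(learner, xk, tau_hat, scheme, exclude, seed = seed)
  # wrap so prediction accepts the full matrix and provably ignores X_s
  structure(list(spec = fit$spec, train_folds = fit$train_folds,
                 n_train = fit$n_train, keep = keep, s = s,
                 .predict = function(newx) {
                   newx <- as.matrix(newx)
                   cols <- if (ncol(newx) == p) keep else seq_along(keep)
                   fit$.predict(newx[, cols, drop = FALSE])
                 }),
            class = "cf_fit")
}
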