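#' Construct a K-fold cross-fitting scheme
#'
#' Assigns `n` rows to `K` folds by a seeded uniform random permutation.
#' Fold sizes differ by at most one and regeneration with the same
#' `(n, K, seed)` reproduces the identical assignment. `K = 1` encodes
#' "no sample splitting": every row belongs to the single fold.
#'
#' @param n number of rows (positive integer).
#' @param K number of folds, `1 <= K <= n`. Cross-fitted algorithms require
#'   `K >= 2` (T-learner pipeline) or `K >= 3` (DR-learner pipeline).
#' @param seed integer RNG seed; fold assignment does not disturb the
#'   caller's RNG state.
#' @param stratify optional vector of length `n` (e.g. the treatment arm);
#'   when supplied, the balanced assignment is performed within each stratum,
#'   which guards against folds lacking a treatment arm in small samples.
#' @return An object of class `fold_scheme`: a list with elements `n`, `K`,
#'   `assignment` (integer vector in `1..K`) and `seed`.
#' @examples
#' f <- make_folds(10, 2, seed = 1)
#' table(f$assignment)
#' @export
make_folds <- function(n, K, seed = 1L, stratify = NULL) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("`n` must be a positive integer")
  if (length(K) != 1L || !is.finite(K) || K < 1 || K != round(K))
    stop("`K` must be an integer >= 1")
  if (K > n) stop("`K` must not exceed `n` (got K = ", K, ", n = ", n, ")")
  n <- as.integer(n); K <- as.integer(K)
  if (K == 1L) {
    assignment <- rep(1L, n)
  } else if (is.null(stratify)) {
    assignment <- withr::with_seed(seed, sample(rep(seq_len(K), length.out = n)))
  } else {
    if (length(stratify) != n) stop("`stratify` must have length n")
    assignment <- integer(n)
    withr::with_seed(seed, {
      for (lev in unique(stratify)) {
        idx <- which(stratify == lev)
        assignment[idx] <- sample(rep(seq_len(K), length.out = length(idx)))
      }
    })
  }
  structure(list(n = n, K = K, assignment = assignment, seed = seed),
            class = "fold_scheme")
}

#' @export
print.fold_scheme <- function(x, ...) {
  cat("Fold scheme: n =", x$n, ", K =", x$K, ", seed =", x$seed, "\n")
  print(table(fold = x$assignment))
  invisible(x)
}

#' Specify a regression learner
#'
#' A `learner_spec` names a routine from the learner registry together with
#' its hyperparameters. Every registered learner can be fitted to a feature
#' matrix and a numeric target (or a binary target for propensity models)
#' and then produce numeric predictions; fitting is deterministic given a
#' seed (stochastic learners are run under a local seed guard).
#'
#' Registered learners:
#' \describe{
#'   \item{`"mean"`}{constant-mean baseline (arm proportion for binary targets).}
#'   \item{`"lm"`}{linear (or logistic) model; hyperparameters `degree`
#'     (polynomial degree applied to continuous features, default 1) and
#'     `interactions` (logical, add pairwise products, default `FALSE`).}
#'   \item{`"glmnet"`}{lasso/elastic-net via cross-validated `glmnet`;
#'     hyperparameter `alpha` (default 1).}
#'   \item{`"gam"`}{spline smoother via \pkg{mgcv}; hyperparameters `k`
#'     (basis dimension per smooth, default 10) and `interactions` (list of
#'     feature-name pairs given tensor-product interaction smooths, or
#'     `TRUE` for all pairs of continuous features).}
#'   \item{`"rf"`}{random forest via \pkg{ranger}; hyperparameters
#'     `num.trees` (default 500), `min.node.size`, `mtry`.}
#'   \item{`"gbt"`}{gradient-boosted trees via \pkg{xgboost}; hyperparameters
#'     `nrounds` (default 200), `eta` (0.1), `max_depth` (3).}
#' }
#'
#' @param name learner name, one of [learner_names()].
#' @param ... hyperparameters (name = value).
#' @return An object of class `learner_spec`.
#' @examples
#' learner_spec("gam", k = 5)
#' @export
learner_spec <- function(name, ...) {
  name <- match.arg(name, learner_names())
  structure(list(name = name, hyper = list(...)), class = "learner_spec")
}

#' @export
print.learner_spec <- function(x, ...) {
  h <- if (length(x$hyper))
    paste0("(", paste(names(x$hyper), vapply(x$hyper, function(v)
      paste(deparse(v), collapse = ""), ""), sep = " = ", collapse = ", "), ")")
  else "(defaults)"
  cat("Learner:", x$name, h, "\n")
  invisible(x)
}

#' Names of registered learners
#' @return Character vector of learner names accepted by [learner_spec()].
#' @export
learner_names <- function() c("mean", "lm", "glmnet", "gam", "rf", "gbt")

hyper_or <- function(hyper, name, default) {
  if (!is.null(hyper[[name]])) hyper[[name]] else default
}

# polynomial / interaction feature expansion for the "lm" learner
expand_features <- function(x, degree = 1L, interactions = FALSE) {
  x <- as.matrix(x)
  out <- x
  if (degree > 1L) {
    cont <- apply(x, 2L, function(col) length(unique(col)) > 2L)
    for (d in 2:degree) {
      xd <- x[, cont, drop = FALSE]^d
      if (ncol(xd)) {
        colnames(xd) <- paste0(colnames(x)[cont], ".pow", d)
        out <- cbind(out, xd)
      }
    }
  }
  if (isTRUE(interactions) && ncol(x) > 1L) {
    pr <- combn(ncol(x), 2L)
    xi <- x[, pr[1L, ], drop = FALSE] * x[, pr[2L, ], drop = FALSE]
    colnames(xi) <- paste0(colnames(x)[pr[1L, ]], ".x.", colnames(x)[pr[2L, ]])
    out <- cbind(out, xi)
  }
  out
}

# mgcv formula builder: smooth continuous features, linear terms for
# near-discrete ones; optional tensor-product interactions
gam_formula <- function(xnames, x, k, interactions) {
  nuniq <- apply(x, 2L, function(col) length(unique(col)))
  smooth <- nuniq >= max(8L, k)
  terms <- ifelse(smooth, paste0("s(", xnames, ", k = ", k, ")"), xnames)
  if (isTRUE(interactions)) {
    cn <- xnames[smooth]
    interactions <- if (length(cn) > 1L) combn(cn, 2L, simplify = FALSE) else list()
  }
  if (is.list(interactions) && length(interactions)) {
    ik <- max(3L, min(5L, k))
    terms <- c(terms, vapply(interactions, function(pr)
      paste0("ti(", pr[1L], ", ", pr[2L], ", k = ", ik, ")"), ""))
  }
  stats::as.formula(paste(".target ~", paste(terms, collapse = " + ")))
}

# Each registry entry fits on (x, y) and returns a closure-based predictor.
# `binary = TRUE` requests a probability model (propensity fitting).
fit_learner_impl <- function(spec, x, y, binary = FALSE, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (anyNA(y) || any(!is.finite(y))) stop("non-finite targets in learner fit")
  hyper <- spec$hyper
  switch(spec$name,
    mean = {
      m <- mean(y)
      list(predict = function(newx) rep(m, nrow(as.matrix(newx))))
    },
    lm = {
      degree <- hyper_or(hyper, "degree", 1L)
      inter <- hyper_or(hyper, "interactions", FALSE)
      xx <- expand_features(x, degree, inter)
      df <- data.frame(.target = y, xx, check.names = FALSE)
      fam <- if (binary) binomial() else gaussian()
      fit <- suppressWarnings(glm(.target ~ ., data = df, family = fam))
      list(predict = function(newx) {
        nd <- as.data.frame(expand_features(ensure_names(newx, colnames(x)), degree, inter))
        as.numeric(predict(fit, newdata = nd, type = "response"))
      })
    },
    glmnet = {
      if (!requireNamespace("glmnet", quietly = TRUE))
        stop("learner 'glmnet' requires the glmnet package")
      alpha <- hyper_or(hyper, "alpha", 1)
      fam <- if (binary) "binomial" else "gaussian"
      fit <- withr::with_seed(seed,
        glmnet::cv.glmnet(x, y, alpha = alpha, family = fam, nfolds = 5))
      list(predict = function(newx)
        as.numeric(predict(fit, newx = ensure_names(newx, colnames(x)),
                           s = "lambda.min", type = "response")))
    },
    gam = {
      k <- hyper_or(hyper, "k", 10L)
      inter <- hyper_or(hyper, "interactions", FALSE)
      fml <- gam_formula(colnames(x), x, k, inter)
      df <- data.frame(.target = y, x, check.names = FALSE)
      fam <- if (binary) binomial() else gaussian()
      fit <- mgcv::gam(fml, data = df, family = fam, method = "GCV.Cp")
      list(predict = function(newx) {
        nd <- as.data.frame(ensure_names(newx, colnames(x)))
        as.numeric(mgcv::predict.gam(fit, newdata = nd, type = "response"))
      })
    },
    rf = {
      if (!requireNamespace("ranger", quietly = TRUE))
        stop("learner 'rf' requires the ranger package")
      fit <- ranger::ranger(
        x = x, y = y,
        num.trees = hyper_or(hyper, "num.trees", 500L),
        mtry = hyper_or(hyper, "mtry", NULL),
        min.node.size = hyper_or(hyper, "min.node.size", if (binary) 10L else 5L),
        seed = seed, num.threads = 1L)
      list(predict = function(newx)
        as.numeric(predict(fit, data = as.data.frame(ensure_names(newx, colnames(x))),
                           num.threads = 1L)$predictions))
    },
    gbt = {
      if (!requireNamespace("xgboost", quietly = TRUE))
        stop("learner 'gbt' requires the xgboost package")
      params <- list(
        eta = hyper_or(hyper, "eta", 0.1),
        max_depth = hyper_or(hyper, "max_depth", 3L),
        objective = if (binary) "binary:logistic" else "reg:squarederror",
        nthread = 1L)
      fit <- withr::with_seed(seed, xgboost::xgboost(
        data = x, label = y, params = params,
        nrounds = hyper_or(hyper, "nrounds", 200L), verbose = 0))
      list(predict = function(newx)
        as.numeric(predict(fit, newdata = ensure_names(newx, colnames(x)))))
    },
    stop("unknown learner: ", spec$name)
  )
}

ensure_names <- function(newx, nms) {
  newx <- as.matrix(newx)
  if (is.null(colnames(newx))) colnames(newx) <- nms
  newx[, nms, drop = FALSE]
}

#' Fit a learner on the rows outside a set of held-out folds
#'
#' Trains `learner` only on rows whose fold is not in `exclude` and returns a
#' predictor that records its training folds, so that downstream code can
#' assert the cross-fitting contract (no prediction for a row from a model
#' whose training set included that row's fold).
#'
#' @param learner a [learner_spec()].
#' @param x feature matrix (n rows).
#' @param y numeric target vector.
#' @param scheme a [make_folds()] scheme for the same `n`.
#' @param exclude integer vector of fold ids to hold out (possibly empty);
#'   must leave a nonempty training set.
#' @param binary fit a probability model for a 0/1 target.
#' @param seed learner seed.
#' @return An object of class `cf_fit` with elements `spec`, `train_folds`,
#'   `n_train` and a `predict(newx)` closure; use [predict.cf_fit()].
#' @examples
#' sch <- make_folds(4, 2, seed = 1)
#' fit <- fit_predict_heldout(learner_spec("mean"), matrix(1:4), c(1, 2, 3, 4),
#'                            sch, exclude = 1)
#' @export
fit_predict_heldout <- function(learner, x, y, scheme, exclude = integer(0),
                                binary = FALSE, seed = 1L) {
  stopifnot(inherits(learner, "learner_spec"), inherits(scheme, "fold_scheme"))
  x <- as.matrix(x)
  if (nrow(x) != scheme$n || length(y) != scheme$n)
    stop("feature/target rows must match the fold scheme")
  exclude <- as.integer(exclude)
  if (length(setdiff(exclude, seq_len(scheme$K))))
    stop("`exclude` contains unknown fold ids")
  train <- which(!(scheme$assignment %in% exclude))
  if (!length(train)) stop("empty training set: all folds excluded")
  model <- fit_learner_impl(learner, x[train, , drop = FALSE], y[train],
                            binary = binary, seed = seed)
  structure(list(spec = learner,
                 train_folds = setdiff(seq_len(scheme$K), exclude),
                 n_train = length(train),
                 .predict = model$predict),
            class = "cf_fit")
}

#' Predict from a cross-fitted learner
#'
#' @param object a `cf_fit` from [fit_predict_heldout()].
#' @param newx feature matrix to predict on.
#' @param fold optional fold id of the rows in `newx`; if supplied and the
#'   fold was part of the training set, a cross-fitting-contract error is
#'   raised.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.cf_fit <- function(object, newx, fold = NULL, ...) {
  if (!is.null(fold) && any(fold %in% object$train_folds) &&
      length(object$train_folds) > 1L)
    stop("cross-fitting contract violated: predicting on fold ",
         paste(intersect(fold, object$train_folds), collapse = ","),
         " which was in the training set")
  p <- object$.predict(newx)
  if (anyNA(p) || any(!is.finite(p))) stop("learner produced non-finite predictions")
  p
}
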