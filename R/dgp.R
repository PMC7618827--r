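#' Benchmark data-generating processes
#'
#' Three synthetic designs with known CATEs, used throughout the package's
#' verification harness:
#' \describe{
#'   \item{DGP 1}{\eqn{X_1, X_2 \sim U(-1, 1)} independent;
#'     \eqn{A \sim Bern\{expit(-0.4X_1 + 0.1X_1X_2)\}};
#'     \eqn{\tau^{(1)}(X) = X_1^3 + 1.4X_1^2 + 25X_2^2/9};
#'     \eqn{Y \sim N(X_1X_2 + 2X_2^2 - X_1 + A\tau^{(1)}(X),\ 1)}.}
#'   \item{DGP 2}{as DGP 1 with \eqn{\tau^{(2)} = \tau^{(1)}/10}: the same
#'     relative importance in a low-heterogeneity regime.}
#'   \item{DGP 3}{three independent bivariate-normal pairs
#'     \eqn{(X_1,X_2), (X_3,X_4), (X_5,X_6)} with unit variances and
#'     within-pair correlation 0.5;
#'     \eqn{A \sim Bern\{expit(-0.4X_1 + 0.1X_1X_2 + 0.2X_5)\}} (note the
#'     propensity depends on \eqn{X_5}, which is absent from the CATE);
#'     \eqn{\tau^{(3)}(X) = X_1 + 2X_2 + X_3};
#'     \eqn{Y \sim N(X_3 - X_6 + A\tau^{(3)}(X),\ 3)} (noise variance 3).}
#' }
#' The returned table carries the oracle nuisance functions evaluated at
#' the sampled rows in `attr(, "oracle")` (`tau`, `pi`, `mu0`, `mu1`), for
#' use in estimator-recovery tests.
#'
#' @param dgp 1, 2 or 3.
#' @param n sample size.
#' @param seed integer seed; generation is reproducible and does not
#'   disturb the caller's RNG state.
#' @return A [te_data()] object with an `"oracle"` attribute.
#' @export
generate_dgp <- function(dgp, n, seed = 1L) {
  if (!dgp %in% 1:3) stop("unknown DGP id: ", dgp)
  if (n < 1) stop("n must be >= 1")
  withr::with_seed(seed, {
    if (dgp %in% c(1, 2)) {
      x1 <- runif(n, -1, 1); x2 <- runif(n, -1, 1)
      x <- cbind(X1 = x1, X2 = x2)
      tau <- (x1^3 + 1.4 * x1^2 + 25 * x2^2 / 9) * if (dgp == 2) 0.1 else 1
      pi <- plogis(-0.4 * x1 + 0.1 * x1 * x2)
      mu0 <- x1 * x2 + 2 * x2^2 - x1
      a <- rbinom(n, 1, pi)
      y <- rnorm(n, mu0 + a * tau, 1)
    } else {
      L <- chol(matrix(c(1, 0.5, 0.5, 1), 2))  # upper-tri: Z %*% L has corr 0.5
      x <- do.call(cbind, lapply(1:3, function(b)
        matrix(rnorm(2 * n), n, 2) %*% L))
      colnames(x) <- paste0("X", 1:6)
      tau <- x[, 1] + 2 * x[, 2] + x[, 3]
      pi <- plogis(-0.4 * x[, 1] + 0.1 * x[, 1] * x[, 2] + 0.2 * x[, 5])
      mu0 <- x[, 3] - x[, 6]
      a <- rbinom(n, 1, pi)
      y <- rnorm(n, mu0 + a * tau, sqrt(3))
    }
    out <- te_data(y = y, a = a, x = x)
    attr(out, "oracle") <- list(tau = tau, pi = pi, mu0 = mu0, mu1 = mu0 + tau)
    out
  })
}

dgp_sigma3 <- function() kronecker(diag(3), matrix(c(1, 0.5, 0.5, 1), 2))

# variance of the linear projection E[a'X | X_B] under N(0, Sigma)
gaussian_projection_var <- function(a, Sigma, keep) {
  if (!length(keep)) return(0)
  cb <- Sigma[, keep, drop = FALSE] %*% solve(Sigma[keep, keep, drop = FALSE])
  drop(t(a) %*% cb %*% Sigma[keep, , drop = FALSE] %*% a)
}

#' Closed-form population truths for the benchmark DGPs
#'
#' Exact values of the ATE \eqn{\tau_p}, the VTE \eqn{\Theta_p}, the
#' TE-VIMs \eqn{\Theta_s} and scaled TE-VIMs \eqn{\Psi_s} for the requested
#' subsets, and (for DGP 3) the per-covariate LOO, KOI-complement and
#' Shapley tables. DGPs 1-2 use polynomial moments of the uniform law
#' (\eqn{EX^2 = 1/3, EX^4 = 1/5, EX^6 = 1/7}); DGP 3 uses Gaussian
#' conditional expectations (linear projections under the block covariance).
#'
#' @param dgp 1, 2 or 3.
#' @param subsets list of integer vectors (defaults to all nonempty subsets
#'   for DGPs 1-2, and LOO plus KOI plus the full set for DGP 3).
#' @return An object of class `truth_table`: list with `tau_p`, `theta_p`,
#'   named vectors `theta_s` and `psi_s`, and for DGP 3 the data frame
#'   `table` (LOO / KOI-complement / Shapley per covariate).
#' @export
dgp_truth <- function(dgp, subsets = NULL) {
  if (!dgp %in% 1:3) stop("unknown DGP id: ", dgp)
  if (dgp %in% c(1, 2)) {
    m2 <- 1/3; m4 <- 1/5; m6 <- 1/7
    scale2 <- if (dgp == 2) 0.01 else 1            # tau scaled by 1/10
    var_g1 <- m6 + 1.4^2 * (m4 - m2^2)             # var(X^3 + 1.4 X^2); odd moments vanish
    var_g2 <- (25 / 9)^2 * (m4 - m2^2)
    tau_p <- (1.4 * m2 + (25 / 9) * m2) * sqrt(scale2)
    theta_p <- (var_g1 + var_g2) * scale2
    if (is.null(subsets)) subsets <- list(1L, 2L, 1:2)
    theta_s <- vapply(subsets, function(s) {
      s <- sort(unique(as.integer(s)))
      if (length(setdiff(s, 1:2))) stop("DGP ", dgp, " has covariates 1..2")
      # dropping s leaves the additive component(s) of the kept covariates
      kept_var <- sum(c(var_g1, var_g2)[setdiff(1:2, s)])
      theta_p - kept_var * scale2
    }, 0)
    names(theta_s) <- vapply(subsets, subset_key, "")
    tab <- NULL
    p <- 2L
  } else {
    Sigma <- dgp_sigma3()
    a <- c(1, 2, 1, 0, 0, 0)
    p <- 6L
    tau_p <- 0
    theta_p <- drop(t(a) %*% Sigma %*% a)
    if (is.null(subsets))
      subsets <- unique(c(lapply(1:6, identity),
                          lapply(1:6, function(j) setdiff(1:6, j)),
                          list(1:6)))
    theta_s <- vapply(subsets, function(s) {
      s <- sort(unique(as.integer(s)))
      theta_p - gaussian_projection_var(a, Sigma, setdiff(1:6, s))
    }, 0)
    names(theta_s) <- vapply(subsets, subset_key, "")
    # per-covariate mode table from all 2^p - 1 subsets
    all_sub <- unlist(lapply(1:6, function(m) combn(6, m, simplify = FALSE)),
                      recursive = FALSE)
    th_all <- vapply(all_sub, function(s)
      theta_p - gaussian_projection_var(a, Sigma, setdiff(1:6, s)), 0)
    names(th_all) <- vapply(all_sub, subset_key, "")
    shap <- shapley_attributions(th_all, 6)
    tab <- data.frame(
      covariate = paste0("X", 1:6),
      loo = th_all[vapply(1:6, subset_key, "")],
      koi = theta_p - th_all[vapply(1:6, function(j) subset_key(setdiff(1:6, j)), "")],
      shapley = shap$estimate,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  psi_s <- theta_s / theta_p
  structure(list(dgp = dgp, p = p, tau_p = tau_p, theta_p = theta_p,
                 theta_s = theta_s, psi_s = psi_s, table = tab),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat("Population truths, DGP", x$dgp, "\n")
  cat("tau_p =", signif(x$tau_p, 5), " Theta_p =", signif(x$theta_p, 5), "\n")
  df <- data.frame(subset = names(x$theta_s), theta_s = x$theta_s,
                   psi_s = x$psi_s, row.names = NULL)
  print(df, digits = 4)
  if (!is.null(x$table)) { cat("Mode table:\n"); print(x$table, digits = 4) }
  invisible(x)
}

#' Monte-Carlo truth oracle
#'
#' Independent brute-force check of [dgp_truth()]: draws covariates from
#' the DGP, evaluates the exact CATE, and computes each subset CATE
#' \eqn{\tau_s} without closed-form variance algebra — by Gauss-Legendre
#' quadrature over the dropped uniform covariates (DGPs 1-2) or by ordinary
#' least squares of \eqn{\tau} on the kept covariates at the sampled draws
#' (DGP 3, where the conditional mean is linear). TE-VIMs are then empirical
#' variances, \eqn{\Theta_s = var(\tau) - var(\tau_s)}.
#'
#' @param dgp 1, 2 or 3.
#' @param subsets list of integer subsets.
#' @param draws Monte-Carlo sample size.
#' @param seed integer seed.
#' @return Named list: `tau_p`, `theta_p`, named vector `theta_s`.
#' @export
dgp_truth_mc <- function(dgp, subsets, draws = 1e6, seed = 1L) {
  if (!dgp %in% 1:3) stop("unknown DGP id: ", dgp)
  withr::with_seed(seed, {
    if (dgp %in% c(1, 2)) {
      sc <- if (dgp == 2) 0.1 else 1
      x1 <- runif(draws, -1, 1); x2 <- runif(draws, -1, 1)
      taufun <- function(u1, u2) (u1^3 + 1.4 * u1^2 + 25 * u2^2 / 9) * sc
      tau <- taufun(x1, x2)
      gl <- pracma::gaussLegendre(24, -1, 1)
      tau_s_fun <- function(s) {
        if (setequal(s, 1:2)) return(rep(mean(tau), draws))
        drop_x1 <- identical(s, 1L)
        acc <- numeric(draws)
        for (i in seq_along(gl$x))   # E[tau | kept covariate]; U(-1,1) density 1/2
          acc <- acc + gl$w[i] *
            (if (drop_x1) taufun(gl$x[i], x2) else taufun(x1, gl$x[i]))
        acc / 2
      }
      theta_s <- vapply(subsets, function(s) {
        ts <- tau_s_fun(sort(unique(as.integer(s))))
        var(tau) - var(ts)
      }, 0)
    } else {
      L <- chol(matrix(c(1, 0.5, 0.5, 1), 2))
      x <- do.call(cbind, lapply(1:3, function(b)
        matrix(rnorm(2 * draws), draws, 2) %*% L))
      tau <- x[, 1] + 2 * x[, 2] + x[, 3]
      theta_s <- vapply(subsets, function(s) {
        keep <- setdiff(1:6, sort(unique(as.integer(s))))
        if (!length(keep)) return(var(tau))
        fit <- stats::lm.fit(cbind(1, x[, keep, drop = FALSE]), tau)
        var(tau) - var(fit$fitted.values)
      }, 0)
    }
    names(theta_s) <- vapply(subsets, subset_key, "")
    list(tau_p = mean(tau), theta_p = var(tau), theta_s = theta_s)
  })
}
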