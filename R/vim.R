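#' @title Variable-importance results
#' @description Container for one estimate with its per-row uncentered
#'   influence-curve values, IC-based standard error, and Wald confidence
#'   interval. For `theta_s`, `theta_p` and `ate` the estimate equals the
#'   mean of the uncentered IC values exactly (the estimating-equation
#'   property); for `psi_s` the stored IC is the scaled-difference curve
#'   used by its variance formula.
#' @name vim_result
NULL

new_vim_result <- function(estimand, ic_uncentered, level = 0.95,
                           subset = NULL, subset_label = "",
                           algorithm = NA_character_,
                           estimate = NULL, se = NULL, flags = character()) {
  n <- length(ic_uncentered)
  if (anyNA(ic_uncentered) || any(!is.finite(ic_uncentered)))
    stop("non-finite influence-curve values")
  if (is.null(estimate)) estimate <- mean(ic_uncentered)
  if (is.null(se)) se <- sqrt(sum((ic_uncentered - estimate)^2)) / n
  z <- qnorm(1 - (1 - level) / 2)
  ci <- c(estimate - z * se, estimate + z * se)
  if (estimand %in% c("theta_s", "theta_p") && estimate < 0)
    flags <- union(flags, "negative-estimate")
  if (estimand %in% c("theta_s", "theta_p", "psi_s") &&
      abs(estimate) < 2 * se)
    flags <- union(flags, "near-null: IC degenerates under the zero-importance null; Wald inference unreliable")
  structure(list(estimand = estimand, subset = subset,
                 subset_label = subset_label, estimate = estimate,
                 ic_uncentered = ic_uncentered, se = se,
                 ci = ci, level = level, n = n,
                 algorithm = algorithm, flags = flags),
            class = "vim_result")
}

#' @export
print.vim_result <- function(x, ...) {
  lab <- switch(x$estimand,
                theta_s = paste0("Theta_s  (s = {", x$subset_label, "})"),
                theta_p = "Theta_p  (VTE)",
                psi_s = paste0("Psi_s    (s = {", x$subset_label, "})"),
                ate = "ATE (AIPW)")
  cat(sprintf("%s: %.5g  SE %.4g  %d%% CI [%.5g, %.5g]  n = %d\n",
              lab, x$estimate, x$se, round(100 * x$level), x$ci[1], x$ci[2], x$n))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.vim_result <- function(x, ...) {
  data.frame(estimand = x$estimand,
             subset = x$subset_label,
             algorithm = x$algorithm,
             estimate = x$estimate, se = x$se,
             ci_lo = x$ci[1], ci_hi = x$ci[2], level = x$level, n = x$n,
             flags = paste(x$flags, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' One-step TE-VIM estimator
#'
#' Computes the estimating-equation estimator of \eqn{\Theta_s} from
#' per-row pseudo-outcomes, CATE evaluations and subset-CATE evaluations:
#' \deqn{\hat\Theta_s = n^{-1} \sum_i \hat\phi_{i,s}, \qquad
#'   \hat\phi_{i,s} = \{\hat\varphi_i - \hat\tau_{s,i}\}^2 -
#'                    \{\hat\varphi_i - \hat\tau_i\}^2,}
#' with IC-based variance \eqn{n^{-2}\sum_i(\hat\phi_{i,s}-\hat\Theta_s)^2}
#' and a Wald interval. Passing the scalar AIPW ATE as `tau_s` yields the
#' VTE estimator \eqn{\hat\Theta_p}.
#'
#' @param phi per-row pseudo-outcome values (vector or pipeline object).
#' @param tau per-row CATE evaluations \eqn{\hat\tau(x_i)}.
#' @param tau_s per-row subset-CATE evaluations \eqn{\hat\tau_s(x_i)}, or a
#'   single scalar (an ATE estimate), in which case the result is labelled
#'   `theta_p`.
#' @param subset integer indices of the covariates in `s` (labelling only).
#' @param subset_label label for reports.
#' @param level confidence level.
#' @param algorithm label recorded in the result.
#' @return A [vim_result].
#' @export
theta_estimate <- function(phi, tau, tau_s, subset = NULL,
                           subset_label = NULL, level = 0.95,
                           algorithm = NA_character_) {
  phi <- phi_values(phi)
  n <- length(phi)
  if (n < 2L) stop("need at least two observations")
  scalar_tau_s <- length(tau_s) == 1L
  if (length(tau) != n || (!scalar_tau_s && length(tau_s) != n))
    stop("phi, tau and tau_s must have equal length")
  if (anyNA(phi) || anyNA(tau) || anyNA(tau_s))
    stop("NaN/NA in estimator inputs")
  ic <- (phi - tau_s)^2 - (phi - tau)^2
  estimand <- if (scalar_tau_s) "theta_p" else "theta_s"
  if (is.null(subset_label))
    subset_label <- if (scalar_tau_s) "all" else paste(subset, collapse = ",")
  new_vim_result(estimand, ic, level = level, subset = subset,
                 subset_label = subset_label, algorithm = algorithm)
}

#' Scaled TE-VIM estimator
#'
#' The ratio \eqn{\hat\Psi_s = \hat\Theta_s / \hat\Theta_p} with
#' influence-curve variance
#' \eqn{(n\hat\Theta_p)^{-2}\sum_i(\hat\phi_{i,s} -
#'   \hat\Psi_s\hat\phi_{i,p})^2}. Both inputs must be computed on the same
#' rows from the same pseudo-outcomes and CATE evaluations. A non-positive
#' VTE estimate yields a flagged result (scaled TE-VIMs are only meaningful
#' when a sensible VTE estimate is obtained); an exactly-zero VTE is an
#' error.
#'
#' @param theta_s [vim_result] for \eqn{\Theta_s}.
#' @param theta_p [vim_result] for \eqn{\Theta_p}.
#' @param level confidence level.
#' @return A [vim_result] with `estimand = "psi_s"`.
#' @export
psi_estimate <- function(theta_s, theta_p, level = 0.95) {
  stopifnot(inherits(theta_s, "vim_result"), inherits(theta_p, "vim_result"))
  if (theta_s$n != theta_p$n)
    stop("theta_s and theta_p must be computed on the same rows")
  if (theta_p$estimate == 0) stop("undefined ratio: VTE estimate is exactly zero")
  psi <- theta_s$estimate / theta_p$estimate
  n <- theta_s$n
  ic <- (theta_s$ic_uncentered - psi * theta_p$ic_uncentered) / theta_p$estimate
  se <- sqrt(sum(ic^2)) / n
  flags <- character()
  if (theta_p$estimate < 0)
    flags <- "negative-VTE: scaled TE-VIMs unreliable"
  new_vim_result("psi_s", ic, level = level, subset = theta_s$subset,
                 subset_label = theta_s$subset_label,
                 algorithm = theta_s$algorithm,
                 estimate = psi, se = se, flags = flags)
}

#' Bounded confidence intervals by transformation
#'
#' Delta-method Wald intervals on a transformed scale, back-transformed to
#' guarantee range-respecting bounds: the log scale for \eqn{\Theta}
#' estimates (interval within \eqn{(0, \infty)}) and the logit scale for
#' \eqn{\Psi} estimates (interval within \eqn{(0, 1)}). Estimates outside
#' the transform's domain return `NA` bounds with a domain flag rather than
#' an error.
#'
#' @param result a [vim_result].
#' @param transform `"log"` or `"logit"`; defaults to log for
#'   `theta_s`/`theta_p`/`ate` and logit for `psi_s`.
#' @param level confidence level (defaults to the result's level).
#' @return List with `lo`, `hi`, `transform`, and `flag` (character,
#'   non-empty when the transform was not applicable).
#' @export
transformed_ci <- function(result, transform = NULL, level = NULL) {
  stopifnot(inherits(result, "vim_result"))
  if (is.null(transform))
    transform <- if (result$estimand == "psi_s") "logit" else "log"
  transform <- match.arg(transform, c("log", "logit"))
  if (is.null(level)) level <- result$level
  z <- qnorm(1 - (1 - level) / 2)
  est <- result$estimate; se <- result$se
  if (transform == "log") {
    if (est <= 0)
      return(list(lo = NA_real_, hi = NA_real_, transform = transform,
                  flag = "domain: estimate <= 0, log interval not available"))
    if (se == 0) return(list(lo = est, hi = est, transform = transform, flag = character()))
    se_t <- se / est
    list(lo = est * exp(-z * se_t), hi = est * exp(z * se_t),
         transform = transform, flag = character())
  } else {
    if (est <= 0 || est >= 1)
      return(list(lo = NA_real_, hi = NA_real_, transform = transform,
                  flag = "domain: estimate outside (0,1), logit interval not available"))
    if (se == 0) return(list(lo = est, hi = est, transform = transform, flag = character()))
    se_t <- se / (est * (1 - est))
    list(lo = plogis(qlogis(est) - z * se_t),
         hi = plogis(qlogis(est) + z * se_t),
         transform = transform, flag = character())
  }
}
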