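#' Covariate subsets for a comparison mode
#'
#' Translates a requested comparison mode into the list of covariate subsets
#' \eqn{s} whose TE-VIMs must be estimated:
#' \describe{
#'   \item{loo}{leave-one-out; `s` contains a single covariate. May
#'     under-represent importance for highly correlated covariates.}
#'   \item{koi}{keep-one-in; `s` contains all but a single covariate. May
#'     over-represent importance for correlated covariates.}
#'   \item{shapley}{every nonempty subset of the covariates
#'     (\eqn{2^p - 1} sets; the empty set contributes \eqn{\Theta_\emptyset
#'     = 0} and needs no estimation). Refused above `shapley_cap` covariates
#'     since the cost is exponential in p.}
#'   \item{groups}{domain-defined covariate blocks, compared block-wise.}
#' }
#'
#' @param p number of covariates.
#' @param mode one of `"loo"`, `"koi"`, `"shapley"`, `"groups"`.
#' @param groups named list of integer vectors partitioning `1..p`
#'   (required for `mode = "groups"`).
#' @param shapley_cap maximum p for Shapley mode (default 15).
#' @param names optional covariate names used for subset labels.
#' @return Named list of sorted integer vectors.
#' @examples
#' subsets_for_mode(3, "loo")
#' subsets_for_mode(3, "shapley")
#' @export
subsets_for_mode <- function(p, mode = c("loo", "koi", "shapley", "groups"),
                             groups = NULL, shapley_cap = 15L, names = NULL) {
  mode <- match.arg(mode)
  if (p < 1) stop("p must be >= 1")
  if (is.null(names)) names <- paste0("X", seq_len(p))
  lab <- function(s) paste(names[s], collapse = ",")
  subsets <- switch(mode,
    loo = lapply(seq_len(p), identity),
    koi = lapply(seq_len(p), function(j) setdiff(seq_len(p), j)),
    shapley = {
      if (p > shapley_cap)
        stop("Shapley mode with p = ", p, " requires 2^p = ", 2^p,
             " subset evaluations and may be computationally impractical; ",
             "cap is ", shapley_cap)
      unlist(lapply(seq_len(p), function(m) combn(p, m, simplify = FALSE)),
             recursive = FALSE)
    },
    groups = {
      if (is.null(groups) || !length(groups))
        stop("mode 'groups' requires a named list of covariate blocks")
      blocks <- lapply(groups, function(g) sort(unique(as.integer(g))))
      if (!setequal(unlist(blocks), seq_len(p)) ||
          length(unlist(blocks)) != p)
        stop("groups must partition the covariate set 1..p")
      if (is.null(base::names(blocks))) base::names(blocks) <- paste0("G", seq_along(blocks))
      blocks
    })
  if (mode == "koi" && p == 1L)
    stop("keep-one-in is undefined for a single covariate")
  out <- lapply(subsets, function(s) sort(as.integer(s)))
  if (mode == "groups") base::names(out) <- base::names(subsets)
  else base::names(out) <- vapply(out, lab, "")
  out
}

subset_key <- function(s) paste(sort(as.integer(s)), collapse = ",")

#' Shapley attributions over explained heterogeneity
#'
#' Defines the cooperative game on kept covariate sets,
#' \eqn{v(S) = \Theta_p - \Theta_{S^c}} (the treatment-effect heterogeneity
#' explained by keeping \eqn{X_S}; \eqn{v(\emptyset) = 0},
#' \eqn{v(\{1..p\}) = \Theta_p}), and computes each covariate's Shapley
#' value
#' \deqn{\phi_j = \sum_{S \subseteq p \setminus \{j\}}
#'   \frac{|S|!\,(p-|S|-1)!}{p!}\,\{v(S \cup \{j\}) - v(S)\}.}
#' By efficiency the attributions sum to \eqn{\Theta_p} exactly. When the
#' per-subset influence curves are supplied, each attribution's standard
#' error is formed from the same linear combination of ICs.
#'
#' @param theta named numeric vector of \eqn{\Theta_s} values for **all**
#'   nonempty subsets, with names produced by joining sorted indices with
#'   commas (e.g. `"1"`, `"1,3"`); the full-set entry is the VTE.
#' @param p number of covariates.
#' @param ics optional matrix (n rows, one column per name of `theta`) of
#'   uncentered IC values \eqn{\hat\phi_{i,s}}.
#' @param level confidence level for per-attribution Wald intervals.
#' @return Data frame with one row per covariate: `covariate`, `estimate`,
#'   and (when `ics` given) `se`, `ci_lo`, `ci_hi`.
#' @export
shapley_attributions <- function(theta, p, ics = NULL, level = 0.95) {
  keys <- vapply(unlist(lapply(seq_len(p), function(m)
    combn(p, m, simplify = FALSE)), recursive = FALSE), subset_key, "")
  missing <- setdiff(keys, names(theta))
  if (length(missing))
    stop("missing Theta_s values for subset(s): ", paste(missing, collapse = "; "))
  # attribution_j = sum over pairs (S u j, S) of w * [Theta_{S^c} - Theta_{(S u j)^c}]
  # where Theta over the empty drop-set is 0 and over the full set is Theta_p.
  coefs <- matrix(0, nrow = length(keys), ncol = p,
                  dimnames = list(keys, paste0("X", seq_len(p))))
  full <- seq_len(p)
  for (j in full) {
    others <- setdiff(full, j)
    for (m in 0:length(others)) {
      Ss <- if (m == 0) list(integer(0)) else combn(others, m, simplify = FALSE)
      w <- factorial(m) * factorial(p - m - 1) / factorial(p)
      for (S in Ss) {
        compT <- setdiff(full, c(S, j))
        # + v(S u j) = Theta_full - Theta_{(S u j)^c}   (drop-set empty -> 0)
        coefs[subset_key(full), j] <- coefs[subset_key(full), j] + w
        if (length(compT))
          coefs[subset_key(compT), j] <- coefs[subset_key(compT), j] - w
        # - v(S) = -(Theta_full - Theta_{S^c}); v(empty) = 0
        if (length(S)) {
          coefs[subset_key(full), j] <- coefs[subset_key(full), j] - w
          compS <- setdiff(full, S)
          coefs[subset_key(compS), j] <- coefs[subset_key(compS), j] + w
        }
      }
    }
  }
  est <- as.numeric(theta[keys] %*% coefs)
  out <- data.frame(covariate = paste0("X", full), estimate = est,
                    stringsAsFactors = FALSE)
  if (!is.null(ics)) {
    if (!all(keys %in% colnames(ics)))
      stop("ics must have one column per subset key")
    icm <- ics[, keys, drop = FALSE] %*% coefs
    n <- nrow(icm)
    se <- sqrt(colSums((icm - rep(est, each = n))^2)) / n
    z <- qnorm(1 - (1 - level) / 2)
    out$se <- se
    out$ci_lo <- est - z * se
    out$ci_hi <- est + z * se
  }
  out
}

#' Keep-one-in report with both conventions
#'
#' For KOI subsets (all covariates but one) reports, per covariate of
#' interest, the raw \eqn{\hat\Theta_s} (low values mean high importance of
#' the kept covariate) and the complement convention
#' \eqn{\hat\Theta_p - \hat\Theta_s} (high values mean high importance).
#' The complement's standard error comes from the IC of the difference,
#' \eqn{n^{-2}\sum_i\{(\hat\phi_{i,p} - \hat\phi_{i,s}) -
#' (\hat\Theta_p - \hat\Theta_s)\}^2}.
#'
#' @param theta_results named list of `theta_s` [vim_result]s for KOI
#'   subsets; names identify the kept covariate.
#' @param theta_p_result [vim_result] for the VTE.
#' @param level confidence level.
#' @return An object of class `mode_report` (data frame with one row per
#'   kept covariate and columns for both conventions).
#' @export
koi_report <- function(theta_results, theta_p_result, level = 0.95) {
  stopifnot(inherits(theta_p_result, "vim_result"))
  z <- qnorm(1 - (1 - level) / 2)
  rows <- lapply(seq_along(theta_results), function(i) {
    r <- theta_results[[i]]
    ic_diff <- theta_p_result$ic_uncentered - r$ic_uncentered
    comp <- theta_p_result$estimate - r$estimate
    se_comp <- sqrt(sum((ic_diff - comp)^2)) / r$n
    data.frame(kept = names(theta_results)[i],
               subset = r$subset_label,
               theta_s = r$estimate, theta_s_se = r$se,
               complement = comp, complement_se = se_comp,
               complement_ci_lo = comp - z * se_comp,
               complement_ci_hi = comp + z * se_comp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(list(mode = "koi", table = out, convention = "complement",
                 theta_p = theta_p_result$estimate),
            class = "mode_report")
}

#' @export
as.data.frame.mode_report <- function(x, ...) x$table

#' @export
print.mode_report <- function(x, ...) {
  cat("Mode report:", x$mode, "\n")
  if (!is.null(x$theta_p)) cat("Theta_p =", signif(x$theta_p, 5), "\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Parse a covariate-grouping specification string
#'
#' Grammar: `"name1:col,col;name2:col"` where columns are covariate names
#' or 1-based indices.
#'
#' @param spec specification string.
#' @param names covariate names (to resolve column references).
#' @return Named list of integer vectors suitable for
#'   [subsets_for_mode()].
#' @export
parse_groups <- function(spec, names) {
  blocks <- strsplit(spec, ";", fixed = TRUE)[[1]]
  out <- list()
  for (b in blocks) {
    kv <- strsplit(b, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("bad group block: ", b)
    cols <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    idx <- suppressWarnings(as.integer(cols))
    named <- match(cols, names)
    idx[is.na(idx)] <- named[is.na(idx)]
    if (anyNA(idx)) stop("unknown covariate in group '", kv[1], "': ",
                         paste(cols[is.na(idx)], collapse = ", "))
    out[[trimws(kv[1])]] <- sort(unique(idx))
  }
  out
}
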