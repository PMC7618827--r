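#' Estimate TE-VIMs from observational or trial data
#'
#' Runs one of the four end-to-end estimation pipelines and returns the ATE,
#' the VTE \eqn{\hat\Theta_p}, and per-subset \eqn{\hat\Theta_s} /
#' \eqn{\hat\Psi_s} estimates with influence-curve standard errors and Wald
#' confidence intervals.
#'
#' Pipelines:
#' \describe{
#'   \item{noSS-A / noSS-B}{single-sample (no splitting, `K = 1`): nuisances
#'     are fit once, pseudo-outcomes evaluated in-sample; the CATE is the
#'     T-learner difference (A) or a DR-learner regression of the
#'     pseudo-outcomes on the covariates (B); subset CATEs project the CATE
#'     evaluations on the retained covariates. Valid under Donsker-type
#'     conditions on the learners; tends to over-estimate TE-VIMs.}
#'   \item{SS-A}{cross-fitting with `K >= 2` folds and the T-learner: per
#'     fold, nuisances are fit on the other folds and evaluated held-out;
#'     subset CATEs are fit on the training rows' T-learner evaluations and
#'     evaluated held-out.}
#'   \item{SS-B}{cross-fitting with `K >= 3` folds and the DR-learner: per
#'     unordered fold pair, nuisances are fit excluding both folds; per
#'     fold, the CATE regression is trained on pseudo-outcomes computed from
#'     fits that exclude that fold, and each row's final pseudo-outcome
#'     averages its `K - 1` pair evaluations. Costs O(K^2) nuisance fits
#'     versus O(K) for SS-A.}
#' }
#'
#' @param data a [te_data()] object (or anything accepted by [te_data()]
#'   packed as a list with `y`, `a`, `x`).
#' @param algorithm `"noSS-A"`, `"noSS-B"`, `"SS-A"` or `"SS-B"`.
#' @param mode subset construction mode, see [subsets_for_mode()];
#'   `"custom"` uses `subsets` as given.
#' @param subsets list of integer covariate-index sets (mode `"custom"`).
#' @param groups named list of covariate blocks (mode `"groups"`), or a
#'   specification string for [parse_groups()].
#' @param K fold count; defaults to 1 for noSS and 8 otherwise.
#' @param outcome_learner,propensity_learner,cate_learner,projection_learner
#'   [learner_spec()]s per role. `cate_learner` is used by the -B variants
#'   only.
#' @param propensity optional known propensity (scalar in (0,1) or length-n
#'   vector); bypasses propensity fitting, as appropriate in randomized
#'   trials.
#' @param level confidence level for Wald intervals.
#' @param clip propensity clipping bound.
#' @param seed top-level seed; folds and all learner seeds derive from it.
#' @param stratify_folds stratify fold assignment by treatment arm (guards
#'   against single-arm folds in small samples).
#' @param shapley_cap maximum p for Shapley mode.
#' @return An object of class `tevim_fit`; see [as.data.frame.tevim_fit()].
#' @examples
#' d <- generate_dgp(1, 500, seed = 7)
#' fit <- tevim(d, algorithm = "noSS-A", mode = "loo",
#'              outcome_learner = learner_spec("lm", degree = 3, interactions = TRUE),
#'              propensity_learner = learner_spec("lm"),
#'              projection_learner = learner_spec("lm", degree = 3))
#' fit
#' @export
tevim <- function(data,
                  algorithm = c("SS-A", "SS-B", "noSS-A", "noSS-B"),
                  mode = c("loo", "koi", "shapley", "groups", "custom"),
                  subsets = NULL, groups = NULL, K = NULL,
                  outcome_learner = learner_spec("gam"),
                  propensity_learner = learner_spec("gam"),
                  cate_learner = learner_spec("gam"),
                  projection_learner = learner_spec("gam"),
                  propensity = NULL, level = 0.95, clip = 0.01,
                  seed = 1L, stratify_folds = FALSE, shapley_cap = 15L) {
  if (!inherits(data, "te_data")) data <- te_data(data$y, data$a, data$x)
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  p <- data$p
  if (is.character(groups)) groups <- parse_groups(groups, data$covariate_names)
  if (mode == "custom") {
    if (is.null(subsets)) stop("mode 'custom' requires `subsets`")
    subsets <- lapply(subsets, function(s) sort(unique(as.integer(s))))
    names(subsets) <- vapply(subsets, function(s)
      paste(data$covariate_names[s], collapse = ","), "")
  } else {
    subsets <- subsets_for_mode(p, mode, groups = groups,
                                shapley_cap = shapley_cap,
                                names = data$covariate_names)
  }
  noSS <- algorithm %in% c("noSS-A", "noSS-B")
  if (is.null(K)) K <- if (noSS) 1L else 8L
  K <- as.integer(K)
  if (noSS && K != 1L) stop("noSS algorithms use K = 1 (no splitting)")
  if (algorithm == "SS-A" && K < 2L) stop("Algorithm SS-A requires K >= 2")
  if (algorithm == "SS-B" && K < 3L) stop("Algorithm SS-B requires K >= 3")

  seeds <- derive_seeds(seed, 4L)
  scheme <- make_folds(data$n, K, seed = seeds[1L],
                       stratify = if (stratify_folds) data$a else NULL)
  cfg <- list(algorithm = algorithm, mode = mode, K = K, level = level,
              clip = clip, seed = seed,
              outcome_learner = outcome_learner,
              propensity_learner = propensity_learner,
              cate_learner = cate_learner,
              projection_learner = projection_learner,
              propensity = propensity,
              seeds = seeds)

  pipe <- switch(algorithm,
                 "noSS-A" = , "noSS-B" = run_noss(data, scheme, subsets, cfg),
                 "SS-A" = run_ssa(data, scheme, subsets, cfg),
                 "SS-B" = run_ssb(data, scheme, subsets, cfg))

  assemble_tevim_fit(data, pipe, subsets, cfg, scheme)
}

log_fit <- function(log, fold, role, learner, n_train) {
  rbind(log, data.frame(fold = fold, role = role, learner = learner,
                        n_train = n_train, stringsAsFactors = FALSE))
}

fit_nuis_logged <- function(data, scheme, exclude, cfg, seed, log, fold_label) {
  nuis <- tryCatch(
    fit_nuisances(data, cfg$outcome_learner, cfg$propensity_learner,
                  propensity = cfg$propensity, scheme = scheme,
                  exclude = exclude, clip = cfg$clip, seed = seed),
    error = function(e)
      stop("nuisance fit excluding fold(s) ", paste(exclude, collapse = ","),
           ": ", conditionMessage(e), call. = FALSE))
  n_train <- sum(!(scheme$assignment %in% exclude))
  log <- log_fit(log, fold_label, "outcome", cfg$outcome_learner$name, n_train)
  if (is.null(cfg$propensity))
    log <- log_fit(log, fold_label, "propensity", cfg$propensity_learner$name, n_train)
  list(nuis = nuis, log = log)
}

# --- Algorithm noSS (variants A and B) --------------------------------------
run_noss <- function(data, scheme, subsets, cfg) {
  log <- data.frame()
  nl <- fit_nuis_logged(data, scheme, integer(0), cfg, cfg$seeds[2L], log, 0L)
  log <- nl$log
  ev <- eval_nuisances(nl$nuis, data, seq_len(data$n))
  prov <- rep(list(1L), data$n)
  phi <- new_pseudo_outcomes(ev$phi, prov)

  if (cfg$algorithm == "noSS-A") {
    tau <- ev$mu1 - ev$mu0
  } else {
    drfit <- dr_learner(phi, data$x, cfg$cate_learner, scheme,
                        exclude = integer(0), seed = cfg$seeds[3L])
    log <- log_fit(log, 0L, "cate", cfg$cate_learner$name, data$n)
    tau <- predict(drfit, data$x)
  }

  tau_s <- matrix(NA_real_, data$n, length(subsets))
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    if (length(s) == data$p) next  # full set: handled by the AIPW ATE
    pc <- project_cate(tau, data$x, s, cfg$projection_learner, scheme,
                       exclude = integer(0), seed = cfg$seeds[4L] + i)
    log <- log_fit(log, 0L, paste0("projection:", names(subsets)[i]),
                   cfg$projection_learner$name, data$n)
    tau_s[, i] <- predict(pc, data$x)
  }
  list(phi = phi, tau = tau, tau_s = tau_s, fit_log = log)
}

# --- Algorithm SS-A: cross-fitting with the T-learner -----------------------
run_ssa <- function(data, scheme, subsets, cfg) {
  n <- data$n; K <- scheme$K
  log <- data.frame()
  phi <- numeric(n); tau <- numeric(n)
  prov <- vector("list", n)
  tau_s <- matrix(NA_real_, n, length(subsets))
  for (k in seq_len(K)) {
    rows_k <- which(scheme$assignment == k)
    nl <- fit_nuis_logged(data, scheme, k, cfg, cfg$seeds[2L] + k, log, k)
    log <- nl$log
    ev <- eval_nuisances(nl$nuis, data, rows_k)
    phi[rows_k] <- ev$phi
    tau[rows_k] <- ev$mu1 - ev$mu0
    prov[rows_k] <- list(setdiff(seq_len(K), k))
    # T-learner evaluations of the fold-k-excluded fit on its own training
    # rows are the regression targets for tau_s
    t_train <- t_learner(nl$nuis, data$x)
    for (i in seq_along(subsets)) {
      s <- subsets[[i]]
      if (length(s) == data$p) next
      pc <- project_cate(t_train, data$x, s, cfg$projection_learner, scheme,
                         exclude = k, seed = cfg$seeds[4L] + K * i + k)
      log <- log_fit(log, k, paste0("projection:", names(subsets)[i]),
                     cfg$projection_learner$name, pc$n_train)
      tau_s[rows_k, i] <- predict(pc, data$x[rows_k, , drop = FALSE], fold = k)
    }
  }
  list(phi = new_pseudo_outcomes(phi, prov), tau = tau, tau_s = tau_s,
       fit_log = log)
}

# --- Algorithm SS-B: cross-fitting with the DR-learner ----------------------
run_ssb <- function(data, scheme, subsets, cfg) {
  n <- data$n; K <- scheme$K
  log <- data.frame()
  fold_of <- scheme$assignment
  # phi_pair[i, j]: pseudo-outcome for row i from the fit excluding
  # {fold(i), j}; defined for j != fold(i)
  phi_pair <- matrix(NA_real_, n, K)
  pair_id <- 0L
  for (j in seq_len(K - 1L)) for (k in (j + 1L):K) {
    pair_id <- pair_id + 1L
    nl <- fit_nuis_logged(data, scheme, c(j, k), cfg,
                          cfg$seeds[2L] + pair_id, log, j * 100L + k)
    log <- nl$log
    rows_j <- which(fold_of == j); rows_k <- which(fold_of == k)
    phi_pair[rows_j, k] <- eval_nuisances(nl$nuis, data, rows_j)$phi
    phi_pair[rows_k, j] <- eval_nuisances(nl$nuis, data, rows_k)$phi
  }

  # Step 2: per fold k, DR-learner trained on phi^{(k)} over the other folds
  tau <- numeric(n)
  for (k in seq_len(K)) {
    rows_k <- which(fold_of == k)
    targets <- phi_pair[, k]
    targets[rows_k] <- 0  # placeholder; fold k is excluded from training
    prov_k <- lapply(seq_len(n), function(i)
      setdiff(seq_len(K), c(fold_of[i], k)))
    phi_k <- structure(list(phi = ifelse(is.na(targets), 0, targets),
                            provenance = prov_k, n = n),
                       class = "pseudo_outcomes")
    drfit <- dr_learner(phi_k, data$x, cfg$cate_learner, scheme,
                        exclude = k, seed = cfg$seeds[3L] + k)
    log <- log_fit(log, k, "cate", cfg$cate_learner$name, drfit$n_train)
    tau[rows_k] <- predict(drfit, data$x[rows_k, , drop = FALSE], fold = k)
  }

  # Step 3: final pseudo-outcomes average the K - 1 pair evaluations
  phi <- rowMeans(phi_pair, na.rm = TRUE)
  n_avg <- rowSums(!is.na(phi_pair))
  if (any(n_avg != K - 1L)) stop("internal error: pair bookkeeping")
  prov <- lapply(seq_len(n), function(i) setdiff(seq_len(K), fold_of[i]))

  # Step 4: subset CATEs project the step-2 CATE evaluations
  tau_s <- matrix(NA_real_, n, length(subsets))
  for (k in seq_len(K)) {
    rows_k <- which(fold_of == k)
    for (i in seq_along(subsets)) {
      s <- subsets[[i]]
      if (length(s) == data$p) next
      pc <- project_cate(tau, data$x, s, cfg$projection_learner, scheme,
                         exclude = k, seed = cfg$seeds[4L] + K * i + k)
      log <- log_fit(log, k, paste0("projection:", names(subsets)[i]),
                     cfg$projection_learner$name, pc$n_train)
      tau_s[rows_k, i] <- predict(pc, data$x[rows_k, , drop = FALSE], fold = k)
    }
  }
  list(phi = new_pseudo_outcomes(phi, prov), tau = tau, tau_s = tau_s,
       fit_log = log)
}

# --- shared estimation layer ------------------------------------------------
assemble_tevim_fit <- function(data, pipe, subsets, cfg, scheme) {
  phi <- pipe$phi; tau <- pipe$tau
  level <- cfg$level
  ate <- aipw_ate(phi, level = level)
  ate$algorithm <- cfg$algorithm
  tau_p_hat <- ate$estimate
  theta_p <- theta_estimate(phi, tau, tau_p_hat, level = level,
                            algorithm = cfg$algorithm)

  theta_s <- vector("list", length(subsets))
  psi_s <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    th <- if (length(s) == data$p) {
      t2 <- theta_p; t2$subset <- s
      t2$subset_label <- names(subsets)[i]
      t2
    } else {
      theta_estimate(phi, tau, pipe$tau_s[, i], subset = s,
                     subset_label = names(subsets)[i], level = level,
                     algorithm = cfg$algorithm)
    }
    theta_s[[i]] <- th
    psi_s[[i]] <- psi_estimate(th, theta_p, level = level)
  }
  names(theta_s) <- names(psi_s) <- names(subsets)

  report <- build_mode_report(cfg$mode, subsets, theta_s, theta_p, data, level)

  structure(list(config = cfg, results = list(ate = ate, theta_p = theta_p,
                                              theta_s = theta_s, psi_s = psi_s),
                 mode_report = report, subsets = subsets,
                 phi = phi, tau = tau, tau_s = pipe$tau_s,
                 fit_log = pipe$fit_log, scheme = scheme),
            class = "tevim_fit")
}

build_mode_report <- function(mode, subsets, theta_s, theta_p, data, level) {
  if (mode == "koi") {
    kept <- vapply(subsets, function(s)
      data$covariate_names[setdiff(seq_len(data$p), s)], "")
    names(theta_s) <- kept
    return(koi_report(theta_s, theta_p, level = level))
  }
  if (mode == "shapley") {
    keys <- vapply(subsets, subset_key, "")
    th <- vapply(theta_s, function(r) r$estimate, 0)
    names(th) <- keys
    ics <- do.call(cbind, lapply(theta_s, function(r) r$ic_uncentered))
    colnames(ics) <- keys
    tab <- shapley_attributions(th, data$p, ics = ics, level = level)
    tab$covariate <- data$covariate_names
    return(structure(list(mode = "shapley", table = tab,
                          convention = "shapley", theta_p = theta_p$estimate),
                     class = "mode_report"))
  }
  tab <- do.call(rbind, lapply(theta_s, as.data.frame))
  rownames(tab) <- NULL
  structure(list(mode = mode, table = tab, convention = "raw_theta",
                 theta_p = theta_p$estimate),
            class = "mode_report")
}

#' Check the cross-fitting contract of a fitted pipeline
#'
#' Asserts that no row's pseudo-outcome was produced by a nuisance model
#' whose training folds include that row's own fold (trivially satisfied
#' for the single-sample algorithms, which make no such promise).
#'
#' @param fit a `tevim_fit`.
#' @return `TRUE` invisibly; error on violation.
#' @export
check_crossfit <- function(fit) {
  stopifnot(inherits(fit, "tevim_fit"))
  if (fit$scheme$K == 1L) return(invisible(TRUE))
  own <- fit$scheme$assignment
  bad <- vapply(seq_len(fit$phi$n), function(i)
    own[i] %in% fit$phi$provenance[[i]], logical(1))
  if (any(bad))
    stop("cross-fitting contract violated for ", sum(bad), " row(s)")
  invisible(TRUE)
}

#' @export
print.tevim_fit <- function(x, ...) {
  cat("TE-VIM fit —", x$config$algorithm, "| mode:", x$config$mode,
      "| K =", x$config$K, "| n =", x$phi$n, "\n\n")
  print(x$results$ate)
  print(x$results$theta_p)
  cat("\n")
  df <- as.data.frame(x)
  print(df[df$estimand %in% c("theta_s", "psi_s"), ], digits = 4)
  invisible(x)
}

#' Tidy table of estimates from a TE-VIM fit
#'
#' @param x a `tevim_fit`.
#' @param ... unused.
#' @return Data frame with columns estimand, subset, algorithm, estimate,
#'   se, ci_lo, ci_hi, level, n, flags.
#' @export
as.data.frame.tevim_fit <- function(x, ...) {
  rows <- c(list(x$results$ate, x$results$theta_p),
            x$results$theta_s, x$results$psi_s)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  out
}
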