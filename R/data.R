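#' Construct an observation table
#'
#' Bundles a continuous outcome, a binary treatment and a covariate matrix
#' into the container consumed by every estimator in the package. Missing or
#' non-finite values are rejected at construction.
#'
#' @param y numeric outcome vector.
#' @param a treatment vector coercible to 0/1 (numeric, logical, or the
#'   strings "0"/"1").
#' @param x covariate matrix or data frame (n rows, p columns).
#' @param covariate_names optional column labels; defaults to the column
#'   names of `x` or `X1..Xp`.
#' @return An object of class `te_data`: list with `y`, `a`, `x` (numeric
#'   matrix), `covariate_names`, `n`, `p`.
#' @examples
#' d <- te_data(y = rnorm(4), a = c(0, 1, 0, 1), x = matrix(rnorm(8), 4))
#' @export
te_data <- function(y, a, x, covariate_names = NULL) {
  y <- as.numeric(y)
  if (is.logical(a)) a <- as.integer(a)
  if (is.character(a) || is.factor(a)) {
    av <- suppressWarnings(as.numeric(as.character(a)))
    if (anyNA(av)) stop("treatment values not coercible to {0,1}: ",
                        paste(unique(a[is.na(av)]), collapse = ", "))
    a <- av
  }
  a <- as.numeric(a)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- length(y)
  if (length(a) != n || nrow(x) != n)
    stop("y, a and x must have the same number of rows")
  if (anyNA(y) || anyNA(a) || anyNA(x) ||
      any(!is.finite(y)) || any(!is.finite(x)))
    stop("missing or non-finite values are not allowed in an observation table")
  bad <- setdiff(unique(a), c(0, 1))
  if (length(bad))
    stop("treatment must be binary {0,1}; offending values: ",
         paste(bad, collapse = ", "))
  if (is.null(covariate_names)) {
    covariate_names <- colnames(x)
    if (is.null(covariate_names)) covariate_names <- paste0("X", seq_len(ncol(x)))
  }
  if (length(covariate_names) != ncol(x))
    stop("covariate_names must have one entry per column of x")
  colnames(x) <- covariate_names
  structure(list(y = y, a = as.integer(a), x = x,
                 covariate_names = covariate_names,
                 n = n, p = ncol(x)),
            class = "te_data")
}

#' @export
print.te_data <- function(x, ...) {
  cat("Observation table: n =", x$n, ", p =", x$p,
      "(", paste(x$covariate_names, collapse = ", "), ")\n")
  cat("Treated:", sum(x$a), "/", x$n, "\n")
  invisible(x)
}

#' Load an observation table from a CSV file
#'
#' Reads an RFC-4180 CSV with a header row and validates it into a
#' [te_data()] object. Rows containing missing values in the used columns
#' are rejected with a count.
#'
#' @param path file path.
#' @param outcome name of the outcome column.
#' @param treatment name of the treatment column (values must parse to 0/1).
#' @param covariates optional character vector of covariate column names;
#'   when omitted, every column other than the outcome and treatment is used.
#' @return A `te_data` object.
#' @export
load_table <- function(path, outcome, treatment, covariates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  need <- c(outcome, treatment, covariates)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(covariates))
    covariates <- setdiff(names(df), c(outcome, treatment))
  if (!length(covariates)) stop("no covariate columns found")
  use <- df[, c(outcome, treatment, covariates), drop = FALSE]
  nmiss <- sum(!stats::complete.cases(use))
  if (nmiss > 0)
    stop(nmiss, " row(s) contain missing values; missing data are not supported")
  te_data(y = use[[outcome]], a = use[[treatment]],
          x = use[, covariates, drop = FALSE], covariate_names = covariates)
}

#' Write results to a tidy CSV report
#'
#' Serializes estimation results (a [tevim()] fit, a list of `vim_result`
#' objects, a mode report or a study table) to a delimited table with stable
#' column order: estimand, subset, mode, algorithm, estimate, se, ci_lo,
#' ci_hi, flags.
#'
#' @param results object(s) to serialize.
#' @param path output CSV path.
#' @param sort sort rows by decreasing point estimate (the display convention
#'   for importance plots).
#' @return Invisibly, the data frame written.
#' @export
render_report <- function(results, path, sort = FALSE) {
  df <- results_to_df(results)
  if (is.null(df) || !nrow(df)) stop("nothing to write: empty results")
  if (sort && "estimate" %in% names(df))
    df <- df[order(-df$estimate), , drop = FALSE]
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE); TRUE },
                 error = function(e) stop("could not write report: ",
                                          conditionMessage(e)))
  invisible(df)
}

results_to_df <- function(results) {
  if (is.data.frame(results)) return(results)
  if (inherits(results, "vim_result")) return(as.data.frame(results))
  if (inherits(results, "tevim_fit")) return(as.data.frame(results))
  if (inherits(results, "mode_report")) return(as.data.frame(results))
  if (inherits(results, "te_study")) return(results$summary)
  if (is.list(results)) {
    if (!length(results)) stop("nothing to write: empty results")
    return(do.call(rbind, lapply(results, results_to_df)))
  }
  stop("unsupported results object of class ", paste(class(results), collapse = "/"))
}
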