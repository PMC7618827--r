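# shared fixtures built in code

# tiny deterministic table: two arms, one covariate
tiny_data <- function() {
  te_data(y = c(0, 0, 2, 2), a = c(0, 0, 1, 1),
          x = matrix(c(-1, 1, -1, 1), 4, 1, dimnames = list(NULL, "X1")))
}

# learner specs used across tests: correctly specified for DGP 1
lm_dgp1 <- function() learner_spec("lm", degree = 3, interactions = TRUE)
lm_prop1 <- function() learner_spec("lm", interactions = TRUE)

# oracle pseudo-outcomes for a generated benchmark dataset
oracle_phi <- function(d) {
  o <- attr(d, "oracle")
  pseudo_outcome(d$y, d$a, o$mu1, o$mu0, o$pi)
}

# DGP 3 closed-form subset CATE evaluations (linear Gaussian projection)
oracle_tau_s_dgp3 <- function(x, s) {
  Sigma <- kronecker(diag(3), matrix(c(1, 0.5, 0.5, 1), 2))
  a <- c(1, 2, 1, 0, 0, 0)
  keep <- setdiff(1:6, s)
  if (!length(keep)) return(rep(0, nrow(x)))
  beta <- solve(Sigma[keep, keep, drop = FALSE],
                Sigma[keep, , drop = FALSE] %*% a)
  drop(x[, keep, drop = FALSE] %*% beta)
}
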