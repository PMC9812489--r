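# Shared fixtures and independent dense-algebra oracles for the test suite.

# Random dosage genotypes guaranteed polymorphic in every column.
make_raw <- function(n, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    x <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
    if (all(apply(x, 2, function(col) length(unique(col)) > 1L))) break
  }
  raw_genotypes(x)
}

make_design <- function(n, m, seed = NULL) {
  raw <- make_raw(n, m, seed)
  standardize(raw, y_raw = rnorm(n))
}

# Dense assembly of the MME coefficient matrix A and right-hand side b,
# the oracle the matrix-free operator and PCG are checked against.
dense_mme <- function(design, lambda) {
  Zs <- design$Z / sqrt(design$m)
  X <- matrix(1, design$n, 1)
  A <- rbind(
    cbind(crossprod(X), crossprod(X, Zs)),
    cbind(crossprod(Zs, X), crossprod(Zs) + lambda * diag(design$m))
  )
  b <- c(crossprod(X, design$y), crossprod(Zs, design$y))
  list(A = unname(A), b = as.numeric(b))
}

# Dense tr[(ZZ'/m)^2] for Hutchinson checks.
dense_trace_omega2 <- function(Z) {
  omega <- tcrossprod(Z) / ncol(Z)
  sum(omega * omega)
}
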