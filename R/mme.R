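#' Matrix-free operator for the SNP-BLUP mixed-model equations
#'
#' Represents the coefficient matrix
#' \deqn{A = [X'X, X'Z*; Z*'X, Z*'Z* + lambda I]}
#' of the mixed-model equations for the additive model
#' y = X theta + Z* u + e, where X is the intercept column and
#' Z* = Z / sqrt(m) is the standardized genotype matrix rescaled so that
#' the ridge parameter lambda = sigma_e2 / sigma_g2 on the GRM scale makes
#' SNP-BLUP algebraically identical to GBLUP with G = ZZ'/m. A is applied
#' to vectors via factored products only — A itself, Z'Z and ZZ' are never
#' formed.
#'
#' @param design a \code{\link{standardize}}d design.
#' @param lambda ridge parameter added to the marker block (> 0).
#' @return Object of class \code{mme_operator} with fields \code{Zs}
#'   (= Z/sqrt(m)), \code{n}, \code{m}, \code{dim} (= m + 1),
#'   \code{lambda}, and the analytic \code{diag} of A
#'   (diag(X'X) = n; diag(Z*'Z*)_j = n/m under divisor-n scaling).
#' @export
mme_operator <- function(design, lambda) {
  stopifnot(inherits(design, "std_design"), lambda > 0)
  n <- design$n
  m <- design$m
  Zs <- if (m > 0L) design$Z / sqrt(m) else NULL
  structure(
    list(Zs = Zs, n = n, m = m, dim = m + 1L, lambda = lambda,
         diag = c(n, rep(n / max(m, 1L) + lambda, m))),
    class = "mme_operator"
  )
}

#' Apply the MME coefficient matrix to a vector
#'
#' Computes A v through the shared intermediate t = X v0 + Z* v1 (length
#' n), returning c(X't, Z*'t + lambda v1). O(nm) work, O(n + m) extra
#' memory.
#'
#' @param op an \code{\link{mme_operator}}.
#' @param v numeric vector of length m + 1 (intercept block first).
#' @return Numeric vector A v of length m + 1.
#' @export
apply_operator <- function(op, v) {
  stopifnot(inherits(op, "mme_operator"))
  if (length(v) != op$dim) {
    stop("operator dimension ", op$dim, " != vector length ", length(v))
  }
  v0 <- v[1L]
  if (op$m == 0L) return(op$n * v0)
  v1 <- v[-1L]
  t <- v0 + drop(op$Zs %*% v1) # X v0 + Z* v1
  c(sum(t), drop(crossprod(op$Zs, t)) + op$lambda * v1)
}

#' Preconditioned conjugate gradient solve of the mixed-model equations
#'
#' Textbook preconditioned CG for the symmetric positive-definite system
#' A x = b with the Jacobi preconditioner M = diag(A), whose entries are
#' known analytically for the MME operator (no dense pass). The recurred
#' residual drives the iteration; the true residual b - A x is recomputed
#' every 50 iterations and at the declared convergence point to guard
#' against drift.
#'
#' @param op an \code{\link{mme_operator}}.
#' @param b right-hand side, length m + 1 (c(X'y, Z*'y) for the MME).
#' @param tol convergence tolerance on the relative residual
#'   ||b - A x|| / ||b||.
#' @param max_iter iteration cap (default 10 (m + 1)).
#' @param preconditioner "jacobi" (M = diag(A)) or "identity" (plain CG).
#' @param x0 optional start vector (default zero).
#' @return Object of class \code{mme_solution}: \code{theta_hat},
#'   \code{u_hat} (marker effects on the Z* = Z/sqrt(m) scale),
#'   \code{iterations}, \code{rel_residual}, \code{converged}.
#' @export
pcg_solve <- function(op, b, tol = 1e-8, max_iter = NULL,
                      preconditioner = c("jacobi", "identity"), x0 = NULL) {
  stopifnot(inherits(op, "mme_operator"), tol > 0, all(is.finite(b)),
            length(b) == op$dim)
  preconditioner <- match.arg(preconditioner)
  if (is.null(max_iter)) max_iter <- 10L * op$dim
  Minv <- if (preconditioner == "jacobi") 1 / op$diag else rep(1, op$dim)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) {
    return(new_mme_solution(numeric(op$dim), op, 0L, 0, TRUE))
  }
  x <- if (is.null(x0)) numeric(op$dim) else as.numeric(x0)
  r <- b - apply_operator(op, x)
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  iter <- 0L
  relres <- sqrt(sum(r^2)) / bnorm
  while (relres > tol && iter < max_iter) {
    iter <- iter + 1L
    Ap <- apply_operator(op, p)
    pAp <- sum(p * Ap)
    if (pAp <= 0) {
      stop("non-SPD behavior detected at iteration ", iter,
           " (p'Ap = ", format(pAp), ")")
    }
    alpha <- rz / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (iter %% 50L == 0L) r <- b - apply_operator(op, x) # drift guard
    relres <- sqrt(sum(r^2)) / bnorm
    if (relres <= tol) {
      # confirm on the true residual before declaring convergence
      r <- b - apply_operator(op, x)
      relres <- sqrt(sum(r^2)) / bnorm
      if (relres <= tol) break
    }
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  new_mme_solution(x, op, iter, relres, relres <= tol)
}

new_mme_solution <- function(x, op, iterations, rel_residual, converged) {
  structure(
    list(theta_hat = x[1L],
         u_hat = if (op$dim > 1L) x[-1L] else numeric(0),
         m = op$m, lambda = op$lambda,
         iterations = iterations, rel_residual = rel_residual,
         converged = converged),
    class = "mme_solution"
  )
}

#' @export
print.mme_solution <- function(x, ...) {
  cat(sprintf(
    "MME solution: theta_hat = %.4f, %d marker effects; %d PCG iterations, rel. residual %.2e (%s)\n",
    x$theta_hat, length(x$u_hat), x$iterations, x$rel_residual,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit SNP-BLUP by RHE heritability plus PCG (the RHEPCG fit)
#'
#' Forms the ridge parameter lambda = (1 - h2) / h2 from the supplied
#' variance components (h2 is clamped into [0.001, 0.999] first so lambda
#' stays finite and nonzero; a clamp at the boundary is reported with a
#' warning because the heritability estimate is then uninformative), builds
#' the matrix-free MME operator and right-hand side c(X'y, Z*'y), and
#' solves by \code{\link{pcg_solve}}.
#'
#' @param design training \code{std_design} with phenotypes.
#' @param components \code{\link{variance_components}} (typically from
#'   \code{\link{rhe_fit}}; pass simulation truth for oracle experiments).
#' @param tol,max_iter passed to \code{\link{pcg_solve}}.
#' @return An \code{mme_solution} with the components used attached as
#'   attribute \code{"components"}.
#' @export
fit_rhepcg <- function(design, components, tol = 1e-8, max_iter = NULL) {
  stopifnot(inherits(design, "std_design"),
            inherits(components, "variance_components"))
  if (is.null(design$y)) stop("design carries no phenotypes")
  h2 <- components$h2
  h2c <- min(max(h2, 0.001), 0.999)
  if (h2c != h2) {
    warning("h2 = ", format(h2), " clamped to ", h2c,
            " before forming lambda; estimate is uninformative")
  }
  lambda <- (1 - h2c) / h2c
  op <- mme_operator(design, lambda)
  b <- c(sum(design$y), drop(crossprod(op$Zs, design$y)))
  sol <- pcg_solve(op, b, tol = tol, max_iter = max_iter)
  attr(sol, "components") <- components
  sol
}

#' Predict genotypic values for candidate individuals
#'
#' Standardizes the candidate genotypes with the training-set means and
#' scales (marker effects live on the training scale) and applies the
#' fitted marker effects: g_hat = (Z_cand / sqrt(m)) u_hat. Predictions are
#' on the standardized-phenotype scale; set \code{rescale = TRUE} to map
#' them back to the raw phenotype scale using the training mean/SD.
#'
#' @param solution an \code{mme_solution} from \code{\link{fit_rhepcg}} or
#'   \code{\link{pcg_solve}}.
#' @param raw_cand candidate \code{\link{raw_genotypes}}.
#' @param reference the training \code{std_design} the model was fitted on.
#' @param rescale return predictions on the raw phenotype scale (adds the
#'   intercept and undoes phenotype standardization).
#' @return Numeric vector of predicted genotypic values.
#' @export
predict_genetic_values <- function(solution, raw_cand, reference,
                                   rescale = FALSE) {
  stopifnot(inherits(solution, "mme_solution"),
            inherits(reference, "std_design"))
  d <- standardize(raw_cand, reference = reference)
  g <- drop(d$Z %*% solution$u_hat) / sqrt(solution$m)
  if (rescale) {
    g <- (g + solution$theta_hat) * reference$y_scale + reference$y_center
  }
  g
}
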