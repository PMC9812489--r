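#' Genomic relationship matrix with cached eigendecomposition
#'
#' G = ZZ'/m from the standardized training design. Under divisor-n column
#' scaling trace(G) = n exactly. The spectral decomposition is computed
#' once and reused by REML and BLUP — the O(n^3) step that the matrix-free
#' RHEPCG path avoids.
#'
#' @param design a \code{\link{standardize}}d training design.
#' @return Object of class \code{grm}: \code{G}, eigen \code{values} and
#'   \code{vectors}, the training \code{Z}, \code{n}, \code{m}.
#' @export
build_grm <- function(design) {
  stopifnot(inherits(design, "std_design"))
  G <- tcrossprod(design$Z) / design$m
  eig <- eigen(G, symmetric = TRUE)
  structure(
    list(G = G, values = eig$values, vectors = eig$vectors,
         Z = design$Z, n = design$n, m = design$m),
    class = "grm"
  )
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("GRM: %d x %d (from %d markers), trace = %.4f, top eigenvalue = %.3f\n",
              x$n, x$n, x$m, sum(diag(x$G)), x$values[1L]))
  invisible(x)
}

#' Profile REML estimation of heritability on the GRM
#'
#' Maximizes the restricted likelihood of y ~ N(1 theta, sigma_g2 G +
#' sigma_e2 I) by one-dimensional optimization over h2 in the eigenbasis of
#' G: for each candidate h2 the total variance and the GLS intercept have
#' closed forms, so Brent search over h2 in [1e-4, 1 - 1e-4] (tolerance
#' 1e-8) is all that remains. Deterministic and O(n^3) once for the
#' decomposition — the conventional-GBLUP cost profile.
#'
#' @param grm a \code{\link{build_grm}} result.
#' @param y phenotypes (typically the standardized \code{design$y}).
#' @return Object of class \code{reml_fit}: \code{components}
#'   (\code{\link{variance_components}}, method "REML"), \code{theta_hat},
#'   \code{loglik} (restricted log-likelihood at the optimum, up to an
#'   additive constant), \code{boundary} flag (optimum at a clamp bound or
#'   likelihood flat, e.g. G = I).
#' @export
reml_fit <- function(grm, y) {
  stopifnot(inherits(grm, "grm"), length(y) == grm$n)
  n <- grm$n
  if (n < 3L) stop("REML needs n >= 3")
  d <- pmax(grm$values, 0)
  yt <- drop(crossprod(grm$vectors, y))
  xt <- drop(crossprod(grm$vectors, rep(1, n)))
  # negative restricted log-likelihood, profiled over theta and total variance
  nll <- function(h2) {
    delta <- h2 * d + (1 - h2)
    w <- 1 / delta
    sxx <- sum(xt^2 * w)
    theta <- sum(xt * yt * w) / sxx
    r <- yt - xt * theta
    sp2 <- sum(r^2 * w) / (n - 1)
    0.5 * (sum(log(delta)) + (n - 1) * log(sp2) + log(sxx) + (n - 1))
  }
  lo <- 1e-4
  hi <- 1 - 1e-4
  opt <- stats::optimize(nll, c(lo, hi), tol = 1e-8)
  h2 <- opt$minimum
  grid <- vapply(seq(lo, hi, length.out = 9L), nll, numeric(1))
  flat <- (max(grid) - min(grid)) < 1e-8
  boundary <- flat || h2 < lo + 1e-3 || h2 > hi - 1e-3
  if (boundary) {
    warning("REML optimum at the boundary or likelihood flat in h2; ",
            "estimate may be unidentifiable")
  }
  delta <- h2 * d + (1 - h2)
  w <- 1 / delta
  theta <- sum(xt * yt * w) / sum(xt^2 * w)
  sp2 <- sum((yt - xt * theta)^2 * w) / (n - 1)
  structure(
    list(components = variance_components(h2 * sp2, (1 - h2) * sp2, "REML"),
         theta_hat = theta, loglik = -opt$objective, boundary = boundary),
    class = "reml_fit"
  )
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("profile REML: h2 = %.4f, restricted loglik = %.3f%s\n",
              x$components$h2, x$loglik,
              if (x$boundary) " [boundary/flat]" else ""))
  invisible(x)
}

#' GBLUP prediction of genotypic values
#'
#' Direct BLUP through the training GRM: with lambda_G = sigma_e2 /
#' sigma_g2 and theta_hat the GLS intercept,
#' alpha = (G + lambda_G I)^{-1} (y - 1 theta_hat), training genetic values
#' are G alpha and candidate values use the train-candidate relationship
#' block (Z_cand Z_train' / m) alpha, with the candidates standardized on
#' the training scale. All solves go through the cached eigendecomposition.
#'
#' @param grm training \code{\link{build_grm}} result.
#' @param components \code{\link{variance_components}} (typically REML).
#' @param y training phenotypes used in the fit.
#' @param Z_cand optional candidate genotype matrix standardized with the
#'   training means/scales (e.g. \code{standardize(raw_cand, reference =
#'   train_design)$Z}).
#' @return Object of class \code{gblup_prediction}: \code{ghat_train},
#'   \code{ghat_cand} (NULL without \code{Z_cand}), \code{theta_hat},
#'   \code{lambda}.
#' @export
gblup_predict <- function(grm, components, y, Z_cand = NULL) {
  stopifnot(inherits(grm, "grm"),
            inherits(components, "variance_components"),
            length(y) == grm$n)
  h2 <- min(max(components$h2, 1e-6), 1 - 1e-6)
  lambda <- (1 - h2) / h2
  d <- pmax(grm$values, 0)
  U <- grm$vectors
  w <- 1 / (d + lambda)
  kinv <- function(v) drop(U %*% (w * drop(crossprod(U, v))))
  one <- rep(1, grm$n)
  k1 <- kinv(one)
  theta <- sum(k1 * y) / sum(k1 * one)
  alpha <- kinv(y - theta)
  ghat_train <- drop(grm$G %*% alpha)
  ghat_cand <- NULL
  if (!is.null(Z_cand)) {
    if (ncol(Z_cand) != grm$m) {
      stop("Z_cand has ", ncol(Z_cand), " markers; GRM was built from ", grm$m)
    }
    ghat_cand <- drop(Z_cand %*% crossprod(grm$Z, alpha)) / grm$m
  }
  structure(
    list(ghat_train = ghat_train, ghat_cand = ghat_cand,
         theta_hat = theta, lambda = lambda),
    class = "gblup_prediction"
  )
}

#' @export
print.gblup_prediction <- function(x, ...) {
  cat(sprintf(
    "GBLUP prediction: theta_hat = %.4f, lambda = %.4g, %d training%s values\n",
    x$theta_hat, x$lambda, length(x$ghat_train),
    if (is.null(x$ghat_cand)) "" else sprintf(" + %d candidate",
                                              length(x$ghat_cand))))
  invisible(x)
}
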