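#' Hutchinson estimate of tr[(ZZ'/m)^2]
#'
#' Randomized trace estimation for the squared genomic relationship matrix
#' omega = ZZ'/m: for each probe w_s with i.i.d. N(0,1) entries,
#' w_s' omega^2 w_s is an unbiased draw of tr[omega^2]. Each probe costs two
#' matrix-vector products with Z (v = Z'w, t = Zv, then ||t||^2 / m^2);
#' neither ZZ' nor its square is ever materialized, so extra memory is
#' O(n + m).
#'
#' @param Z standardized genotype matrix (n x m).
#' @param S number of random probes (>= 1); 5 is the working default of
#'   the full heritability fit.
#' @return Scalar estimate of tr[omega^2], with the per-probe draws in
#'   attribute \code{"probes"}.
#' @export
estimate_trace_omega2 <- function(Z, S = 5L) {
  if (S < 1L) stop("probe count S must be >= 1")
  n <- nrow(Z)
  m <- ncol(Z)
  draws <- numeric(S)
  for (s in seq_len(S)) {
    w <- stats::rnorm(n)
    v <- drop(crossprod(Z, w)) # Z'w, length m
    t <- drop(Z %*% v)         # ZZ'w, length n
    draws[s] <- sum(t * t) / m^2
  }
  structure(mean(draws), probes = draws)
}

#' Heritability by randomized Haseman-Elston regression
#'
#' Method-of-moments estimator of the additive and residual variance on the
#' GRM scale. Regressing phenotype products y_i y_j on genomic relatedness
#' omega_ij leads to the two-moment system
#' \deqn{[tr(omega^2), tr(omega); tr(omega), n] (sigma_g2, sigma_e2)' =
#'       (y' omega y, y'y)'}
#' in which tr(omega) = n exactly under divisor-n genotype scaling, y'omega
#' y = ||Z'y||^2 / m is computed exactly in one O(nm) pass, and tr(omega^2)
#' comes from \code{\link{estimate_trace_omega2}}. Total cost is O(nm S)
#' time and O(n + m) extra memory; the GRM is never formed.
#'
#' sigma_g2 is clamped to [0, sigma_y2] (the moment estimator can go
#' negative when there is no genetic signal) and sigma_e2 to be
#' non-negative; the reported h2 therefore lies in [0, 1].
#'
#' @param design a \code{\link{standardize}}d training design with
#'   phenotypes.
#' @param S number of random probes (default 5).
#' @param probe_seed optional seed for the probe substream; the caller's
#'   RNG state is restored afterwards.
#' @return Object of class \code{he_fit}: \code{components}
#'   (\code{\link{variance_components}}, method "RHE"),
#'   \code{trace_omega2_hat}, \code{yT_omega_y}, \code{sigma_y2}, \code{S},
#'   \code{n}, \code{m}.
#' @examples
#' pop <- simulate_f2(300, 50, h2 = 0.5, m = 400, seed = 2)
#' d <- standardize(subset_genotypes(pop$genotypes, pop$train),
#'                  y_raw = pop$phenotypes[pop$train])
#' rhe_fit(d, S = 5, probe_seed = 99)$components$h2
#' @export
rhe_fit <- function(design, S = 5L, probe_seed = NULL) {
  stopifnot(inherits(design, "std_design"))
  y <- design$y
  if (is.null(y)) stop("design carries no phenotypes")
  n <- design$n
  m <- design$m
  yy <- sum(y^2)
  sigma_y2 <- (yy - n * mean(y)^2) / (n - 1)
  if (sigma_y2 <= 0) stop("phenotype is constant; heritability undefined")
  y_omega_y <- sum(drop(crossprod(design$Z, y))^2) / m
  tr2 <- with_seed(probe_seed, estimate_trace_omega2(design$Z, S))
  denom <- as.numeric(tr2) - n
  if (denom <= 1e-8 * n) {
    stop("degenerate relatedness: tr[omega^2] ~ n, omega is indistinguishable from I")
  }
  sigma_g2 <- (y_omega_y - yy) / denom
  sigma_g2 <- min(max(sigma_g2, 0), sigma_y2)
  sigma_e2 <- max(yy / n - sigma_g2, 0)
  structure(
    list(components = variance_components(sigma_g2, sigma_e2, "RHE"),
         trace_omega2_hat = as.numeric(tr2), yT_omega_y = y_omega_y,
         sigma_y2 = sigma_y2, S = S, n = n, m = m),
    class = "he_fit"
  )
}

#' @export
print.he_fit <- function(x, ...) {
  cat(sprintf(
    "randomized HE fit (S = %d probes): h2 = %.4f (sigma_g2 = %.4g, sigma_e2 = %.4g)\n",
    x$S, x$components$h2, x$components$sigma_g2, x$components$sigma_e2))
  cat(sprintf("  tr[omega^2] estimate = %.2f (n = %d)\n",
              x$trace_omega2_hat, x$n))
  invisible(x)
}
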