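#' Simulate F2 gametes along a single chromosome
#'
#' Each gamete is a binary vector marking which parental allele is carried
#' at each of m equally spaced markers. The first marker's allele is
#' Bernoulli(0.5); the allele then switches between adjacent markers with
#' probability exactly \code{c} (a first-order Markov chain with constant
#' recombination fraction per interval, no interference).
#'
#' @param n_gametes number of gametes to draw.
#' @param m number of markers.
#' @param c recombination fraction between adjacent markers, 0 < c < 0.5.
#' @return Binary matrix \code{n_gametes x m}.
#' @export
simulate_gametes <- function(n_gametes, m, c = 0.01) {
  stopifnot(n_gametes >= 1L, m >= 1L, c >= 0, c < 0.5)
  first <- stats::rbinom(n_gametes, 1L, 0.5)
  if (m == 1L) return(matrix(first, ncol = 1L))
  switches <- matrix(stats::rbinom(n_gametes * (m - 1L), 1L, c),
                     nrow = n_gametes)
  # allele at marker k = (first + #switches before k) mod 2
  al <- t(apply(cbind(first, switches), 1L, cumsum)) %% 2L
  dimnames(al) <- NULL
  al
}

#' Simulate an F2 population with a controlled heritability
#'
#' Emulates a cross of two inbred lines: one chromosome of length
#' \code{m - 1} intervals at recombination fraction \code{c} per interval
#' (the default m = 2000 at c = 0.01 corresponds to a 2,000 cM chromosome
#' with markers ~1 cM apart), every marker a QTL. Each F2 individual's
#' dosage is the sum of two independent gametes. Marker effects are i.i.d.
#' standard normal; genetic values are computed on the centered/scaled
#' cohort design so that simulated additive variance lives on the same
#' GRM scale the estimators report. The residual variance is calibrated to
#' the realized genetic variance, sigma_e2 = Var(g) (1 - h2) / h2, so each
#' replicate's realized heritability matches the target.
#'
#' Draw order under one RNG stream (reproducibility contract): gametes,
#' then marker effects, then residuals.
#'
#' @param n_train training-population size (>= 2).
#' @param n_cand candidate-population size (>= 1).
#' @param h2 target heritability in (0, 1).
#' @param m marker (= QTL) count, default 2000.
#' @param c recombination fraction per marker interval, default 0.01.
#' @param seed optional integer seed; identical seed + configuration gives
#'   a bit-identical population.
#' @return An object of class \code{f2_population}: \code{genotypes}
#'   (\code{\link{raw_genotypes}} for all n_train + n_cand individuals),
#'   \code{beta_true}, \code{g_true}, \code{phenotypes},
#'   \code{train}/\code{cand} index sets, \code{sigma_e2_used}, and the
#'   configuration echo.
#' @examples
#' pop <- simulate_f2(50, 10, h2 = 0.5, m = 100, seed = 1)
#' var(pop$g_true) / var(pop$phenotypes) # close to 0.5
#' @export
simulate_f2 <- function(n_train, n_cand, h2, m = 2000L, c = 0.01,
                        seed = NULL) {
  stopifnot(n_train >= 2L, n_cand >= 1L, h2 > 0, h2 < 1, c > 0, c < 0.5,
            m >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n <- n_train + n_cand
  repeat {
    gam <- simulate_gametes(2L * n, m, c)
    dosage <- gam[seq_len(n), , drop = FALSE] +
      gam[n + seq_len(n), , drop = FALSE]
    rng <- matrixStats_range(dosage)
    if (all(rng[2L, ] > rng[1L, ])) break
    warning("monomorphic marker in simulated cohort; resampling")
  }
  genotypes <- raw_genotypes(dosage)
  beta <- stats::rnorm(m)
  cohort <- standardize(genotypes)
  g <- drop(cohort$Z %*% beta)
  var_g <- stats::var(g)
  sigma_e2 <- var_g * (1 - h2) / h2
  e <- stats::rnorm(n, 0, sqrt(sigma_e2))
  structure(
    list(genotypes = genotypes, beta_true = beta, g_true = g,
         phenotypes = g + e,
         train = seq_len(n_train), cand = n_train + seq_len(n_cand),
         sigma_e2_used = sigma_e2,
         config = list(n_train = n_train, n_cand = n_cand, h2 = h2, m = m,
                       c = c, seed = seed)),
    class = "f2_population"
  )
}

# columnwise min/max without allocating beyond 2 x m
matrixStats_range <- function(x) {
  rbind(apply(x, 2L, min), apply(x, 2L, max))
}

#' @export
print.f2_population <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "F2 population: %d train + %d candidate individuals, %d markers (c = %g), target h2 = %g\n",
    cfg$n_train, cfg$n_cand, cfg$m, cfg$c, cfg$h2))
  cat(sprintf("realized Var(g) = %.3f, sigma_e2 = %.3f\n",
              stats::var(x$g_true), x$sigma_e2_used))
  invisible(x)
}
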