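test_that("the GRM has unit diagonal structure implied by divisor-n scaling", {
  # single marker, n = 2: perfect negative relatedness
  d <- standardize(raw_genotypes(cbind(c(0, 2), c(1, 2))))
  d$Z <- d$Z[, 1L, drop = FALSE]
  d$m <- 1L
  g <- build_grm(d)
  expect_equal(g$G, rbind(c(1, -1), c(-1, 1)), tolerance = 1e-12)

  d <- make_design(25, 12, seed = 41)
  g <- build_grm(d)
  expect_equal(sum(diag(g$G)), d$n, tolerance = 1e-8)
  expect_lt(max(abs(g$G - t(g$G))), 1e-10)
  expect_gt(min(g$values), -1e-8)
  # entries match the manual pairwise arithmetic sum_k z_ik z_jk / m
  raw4 <- make_raw(4, 3, seed = 42)
  d4 <- standardize(raw4)
  g4 <- build_grm(d4)
  for (i in 1:4) for (j in 1:4) {
    manual <- sum(d4$Z[i, ] * d4$Z[j, ]) / 3
    expect_equal(g4$G[i, j], manual, tolerance = 1e-12)
  }
})

test_that("profile REML maximizes the restricted likelihood", {
  pop <- simulate_f2(150, 20, h2 = 0.5, m = 300, seed = 43)
  d <- standardize(subset_genotypes(pop$genotypes, pop$train),
                   y_raw = pop$phenotypes[pop$train])
  g <- build_grm(d)
  fit <- reml_fit(g, d$y)
  expect_false(fit$boundary)
  expect_true(is.finite(fit$loglik))
  # optimality against a 50-point grid of the same restricted likelihood
  n <- d$n
  dvals <- pmax(g$values, 0)
  yt <- drop(crossprod(g$vectors, d$y))
  xt <- drop(crossprod(g$vectors, rep(1, n)))
  ll <- function(h2) {
    delta <- h2 * dvals + (1 - h2)
    w <- 1 / delta
    theta <- sum(xt * yt * w) / sum(xt^2 * w)
    sp2 <- sum((yt - xt * theta)^2 * w) / (n - 1)
    -0.5 * (sum(log(delta)) + (n - 1) * log(sp2) + log(sum(xt^2 * w)) +
              (n - 1))
  }
  grid <- vapply(seq(0.001, 0.999, length.out = 50), ll, numeric(1))
  expect_gte(fit$loglik, max(grid) - 1e-6)
})

test_that("an identity-like GRM is flagged as unidentifiable", {
  d <- make_design(10, 4, seed = 44)
  g <- build_grm(d)
  g$G <- diag(10)
  g$values <- rep(1, 10)
  g$vectors <- diag(10)
  expect_warning(fit <- reml_fit(g, d$y), "boundary|flat")
  expect_true(fit$boundary)
})

test_that("profile REML agrees with a generic two-parameter REML optimizer", {
  # independent route: direct dense restricted likelihood in (sigma_g2,
  # sigma_e2), optimized by Nelder-Mead on the log scale
  generic_reml_h2 <- function(G, y) {
    n <- length(y)
    X <- matrix(1, n, 1)
    nll <- function(par) {
      sg <- exp(par[1]); se <- exp(par[2])
      V <- sg * G + se * diag(n)
      cV <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(cV)) return(1e10)
      Vi <- chol2inv(cV)
      XtVX <- drop(crossprod(X, Vi %*% X))
      theta <- drop(crossprod(X, Vi %*% y)) / XtVX
      r <- y - X %*% theta
      0.5 * (2 * sum(log(diag(cV))) + log(XtVX) + drop(crossprod(r, Vi %*% r)))
    }
    o <- optim(c(0, 0), nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
    exp(o$par[1]) / sum(exp(o$par))
  }
  set.seed(45)
  for (k in 1:10) {
    pop <- simulate_f2(60, 5, h2 = runif(1, 0.3, 0.7), m = 150,
                       seed = 4500L + k)
    d <- standardize(subset_genotypes(pop$genotypes, pop$train),
                     y_raw = pop$phenotypes[pop$train])
    g <- build_grm(d)
    fit <- reml_fit(g, d$y)
    expect_equal(fit$components$h2, generic_reml_h2(g$G, d$y),
                 tolerance = 1e-4)
  }
})

test_that("complete shrinkage drives GBLUP predictions to zero", {
  d <- make_design(30, 10, seed = 46)
  g <- build_grm(d)
  cand <- standardize(make_raw(8, 10, seed = 47), reference = d)$Z
  pred <- gblup_predict(g, variance_components(1e-9, 1, "TRUE"), d$y,
                        Z_cand = cand)
  expect_lt(max(abs(pred$ghat_cand)), 1e-5)
  expect_lt(max(abs(pred$ghat_train)), 1e-5)
})

test_that("SNP-BLUP via PCG and GBLUP give identical predictions under shared lambda", {
  set.seed(48)
  for (k in 1:5) {
    pop <- simulate_f2(80, 15, h2 = runif(1, 0.3, 0.8), m = 200,
                       seed = 4800L + k)
    d <- standardize(subset_genotypes(pop$genotypes, pop$train),
                     y_raw = pop$phenotypes[pop$train])
    raw_cand <- subset_genotypes(pop$genotypes, pop$cand)
    comp <- variance_components(0.6, 0.4, "TRUE")
    sol <- fit_rhepcg(d, comp, tol = 1e-12)
    snp_blup <- predict_genetic_values(sol, raw_cand, d)
    g <- build_grm(d)
    Zc <- standardize(raw_cand, reference = d)$Z
    gblup <- gblup_predict(g, comp, d$y, Z_cand = Zc)
    expect_lt(max(abs(snp_blup - gblup$ghat_cand)), 1e-6)
    expect_equal(sol$theta_hat, gblup$theta_hat, tolerance = 1e-6)
  }
})

test_that("REML heritability bias shrinks as the training population grows", {
  bias <- vapply(c(200L, 800L), function(n) {
    est <- vapply(1:8, function(r) {
      pop <- simulate_f2(n, 10, h2 = 0.5, m = 500, seed = 50000L + n + r)
      d <- standardize(subset_genotypes(pop$genotypes, pop$train),
                       y_raw = pop$phenotypes[pop$train])
      reml_fit(build_grm(d), d$y)$components$h2
    }, numeric(1))
    abs(mean(est) - 0.5)
  }, numeric(1))
  expect_lt(bias[2L], bias[1L] + 0.03)
})
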