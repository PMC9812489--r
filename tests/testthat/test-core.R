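test_that("delimited genotype files parse and domain violations are caught", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0\t1", "2\t2", "1\t0"), tsv)
  suppressMessages(raw <- load_genotypes(tsv, dialect = "tsv"))
  expect_equal(raw$n, 3L)
  expect_equal(raw$m, 2L)
  expect_equal(raw$matrix, rbind(c(0, 1), c(2, 2), c(1, 0)))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("3\t1", "0\t2"), bad)
  expect_error(suppressMessages(load_genotypes(bad)),
               "row 1, column 1")

  ragged <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0\t1\t2", "0\t1"), ragged)
  expect_error(suppressMessages(load_genotypes(ragged)), "format error")

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,m1,m2", "i1,0,2", "i2,1,1"), csv)
  suppressMessages(raw <- load_genotypes(csv, dialect = "csv", header = TRUE,
                                         id_column = TRUE))
  expect_equal(raw$ids, c("i1", "i2"))
  expect_equal(raw$marker_names, c("m1", "m2"))
})

test_that("PLINK .raw dialect takes dosages from column 7 on and IDs from IID", {
  path <- system.file("extdata", "toy_f2_synthetic.raw", package = "rhepcg")
  suppressMessages(raw <- load_genotypes(path, dialect = "plink_raw"))
  expect_equal(raw$n, 2L)
  expect_equal(raw$m, 3L)
  expect_equal(raw$ids, c("id1", "id2"))
  expect_equal(raw$marker_names, c("snp1_A", "snp2_G", "snp3_T"))
  expect_equal(raw$matrix, rbind(c(0, 1, 2), c(2, 0, 1)))
})

test_that("missing genotypes are rejected by default and mean-imputed on request", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0\tNA", "2\t2", "1\t0"), tsv)
  expect_error(suppressMessages(load_genotypes(tsv)), "missing genotype")
  suppressMessages(raw <- load_genotypes(tsv, impute_missing = TRUE))
  expect_equal(raw$matrix[1L, 2L], 1) # round(mean(2, 0))
})

test_that("phenotype loader aligns two-column files against genotype IDs", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("i2\t5.5", "i1\t-1.25"), p)
  expect_equal(load_phenotypes(p, ids = c("i1", "i2")), c(-1.25, 5.5))
  expect_error(load_phenotypes(p, ids = c("i1", "i3")), "missing IDs")
})

test_that("standardization centers to mean 0 and scales to sum of squares n", {
  # single column (0,1,2): mean 1, divisor-3 variance 2/3
  d <- standardize(raw_genotypes(cbind(0:2, c(2, 0, 2))),
                   y_raw = c(10, 20, 60))
  expect_equal(d$Z[, 1L], c(-1, 0, 1) * sqrt(3 / 2))
  for (j in 1:2) {
    expect_lt(abs(mean(d$Z[, j])), 1e-10)
    expect_equal(sum(d$Z[, j]^2), 3, tolerance = 1e-10)
  }
  expect_equal(mean(d$y), 0, tolerance = 1e-12)
  expect_equal(var(d$y), 1, tolerance = 1e-12)
  expect_equal(d$y * d$y_scale + d$y_center, c(10, 20, 60))

  raw <- make_raw(40, 15, seed = 11)
  d <- standardize(raw, y_raw = rnorm(40))
  expect_lt(max(abs(colMeans(d$Z))), 1e-10)
  expect_equal(unname(colSums(d$Z^2)), rep(40, 15), tolerance = 1e-10)
  # trace identity tr(ZZ'/m) = n under divisor-n scaling
  expect_equal(sum(d$Z^2) / d$m, d$n, tolerance = 1e-8)
})

test_that("reference standardization applies training statistics deterministically", {
  train <- make_raw(30, 8, seed = 3)
  d_train <- standardize(train, y_raw = rnorm(30))
  cand <- make_raw(10, 8, seed = 4)
  d1 <- standardize(cand, reference = d_train)
  d2 <- standardize(cand, reference = d_train)
  expect_identical(d1$Z, d2$Z)
  expect_equal(d1$Z,
               sweep(sweep(cand$matrix, 2, d_train$col_means, "-"),
                     2, d_train$col_scales, "/"))
})

test_that("constant markers are a degenerate-marker error naming the offenders", {
  x <- make_raw(10, 3, seed = 5)$matrix
  x[, 2L] <- 1
  raw <- raw_genotypes(x, marker_names = c("a", "b", "c"))
  expect_error(standardize(raw), "degenerate.*b")
})

test_that("variance components validate and compute h2", {
  vc <- variance_components(0.3, 0.7, "RHE")
  expect_equal(vc$h2, 0.3)
  expect_error(variance_components(-0.1, 0.5))
})
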