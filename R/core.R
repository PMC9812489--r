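#' Raw allele-dosage genotypes
#'
#' Container for an unscaled biallelic genotype matrix coded as allele
#' dosages 0/1/2 (copies of the counted allele), one row per individual and
#' one column per marker. All downstream machinery (standardization,
#' heritability estimation, SNP-BLUP) starts from this object.
#'
#' @param matrix integer-valued matrix of dosages in \{0, 1, 2\}, n
#'   individuals by m markers. No missing values are allowed here; the
#'   loader handles imputation or rejection.
#' @param ids optional character vector of individual identifiers
#'   (default \code{"ind1"..."indN"}).
#' @param marker_names optional character vector of marker identifiers
#'   (default \code{"m1"..."mM"}).
#' @return An object of class \code{raw_genotypes} with elements
#'   \code{matrix}, \code{ids}, \code{marker_names}, \code{n}, \code{m}.
#' @examples
#' g <- raw_genotypes(rbind(c(0, 1), c(2, 2), c(1, 0)))
#' g$n
#' @export
raw_genotypes <- function(matrix, ids = NULL, marker_names = NULL) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 2L) {
    stop("need at least 2 individuals, got ", nrow(matrix))
  }
  if (ncol(matrix) < 1L) {
    stop("need at least 1 marker")
  }
  bad <- which(is.na(matrix) | !(matrix %in% c(0, 1, 2)))
  if (length(bad) > 0L) {
    i <- ((bad[1L] - 1L) %% nrow(matrix)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(matrix)) + 1L
    stop(sprintf(
      "genotype format error: value '%s' at row %d, column %d is not an allele dosage in {0,1,2}",
      format(matrix[i, j]), i, j
    ))
  }
  storage.mode(matrix) <- "double"
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(matrix)))
  if (is.null(marker_names)) marker_names <- paste0("m", seq_len(ncol(matrix)))
  stopifnot(length(ids) == nrow(matrix), length(marker_names) == ncol(matrix))
  dimnames(matrix) <- NULL
  structure(
    list(matrix = matrix, ids = as.character(ids),
         marker_names = as.character(marker_names),
         n = nrow(matrix), m = ncol(matrix)),
    class = "raw_genotypes"
  )
}

#' @export
print.raw_genotypes <- function(x, ...) {
  cat("raw_genotypes:", x$n, "individuals x", x$m, "markers (dosage 0/1/2)\n")
  invisible(x)
}

#' Subset individuals of a genotype object
#'
#' @param raw a \code{raw_genotypes} object.
#' @param idx integer (or logical) index of individuals to keep.
#' @return A \code{raw_genotypes} object for the selected rows.
#' @export
subset_genotypes <- function(raw, idx) {
  stopifnot(inherits(raw, "raw_genotypes"))
  raw_genotypes(raw$matrix[idx, , drop = FALSE], ids = raw$ids[idx],
                marker_names = raw$marker_names)
}

#' Load a genotype dosage matrix from a delimited text file
#'
#' Supported dialects: plain TSV/CSV with one individual per row, and the
#' PLINK \code{.raw} additive-dosage export (whitespace-delimited, header
#' line, six leading metadata columns FID IID PAT MAT SEX PHENOTYPE, dosage
#' columns from column 7 on).
#'
#' @param path file path.
#' @param dialect one of \code{"tsv"}, \code{"csv"}, \code{"plink_raw"}.
#' @param header for tsv/csv: does the first line carry marker names?
#' @param id_column for tsv/csv: is the first column an individual ID?
#' @param impute_missing replace missing dosages by the rounded column mean
#'   (so entries remain in \{0,1,2\}). Default \code{FALSE}: missing values
#'   are a format error.
#' @return A \code{\link{raw_genotypes}} object.
#' @export
load_genotypes <- function(path, dialect = c("tsv", "csv", "plink_raw"),
                           header = FALSE, id_column = FALSE,
                           impute_missing = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  ids <- NULL
  marker_names <- NULL
  if (dialect == "plink_raw") {
    tab <- tryCatch(
      utils::read.table(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE),
      error = function(e) stop("genotype format error in '", path, "': ",
                               conditionMessage(e))
    )
    if (ncol(tab) < 7L) {
      stop("plink .raw file must have >= 7 columns (6 metadata + dosages)")
    }
    ids <- as.character(tab[[2L]]) # IID
    marker_names <- colnames(tab)[-(1:6)]
    x <- as.matrix(tab[, -(1:6), drop = FALSE])
  } else {
    sep <- if (dialect == "csv") "," else ""
    tab <- tryCatch(
      utils::read.table(path, header = header, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE),
      error = function(e) stop("genotype format error in '", path, "': ",
                               conditionMessage(e))
    )
    if (id_column) {
      ids <- as.character(tab[[1L]])
      tab <- tab[, -1L, drop = FALSE]
    }
    if (header) marker_names <- colnames(tab)
    x <- as.matrix(tab)
  }
  if (!is.numeric(x)) {
    stop("genotype format error in '", path, "': non-numeric entries present")
  }
  if (anyNA(x)) {
    if (!impute_missing) {
      bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "missing genotype at row %d, column %d (use impute_missing = TRUE to mean-impute)",
        bad[1L], bad[2L]
      ))
    }
    for (j in which(colSums(is.na(x)) > 0L)) {
      mj <- round(mean(x[, j], na.rm = TRUE))
      x[is.na(x[, j]), j] <- mj
    }
  }
  raw <- raw_genotypes(x, ids = ids, marker_names = marker_names)
  message(sprintf("loaded %d individuals x %d markers from %s",
                  raw$n, raw$m, path))
  raw
}

#' Load a phenotype vector from a delimited text file
#'
#' Accepts either a single numeric column or two columns (ID, value). When
#' IDs are present in both the phenotype file and \code{ids}, they are
#' cross-checked and the phenotypes reordered to match.
#'
#' @param path file path (whitespace- or comma-delimited, no header by
#'   default).
#' @param ids optional individual IDs (e.g. from the genotype object) to
#'   align against.
#' @param header logical; skip a header line.
#' @return Numeric vector of phenotypes.
#' @export
load_phenotypes <- function(path, ids = NULL, header = FALSE) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  sep <- if (grepl("\\.csv$", path)) "," else ""
  tab <- utils::read.table(path, header = header, sep = sep,
                           stringsAsFactors = FALSE)
  if (ncol(tab) == 1L) {
    y <- as.numeric(tab[[1L]])
  } else {
    file_ids <- as.character(tab[[1L]])
    y <- as.numeric(tab[[2L]])
    if (!is.null(ids)) {
      pos <- match(ids, file_ids)
      if (anyNA(pos)) {
        stop("phenotype file is missing IDs: ",
             paste(utils::head(ids[is.na(pos)], 5L), collapse = ", "))
      }
      y <- y[pos]
    }
  }
  if (anyNA(y)) stop("phenotype file contains missing/non-numeric values")
  y
}

#' Standardize genotypes (and phenotypes) for the additive model
#'
#' Builds the design of the additive genetic model y = X theta + Z u + e:
#' each genotype column is centered and scaled so that a column built
#' without a reference has mean 0 and sum of squares exactly n (scale =
#' root mean squared deviation, divisor n). This divisor-n convention makes
#' trace(ZZ'/m) = n an exact identity, the normalization the genomic
#' relationship matrix omega = ZZ'/m relies on. Candidate individuals must
#' be standardized with the training-set statistics (pass the training
#' design as \code{reference}) because marker effects are estimated on the
#' training scale.
#'
#' @param raw a \code{\link{raw_genotypes}} object.
#' @param y_raw optional numeric phenotype vector of length n.
#' @param reference optional \code{std_design} whose column means/scales are
#'   applied (candidate-set standardization).
#' @param standardize_phenotype center and scale y to mean 0, unit variance
#'   (divisor n-1); the raw mean/SD are retained for back-transformation.
#' @return An object of class \code{std_design}: \code{Z} (n x m), \code{y}
#'   (or NULL), \code{X} (vector of ones), \code{col_means},
#'   \code{col_scales}, \code{y_center}, \code{y_scale}, \code{n}, \code{m},
#'   \code{marker_names}.
#' @examples
#' g <- raw_genotypes(cbind(c(0, 1, 2)), ids = c("a", "b", "c"))
#' d <- standardize(g, y_raw = c(1.2, 0.7, 2.4))
#' colMeans(d$Z)          # ~0
#' colSums(d$Z^2)         # = n
#' @export
standardize <- function(raw, y_raw = NULL, reference = NULL,
                        standardize_phenotype = TRUE) {
  stopifnot(inherits(raw, "raw_genotypes"))
  x <- raw$matrix
  n <- nrow(x)
  if (is.null(reference)) {
    cm <- colMeans(x)
    cs <- sqrt(colMeans(x^2) - cm^2) # divisor n
    const <- which(cs < 1e-12)
    if (length(const) > 0L) {
      stop("degenerate (constant) markers cannot be standardized: ",
           paste(utils::head(raw$marker_names[const], 10L), collapse = ", "))
    }
  } else {
    stopifnot(inherits(reference, "std_design"))
    if (reference$m != raw$m) {
      stop("reference has ", reference$m, " markers but genotypes have ", raw$m)
    }
    cm <- reference$col_means
    cs <- reference$col_scales
  }
  Z <- sweep(sweep(x, 2L, cm, "-"), 2L, cs, "/")
  y <- NULL
  y_center <- 0
  y_scale <- 1
  if (!is.null(y_raw)) {
    if (length(y_raw) != n) {
      stop("phenotype length ", length(y_raw), " != number of individuals ", n)
    }
    if (standardize_phenotype) {
      y_center <- mean(y_raw)
      y_scale <- stats::sd(y_raw)
      if (y_scale < 1e-12) stop("phenotype is constant; cannot standardize")
      y <- (y_raw - y_center) / y_scale
    } else {
      y <- as.numeric(y_raw)
    }
  }
  structure(
    list(Z = Z, y = y, X = rep(1, n), col_means = cm, col_scales = cs,
         y_center = y_center, y_scale = y_scale,
         n = n, m = raw$m, marker_names = raw$marker_names),
    class = "std_design"
  )
}

#' @export
print.std_design <- function(x, ...) {
  cat("std_design:", x$n, "individuals x", x$m, "standardized markers",
      if (!is.null(x$y)) "(with phenotypes)" else "(no phenotypes)", "\n")
  invisible(x)
}

#' Variance components on the GRM scale
#'
#' @param sigma_g2 additive genetic variance (scale of omega = ZZ'/m).
#' @param sigma_e2 residual variance.
#' @param method label: "RHE", "REML" or "TRUE".
#' @return Object of class \code{variance_components} with \code{h2} =
#'   sigma_g2 / (sigma_g2 + sigma_e2).
#' @export
variance_components <- function(sigma_g2, sigma_e2,
                                method = c("RHE", "REML", "TRUE")) {
  method <- match.arg(method)
  stopifnot(sigma_g2 >= 0, sigma_e2 >= 0, sigma_g2 + sigma_e2 > 0)
  structure(
    list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
         h2 = sigma_g2 / (sigma_g2 + sigma_e2), method = method),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance components (%s): sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.4f\n",
              x$method, x$sigma_g2, x$sigma_e2, x$h2))
  invisible(x)
}

# Run code under a temporary RNG seed, restoring the caller's stream.
# Used to give the Hutchinson probes a named substream so heritability
# estimates are reproducible independently of simulation draws.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
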