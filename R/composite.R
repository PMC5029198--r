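# Composite reading measure: z-transformation and correlation-matrix PCA,
# with first-component scores used as the reading-skill composite.

#' Z-transform columns
#'
#' Centres each column to mean 0 and scales to sample (n - 1) SD 1.
#'
#' @param x Numeric matrix or data frame.
#' @return A numeric matrix of the same dimensions.
#' @export
z_transform <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("columns must be numeric", call. = FALSE)
  for (j in seq_len(ncol(x))) {
    if (length(unique(x[, j])) < 2L) {
      stop("column ", j, " is constant; z-transform is undefined",
           call. = FALSE)
    }
  }
  scale(x)[, , drop = FALSE]
}

#' First-principal-component reading composite
#'
#' Performs PCA on the correlation matrix of the supplied score columns
#' (columns are z-transformed internally, which makes the covariance and
#' correlation analyses coincide) and returns the first component:
#' eigenvalues, loadings (`sqrt(lambda_1) * v_1`, whose squared sum equals
#' the first eigenvalue), percent variance explained
#' (`100 * lambda_1 / p`) and per-row scores (the z-scored data projected
#' on the first unit eigenvector, hence mean zero with variance
#' `lambda_1`). The eigenvector sign is fixed so the loadings are
#' positive -- a higher composite means better reading -- with ties broken
#' by the first coordinate.
#'
#' @param x Matrix or data frame of score columns (typically the three
#'   reading measures).
#' @param standardize_scores If `TRUE`, scores are rescaled to unit
#'   sample SD.
#' @return An object of class `composite_result` with fields `loadings`,
#'   `eigenvalues`, `variance_explained_pct` and `scores`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3)
#' res <- pca_composite(x)
#' sum(res$eigenvalues)  # equals the number of columns
#' @export
pca_composite <- function(x, standardize_scores = FALSE) {
  z <- z_transform(x)
  p <- ncol(z)
  if (nrow(z) < 4L) stop("need at least 4 rows", call. = FALSE)
  r <- stats::cor(z)
  eig <- eigen(r, symmetric = TRUE)
  if (eig$values[p] < 1e-10) {
    warning("correlation matrix is rank-deficient (smallest eigenvalue ",
            format(eig$values[p], digits = 3), ")", call. = FALSE)
  }
  v1 <- eig$vectors[, 1]
  s <- sum(v1)
  if (s < 0 || (s == 0 && v1[1] < 0)) v1 <- -v1
  loadings <- sqrt(eig$values[1]) * v1
  scores <- as.numeric(z %*% v1)
  if (standardize_scores) scores <- scores / stats::sd(scores)
  names(loadings) <- colnames(x) %||% paste0("col", seq_len(p))
  structure(
    list(loadings = loadings, eigenvalues = eig$values,
         variance_explained_pct = 100 * eig$values[1] / p,
         scores = scores),
    class = "composite_result")
}

#' @export
print.composite_result <- function(x, ...) {
  cat("<composite_result> first component explains ",
      format(x$variance_explained_pct, digits = 4), "% of variance\n",
      "  eigenvalues: ",
      paste(format(x$eigenvalues, digits = 3), collapse = ", "), "\n",
      "  loadings: ",
      paste(names(x$loadings), format(x$loadings, digits = 3),
            sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}
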