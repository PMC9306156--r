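# Bhattacharyya distance between gesture classes and the multi-class
# separability index (mean over all unordered class pairs).

#' Fit a Gaussian to one class
#'
#' Mean and covariance of the class windows, with the covariance shrunk by
#' the same rule as the LDA classifier so both operate in the same
#' conditioning regime.
#'
#' @param X windows x features matrix of one class.
#' @param lambda shrinkage coefficient.
#' @param label optional class label carried along.
#' @return an object of class `class_gaussian`: list with `mean`, `cov`,
#'   `label`.
#' @export
class_gaussian <- function(X, lambda = 1e-3, label = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples to fit a class Gaussian")
  S <- stats::cov(X)
  C <- (1 - lambda) * S
  diag(C) <- diag(S)
  structure(list(mean = colMeans(X), cov = C, label = label),
            class = "class_gaussian")
}

# log-determinant via Cholesky; error message names the non-PD matrix.
logdet_pd <- function(C, what = "covariance") {
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R))
    stop(what, " is not positive definite (after regularisation)")
  list(logdet = 2 * sum(log(diag(R))), chol = R)
}

#' Bhattacharyya distance between two Gaussian classes
#'
#' Closed form for Gaussians:
#' `D = 1/8 (mu_a - mu_b)' Sbar^-1 (mu_a - mu_b)
#'    + 1/2 log( det(Sbar) / sqrt(det(Sa) det(Sb)) )`,
#' with `Sbar = (Sa + Sb) / 2`. Determinants are computed through
#' log-determinant Cholesky factorisations to avoid overflow.
#'
#' @param a,b `class_gaussian` objects of equal dimension.
#' @return non-negative distance (0 for identical classes).
#' @export
bhattacharyya_pair <- function(a, b) {
  stopifnot(inherits(a, "class_gaussian"), inherits(b, "class_gaussian"))
  if (length(a$mean) != length(b$mean))
    stop("dimension mismatch between the two classes")
  Sbar <- (a$cov + b$cov) / 2
  ld_bar <- logdet_pd(Sbar, "averaged covariance")
  ld_a <- logdet_pd(a$cov, "class covariance")$logdet
  ld_b <- logdet_pd(b$cov, "class covariance")$logdet
  dm <- a$mean - b$mean
  u <- backsolve(ld_bar$chol, dm, transpose = TRUE)
  drop(sum(u^2) / 8 + 0.5 * (ld_bar$logdet - 0.5 * (ld_a + ld_b)))
}

#' Multi-class separability index
#'
#' Mean Bhattacharyya distance over all unordered pairs of gesture classes,
#' fitted on a feature subspace (by default the columns given, e.g. the
#' SFS-selected 8-channel feature space).
#'
#' @param x a `feature_matrix`, or a plain windows x features matrix (then
#'   `y` is required).
#' @param y class labels when `x` is a matrix.
#' @param columns optional column indices restricting the feature subspace.
#' @param lambda covariance shrinkage, as in [fit_lda()].
#' @return mean pairwise distance (scalar).
#' @export
separability_index <- function(x, y = NULL, columns = NULL, lambda = 1e-3) {
  if (inherits(x, "feature_matrix")) {
    y <- x$y
    x <- x$X
  }
  if (is.null(y)) stop("class labels are required")
  x <- as.matrix(x)
  if (!is.null(columns)) x <- x[, columns, drop = FALSE]
  y <- droplevels(factor(y))
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  cnt <- table(y)
  if (any(cnt < 2L))
    stop("class '", names(cnt)[which(cnt < 2L)[1L]], "' has fewer than 2 samples")
  gs <- lapply(levels(y), function(cl)
    class_gaussian(x[y == cl, , drop = FALSE], lambda = lambda, label = cl))
  pairs <- utils::combn(length(gs), 2L)
  mean(vapply(seq_len(ncol(pairs)), function(i)
    bhattacharyya_pair(gs[[pairs[1L, i]]], gs[[pairs[2L, i]]]), numeric(1)))
}

#' Separability report across wrist conditions
#'
#' The separability index computed from the same feature subspace for each
#' single wrist position (P, N, S) and for all wrist positions combined
#' (comb), the four conditions of the wrist-complexity analysis.
#'
#' @param fm a `feature_matrix` covering all wrist positions.
#' @param columns column indices of the feature subspace (e.g. the SFS
#'   8-channel feature columns).
#' @param lambda covariance shrinkage.
#' @return data frame with columns `condition` (`"P"`, `"N"`, `"S"`,
#'   `"comb"`) and `index`.
#' @export
separability_report <- function(fm, columns = NULL, lambda = 1e-3) {
  stopifnot(inherits(fm, "feature_matrix"))
  conds <- c(P = "pronation", N = "neutral", S = "supination")
  idx <- vapply(conds, function(w) {
    separability_index(fm_rows(fm, fm$meta$wrist == w), columns = columns,
                       lambda = lambda)
  }, numeric(1))
  data.frame(condition = c(names(conds), "comb"),
             index = c(idx, separability_index(fm, columns = columns,
                                               lambda = lambda)))
}
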