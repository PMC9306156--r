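# Shrinkage linear discriminant analysis.
#
# Gaussian classifier with a shared within-class covariance. The pooled
# covariance is shrunk toward its own diagonal,
#   Sigma = (1 - lambda) S + lambda diag(S),
# which keeps the discriminant well defined when the feature dimension (up
# to 1280 for the full channel set) approaches the number of training
# windows. The diagonal target is equivariant under per-feature rescaling -
# essential here because the time-domain features live on wildly different
# scales (waveform length ~1e4 vs log-variance ~1), so an identity-target
# ridge would drown the small-scale features. The discriminant of class k is
#   delta_k(x) = x' Sigma^-1 mu_k - 1/2 mu_k' Sigma^-1 mu_k + log pi_k.

#' Fit a shrinkage LDA classifier
#'
#' @param X numeric matrix, windows x features.
#' @param y class labels (factor or character), at least 2 classes with at
#'   least 2 samples each.
#' @param lambda shrinkage coefficient in `[0, 1]`. With the default 1e-3 the
#'   coefficient is raised automatically (by factors of 10, up to 0.1) if the
#'   Cholesky factorisation of the shrunk covariance fails; an explicit
#'   `lambda = 0` fails hard on singular pooled covariance.
#' @param priors class prior probabilities (named or in class order); equal
#'   by default, matching the balanced recording protocol.
#' @return an object of class `emg_lda`: class list, class means, Cholesky
#'   factor of the shrunk pooled covariance, priors and the shrinkage
#'   actually used.
#' @export
fit_lda <- function(X, y, lambda = 1e-3, priors = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  y <- droplevels(y)
  classes <- levels(y)
  if (length(classes) < 2L) stop("need at least 2 classes")
  cnt <- table(y)
  if (any(cnt < 2L))
    stop("class '", names(cnt)[which(cnt < 2L)[1L]], "' has fewer than 2 samples")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  n <- nrow(X)
  d <- ncol(X)
  K <- length(classes)
  means <- rowsum(X, y) / as.vector(cnt)
  Xc <- X - means[as.integer(y), , drop = FALSE]
  S <- crossprod(Xc) / (n - K)
  lam <- lambda
  R <- NULL
  repeat {
    Sig <- (1 - lam) * S
    diag(Sig) <- diag(S)
    R <- tryCatch(chol(Sig), error = function(e) NULL)
    if (!is.null(R)) break
    if (lambda == 0)
      stop("pooled covariance is singular; refit with lambda > 0")
    if (lam >= 0.1)
      stop("covariance not positive definite even at lambda = 0.1")
    lam <- lam * 10
  }
  if (is.null(priors)) {
    priors <- rep(1 / K, K)
  } else {
    if (!is.null(names(priors))) priors <- priors[classes]
    priors <- priors / sum(priors)
  }
  names(priors) <- classes
  structure(list(classes = classes, means = means, chol = R,
                 priors = priors, lambda = lam, d = d),
            class = "emg_lda")
}

#' @export
print.emg_lda <- function(x, ...) {
  cat("shrinkage LDA:", length(x$classes), "classes,", x$d,
      "features, lambda =", x$lambda, "\n")
  invisible(x)
}

#' Predict gesture classes with a fitted LDA model
#'
#' Deterministic argmax of the class discriminants; ties are broken toward
#' the lowest class index.
#'
#' @param object an `emg_lda` model.
#' @param newdata matrix with the model's feature columns.
#' @param type `"class"` for labels, `"score"` for the discriminant matrix.
#' @param ... unused.
#' @return factor of predicted classes, or a windows x classes score matrix.
#' @export
predict.emg_lda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d)
    stop("feature dimension mismatch: model has ", object$d,
         ", data has ", ncol(newdata))
  R <- object$chol
  # Sigma^-1 t(means) via the Cholesky factor (Sigma = R'R)
  SinvMt <- backsolve(R, backsolve(R, t(object$means), transpose = TRUE))
  scores <- newdata %*% SinvMt
  const <- -0.5 * colSums(t(object$means) * SinvMt) + log(object$priors)
  scores <- sweep(scores, 2L, const, "+")
  colnames(scores) <- object$classes
  if (type == "score") return(scores)
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$classes)
}

#' Classification accuracy
#'
#' Fraction of windows whose predicted class equals the label.
#'
#' @param model an `emg_lda` model.
#' @param X feature matrix (windows x features).
#' @param y true labels.
#' @return accuracy in `[0, 1]`.
#' @export
classification_accuracy <- function(model, X, y) {
  if (length(y) == 0L) stop("empty test set")
  mean(as.character(predict(model, X)) == as.character(y))
}
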