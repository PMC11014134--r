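#' Fit a linear discriminant classifier
#'
#' Closed-form LDA: per-class means, pooled within-class covariance with a
#' small ridge (`lambda * I`, default `1e-6 * trace(Sigma) / d`) to guard
#' against singularity at small sample sizes, and empirical class priors.
#'
#' @param x Numeric matrix, one row per sample.
#' @param y Class labels (coerced to character).
#' @param lambda Ridge added to the covariance diagonal; `NULL` for the
#'   default.
#' @return Object of class `fessemg_lda`: class means, pooled covariance,
#'   its inverse, priors and labels.
#' @export
lda_fit <- function(x, y, lambda = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  classes <- sort(unique(y))
  if (length(classes) < 2) stop_input("lda_fit: need >= 2 classes")
  d <- ncol(x)
  n <- nrow(x)
  means <- t(vapply(classes, function(k) colMeans(x[y == k, , drop = FALSE]),
                    numeric(d)))
  S <- matrix(0, d, d)
  for (k in classes) {
    xk <- x[y == k, , drop = FALSE]
    if (nrow(xk) > 1) {
      cc <- sweep(xk, 2, colMeans(xk))
      S <- S + crossprod(cc)
    }
  }
  S <- S / max(n - length(classes), 1)
  if (is.null(lambda)) lambda <- 1e-6 * sum(diag(S)) / d
  S <- S + diag(lambda, d)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop_input("lda_fit: pooled covariance is singular even after ridge ",
               "regularization (lambda=", signif(lambda, 3),
               "); increase lambda or add samples"))
  priors <- as.numeric(table(factor(y, levels = classes))) / n
  structure(list(means = means, cov = S, cov_inv = Sinv,
                 priors = priors, classes = classes,
                 lambda = lambda, dim = d),
            class = "fessemg_lda")
}

#' Predict classes with a fitted LDA model
#'
#' Argmax over the linear discriminant scores
#' `delta_k(x) = x' Sinv mu_k - mu_k' Sinv mu_k / 2 + log pi_k`; ties break
#' deterministically toward the earlier class in sorted order.
#'
#' @param model A `fessemg_lda`.
#' @param x Feature matrix (rows = samples) with `model$dim` columns.
#' @param scores If `TRUE`, return the score matrix instead of labels.
#' @return Character vector of predicted labels (or score matrix).
#' @export
lda_predict <- function(model, x, scores = FALSE) {
  stopifnot(inherits(model, "fessemg_lda"))
  x <- as.matrix(x)
  if (ncol(x) != model$dim)
    stop_input("lda_predict: feature dimension ", ncol(x),
               " does not match model dimension ", model$dim)
  A <- model$cov_inv %*% t(model$means)              # d x K
  const <- -0.5 * colSums(t(model$means) * A) + log(model$priors)
  sc <- x %*% A + matrix(const, nrow(x), length(const), byrow = TRUE)
  colnames(sc) <- model$classes
  if (scores) return(sc)
  model$classes[apply(sc, 1, which.max)]
}

#' @export
print.fessemg_lda <- function(x, ...) {
  cat("<fessemg_lda> ", length(x$classes), " classes, dim ", x$dim,
      ", lambda ", signif(x$lambda, 3), "\n", sep = "")
  invisible(x)
}
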