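# Linear discriminant analysis on time-domain feature samples. Gaussian
# classes with a shared covariance: delta_k(x) = x' S^-1 m_k -
# 0.5 m_k' S^-1 m_k + log pi_k, with diagonal shrinkage on the pooled
# within-class covariance. With 4 x channels features and few training
# repetitions the pooled covariance is routinely rank-deficient, so the
# shrinkage is not optional in practice.

# Flatten a feature SampleSet to an n x (channels * 4) matrix.
featureMatrix <- function(samples) {
  stopifnot(is(samples, "SampleSet"), samples@kind == "feature")
  d <- samples@data
  t(matrix(d, dim(d)[1] * dim(d)[2], dim(d)[3]))
}

#' Fit a linear discriminant classifier
#'
#' @param features a [SampleSet-class] of kind "feature", or an n x p
#'   numeric matrix.
#' @param labels class labels (defaults to the SampleSet gestures).
#' @param shrinkage diagonal loading added to the pooled covariance as
#'   `shrinkage * trace(S)/p`; default 1e-4.
#' @return an [LdaModel-class].
#' @export
ldaFit <- function(features, labels = NULL, shrinkage = 1e-4) {
  if (is(features, "SampleSet")) {
    if (is.null(labels)) labels <- features@labels$gesture
    features <- featureMatrix(features)
  }
  stopifnot(nrow(features) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  p <- ncol(features)
  means <- matrix(0, length(classes), p)
  pooled <- matrix(0, p, p)
  priors <- numeric(length(classes))
  for (k in seq_along(classes)) {
    Xk <- features[labels == classes[k], , drop = FALSE]
    means[k, ] <- colMeans(Xk)
    cent <- sweep(Xk, 2, means[k, ])
    pooled <- pooled + crossprod(cent)
    priors[k] <- nrow(Xk) / nrow(features)
  }
  pooled <- pooled / max(1, nrow(features) - length(classes))
  pooled <- pooled + diag(shrinkage * sum(diag(pooled)) / p, p)
  covInv <- tryCatch(chol2inv(chol(pooled)), error = function(e)
    stop("singular pooled covariance: raise the shrinkage"))
  new("LdaModel", means = means, covInv = covInv, priors = priors,
    classes = as.integer(classes))
}

#' Predict with a linear discriminant classifier
#'
#' @param model an [LdaModel-class].
#' @param features a feature [SampleSet-class] or an n x p matrix.
#' @return integer vector of predicted class labels.
#' @export
ldaPredict <- function(model, features) {
  if (is(features, "SampleSet")) features <- featureMatrix(features)
  # delta_k(x) = x' S^-1 m_k - 0.5 m_k' S^-1 m_k + log pi_k
  B <- model@covInv %*% t(model@means)          # p x K
  const <- -0.5 * colSums(t(model@means) * B) + log(model@priors)
  scores <- features %*% B + matrix(const, nrow(features),
    length(const), byrow = TRUE)
  model@classes[max.col(scores)]
}

#' Accuracy of an LDA model on a labelled feature set
#'
#' @param model an [LdaModel-class].
#' @param features a feature [SampleSet-class].
#' @return accuracy in [0, 1].
#' @export
ldaEvaluate <- function(model, features) {
  mean(ldaPredict(model, features) == features@labels$gesture)
}
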