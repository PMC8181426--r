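# Linear discriminant analysis with pooled covariance, the classifier
# used by every handcrafted-feature pipeline.

#' Fit an LDA model
#'
#' Class means are per-class sample means; the pooled covariance is the
#' within-class scatter divided by (n - C). Priors are uniform by
#' default (all evaluation frameworks use balanced repetitions per
#' class). If the covariance cannot be factorized, a ridge
#' \code{1e-9 * trace/d} is added to the diagonal (and noted via a
#' message) — silent shrinkage would change results invisibly.
#'
#' @param features a \linkS4class{FeatureMatrix}, or a plain matrix with
#'   \code{labels} supplied.
#' @param labels integer class labels (ignored when \code{features} is a
#'   FeatureMatrix).
#' @param priors "uniform" (default) or "empirical".
#' @return An object of class \code{"LdaModel"}.
#' @export
fitLda <- function(features, labels = NULL, priors = c("uniform", "empirical")) {
  priors <- match.arg(priors)
  if (is(features, "FeatureMatrix")) {
    labels <- gestureLabels(features)
    x <- featureValues(features)
  } else x <- as.matrix(features)
  stopifnot(length(labels) == nrow(x), ncol(x) >= 1)
  classIds <- sort(unique(labels))
  C <- length(classIds)
  n <- nrow(x); d <- ncol(x)
  counts <- table(factor(labels, levels = classIds))
  if (any(counts < 2))
    stop("class(es) with fewer than 2 samples: ",
         paste(classIds[counts < 2], collapse = ", "))
  means <- matrix(0, C, d)
  scatter <- matrix(0, d, d)
  for (i in seq_len(C)) {
    xi <- x[labels == classIds[i], , drop = FALSE]
    means[i, ] <- colMeans(xi)
    xc <- sweep(xi, 2, means[i, ])
    scatter <- scatter + crossprod(xc)
  }
  sigma <- scatter / (n - C)
  sigma <- (sigma + t(sigma)) / 2
  inv <- tryCatch(chol2inv(chol(sigma)), error = function(e) NULL)
  if (is.null(inv)) {
    eps <- 1e-9 * sum(diag(sigma)) / d
    if (eps <= 0) eps <- 1e-12
    message("pooled covariance not positive definite; adding ridge ", eps)
    sigma <- sigma + diag(eps, d)
    inv <- chol2inv(chol(sigma))
  }
  pr <- if (priors == "uniform") rep(1 / C, C)
        else as.numeric(counts) / n
  structure(list(classMeans = means, pooledCovariance = sigma,
                 covInverse = inv, priors = pr, classIds = classIds),
            class = "LdaModel")
}

#' Predict gesture labels with an LDA model
#'
#' Argmax over the linear discriminant
#' \eqn{g_c(x) = x^T \Sigma^{-1} \mu_c - \frac{1}{2}\mu_c^T \Sigma^{-1}
#' \mu_c + \log \pi_c}; ties break to the lowest class id.
#'
#' @param model an \code{"LdaModel"} from \code{\link{fitLda}}.
#' @param features a \linkS4class{FeatureMatrix} or matrix.
#' @return Integer vector of predicted class labels.
#' @export
predictLda <- function(model, features) {
  stopifnot(inherits(model, "LdaModel"))
  x <- if (is(features, "FeatureMatrix")) featureValues(features)
       else as.matrix(features)
  if (ncol(x) != ncol(model$classMeans))
    stop("feature dimension (", ncol(x), ") does not match model (",
         ncol(model$classMeans), ")")
  A <- model$covInverse %*% t(model$classMeans)         # d x C
  const <- -0.5 * colSums(t(model$classMeans) * A) + log(model$priors)
  scores <- x %*% A + matrix(const, nrow(x), length(const), byrow = TRUE)
  # max.col with ties.method = "first" breaks ties to the lowest class id
  model$classIds[max.col(scores, ties.method = "first")]
}

#' @export
print.LdaModel <- function(x, ...) {
  cat(sprintf("LdaModel: %d classes, %d features\n",
              length(x$classIds), ncol(x$classMeans)))
  invisible(x)
}

#' Per-window classification accuracy
#'
#' @param predicted,truth equal-length label vectors.
#' @return Fraction of exact matches in [0, 1].
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("length mismatch: ", length(predicted), " vs ", length(truth))
  if (!length(predicted)) stop("empty label vectors")
  mean(predicted == truth)
}

# C x C confusion counts (rows = truth) over the label space classIds.
confusionCounts <- function(predicted, truth, classIds) {
  tab <- table(factor(truth, levels = classIds),
               factor(predicted, levels = classIds))
  m <- matrix(as.integer(tab), length(classIds), length(classIds),
              dimnames = list(truth = classIds, predicted = classIds))
  m
}
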