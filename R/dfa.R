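#' Two-group linear discriminant analysis
#'
#' Fits the classical linear discriminant between two groups: group centroids,
#' pooled within-group covariance, and the discriminant coefficient vector
#' `solve(S_pooled, mu1 - mu2)`. Priors are equal by default (the legacy
#' desktop-statistics convention), or proportional to group sizes. A
#' near-singular pooled covariance is ridge-regularized by `1e-8 * trace` on
#' the diagonal, with a warning.
#'
#' @param x numeric matrix or data.frame of features (rows = observations), or
#'   a formula `group ~ f1 + f2 + ...`.
#' @param grouping factor (or coercible) with exactly two levels.
#' @param prior `"equal"` or `"proportional"`, or a numeric pair summing to 1.
#' @param data data.frame, for the formula method.
#' @param ... unused.
#' @return object of class `dfa`: list with `means` (2 x p centroid matrix),
#'   `cov` (pooled within-group covariance), `coefficients`, `prior`,
#'   `counts`, `levels`, `features`.
#' @examples
#' d <- rbind(data.frame(g = "a", x = rnorm(20), y = rnorm(20)),
#'            data.frame(g = "b", x = rnorm(20, 3), y = rnorm(20)))
#' fit <- dfa(g ~ x + y, d)
#' coef(fit)
#' predict(fit, d)$class
#' @export
dfa <- function(x, ...) UseMethod("dfa")

#' @rdname dfa
#' @export
dfa.formula <- function(x, data, prior = "equal", ...) {
  mf <- stats::model.frame(x, data)
  grouping <- mf[[1L]]
  feats <- mf[-1L]
  fit <- dfa.default(feats, grouping, prior = prior)
  fit$call <- match.call()
  fit
}

#' @rdname dfa
#' @export
dfa.default <- function(x, grouping, prior = "equal", ...) {
  x <- as.matrix(as.data.frame(x))
  if (!is.numeric(x)) stop_volecall("features must be numeric")
  g <- droplevels(as.factor(grouping))
  if (nlevels(g) != 2L)
    stop_volecall("dfa needs exactly two groups, got ", nlevels(g))
  if (any(table(g) < 2L)) stop_volecall("each group needs at least 2 rows")
  if (anyNA(x)) stop_volecall("missing values in the feature set")
  lev <- levels(g)
  p <- ncol(x)
  mu <- rbind(colMeans(x[g == lev[1], , drop = FALSE]),
              colMeans(x[g == lev[2], , drop = FALSE]))
  rownames(mu) <- lev
  n1 <- sum(g == lev[1]); n2 <- sum(g == lev[2])
  S <- ((n1 - 1) * stats::cov(x[g == lev[1], , drop = FALSE]) +
        (n2 - 1) * stats::cov(x[g == lev[2], , drop = FALSE])) / (n1 + n2 - 2)
  if (rcond_safe(S) < 1e-10) {
    warning("near-singular pooled covariance; ridge-regularizing",
            call. = FALSE)
    S <- S + diag(1e-8 * sum(diag(S)), p)
  }
  pr <- if (identical(prior, "equal")) c(0.5, 0.5)
        else if (identical(prior, "proportional")) c(n1, n2) / (n1 + n2)
        else prior
  if (length(pr) != 2L || abs(sum(pr) - 1) > 1e-9 || any(pr <= 0))
    stop_volecall("prior must be 'equal', 'proportional', or a positive ",
                  "pair summing to 1")
  names(pr) <- lev
  structure(list(means = mu, cov = S,
                 coefficients = drop(solve(S, mu[1, ] - mu[2, ])),
                 prior = pr, counts = c(n1, n2), levels = lev,
                 features = colnames(x), call = match.call()),
            class = "dfa")
}

rcond_safe <- function(S) {
  out <- tryCatch(rcond(S), error = function(e) 0)
  if (!is.finite(out)) 0 else out
}

#' @export
print.dfa <- function(x, ...) {
  cat("Linear discriminant analysis:",
      paste(x$levels, collapse = " vs "),
      sprintf("(n = %d/%d, priors %.2f/%.2f)\n",
              x$counts[1], x$counts[2], x$prior[1], x$prior[2]))
  cat("Coefficients (Sigma^-1 (mu1 - mu2)):\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.dfa <- function(object, ...) object$coefficients

#' Classify observations with a fitted discriminant
#'
#' @param object a [dfa] fit.
#' @param newdata data.frame or matrix containing the model's feature columns.
#' @param ... unused.
#' @return list with `class` (factor), `posterior` (n x 2 matrix) and `d2`
#'   (squared Mahalanobis distances to the two centroids).
#' @export
predict.dfa <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    missing <- setdiff(object$features, names(newdata))
    if (length(missing) > 0)
      stop_volecall("newdata lacks feature(s): ",
                    paste(missing, collapse = ", "))
    newdata <- newdata[object$features]
  }
  x <- as.matrix(newdata)
  if (ncol(x) != length(object$features))
    stop_volecall("feature mismatch between model and newdata")
  d2 <- cbind(stats::mahalanobis(x, object$means[1, ], object$cov),
              stats::mahalanobis(x, object$means[2, ], object$cov))
  colnames(d2) <- object$levels
  logpost <- sweep(-d2 / 2, 2, log(object$prior), `+`)
  post <- exp(logpost - apply(logpost, 1, max))
  post <- post / rowSums(post)
  cls <- factor(object$levels[max.col(post, ties.method = "first")],
                levels = object$levels)
  list(class = cls, posterior = post, d2 = d2)
}

#' @export
summary.dfa <- function(object, ...) {
  print(object)
  cat("\nPooled within-group covariance:\n")
  print(object$cov)
  invisible(object)
}

#' Classification performance of a discriminant on labelled data
#'
#' Assigns every row to the higher-posterior group and tabulates the result
#' against the true labels. The contribution of each feature to the
#' discrimination is reported as its partial Wilks lambda — the ratio of the
#' full model's Wilks lambda to the lambda of the model with that feature
#' removed; smaller values mark features that carry more of the separation.
#'
#' @param model a [dfa] fit.
#' @param data data.frame containing the model's features and a group column.
#' @param group name of the group column (default `"group"`).
#' @return object of class `dfa_classification`: list with `confusion`
#'   (rows = true groups), `percent_correct`, `wilks_lambda` (full model) and
#'   `wilks_partial` (per feature).
#' @export
classify <- function(model, data, group = "group") {
  g <- droplevels(factor(data[[group]], levels = model$levels))
  if (anyNA(g))
    stop_volecall("data contains groups outside the model's levels")
  pred <- predict(model, data)$class
  confusion <- table(true = g, predicted = pred)
  x <- as.matrix(data[model$features])
  lam <- wilks_lambda(x, g)
  partial <- vapply(seq_along(model$features), function(j)
    lam / wilks_lambda(x[, -j, drop = FALSE], g), numeric(1))
  names(partial) <- model$features
  structure(list(confusion = confusion,
                 percent_correct = 100 * sum(diag(confusion)) /
                   sum(confusion),
                 wilks_lambda = lam, wilks_partial = partial),
            class = "dfa_classification")
}

# Wilks lambda det(W)/det(T) for a feature matrix and grouping factor.
wilks_lambda <- function(x, g) {
  x <- as.matrix(x)
  if (ncol(x) == 0L) return(1)
  total <- crossprod(scale(x, scale = FALSE))
  within <- Reduce(`+`, lapply(levels(g), function(l)
    crossprod(scale(x[g == l, , drop = FALSE], scale = FALSE))))
  det(within) / det(total)
}

#' @export
print.dfa_classification <- function(x, ...) {
  cat(sprintf("Correct attribution: %.1f%%\n", x$percent_correct))
  print(x$confusion)
  cat(sprintf("Wilks lambda %.4f; partial lambda per feature:\n",
              x$wilks_lambda))
  print(round(x$wilks_partial, 4))
  invisible(x)
}
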