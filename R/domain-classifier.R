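#' Proxy A-distance from a domain-classifier error
#'
#' Maps the held-out error \eqn{\hat e} of a classifier discriminating the
#' training domain from the unseen domain onto the distance
#' \eqn{d_A = 2(1 - 2\hat e)}, clamped below at 0 so the result always lies
#' in \eqn{[0, 2]}. An error of 0 (perfectly separable domains) gives 2; an
#' error of 0.5 (indistinguishable domains) gives 0. Errors above 0.5, which
#' occur by chance when domains coincide, would give negative distances and
#' are clamped.
#'
#' @param cv_error Held-out domain-classification error in `[0, 1]`.
#' @return Proxy A-distance in `[0, 2]`.
#' @examples
#' proxy_a_distance(0)    # 2: perfectly separable
#' proxy_a_distance(0.5)  # 0: indistinguishable
#' @export
proxy_a_distance <- function(cv_error) {
  if (!is.numeric(cv_error) || anyNA(cv_error) ||
      any(cv_error < 0 | cv_error > 1)) {
    stop_drcheck("`cv_error` must lie in [0, 1].", "drcheck_invalid_input")
  }
  pmax(0, 2 * (1 - 2 * cv_error))
}

#' Train the domain classifier
#'
#' Fits an L2-regularized (ridge) logistic regression discriminating domain T
#' from domain U, with the regularization strength selected by internal
#' stratified k-fold cross-validation over instances. The fit is deterministic
#' given `seed` (fold assignment is derived from it).
#'
#' @param train A [domain_sample()] containing both domains.
#' @param folds Number of cross-validation folds for selecting the
#'   regularization strength (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @param lambda_rule `"min"` (default) uses the strength minimizing the
#'   cross-validated deviance; `"1se"` uses the strongest regularization
#'   within one standard error of that minimum.
#' @return A `domain_classifier` object.
#' @export
train_domain_classifier <- function(train, folds = 5, seed = 1,
                                    lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  if (!inherits(train, "domain_sample")) {
    stop_drcheck("`train` must be a domain_sample.", "drcheck_invalid_input")
  }
  y <- as.integer(train$domain == "U")
  if (length(unique(y)) < 2L) {
    stop_drcheck("Training data must contain both domains T and U.",
                 "drcheck_invalid_input")
  }
  x <- train$features
  sds <- apply(x, 2, sd)
  if (all(sds == 0)) {
    warn("All features have zero variance; fitting an intercept-only model.")
    p0 <- mean(y)
    fit <- structure(list(intercept_only = TRUE, p = p0), class = "list")
    return(structure(list(fit = fit, lambda_rule = lambda_rule,
                          folds = folds, seed = seed,
                          n_train = length(y), intercept_only = TRUE),
                     class = "domain_classifier"))
  }
  foldid <- with_seed(derive_seed(seed, 101L), {
    # stratified fold assignment per class
    f <- integer(length(y))
    for (cl in c(0L, 1L)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    f
  })
  cv <- with_seed(derive_seed(seed, 102L), {
    glmnet::cv.glmnet(x, y, family = "binomial", alpha = 0, foldid = foldid)
  })
  structure(list(fit = cv, lambda_rule = lambda_rule, folds = folds,
                 seed = seed, n_train = length(y), intercept_only = FALSE),
            class = "domain_classifier")
}

#' @export
print.domain_classifier <- function(x, ...) {
  cat("Domain classifier (L2 logistic regression)\n")
  cat("  training instances:", x$n_train, "\n")
  if (x$intercept_only) {
    cat("  intercept-only fit (degenerate features)\n")
  } else {
    s <- if (x$lambda_rule == "min") x$fit$lambda.min else x$fit$lambda.1se
    cat(sprintf("  lambda (%s rule): %.4g, %d-fold CV\n", x$lambda_rule, s,
                x$folds))
  }
  invisible(x)
}

predict_domain_prob <- function(model, sample) {
  if (model$intercept_only) {
    return(rep(model$fit$p, nrow(sample)))
  }
  s <- if (model$lambda_rule == "min") "lambda.min" else "lambda.1se"
  as.numeric(predict(model$fit, sample$features, s = s, type = "response"))
}

#' Evaluate the domain classifier on held-out scans
#'
#' Returns the held-out domain-classification error (the \eqn{\hat e} feeding
#' the proxy A-distance) together with the per-instance probability of
#' belonging to domain U. The predicted domain is the more probable one; exact
#' ties at probability 0.5 are broken toward domain T for determinism.
#'
#' @param model A `domain_classifier`.
#' @param test A [domain_sample()] of held-out instances.
#' @return A list of class `domain_classifier_result` with `cv_error`,
#'   `prob_u`, `n_test`, `n_ties` and model metadata.
#' @export
evaluate_domain_classifier <- function(model, test) {
  if (!inherits(test, "domain_sample") || nrow(test) == 0L) {
    stop_drcheck("`test` must be a non-empty domain_sample.",
                 "drcheck_invalid_input")
  }
  p <- predict_domain_prob(model, test)
  y <- as.integer(test$domain == "U")
  pred <- as.integer(p > 0.5)  # ties (p == 0.5) predict T
  n_ties <- sum(p == 0.5)
  structure(list(cv_error = mean(pred != y), prob_u = p,
                 n_test = length(y), n_ties = n_ties,
                 lambda_rule = model$lambda_rule, folds = model$folds),
            class = "domain_classifier_result")
}

#' Pool both class probabilities of every test instance
#'
#' For each held-out instance the domain classifier yields two probabilities,
#' one per domain, summing to one. Both are pooled into a single vector, so a
#' test set of m instances yields 2m values whose mean is exactly 0.5 and
#' whose multiset is symmetric under \eqn{p \mapsto 1 - p}. The separability
#' beta distribution is fitted on this pooled vector.
#'
#' @inheritParams evaluate_domain_classifier
#' @return Numeric vector of length `2 * nrow(test)`.
#' @export
pool_probabilities <- function(model, test) {
  res <- evaluate_domain_classifier(model, test)
  c(res$prob_u, 1 - res$prob_u)
}
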