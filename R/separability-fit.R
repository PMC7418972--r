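#' Fit the separability beta distribution
#'
#' Fits a beta distribution by maximum likelihood (support fixed to `[0, 1]`)
#' on the pooled domain-classification probabilities, with a method-of-moments
#' fallback when the optimizer fails. Values outside
#' `[clip_epsilon, 1 - clip_epsilon]` are clipped before fitting, since
#' cross-validated logistic probabilities can reach numerical 0/1 even for
#' overlapping domains.
#'
#' The fit is flagged *improper* (`proper = FALSE`) when no usable shape pair
#' can be estimated:
#' \itemize{
#'   \item degenerate sample: all values identical (zero variance), as when
#'     every probability is exactly 0.5;
#'   \item unbounded likelihood: exact 0s or 1s present with
#'     `clip_epsilon = 0`;
#'   \item divergent fit: non-convergence, non-finite shapes, or shapes above
#'     `max_shape`;
#'   \item endpoint concentration: the fitted density is U-shaped (a shape
#'     below `min_shape = 1`), i.e. flatter than the flat worst-case
#'     benchmark `Beta(1, 1)` with unbounded density at the endpoints. The
#'     worst-case benchmark is, by construction, the proper stand-in for the
#'     completely separable limit, so any fit more extreme than it lies
#'     outside the criterion's domain. This is the regime of (near-)
#'     completely separable domains: probabilities pile up towards 0 and 1
#'     (how closely they approach the endpoints depends only on the
#'     classifier's regularization, which is why the rule keys on the fitted
#'     shape rather than on raw extreme values).
#' }
#' The last rule is deliberately two-sided: a mildly U-shaped fit on broadly
#' spread probabilities stays proper (the flat benchmark `Beta(1, 1)` itself
#' is proper), and occasional numerically extreme probabilities do not poison
#' an otherwise concentrated fit.
#'
#' @param probabilities Numeric vector in `[0, 1]`, at least 10 values.
#' @param clip_epsilon Clipping margin applied before fitting (default 1e-6).
#' @param max_shape Shape magnitude above which the fit is declared divergent
#'   (default 1e6).
#' @param min_shape Shape below which the fit counts as endpoint-concentrated
#'   (default 1, the flat worst-case benchmark).
#' @return A `separability_fit`: `shape` ([beta_shape()] or `NULL`),
#'   `alpha`/`beta` estimates, `proper`, `reason`, `clip_applied`,
#'   `n_probabilities` and the fit `method` (`"mle"` or `"moments"`).
#' @export
fit_separability <- function(probabilities, clip_epsilon = 1e-6,
                             max_shape = 1e6, min_shape = 1) {
  x <- probabilities
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop_drcheck("`probabilities` must be numbers in [0, 1].",
                 "drcheck_invalid_input")
  }
  if (length(x) < 10L) {
    stop_drcheck("At least 10 probabilities are required for a stable fit.",
                 "drcheck_invalid_input")
  }
  check_scalar_number(clip_epsilon, "clip_epsilon", lower = 0, upper = 0.4)

  n <- length(x)
  endpoint_share <- mean(x <= 0.05 | x >= 0.95)

  improper <- function(reason, method = NA_character_,
                       alpha = NA_real_, beta = NA_real_) {
    structure(list(shape = NULL, alpha = alpha, beta = beta, proper = FALSE,
                   reason = reason, clip_applied = clip_applied,
                   n_probabilities = n, method = method,
                   endpoint_share = endpoint_share),
              class = "separability_fit")
  }

  clip_applied <- any(x < clip_epsilon | x > 1 - clip_epsilon)
  if (clip_epsilon == 0 && any(x == 0 | x == 1)) {
    return(improper("unbounded_likelihood"))
  }
  x <- pmin(pmax(x, clip_epsilon), 1 - clip_epsilon)

  m <- mean(x)
  v <- var(x)
  if (v < .Machine$double.eps * 100) {
    return(improper("degenerate_sample"))
  }

  # method-of-moments start
  k <- m * (1 - m) / v - 1
  mom <- c(alpha = m * k, beta = (1 - m) * k)
  method <- "mle"
  nll <- function(lp) -sum(dbeta(x, exp(lp[1]), exp(lp[2]), log = TRUE))
  opt <- tryCatch(
    optim(log(pmax(mom, 1e-4)), nll, method = "Nelder-Mead",
          control = list(maxit = 2000)),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0 || any(!is.finite(opt$par))) {
    if (any(!is.finite(mom)) || any(mom <= 0)) {
      return(improper("fit_failed"))
    }
    method <- "moments"
    est <- mom
  } else {
    est <- exp(opt$par)
  }

  if (any(!is.finite(est)) || any(est <= 0)) {
    return(improper("fit_failed", method, est[1], est[2]))
  }
  if (any(est > max_shape)) {
    return(improper("divergent_concentration", method, est[1], est[2]))
  }
  if (min(est) < min_shape) {
    return(improper("endpoint_concentration", method, est[1], est[2]))
  }

  structure(list(shape = beta_shape(est[1], est[2]),
                 alpha = unname(est[1]), beta = unname(est[2]),
                 proper = TRUE, reason = NA_character_,
                 clip_applied = clip_applied, n_probabilities = n,
                 method = method, endpoint_share = endpoint_share),
            class = "separability_fit")
}

#' @export
print.separability_fit <- function(x, ...) {
  cat("Separability fit on", x$n_probabilities, "pooled probabilities\n")
  if (x$proper) {
    cat(sprintf("  %s (%s fit)%s\n", format(x$shape), x$method,
                if (x$clip_applied) ", clipping applied" else ""))
  } else {
    cat("  improper:", x$reason, "\n")
  }
  invisible(x)
}

#' @method tidy separability_fit
#' @export
tidy.separability_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, beta = x$beta, proper = x$proper,
                 reason = x$reason, method = x$method,
                 clip_applied = x$clip_applied,
                 endpoint_share = x$endpoint_share,
                 n_probabilities = x$n_probabilities)
}
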