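#' Beta shape pair
#'
#' A pair of strictly positive, finite shape parameters \eqn{(\alpha, \beta)}
#' describing a beta distribution on the domain-classification probability
#' \eqn{\theta \in [0, 1]}. Shapes of this type stand for the fitted
#' separability distribution \eqn{\pi_{TU}(\theta)} as well as the two fixed
#' benchmark priors \eqn{\pi_{bm1}(\theta)} (the profile of two *similar* data
#' sets, e.g. `beta_shape(25, 25)`) and \eqn{\pi_{bm2}(\theta)} (the flat
#' worst case `beta_shape(1, 1)` representing *dissimilar* data sets).
#'
#' Non-finite or non-positive shapes describe an improper distribution and are
#' rejected: they arise when a beta fit degenerates on completely separable
#' data, and no divergence can be computed from them.
#'
#' @param alpha,beta Positive finite shape parameters.
#' @return An object of class `beta_shape`.
#' @examples
#' beta_shape(25, 25)
#' @export
beta_shape <- function(alpha, beta) {
  for (nm in c("alpha", "beta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L) {
      stop_drcheck(sprintf("Shape `%s` must be a single number.", nm),
                   "drcheck_improper_distribution")
    }
    if (!is.finite(v) || v <= 0) {
      stop_drcheck(
        sprintf(paste0("Shape `%s` = %s gives an improper distribution: ",
                       "beta shapes must be positive and finite."),
                nm, format(v)),
        "drcheck_improper_distribution")
    }
  }
  structure(list(alpha = as.double(alpha), beta = as.double(beta)),
            class = "beta_shape")
}

#' @rdname beta_shape
#' @param x Object to test or print.
#' @export
is_beta_shape <- function(x) inherits(x, "beta_shape")

#' @export
format.beta_shape <- function(x, ...) {
  sprintf("Beta(%g, %g)", x$alpha, x$beta)
}

#' @export
print.beta_shape <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

as_beta_shape <- function(x, name = "shape") {
  if (is_beta_shape(x)) return(x)
  if (is.numeric(x) && length(x) == 2L) return(beta_shape(x[1], x[2]))
  stop_drcheck(sprintf("`%s` must be a beta_shape or a length-2 numeric.",
                       name),
               "drcheck_invalid_input")
}

shapes_equal <- function(p, q, tol = 0) {
  abs(p$alpha - q$alpha) <= tol && abs(p$beta - q$beta) <= tol
}
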