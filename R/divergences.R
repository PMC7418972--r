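#' Kullback-Leibler divergence between two beta distributions (closed form)
#'
#' Computes \eqn{KL(p \,\|\, q) = \int_0^1 p(\theta) \log\frac{p(\theta)}{q(\theta)} d\theta}
#' in nats via the exact closed form
#' \deqn{\log B(\alpha_q, \beta_q) - \log B(\alpha_p, \beta_p)
#'   + (\alpha_p - \alpha_q)\psi(\alpha_p) + (\beta_p - \beta_q)\psi(\beta_p)
#'   + (\alpha_q - \alpha_p + \beta_q - \beta_p)\psi(\alpha_p + \beta_p),}
#' where \eqn{B} is the beta function and \eqn{\psi} the digamma function.
#' The divergence measures the information lost when \eqn{q} is used to
#' approximate the reference distribution \eqn{p}; it is nonnegative and zero
#' exactly when the two shapes coincide.
#'
#' All divergences in this package are reported in nats (natural logarithm);
#' the DRC ratio is base-invariant, so this choice affects only the two KL
#' terms themselves.
#'
#' @param p,q [beta_shape()] objects (or length-2 numerics) for the reference
#'   and approximating distribution.
#' @return A single nonnegative number (nats).
#' @seealso [kl_beta_numeric()] for the direct quadrature evaluation used as
#'   an independent numerical check.
#' @examples
#' kl_beta(beta_shape(0.5, 0.5), beta_shape(1, 1))  # log(4/pi)
#' @export
kl_beta <- function(p, q) {
  p <- as_beta_shape(p, "p")
  q <- as_beta_shape(q, "q")
  a1 <- p$alpha; b1 <- p$beta
  a2 <- q$alpha; b2 <- q$beta
  kl <- lbeta(a2, b2) - lbeta(a1, b1) +
    (a1 - a2) * digamma(a1) +
    (b1 - b2) * digamma(b1) +
    (a2 - a1 + b2 - b1) * digamma(a1 + b1)
  # guard the tiny negative round-off that can occur for near-equal shapes
  max(kl, 0)
}

#' Kullback-Leibler divergence between beta distributions by quadrature
#'
#' Evaluates the KL integral numerically, serving as an independent oracle for
#' [kl_beta()]. The integral is transformed with \eqn{\theta = \sin^2\phi},
#' which removes the integrable endpoint singularities that occur for shapes
#' below 1, and is integrated panel-by-panel between quantiles of the
#' reference distribution so that sharply concentrated densities are resolved.
#' The log-density is evaluated directly in \eqn{\phi} (using
#' \eqn{\log\cos\phi} rather than \eqn{\log(1 - \theta)}) to avoid
#' catastrophic underflow of \eqn{1-\theta} near the upper endpoint.
#'
#' @inheritParams kl_beta
#' @param tolerance Target absolute error of the quadrature (> 0).
#' @return A single nonnegative number (nats).
#' @export
kl_beta_numeric <- function(p, q, tolerance = 1e-9) {
  p <- as_beta_shape(p, "p")
  q <- as_beta_shape(q, "q")
  check_scalar_number(tolerance, "tolerance")
  if (tolerance <= 0) {
    stop_drcheck("`tolerance` must be > 0.", "drcheck_invalid_input")
  }
  a1 <- p$alpha; b1 <- p$beta
  a2 <- q$alpha; b2 <- q$beta

  # integrand after theta = sin^2(phi):
  #   2 sin^(2a1-1) cos^(2b1-1) / B(a1,b1) * log(p/q)(theta)
  g <- function(phi) {
    ls <- log(sin(phi))
    lc <- log(cos(phi))
    dens <- exp(log(2) + (2 * a1 - 1) * ls + (2 * b1 - 1) * lc - lbeta(a1, b1))
    lr <- lbeta(a2, b2) - lbeta(a1, b1) +
      2 * (a1 - a2) * ls + 2 * (b1 - b2) * lc
    v <- dens * lr
    v[!is.finite(v)] <- 0
    v
  }

  qs <- c(1e-12, 1e-6, 1e-3, 0.05, 0.25, 0.5, 0.75, 0.95,
          1 - 1e-3, 1 - 1e-6, 1 - 1e-12)
  brk <- sort(unique(c(0, asin(sqrt(qbeta(qs, a1, b1))), pi / 2)))

  # per-panel tolerance ladder: panels carrying the bulk of the integral
  # converge at the tight setting; slivers near the endpoints carry at most
  # ~1e-10 absolute error each at the looser settings.
  ladder <- list(c(1e-11, 1e-13), c(1e-8, 1e-11), c(1e-5, 1e-10))
  total <- 0
  err <- 0
  for (k in seq_len(length(brk) - 1L)) {
    if (brk[k + 1L] <= brk[k]) next
    res <- NULL
    for (tl in ladder) {
      res <- tryCatch(
        integrate(g, brk[k], brk[k + 1L], rel.tol = tl[1], abs.tol = tl[2],
                  subdivisions = 2000L),
        error = function(e) NULL)
      if (!is.null(res)) break
    }
    if (is.null(res)) {
      stop_drcheck(
        sprintf("Quadrature failed to converge for KL(%s || %s).",
                format(p), format(q)),
        "drcheck_numeric_failure")
    }
    total <- total + res$value
    err <- err + res$abs.error
  }
  if (err > tolerance && err > 1e-8) {
    stop_drcheck(
      sprintf("Quadrature error %.3g exceeds tolerance %.3g for KL(%s || %s).",
              err, tolerance, format(p), format(q)),
      "drcheck_numeric_failure")
  }
  max(total, 0)
}

#' Data Representativeness Criterion from beta shapes
#'
#' Forms the DRC ratio
#' \deqn{DRC = \frac{KL[\pi_{TU} \| \pi_{bm1}]}{KL[\pi_{TU} \| \pi_{bm2}]}}
#' for a fitted separability distribution `pi_tu` and two benchmark priors,
#' and issues a three-way verdict. A DRC below 1 means the separability
#' profile resembles benchmark prior 1 (two similar data sets) more than
#' benchmark prior 2 (the dissimilar worst case), i.e. the training data are
#' representative of the unseen data; above 1, they are not. Values within
#' `band` of 1 are ruled inconclusive: the criterion is then too close to its
#' threshold to act on, and proceeding with caution is advised.
#'
#' @param pi_tu Fitted separability shape ([beta_shape()]).
#' @param bm1 Benchmark prior 1: the separability profile of two similar data
#'   sets; a concentrated symmetric shape such as `beta_shape(25, 25)`. Its
#'   concentration sets the strictness of the criterion.
#' @param bm2 Benchmark prior 2: the dissimilar worst case; defaults to the
#'   flat `beta_shape(1, 1)`.
#' @param band Half-width \eqn{\tau} of the inconclusive zone around 1
#'   (default 0.05).
#' @return A `drc_report` with elements `kl_bm1`, `kl_bm2`, `drc`, `verdict`
#'   (`"representative"`, `"not_representative"` or `"inconclusive"`),
#'   `bm1`, `bm2`, `pi_tu` and `band`.
#' @examples
#' drc(beta_shape(200, 200), bm1 = beta_shape(25, 25))
#' @export
drc <- function(pi_tu, bm1, bm2 = beta_shape(1, 1), band = 0.05) {
  pi_tu <- as_beta_shape(pi_tu, "pi_tu")
  bm1 <- as_beta_shape(bm1, "bm1")
  bm2 <- as_beta_shape(bm2, "bm2")
  check_scalar_number(band, "band", lower = 0)

  if (shapes_equal(pi_tu, bm2)) {
    stop_drcheck(
      paste0("`pi_tu` equals benchmark prior 2, so KL[pi_tu || bm2] = 0 and ",
             "the DRC ratio is undefined; choose a different bm2 (this is a ",
             "configuration error, not a data property)."),
      "drcheck_degenerate_ratio")
  }

  kl1 <- kl_beta(pi_tu, bm1)
  kl2 <- kl_beta(pi_tu, bm2)
  if (kl2 <= 0) {
    stop_drcheck(
      "KL[pi_tu || bm2] is zero; the DRC ratio is undefined.",
      "drcheck_degenerate_ratio")
  }
  ratio <- kl1 / kl2
  new_drc_report(kl_bm1 = kl1, kl_bm2 = kl2, drc = ratio,
                 verdict = drc_verdict(ratio, band),
                 bm1 = bm1, bm2 = bm2, pi_tu = pi_tu, band = band)
}

drc_verdict <- function(ratio, band) {
  if (!is.finite(ratio)) return("not_representative")
  if (ratio < 1 - band) "representative"
  else if (ratio > 1 + band) "not_representative"
  else "inconclusive"
}

new_drc_report <- function(kl_bm1, kl_bm2, drc, verdict, bm1, bm2, pi_tu,
                           band, proper = TRUE, reason = NA_character_) {
  structure(
    list(kl_bm1 = kl_bm1, kl_bm2 = kl_bm2, drc = drc, verdict = verdict,
         bm1 = bm1, bm2 = bm2, pi_tu = pi_tu, band = band,
         proper = proper, reason = reason),
    class = "drc_report")
}

#' @export
print.drc_report <- function(x, ...) {
  cat("Data representativeness criterion\n")
  if (!is.null(x$pi_tu)) cat("  separability fit:", format(x$pi_tu), "\n")
  cat("  benchmark priors:", format(x$bm1), "vs", format(x$bm2), "\n")
  if (x$proper) {
    cat(sprintf("  KL terms: %.4f / %.4f nats\n", x$kl_bm1, x$kl_bm2))
    cat(sprintf("  DRC = %.4g  ->  %s (band %.2g)\n", x$drc, x$verdict,
                x$band))
  } else {
    cat("  improper separability fit:", x$reason, "\n")
    cat("  DRC undefined  ->  flagged", x$verdict, "\n")
  }
  invisible(x)
}

#' @method tidy drc_report
#' @export
tidy.drc_report <- function(x, ...) {
  tibble::tibble(
    bm1_alpha = x$bm1$alpha, bm1_beta = x$bm1$beta,
    bm2_alpha = x$bm2$alpha, bm2_beta = x$bm2$beta,
    pi_tu_alpha = if (is.null(x$pi_tu)) NA_real_ else x$pi_tu$alpha,
    pi_tu_beta = if (is.null(x$pi_tu)) NA_real_ else x$pi_tu$beta,
    kl_bm1 = x$kl_bm1, kl_bm2 = x$kl_bm2, drc = x$drc,
    proper = x$proper, verdict = x$verdict)
}
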