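#' Build a domain sample from a feature matrix
#'
#' A domain sample is the unit of input to the domain-classification pipeline:
#' a tibble with one row per instance (patch), a `domain` factor with levels
#' `"T"` (training) and `"U"` (unseen), a `scan_id` grouping identifier and a
#' `features` matrix column holding the flattened pixel intensities or generic
#' feature vector.
#'
#' Scan identifiers matter: the domain classifier is built and tested on
#' disjoint sets of scans, so probabilities reflect generalization across
#' scans rather than memorized within-scan structure.
#'
#' @param features Numeric matrix, one row per instance, no missing values.
#' @param domain Per-row domain tag; anything coercible to a factor with
#'   levels `T`/`U` (0/1 and logical are accepted, 0/`FALSE` meaning `T`).
#' @param scan_id Per-row scan identifier (recycled if length 1).
#' @param coords Optional two-column matrix of patch-center `(row, col)`
#'   positions.
#' @return A tibble of class `domain_sample`.
#' @export
domain_sample <- function(features, domain, scan_id = "scan1", coords = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features) || anyNA(features)) {
    stop_drcheck("`features` must be a numeric matrix without missing values.",
                 "drcheck_invalid_input")
  }
  n <- nrow(features)
  if (n == 0L) {
    stop_drcheck("`features` must contain at least one instance.",
                 "drcheck_invalid_input")
  }
  domain <- canonical_domain(domain, n)
  if (length(scan_id) == 1L) scan_id <- rep(scan_id, n)
  if (length(scan_id) != n) {
    stop_drcheck("`scan_id` must have one entry per instance.",
                 "drcheck_invalid_input")
  }
  out <- tibble::tibble(scan_id = as.character(scan_id), domain = domain)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == n, ncol(coords) == 2L)
    out$row <- coords[, 1]
    out$col <- coords[, 2]
  }
  out$features <- features
  class(out) <- c("domain_sample", class(out))
  out
}

canonical_domain <- function(domain, n) {
  if (is.logical(domain) || is.numeric(domain)) {
    domain <- ifelse(as.numeric(domain) > 0, "U", "T")
  }
  domain <- as.character(domain)
  if (length(domain) == 1L) domain <- rep(domain, n)
  if (!all(domain %in% c("T", "U"))) {
    stop_drcheck("`domain` entries must be 'T' or 'U' (or 0/1).",
                 "drcheck_invalid_input")
  }
  factor(domain, levels = c("T", "U"))
}

#' Combine per-scan patch sets into one domain sample
#'
#' @param ... `patch_set` tibbles (see [extract_patches()]) or
#'   `domain_sample` objects.
#' @param domain Domain tag applied to all rows (`"T"` or `"U"`); ignored for
#'   inputs that already carry a domain.
#' @return A `domain_sample` tibble.
#' @export
bind_domain_sample <- function(..., domain = NULL) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !is.data.frame(parts[[1]])) {
    parts <- parts[[1]]
  }
  samples <- purrr::map(parts, function(p) {
    if (inherits(p, "domain_sample")) return(p)
    if (inherits(p, "patch_set")) {
      if (is.null(domain)) {
        stop_drcheck("`domain` is required when binding patch sets.",
                     "drcheck_invalid_input")
      }
      return(domain_sample(p$features, domain,
                           scan_id = p$subject_id,
                           coords = cbind(p$center_row, p$center_col)))
    }
    stop_drcheck("Inputs must be patch_set or domain_sample objects.",
                 "drcheck_invalid_input")
  })
  out <- dplyr::bind_rows(samples)
  class(out) <- c("domain_sample", setdiff(class(out), "domain_sample"))
  out
}

#' Synthetic Gaussian domains with per-scan variability
#'
#' Generates two feature-space domains for controlled experiments: domain T is
#' centred at the origin, domain U is shifted by `delta` along the first
#' feature. Each scan receives its own random mean offset (standard deviation
#' `scan_sd` per feature), emulating the scan-level acquisition variability
#' that patch data inherit from their source scan. Sampling is deterministic
#' given `seed`.
#'
#' @param delta Mean separation between the two domains (in units of the
#'   within-scan standard deviation).
#' @param n_scans Scans per domain.
#' @param n_per_scan Instances per scan.
#' @param n_features Feature dimension.
#' @param scan_sd Standard deviation of the per-scan random mean offset.
#' @param seed Integer seed.
#' @return A `domain_sample` tibble containing both domains.
#' @export
gaussian_domain_scans <- function(delta, n_scans = 12, n_per_scan = 100,
                                  n_features = 10, scan_sd = 0.2, seed = 1) {
  check_scalar_number(delta, "delta", lower = 0)
  mk_scan <- function(mu, scan_seed) {
    with_seed(scan_seed, {
      off <- rnorm(n_features, 0, scan_sd)
      matrix(rnorm(n_per_scan * n_features), n_per_scan) +
        rep(mu + off, each = n_per_scan)
    })
  }
  mu_t <- rep(0, n_features)
  mu_u <- c(delta, rep(0, n_features - 1))
  xs <- list()
  dom <- list()
  sid <- list()
  for (i in seq_len(n_scans)) {
    xs[[i]] <- mk_scan(mu_t, derive_seed(seed, 1L, i))
    dom[[i]] <- rep("T", n_per_scan)
    sid[[i]] <- rep(sprintf("T_scan%02d", i), n_per_scan)
  }
  for (i in seq_len(n_scans)) {
    xs[[n_scans + i]] <- mk_scan(mu_u, derive_seed(seed, 2L, i))
    dom[[n_scans + i]] <- rep("U", n_per_scan)
    sid[[n_scans + i]] <- rep(sprintf("U_scan%02d", i), n_per_scan)
  }
  domain_sample(do.call(rbind, xs), unlist(dom), unlist(sid))
}

#' Split a domain sample into build and test scans
#'
#' Splits by scan (never by instance): the first `n_build` scans of each
#' domain go to the build set, the next `n_test` to the test set.
#'
#' @param sample A `domain_sample`.
#' @param n_build,n_test Scans per domain for building and testing.
#' @return A list with `build` and `test` domain samples.
#' @export
split_by_scan <- function(sample, n_build, n_test) {
  pick <- function(dom) {
    ids <- unique(sample$scan_id[sample$domain == dom])
    if (length(ids) < n_build + n_test) {
      stop_drcheck(sprintf(
        "Domain %s has %d scans; %d build + %d test required.",
        dom, length(ids), n_build, n_test), "drcheck_invalid_input")
    }
    list(build = ids[seq_len(n_build)],
         test = ids[n_build + seq_len(n_test)])
  }
  t_ids <- pick("T")
  u_ids <- pick("U")
  subset_ds <- function(ids) {
    out <- sample[sample$scan_id %in% ids, , drop = FALSE]
    class(out) <- c("domain_sample", setdiff(class(out), "domain_sample"))
    out
  }
  list(build = subset_ds(c(t_ids$build, u_ids$build)),
       test = subset_ds(c(t_ids$test, u_ids$test)))
}
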