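#' End-to-end DRC analysis from two domain samples
#'
#' Runs the full domain-classification pipeline: trains the L2 logistic
#' domain classifier on the build sample, evaluates it on held-out scans,
#' pools both class probabilities per test instance, fits the separability
#' beta distribution, and forms the DRC against the benchmark priors. The
#' proxy A-distance is reported from the same held-out error.
#'
#' If the separability fit is improper (completely or near-completely
#' separable domains), the analysis does not error: the report carries the
#' verdict `not_representative` with an undefined, flagged DRC, while the
#' proxy A-distance — which needs only the error rate — is still reported.
#'
#' @param train,test [domain_sample()] objects with disjoint scan ids; both
#'   must contain both domains.
#' @param bm1 Benchmark prior 1 ([beta_shape()]).
#' @param bm2 Benchmark prior 2 (default `beta_shape(1, 1)`).
#' @param band Inconclusive half-width around DRC = 1 (default 0.05).
#' @param seed Integer seed (fold assignment).
#' @param clip_epsilon Probability clipping before the beta fit.
#' @param lambda_rule Regularization selection rule, see
#'   [train_domain_classifier()].
#' @param .fit_override Internal testing seam: a precomputed
#'   `separability_fit` used instead of fitting.
#' @return A `drc_analysis` list: `report` (`drc_report`), `fit`
#'   (`separability_fit`), `classifier` (`domain_classifier_result`),
#'   `cv_error`, `proxy_a_distance`, `seed`.
#' @export
drc_from_domains <- function(train, test, bm1, bm2 = beta_shape(1, 1),
                             band = 0.05, seed = 1, clip_epsilon = 1e-6,
                             lambda_rule = "min", .fit_override = NULL) {
  bm1 <- as_beta_shape(bm1, "bm1")
  bm2 <- as_beta_shape(bm2, "bm2")
  if (any(train$scan_id %in% test$scan_id)) {
    stop_drcheck("Train and test samples share scan ids; the split must be by scan.",
                 "drcheck_invalid_input")
  }
  model <- train_domain_classifier(train, seed = seed,
                                   lambda_rule = lambda_rule)
  res <- evaluate_domain_classifier(model, test)
  pooled <- c(res$prob_u, 1 - res$prob_u)
  fit <- .fit_override %||% fit_separability(pooled, clip_epsilon)

  report <- if (fit$proper) {
    drc(fit$shape, bm1, bm2, band)
  } else {
    new_drc_report(kl_bm1 = NA_real_, kl_bm2 = NA_real_, drc = NA_real_,
                   verdict = "not_representative", bm1 = bm1, bm2 = bm2,
                   pi_tu = NULL, band = band, proper = FALSE,
                   reason = fit$reason)
  }
  structure(list(report = report, fit = fit, classifier = res,
                 cv_error = res$cv_error,
                 proxy_a_distance = proxy_a_distance(res$cv_error),
                 seed = seed),
            class = "drc_analysis")
}

#' @export
print.drc_analysis <- function(x, ...) {
  cat(sprintf("Domain classification: held-out error %.3f, proxy A-distance %.3f\n",
              x$cv_error, x$proxy_a_distance))
  print(x$report)
  invisible(x)
}

#' @method tidy drc_analysis
#' @export
tidy.drc_analysis <- function(x, ...) {
  dplyr::mutate(tidy(x$report),
                cv_error = x$cv_error,
                proxy_a_distance = x$proxy_a_distance,
                .before = 1)
}

#' @method glance drc_analysis
#' @export
glance.drc_analysis <- function(x, ...) {
  tibble::tibble(cv_error = x$cv_error,
                 proxy_a_distance = x$proxy_a_distance,
                 drc = x$report$drc,
                 proper = x$fit$proper,
                 verdict = x$report$verdict,
                 n_test = x$classifier$n_test)
}

#' Replication sweep of DRC and proxy A-distance over patch budgets
#'
#' Repeats the domain-classification experiment for each patch budget and
#' replication: per scan, `patch_count` patches are drawn at random (without
#' replacement), the classifier is built on the build scans of both domains
#' and tested on the held-out scans, and the DRC is computed for every
#' benchmark prior 1 in `bm1_list`. Replications differ only in the patch
#' sampling and fold seeds, all derived deterministically from `seed`.
#'
#' @param scans_t,scans_u Lists of `masked_image` scans for domains T and U.
#' @param patch_counts Integer vector of patches to draw per scan.
#' @param reps Number of replications per budget.
#' @param bm1_list List of benchmark-prior-1 shapes (defaults to the standard
#'   symmetric ladder 25...400).
#' @param bm2,band,clip_epsilon,lambda_rule Passed to [drc_from_domains()].
#' @param n_build,n_test Scans per domain used for building/testing (defaults
#'   15 and 5; reduced automatically only by erroring, never silently).
#' @param patch_size Patch side length (odd, default 15).
#' @param seed Master seed.
#' @return A tibble of class `drc_sweep` with one row per
#'   (patch_count, rep, bm1): columns `patch_count`, `rep`, `bm1_alpha`,
#'   `bm1_beta`, `kl_bm1`, `kl_bm2`, `drc`, `proxy_a_distance`, `cv_error`,
#'   `proper`, `verdict`.
#' @export
stability_sweep <- function(scans_t, scans_u, patch_counts = c(100, 500),
                            reps = 5, bm1_list = benchmark_priors(),
                            bm2 = beta_shape(1, 1), band = 0.05,
                            n_build = 15, n_test = 5, patch_size = 15,
                            clip_epsilon = 1e-6, lambda_rule = "min",
                            seed = 1) {
  bm1_list <- purrr::map(bm1_list, as_beta_shape)
  n_scans <- n_build + n_test
  if (length(scans_t) < n_scans || length(scans_u) < n_scans) {
    stop_drcheck(sprintf(
      "Need %d scans per domain (%d build + %d test); got %d (T) and %d (U).",
      n_scans, n_build, n_test, length(scans_t), length(scans_u)),
      "drcheck_invalid_input")
  }
  rows <- list()
  for (pc in patch_counts) {
    for (r in seq_len(reps)) {
      rep_seed <- derive_seed(seed, match(pc, patch_counts), r)
      ds <- sample_scan_patches(scans_t, scans_u, pc, patch_size, rep_seed)
      split <- list(
        build = ds[ds$scan_id %in% scan_subset_ids(scans_t, scans_u,
                                                   seq_len(n_build)), ],
        test = ds[ds$scan_id %in% scan_subset_ids(scans_t, scans_u,
                                                  n_build + seq_len(n_test)), ])
      for (s in c("build", "test")) {
        class(split[[s]]) <- c("domain_sample",
                               setdiff(class(split[[s]]), "domain_sample"))
      }
      base <- drc_from_domains(split$build, split$test, bm1 = bm1_list[[1]],
                               bm2 = bm2, band = band, seed = rep_seed,
                               clip_epsilon = clip_epsilon,
                               lambda_rule = lambda_rule)
      for (bm1 in bm1_list) {
        rep_report <- if (base$fit$proper) {
          drc(base$fit$shape, bm1, bm2, band)
        } else {
          base$report
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          patch_count = pc, rep = r,
          bm1_alpha = bm1$alpha, bm1_beta = bm1$beta,
          kl_bm1 = rep_report$kl_bm1, kl_bm2 = rep_report$kl_bm2,
          drc = rep_report$drc,
          proxy_a_distance = base$proxy_a_distance,
          cv_error = base$cv_error,
          proper = base$fit$proper, verdict = rep_report$verdict)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("drc_sweep", class(out))
  out
}

#' The standard benchmark-prior-1 ladder
#'
#' Symmetric shapes Beta(25,25), Beta(50,50), Beta(100,100), Beta(200,200),
#' Beta(300,300), Beta(400,400), ordered from lenient to strict.
#'
#' @return A named list of [beta_shape()] objects.
#' @export
benchmark_priors <- function() {
  ks <- c(25, 50, 100, 200, 300, 400)
  setNames(purrr::map(ks, ~ beta_shape(.x, .x)), paste0("beta_", ks))
}

scan_subset_ids <- function(scans_t, scans_u, idx) {
  c(vapply(scans_t[idx], function(s) s$subject_id, character(1)),
    vapply(scans_u[idx], function(s) s$subject_id, character(1)))
}

# Draw `n_per_scan` patches from every scan of both domains and assemble one
# domain_sample. Scan ids are taken from the images' subject ids and must be
# unique across the two lists.
sample_scan_patches <- function(scans_t, scans_u, n_per_scan, patch_size,
                                seed) {
  grab <- function(scans, dom, block) {
    parts <- purrr::imap(scans, function(sc, i) {
      ps <- sample_patch_features(sc, patch_size, n_per_scan,
                                  seed = derive_seed(seed, block, i))
      domain_sample(ps$features, dom, scan_id = ps$subject_id,
                    coords = cbind(ps$center_row, ps$center_col))
    })
    dplyr::bind_rows(parts)
  }
  out <- dplyr::bind_rows(grab(scans_t, "T", 1L), grab(scans_u, "U", 2L))
  class(out) <- c("domain_sample", setdiff(class(out), "domain_sample"))
  out
}

#' @method autoplot drc_sweep
#' @export
autoplot.drc_sweep <- function(object, ...) {
  df <- dplyr::mutate(object,
                      bm1 = sprintf("Beta(%g, %g)", .data$bm1_alpha,
                                    .data$bm1_beta))
  summ <- df |>
    dplyr::group_by(.data$patch_count, .data$bm1) |>
    dplyr::summarise(mean_drc = mean(.data$drc, na.rm = TRUE),
                     se = sd(.data$drc, na.rm = TRUE) /
                       sqrt(sum(!is.na(.data$drc))),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$patch_count,
                                     y = .data$mean_drc,
                                     colour = .data$bm1)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_drc - .data$se,
                                      ymax = .data$mean_drc + .data$se,
                                      fill = .data$bm1),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "patches per scan", y = "mean DRC",
                  colour = "benchmark prior 1", fill = "benchmark prior 1") +
    ggplot2::theme_minimal()
}
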