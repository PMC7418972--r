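#' Sample tissue-labelled patches from a simulated scan
#'
#' Draws patches as [sample_patch_features()] and attaches the tissue class
#' of each patch's middle pixel, read from the phantom the scan was rendered
#' from. Background-centred patches are excluded by construction.
#'
#' @param img A [masked_image()] carrying a `"phantom"` attribute (as
#'   returned by [simulate_scanner_domain()]), or supply `phantom`.
#' @param phantom Optional [generate_phantom()] result overriding the
#'   attribute.
#' @param k Patch side length (odd).
#' @param n Patches to draw.
#' @param seed Integer seed.
#' @return A `tissue_patch_set` tibble: `patch_set` columns plus a `tissue`
#'   factor (CSF/GM/WM).
#' @export
tissue_patches <- function(img, phantom = attr(img, "phantom"), k = 15,
                           n = 500, seed = 1) {
  if (is.null(phantom)) {
    stop_drcheck("No phantom available to label patches from.",
                 "drcheck_invalid_input")
  }
  ps <- sample_patch_features(img, k, n, seed)
  lab <- phantom$labels[cbind(ps$center_row, ps$center_col)]
  ps$tissue <- factor(c("CSF", "GM", "WM")[lab], levels = c("CSF", "GM", "WM"))
  class(ps) <- c("tissue_patch_set", class(ps))
  ps
}

#' Fit the surrogate tissue classifier
#'
#' Fits a multinomial L2-regularized linear model on flattened patches,
#' classifying CSF vs GM vs WM. This is a deliberately small, deterministic
#' surrogate for the (unspecified) convolutional network of the original
#' experiment: on piecewise-constant synthetic images it is sufficient to
#' reproduce the qualitative relationship between data-set similarity and
#' tissue-classification performance. The backend regularization path is
#' configurable through `model_cfg`.
#'
#' @param patches A `tissue_patch_set` (all three classes present).
#' @param model_cfg List with optional `lambda` (final penalty, default 1e-3)
#'   and `nlambda` (path length, default 25).
#' @param seed Integer seed (kept for interface symmetry; the fit itself is
#'   deterministic).
#' @return A `tissue_classifier` object.
#' @export
build_tissue_classifier <- function(patches, model_cfg = list(), seed = 1) {
  stopifnot(inherits(patches, "tissue_patch_set"))
  y <- droplevels(patches$tissue)
  if (nlevels(y) < 3L || any(table(y) < 2L)) {
    stop_drcheck(paste0("All three tissue classes must be present (>= 2 ",
                        "patches each) for training; increase the patch ",
                        "budget or image size."),
                 "drcheck_invalid_input")
  }
  lambda_final <- model_cfg$lambda %||% 1e-3
  nlambda <- model_cfg$nlambda %||% 25
  path <- exp(seq(log(10), log(lambda_final), length.out = nlambda))
  fit <- with_seed(derive_seed(seed, 9L), {
    glmnet::glmnet(patches$features, y, family = "multinomial", alpha = 0,
                   lambda = path)
  })
  structure(list(fit = fit, lambda = lambda_final,
                 levels = levels(patches$tissue)),
            class = "tissue_classifier")
}

#' @export
predict.tissue_classifier <- function(object, newdata, ...) {
  feats <- if (inherits(newdata, "tissue_patch_set") ||
               inherits(newdata, "patch_set")) newdata$features else newdata
  cls <- predict(object$fit, feats, s = object$lambda, type = "class")
  factor(as.character(cls), levels = object$levels)
}

tissue_error <- function(model, patches) {
  mean(predict(model, patches) != patches$tissue)
}

#' Learning-curve experiment: training+unseen vs unseen-only classifiers
#'
#' For each unseen-patch budget and replication, builds two tissue
#' classifiers — one on training-domain patches plus the budgeted unseen
#' patches, one on the budgeted unseen patches alone — and evaluates both on
#' held-out unseen scans. The sign of the error difference at small budgets
#' exposes the turning point: when the domains match, training data help;
#' when they are grossly mismatched, they hurt.
#'
#' @param scans_t Training-domain scans (list of [masked_image()] with
#'   phantom attributes).
#' @param scans_u_build Unseen-domain scans used for building.
#' @param scans_u_test Held-out unseen-domain scans used for testing (must be
#'   distinct subjects from `scans_u_build`).
#' @param unseen_budgets Unseen patches per build scan to sweep.
#' @param reps Replications (patch resampling) per budget.
#' @param n_train_patches Training-domain patches per scan (default 500).
#' @param n_test_patches Test patches per held-out scan (default 500).
#' @param k Patch side length.
#' @param model_cfg Passed to [build_tissue_classifier()].
#' @param seed Master seed.
#' @return A tibble of class `learning_curve`: one row per
#'   (rep, budget, classifier kind) with columns `rep`,
#'   `n_unseen_patches`, `classifier_kind`
#'   (`"training_plus_unseen"`/`"unseen_only"`) and `test_error`.
#' @export
learning_curve_experiment <- function(scans_t, scans_u_build, scans_u_test,
                                      unseen_budgets = c(50, 200, 1000),
                                      reps = 3, n_train_patches = 500,
                                      n_test_patches = 500, k = 15,
                                      model_cfg = list(), seed = 1) {
  build_ids <- vapply(scans_u_build, function(s) s$subject_id, character(1))
  test_ids <- vapply(scans_u_test, function(s) s$subject_id, character(1))
  if (length(intersect(build_ids, test_ids)) > 0L) {
    stop_drcheck("Unseen build and test scans must be disjoint subjects.",
                 "drcheck_invalid_input")
  }
  grab <- function(scans, n, block, r) {
    dplyr::bind_rows(purrr::imap(scans, function(sc, i) {
      tissue_patches(sc, k = k, n = n, seed = derive_seed(seed, block, r, i))
    }))
  }
  as_tps <- function(df) {
    class(df) <- c("tissue_patch_set", setdiff(class(df), "tissue_patch_set"))
    df
  }
  rows <- list()
  for (r in seq_len(reps)) {
    train_pool <- as_tps(grab(scans_t, n_train_patches, 1L, r))
    test_pool <- as_tps(grab(scans_u_test, n_test_patches, 2L, r))
    for (b in unseen_budgets) {
      unseen_pool <- as_tps(grab(scans_u_build, b, 3L, r))
      both <- as_tps(dplyr::bind_rows(train_pool, unseen_pool))
      m_both <- build_tissue_classifier(both, model_cfg,
                                        seed = derive_seed(seed, 4L, r, b))
      m_unseen <- build_tissue_classifier(unseen_pool, model_cfg,
                                          seed = derive_seed(seed, 5L, r, b))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        rep = r, n_unseen_patches = b,
        classifier_kind = c("training_plus_unseen", "unseen_only"),
        test_error = c(tissue_error(m_both, test_pool),
                       tissue_error(m_unseen, test_pool)))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("learning_curve", class(out))
  out
}

#' @method autoplot learning_curve
#' @export
autoplot.learning_curve <- function(object, ...) {
  summ <- object |>
    dplyr::group_by(.data$n_unseen_patches, .data$classifier_kind) |>
    dplyr::summarise(mean_error = mean(.data$test_error),
                     se = sd(.data$test_error) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$n_unseen_patches,
                                     y = .data$mean_error,
                                     colour = .data$classifier_kind)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_error - .data$se,
                                      ymax = .data$mean_error + .data$se,
                                      fill = .data$classifier_kind),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "unseen building patches per scan",
                  y = "tissue classification error",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Paint predicted tissue classes back into an image
#'
#' Inspection utility: classifies every valid patch of a scan and returns a
#' label image of the predictions (no accuracy claims are attached to it).
#'
#' @param model A `tissue_classifier`.
#' @param img A [masked_image()].
#' @param k Patch side length.
#' @return An integer matrix (0 background/border, 1 CSF, 2 GM, 3 WM).
#' @export
paint_predictions <- function(model, img, k = 15) {
  ps <- extract_patches(img, k)
  out <- matrix(0L, nrow(img$pixels), ncol(img$pixels))
  if (nrow(ps) == 0L) return(out)
  pred <- predict(model, ps)
  out[cbind(ps$center_row, ps$center_col)] <- as.integer(pred)
  out
}
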