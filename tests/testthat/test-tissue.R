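make_tissue_scans <- function(cfg, n, offset, size = 128) {
  simulate_scanner_domain(cfg, n, seed_offset = offset, size = size)
}

test_that("tissue patches carry the phantom class of their center pixel", {
  scans <- make_tissue_scans(scanner_presets()$scanner1, 1, 0)
  tp <- tissue_patches(scans[[1]], n = 300, seed = 2)
  ph <- attr(scans[[1]], "phantom")
  expect_identical(as.integer(tp$tissue),
                   ph$labels[cbind(tp$center_row, tp$center_col)])
  expect_true(all(as.integer(tp$tissue) %in% 1:3))
})

test_that("the surrogate classifier behaves sanely on its training regime", {
  cfg0 <- scanner_config(3, tr = 8, te = 3, flip_deg = 12, noise_sigma = 0)
  scans <- simulate_scanner_domain(cfg0, 2, seed_offset = 0, size = 128)
  tp <- dplyr::bind_rows(tissue_patches(scans[[1]], n = 400, seed = 1),
                         tissue_patches(scans[[2]], n = 400, seed = 2))
  class(tp) <- c("tissue_patch_set", setdiff(class(tp), "tissue_patch_set"))
  m <- build_tissue_classifier(tp, seed = 1)
  # noise-free piecewise-constant patches are (almost) linearly separable
  expect_lt(mean(predict(m, tp) != tp$tissue), 0.02)

  # shuffled labels: chance level on three balanced-ish classes
  shuf <- tp
  shuf$tissue <- with_seed_local(5, sample(shuf$tissue))
  m_shuf <- build_tissue_classifier(shuf, seed = 1)
  held <- tissue_patches(simulate_scanner_domain(cfg0, 1, seed_offset = 50,
                                                 size = 128)[[1]],
                         n = 400, seed = 3)
  err_shuf <- mean(predict(m_shuf, held) != held$tissue)
  expect_gt(err_shuf, 0.4)

  # moderate noise, same scanner: far better than chance
  scans_n <- make_tissue_scans(scanner_presets()$scanner1, 2, 0)
  tpn <- dplyr::bind_rows(tissue_patches(scans_n[[1]], n = 400, seed = 1),
                          tissue_patches(scans_n[[2]], n = 400, seed = 2))
  class(tpn) <- c("tissue_patch_set", setdiff(class(tpn), "tissue_patch_set"))
  mn <- build_tissue_classifier(tpn, seed = 1)
  held_n <- tissue_patches(make_tissue_scans(scanner_presets()$scanner1, 1,
                                             60)[[1]], n = 400, seed = 4)
  expect_lt(mean(predict(mn, held_n) != held_n$tissue), 0.2)

  # missing class errors out
  two <- tp[tp$tissue != "CSF", ]
  class(two) <- c("tissue_patch_set", setdiff(class(two), "tissue_patch_set"))
  expect_error(build_tissue_classifier(two), class = "drcheck_invalid_input")
})

test_that("learning curve contract: rows, disjointness, and matched benefit", {
  p <- scanner_presets()
  scans_t <- make_tissue_scans(p$scanner1, 3, 0)
  scans_ub <- make_tissue_scans(p$scanner1, 3, 100)
  scans_ut <- make_tissue_scans(p$scanner1, 2, 200)

  lc1 <- learning_curve_experiment(scans_t, scans_ub, scans_ut,
                                   unseen_budgets = 150, reps = 1,
                                   n_train_patches = 250,
                                   n_test_patches = 250, seed = 2)
  expect_identical(nrow(lc1), 2L)
  expect_setequal(lc1$classifier_kind,
                  c("training_plus_unseen", "unseen_only"))
  expect_true(all(lc1$test_error >= 0 & lc1$test_error <= 1))

  expect_error(
    learning_curve_experiment(scans_t, scans_ub, scans_ub,
                              unseen_budgets = 100),
    class = "drcheck_invalid_input")

  # identical domains: training data help at the smallest budget
  expect_lte(lc1$test_error[lc1$classifier_kind == "training_plus_unseen"],
             lc1$test_error[lc1$classifier_kind == "unseen_only"])
})

test_that("unseen-only error is non-increasing in the budget", {
  p <- scanner_presets()
  scans_t <- make_tissue_scans(p$scanner1, 2, 0)
  scans_ub <- make_tissue_scans(p$scanner4, 3, 100)
  scans_ut <- make_tissue_scans(p$scanner4, 2, 200)
  lc <- learning_curve_experiment(scans_t, scans_ub, scans_ut,
                                  unseen_budgets = c(50, 200, 800),
                                  reps = 2, n_train_patches = 200,
                                  n_test_patches = 300, seed = 6)
  unseen <- lc |>
    dplyr::filter(.data$classifier_kind == "unseen_only") |>
    dplyr::group_by(.data$n_unseen_patches) |>
    dplyr::summarise(err = mean(.data$test_error))
  expect_true(all(diff(unseen$err) <= 0.02))
})

test_that("prediction painting produces a label image", {
  scans <- make_tissue_scans(scanner_presets()$scanner1, 2, 0, size = 96)
  tp <- dplyr::bind_rows(tissue_patches(scans[[1]], n = 300, seed = 1),
                         tissue_patches(scans[[2]], n = 300, seed = 2))
  class(tp) <- c("tissue_patch_set", setdiff(class(tp), "tissue_patch_set"))
  m <- build_tissue_classifier(tp, seed = 1)
  painted <- paint_predictions(m, scans[[1]], k = 15)
  expect_identical(dim(painted), dim(scans[[1]]$pixels))
  expect_true(all(painted %in% 0:3))
  expect_gt(sum(painted > 0), 0)
})
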