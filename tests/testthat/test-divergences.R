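test_that("beta shapes reject improper parameters", {
  expect_s3_class(beta_shape(0.5, 400), "beta_shape")
  expect_error(beta_shape(0, 1), class = "drcheck_improper_distribution")
  expect_error(beta_shape(-2, 1), class = "drcheck_improper_distribution")
  expect_error(beta_shape(Inf, 1), class = "drcheck_improper_distribution")
  expect_error(beta_shape(1, NaN), class = "drcheck_improper_distribution")
  # the offending parameter is named
  expect_error(beta_shape(1, -1), "beta")
})

test_that("closed-form KL matches its analytic and quadrature values", {
  expect_identical(kl_beta(beta_shape(1, 1), beta_shape(1, 1)), 0)
  # KL(Beta(0.5,0.5) || Beta(1,1)) = log(4/pi), cross-checked by quadrature
  expect_equal(kl_beta(beta_shape(0.5, 0.5), beta_shape(1, 1)), log(4 / pi),
               tolerance = 1e-12)
  expect_equal(kl_beta_numeric(beta_shape(0.5, 0.5), beta_shape(1, 1), 1e-8),
               0.2415645, tolerance = 1e-6)
  expect_equal(kl_beta(beta_shape(100, 100), beta_shape(25, 25)),
               kl_beta_numeric(beta_shape(100, 100), beta_shape(25, 25)),
               tolerance = 1e-6)
})

test_that("KL is nonnegative and zero only for equal shapes", {
  grid <- expand.grid(a = c(0.5, 2, 25), b = c(0.5, 2, 100))
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(nrow(grid))) {
      p <- beta_shape(grid$a[i], grid$b[i])
      q <- beta_shape(grid$a[j], grid$b[j])
      v <- kl_beta(p, q)
      expect_gte(v, 0)
      if (i == j) expect_equal(v, 0, tolerance = 1e-12)
      else if (grid$a[i] != grid$a[j] || grid$b[i] != grid$b[j]) {
        expect_gt(v, 0)
      }
    }
  }
})

test_that("quadrature agrees with the closed form for swapped shapes", {
  expect_equal(kl_beta_numeric(beta_shape(2, 2), beta_shape(2, 2), 1e-10), 0,
               tolerance = 1e-10)
  expect_equal(kl_beta_numeric(beta_shape(3, 1), beta_shape(1, 3), 1e-8),
               kl_beta(beta_shape(3, 1), beta_shape(1, 3)),
               tolerance = 1e-7)
  expect_error(kl_beta_numeric(beta_shape(1, 1), beta_shape(1, 1), -1),
               class = "drcheck_invalid_input")
})

test_that("drc forms the ratio, records both KL terms and issues verdicts", {
  # numerator zero when the fit coincides with benchmark prior 1
  r0 <- drc(beta_shape(25, 25), bm1 = beta_shape(25, 25))
  expect_equal(r0$drc, 0)
  expect_identical(r0$verdict, "representative")

  expect_error(drc(beta_shape(1, 1), bm1 = beta_shape(25, 25)),
               class = "drcheck_degenerate_ratio")

  # a flat-ish U-shaped fit is far from a concentrated benchmark: the ratio
  # is two orders of magnitude above 1 (both terms checked by quadrature)
  r <- drc(beta_shape(0.5, 0.5), bm1 = beta_shape(25, 25))
  num <- kl_beta_numeric(beta_shape(0.5, 0.5), beta_shape(25, 25))
  den <- kl_beta_numeric(beta_shape(0.5, 0.5), beta_shape(1, 1))
  expect_equal(r$drc, num / den, tolerance = 1e-6)
  expect_gt(r$drc, 100)
  expect_identical(r$verdict, "not_representative")
  expect_equal(r$kl_bm1, num, tolerance = 1e-6)
  expect_equal(r$kl_bm2, den, tolerance = 1e-6)

  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("bm1_alpha", "bm1_beta", "bm2_alpha", "bm2_beta",
                     "pi_tu_alpha", "pi_tu_beta", "kl_bm1", "kl_bm2",
                     "drc", "proper", "verdict"))
})

test_that("drc is monotone in the fit concentration between bm2 and bm1", {
  # For bm1 = Beta(k,k) and bm2 = Beta(1,1), the ratio falls as the fitted
  # concentration s rises from 1 toward k, and rises as s falls below 1.
  k <- 25
  up <- vapply(c(1.5, 3, 6, 12, 24),
               function(s) drc(beta_shape(s, s), beta_shape(k, k))$drc,
               numeric(1))
  expect_true(all(diff(up) < 0))
  # below s = 1 the denominator KL to the flat benchmark grows as the fit
  # becomes U-shaped, so the ratio falls again; the peak sits at s -> 1,
  # where pi_TU approaches bm2 and the ratio diverges
  down <- vapply(c(0.9, 0.7, 0.5, 0.3),
                 function(s) drc(beta_shape(s, s), beta_shape(k, k))$drc,
                 numeric(1))
  expect_true(all(diff(down) < 0))
  expect_gt(down[1], up[length(up)])
})

test_that("verdict flips exactly at drc = 1 +/- band", {
  # pick shapes whose ratio brackets the thresholds tightly via root search
  band <- 0.05
  ratio_at <- function(s) drc(beta_shape(s, s), beta_shape(25, 25),
                              band = band)$drc
  # ratio is continuous and decreasing in s on (1, 25); find s* with ratio ~ 1-band
  f <- function(s) ratio_at(s) - (1 - band)
  s_star <- uniroot(f, c(5, 24))$root
  expect_identical(drc(beta_shape(s_star * 1.01, s_star * 1.01),
                       beta_shape(25, 25), band = band)$verdict,
                   "representative")
  expect_identical(drc(beta_shape(s_star * 0.99, s_star * 0.99),
                       beta_shape(25, 25), band = band)$verdict,
                   "inconclusive")
  g <- function(s) ratio_at(s) - (1 + band)
  s_hi <- uniroot(g, c(5, 24))$root
  expect_identical(drc(beta_shape(s_hi * 0.99, s_hi * 0.99),
                       beta_shape(25, 25), band = band)$verdict,
                   "not_representative")
  expect_identical(drc(beta_shape(s_hi * 1.01, s_hi * 1.01),
                       beta_shape(25, 25), band = band)$verdict,
                   "inconclusive")
})
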