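test_that("phantoms are deterministic, varied and anatomically plausible", {
  p1 <- generate_phantom(1, 256)
  expect_identical(p1$labels, generate_phantom(1, 256)$labels)
  expect_setequal(unique(as.vector(p1$labels)), 0:3)
  frac <- mean(p1$mask == 1)
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.7)

  labs <- lapply(1:20, function(s) generate_phantom(s, 96)$labels)
  for (i in 1:19) {
    for (j in (i + 1):20) {
      expect_false(identical(labs[[i]], labs[[j]]))
    }
  }
  expect_error(generate_phantom(1, 32), class = "drcheck_invalid_input")
})

test_that("spoiled gradient-echo signal has the right limits", {
  tis <- tissue_properties()
  wm <- tis[tis$tissue == "WM" & tis$b0 == 3, ]
  # saturation recovery: 90 degrees, TR >> T1, TE -> 0 gives PD
  cfg <- scanner_config(3, tr = 100 * wm$t1, te = 1e-6, flip_deg = 90)
  expect_equal(spgr_signal(cfg, wm$t1, wm$t2star, wm$proton_density),
               wm$proton_density, tolerance = 1e-6)
  # vanishing flip angle kills the signal
  cfg0 <- scanner_config(3, tr = 10, te = 3, flip_deg = 1e-6)
  expect_lt(spgr_signal(cfg0, wm$t1, wm$t2star, wm$proton_density), 1e-6)
  # at 90 degrees the signal is non-decreasing in TR
  sig <- vapply(c(5, 10, 50, 200, 1000, 5000), function(tr) {
    spgr_signal(scanner_config(3, tr = tr, te = 3, flip_deg = 90),
                wm$t1, wm$t2star, wm$proton_density)
  }, numeric(1))
  expect_true(all(diff(sig) >= 0))
})

test_that("scanner config enforces physical invariants", {
  expect_error(scanner_config(3, tr = 5, te = 10), "smaller")
  expect_error(scanner_config(3, flip_deg = 0), "flip")
  expect_error(scanner_config(-1), class = "drcheck_invalid_input")
})

test_that("rendering is piecewise constant plus seeded noise", {
  ph <- generate_phantom(3, 96)
  cfg <- scanner_config(3, tr = 8, te = 3, flip_deg = 12, noise_sigma = 0)
  img <- simulate_scan(ph, cfg, seed = 1)
  vals <- unique(round(img$pixels[ph$mask == 1], 12))
  expect_identical(length(vals), 3L)
  expect_true(all(img$pixels[ph$mask == 0] == 0))

  cfgn <- scanner_config(3, tr = 8, te = 3, flip_deg = 12,
                         noise_sigma = 0.02)
  i1 <- simulate_scan(ph, cfgn, seed = 5)
  i2 <- simulate_scan(ph, cfgn, seed = 5)
  expect_identical(i1$pixels, i2$pixels)
  expect_false(identical(i1$pixels, simulate_scan(ph, cfgn, seed = 6)$pixels))

  # a large TR change moves the per-tissue mean intensities
  far <- simulate_scan(ph, scanner_config(3, tr = 800, te = 3,
                                          flip_deg = 12, noise_sigma = 0),
                       seed = 1)
  for (cls in 1:3) {
    expect_false(isTRUE(all.equal(mean(img$pixels[ph$labels == cls]),
                                  mean(far$pixels[ph$labels == cls]))))
  }
})

test_that("presets form a seven-scanner ladder with a 1.5T outlier", {
  pres <- scanner_presets()
  expect_length(pres, 7L)
  expect_identical(vapply(pres, function(p) p$b0, numeric(1)),
                   c(scanner1 = 3, scanner2 = 3, scanner3 = 3, scanner4 = 3,
                     scanner5 = 3, scanner6 = 3, scanner7 = 1.5))
  # TR strictly increases along the 3T gradient-echo sweep
  trs <- vapply(pres[1:5], function(p) p$tr, numeric(1))
  expect_true(all(diff(trs) > 0))
})

test_that("rendered similarity to scanner 1 decreases along the presets", {
  pres <- scanner_presets()
  scans_t <- simulate_scanner_domain(pres$scanner1, 5, seed_offset = 0,
                                     size = 256)
  pad <- rep(NA_real_, 6)
  improper <- rep(NA, 6)
  for (cond in 1:6) {
    scans_u <- simulate_scanner_domain(pres[[cond + 1]], 5,
                                       seed_offset = 1000, size = 256)
    sw <- stability_sweep(scans_t, scans_u, patch_counts = 500, reps = 3,
                          bm1_list = list(beta_shape(25, 25)),
                          n_build = 4, n_test = 1, seed = 31)
    pad[cond] <- mean(sw$proxy_a_distance)
    improper[cond] <- any(!sw$proper)
  }
  # mean proxy A-distance non-decreasing over conditions 1..6 (small slack
  # for Monte-Carlo noise between near-tied adjacent conditions)
  expect_true(all(diff(pad) >= -0.05))
  expect_gt(pad[6], pad[1])
  # far presets drive the fit improper, near presets keep it proper
  expect_false(improper[1])
  expect_true(improper[6])
})
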