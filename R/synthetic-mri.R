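#' Scanner acquisition configuration
#'
#' Parameters of the simulated T1-weighted acquisition: main field strength
#' B0 (Tesla), repetition time TR and echo time TE (ms), flip angle (degrees),
#' a sequence tag, and the additive noise scale as a fraction of the maximum
#' tissue signal.
#'
#' @param b0 Field strength in Tesla (> 0).
#' @param tr Repetition time in ms (> 0).
#' @param te Echo time in ms (> 0, < `tr`).
#' @param flip_deg Flip angle in degrees, in (0, 180].
#' @param sequence Free-text sequence tag.
#' @param noise_sigma Gaussian noise standard deviation as a fraction of the
#'   maximum tissue signal (>= 0).
#' @return An object of class `scanner_config`.
#' @export
scanner_config <- function(b0 = 3, tr = 8, te = 3, flip_deg = 12,
                           sequence = "3D-SPGR", noise_sigma = 0.02) {
  check_scalar_number(b0, "b0", lower = 1e-6)
  check_scalar_number(tr, "tr", lower = 1e-6)
  check_scalar_number(te, "te", lower = 1e-6)
  check_scalar_number(flip_deg, "flip_deg")
  check_scalar_number(noise_sigma, "noise_sigma", lower = 0)
  if (te >= tr) {
    stop_drcheck("`te` must be smaller than `tr`.", "drcheck_invalid_input")
  }
  if (flip_deg <= 0 || flip_deg > 180) {
    stop_drcheck("`flip_deg` must lie in (0, 180].", "drcheck_invalid_input")
  }
  structure(list(b0 = b0, tr = tr, te = te, flip_deg = flip_deg,
                 sequence = as.character(sequence),
                 noise_sigma = noise_sigma),
            class = "scanner_config")
}

#' @export
print.scanner_config <- function(x, ...) {
  cat(sprintf("scanner_config: %.1fT %s, TR %g ms, TE %g ms, flip %g deg, noise %g\n",
              x$b0, x$sequence, x$tr, x$te, x$flip_deg, x$noise_sigma))
  invisible(x)
}

#' Relaxation properties of the three tissue classes
#'
#' Longitudinal relaxation time T1, effective transverse relaxation time T2*
#' (both ms) and relative proton density for cerebrospinal fluid (CSF), grey
#' matter (GM) and white matter (WM), at 1.5 T and 3.0 T. Values are
#' representative literature ranges; only the resulting *contrast ordering*
#' matters to the pipeline, and the table can be edited and passed to
#' [simulate_scan()].
#'
#' @return A tibble with columns `tissue`, `b0`, `t1`, `t2star`,
#'   `proton_density`.
#' @export
tissue_properties <- function() {
  tibble::tribble(
    ~tissue, ~b0, ~t1, ~t2star, ~proton_density,
    "CSF", 3.0, 4000, 400, 1.00,
    "GM",  3.0, 1330,  45, 0.85,
    "WM",  3.0,  830,  40, 0.70,
    "CSF", 1.5, 3500, 450, 1.00,
    "GM",  1.5, 1100,  60, 0.85,
    "WM",  1.5,  650,  55, 0.70)
}

#' Spoiled gradient-echo steady-state signal
#'
#' Closed-form signal of a spoiled gradient-echo acquisition:
#' \deqn{S = PD \cdot \sin\alpha \cdot
#'   \frac{1 - e^{-TR/T_1}}{1 - \cos\alpha \; e^{-TR/T_1}} \cdot
#'   e^{-TE/T_2^*}.}
#' At a 90-degree flip with long TR and short TE the signal saturates at the
#' proton density; it vanishes as the flip angle approaches zero.
#'
#' @param cfg A [scanner_config()].
#' @param t1,t2star Relaxation times in ms.
#' @param proton_density Relative proton density.
#' @return Nonnegative signal value (arbitrary units).
#' @export
spgr_signal <- function(cfg, t1, t2star, proton_density) {
  stopifnot(inherits(cfg, "scanner_config"))
  a <- cfg$flip_deg * pi / 180
  e1 <- exp(-cfg$tr / t1)
  proton_density * sin(a) * (1 - e1) / (1 - cos(a) * e1) *
    exp(-cfg$te / t2star)
}

#' Generate a labelled brain-like phantom
#'
#' Procedurally generates a 2-D three-tissue phantom: an elliptical head of
#' grey matter, an inner white-matter region and two cerebrospinal-fluid
#' ventricles near the centre. Axes, rotation, centre and ventricle geometry
#' are jittered per seed, emulating anatomical variability between subjects.
#' Deterministic given `seed`.
#'
#' @param seed Integer subject seed.
#' @param size Image side length in pixels (>= 64, default 256).
#' @return A `labeled_phantom`: integer `labels` matrix (0 background, 1 CSF,
#'   2 GM, 3 WM), binary `mask`, `subject_seed`, `size`.
#' @export
generate_phantom <- function(seed = 1, size = 256) {
  if (!is.numeric(size) || size < 64) {
    stop_drcheck("`size` must be at least 64.", "drcheck_invalid_input")
  }
  size <- as.integer(size)
  with_seed(derive_seed(seed, 77L), {
    u <- function(lo, hi) runif(1, lo, hi)
    cx <- u(-0.04, 0.04); cy <- u(-0.04, 0.04)
    rot <- u(-10, 10) * pi / 180
    ax <- 0.78 + u(-0.05, 0.05); ay <- 0.92 + u(-0.05, 0.05)
    g <- seq(-1, 1, length.out = size)
    X <- matrix(g, size, size)
    Y <- matrix(g, size, size, byrow = TRUE)
    xr <- (X - cx) * cos(rot) + (Y - cy) * sin(rot)
    yr <- -(X - cx) * sin(rot) + (Y - cy) * cos(rot)
    in_ellipse <- function(x0, y0, a, b, th = 0) {
      xa <- (xr - x0) * cos(th) + (yr - y0) * sin(th)
      yb <- -(xr - x0) * sin(th) + (yr - y0) * cos(th)
      (xa / a)^2 + (yb / b)^2 <= 1
    }
    head <- in_ellipse(0, 0, ax, ay)
    wm <- in_ellipse(0, u(-0.03, 0.03),
                     ax * (0.70 + u(-0.04, 0.04)),
                     ay * (0.72 + u(-0.04, 0.04)))
    vx <- 0.13 + u(-0.02, 0.02)
    vw <- 0.06 + u(-0.015, 0.015)
    vl <- 0.20 + u(-0.04, 0.04)
    vth <- u(-0.12, 0.12)
    vy <- u(-0.05, 0.05)
    vent <- in_ellipse(-vx, vy, vw, vl, vth) |
      in_ellipse(vx, vy, vw, vl, -vth)
    labels <- matrix(0L, size, size)
    labels[head] <- 2L
    labels[wm & head] <- 3L
    labels[vent & head] <- 1L
    structure(list(labels = labels, mask = (labels != 0L) * 1L,
                   subject_seed = as.integer(seed), size = size),
              class = "labeled_phantom")
  })
}

#' @export
print.labeled_phantom <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:3,
                      labels = c("background", "CSF", "GM", "WM")))
  cat(sprintf("labeled_phantom %dx%d (subject seed %d)\n", x$size, x$size,
              x$subject_seed))
  print(tab)
  invisible(x)
}

#' Render a phantom under an acquisition configuration
#'
#' Assigns each tissue its spoiled gradient-echo signal for the given
#' configuration (using the relaxation table for the configuration's field
#' strength), adds zero-mean Gaussian noise of standard deviation
#' `noise_sigma` times the maximum tissue signal, and keeps the background at
#' exactly zero. Deterministic given `seed`.
#'
#' @param phantom A [generate_phantom()] result.
#' @param cfg A [scanner_config()].
#' @param seed Integer noise seed.
#' @param properties Relaxation table, defaults to [tissue_properties()].
#' @return A [masked_image()] whose `scanner_id` records the sequence tag.
#' @export
simulate_scan <- function(phantom, cfg, seed = 1,
                          properties = tissue_properties()) {
  stopifnot(inherits(phantom, "labeled_phantom"),
            inherits(cfg, "scanner_config"))
  tab <- properties[abs(properties$b0 - cfg$b0) ==
                      min(abs(properties$b0 - cfg$b0)), ]
  sig <- vapply(c("CSF", "GM", "WM"), function(tis) {
    row <- tab[tab$tissue == tis, ]
    spgr_signal(cfg, row$t1, row$t2star, row$proton_density)
  }, numeric(1))
  img <- matrix(0, phantom$size, phantom$size)
  for (i in 1:3) img[phantom$labels == i] <- sig[i]
  noisy <- with_seed(derive_seed(seed, 55L), {
    img + matrix(rnorm(length(img), 0, cfg$noise_sigma * max(sig)),
                 nrow(img))
  })
  noisy[phantom$labels == 0L] <- 0
  masked_image(noisy, phantom$mask,
               subject_id = sprintf("subj%05d", phantom$subject_seed),
               scanner_id = cfg$sequence)
}

#' The seven scanner presets
#'
#' Named acquisition configurations emulating a multi-scanner comparison:
#' scanners 1-5 form a 3.0 T spoiled-gradient-echo TR sweep (TR 8, 10, 14,
#' 22, 35 ms) so that the difference from scanner 1 grows along the list;
#' scanner 6 is a proton-density-weighted standard 3.0 T protocol and
#' scanner 7 a T2-weighted standard 1.5 T protocol, both producing normalized
#' tissue contrast far from scanner 1's T1 weighting. The numeric values are
#' an emulation chosen so that rendered similarity to scanner 1 decreases
#' monotonically along the list (validated end-to-end by the separability
#' pipeline); they are configurable and make no claim to match any particular
#' hardware.
#'
#' @return A named list of 7 [scanner_config()] objects.
#' @export
scanner_presets <- function() {
  list(
    scanner1 = scanner_config(3.0, tr = 8, te = 3, flip_deg = 12,
                              sequence = "SPGR-TR8"),
    scanner2 = scanner_config(3.0, tr = 10, te = 3, flip_deg = 12,
                              sequence = "SPGR-TR10"),
    scanner3 = scanner_config(3.0, tr = 14, te = 3, flip_deg = 12,
                              sequence = "SPGR-TR14"),
    scanner4 = scanner_config(3.0, tr = 22, te = 3, flip_deg = 12,
                              sequence = "SPGR-TR22"),
    scanner5 = scanner_config(3.0, tr = 35, te = 3, flip_deg = 12,
                              sequence = "SPGR-TR35"),
    scanner6 = scanner_config(3.0, tr = 3000, te = 15, flip_deg = 90,
                              sequence = "SE-PD"),
    scanner7 = scanner_config(1.5, tr = 4000, te = 90, flip_deg = 90,
                              sequence = "SE-T2"))
}

#' Simulate a set of scans for one scanner
#'
#' Generates `n_scans` subjects (phantom seeds `seed_offset + 1 ...`) and
#' renders each under `cfg`, returning normalized masked images ready for
#' patch extraction.
#'
#' @param cfg A [scanner_config()].
#' @param n_scans Number of scans.
#' @param seed_offset Offset added to the subject index to form the phantom
#'   seed, so domains can draw disjoint subject pools.
#' @param size Image side length.
#' @param normalize Whether to min-max normalize each scan (default TRUE).
#' @return A list of [masked_image()] objects; each carries its phantom as
#'   attribute `"phantom"` for tissue labelling.
#' @export
simulate_scanner_domain <- function(cfg, n_scans = 10, seed_offset = 0,
                                    size = 256, normalize = TRUE) {
  purrr::map(seq_len(n_scans), function(i) {
    ph <- generate_phantom(seed_offset + i, size)
    img <- simulate_scan(ph, cfg, seed = derive_seed(seed_offset, i, 3L))
    if (normalize) img <- normalize_image(img)
    attr(img, "phantom") <- ph
    img
  })
}
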