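# Shared fixtures, all generated in code at test time.

# Hierarchical Gaussian domains split by scan: the standard small-scale
# condition for pipeline tests (8 build + 4 test scans per domain).
gaussian_split <- function(delta, seed = 1, n_scans = 12, n_per_scan = 100,
                           n_features = 10, scan_sd = 0.2) {
  ds <- gaussian_domain_scans(delta, n_scans = n_scans,
                              n_per_scan = n_per_scan,
                              n_features = n_features, scan_sd = scan_sd,
                              seed = seed)
  split_by_scan(ds, n_build = round(2 * n_scans / 3),
                n_test = n_scans - round(2 * n_scans / 3))
}

# Two plain i.i.d. Gaussian domains with an instance-level half split
# (pseudo-scans so the scan-disjointness contract is satisfied).
plain_gaussian_split <- function(delta, n = 5000, seed = 1) {
  with_seed_local(seed, {
    x <- rbind(cbind(rnorm(n), rnorm(n)),
               cbind(rnorm(n, delta), rnorm(n)))
    dom <- rep(c("T", "U"), each = n)
    half <- sample(rep(c("build", "test"), length.out = n))
    sid <- paste0(dom, "_", c(half, half))
    ds <- domain_sample(x, dom, scan_id = sid)
    list(build = as_ds(ds[grepl("build", ds$scan_id), ]),
         test = as_ds(ds[grepl("test", ds$scan_id), ]))
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

as_ds <- function(df) {
  class(df) <- c("domain_sample", setdiff(class(df), "domain_sample"))
  df
}

# Small rendered scan sets for the image pipeline.
image_domains <- function(cfg_t, cfg_u, n_scans = 4, size = 128,
                          offset_u = 1000) {
  list(t = simulate_scanner_domain(cfg_t, n_scans, seed_offset = 0,
                                   size = size),
       u = simulate_scanner_domain(cfg_u, n_scans, seed_offset = offset_u,
                                   size = size))
}

# A tiny fully-foreground image with known intensities.
flat_image <- function(n = 32, value = seq_len(n * n) / (n * n)) {
  masked_image(matrix(value, n, n), matrix(1, n, n))
}
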