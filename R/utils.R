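# Internal helpers shared across modules.

# Deterministic child-seed derivation from a master seed and integer indices.
# A small multiplicative mix keeps children well separated while staying inside
# the 32-bit range R requires of set.seed().
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k) * 2654435761) %% 2147483647
  }
  as.integer(h %% 2147483629 + 1)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_drcheck <- function(msg, class) {
  abort(msg, class = c(class, "drcheck_error"))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_drcheck(sprintf("`%s` must be a single finite number.", name),
                 "drcheck_invalid_input")
  }
  if (x < lower || x > upper) {
    stop_drcheck(sprintf("`%s` must lie in [%s, %s] (got %g).",
                         name, format(lower), format(upper), x),
                 "drcheck_invalid_input")
  }
  invisible(x)
}

# FNV-1a style fingerprint of a canonical key=value string; used for
# provenance stamps in manifests and reports.
config_fingerprint <- function(x) {
  s <- paste(names(x), vapply(x, function(v) paste(format(v, digits = 12),
                                                   collapse = ","),
                              character(1)),
             sep = "=", collapse = ";")
  bytes <- utf8ToInt(s)
  h <- 216613626
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(b))
    h <- (as.double(h) * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
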