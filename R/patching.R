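#' Masked grayscale image
#'
#' Container for a 2-D intensity grid plus a binary foreground mask (1 =
#' brain/foreground) and pixel spacing in millimetres. The default geometry of
#' the synthetic scans is 256 x 256 pixels at 1.0 x 1.0 mm.
#'
#' @param pixels Numeric matrix of intensities.
#' @param mask Binary matrix (0/1 or logical) of the same shape.
#' @param spacing Physical pixel size `(row, col)` in mm.
#' @param subject_id,scanner_id Identifiers carried into patch provenance.
#' @return An object of class `masked_image`.
#' @export
masked_image <- function(pixels, mask, spacing = c(1, 1),
                         subject_id = "subject", scanner_id = "scanner") {
  pixels <- as.matrix(pixels)
  mask <- as.matrix(mask)
  if (!all(dim(pixels) == dim(mask))) {
    stop_drcheck("`pixels` and `mask` must have identical dimensions.",
                 "drcheck_invalid_input")
  }
  if (is.logical(mask)) mask <- mask * 1
  if (!all(mask %in% c(0, 1))) {
    stop_drcheck("`mask` must be strictly binary.", "drcheck_invalid_input")
  }
  # canonical plain double matrices (strip nifti/array subclasses)
  pixels <- matrix(as.double(pixels), nrow(pixels), ncol(pixels))
  mask <- matrix(as.double(mask), nrow(mask), ncol(mask))
  structure(list(pixels = pixels, mask = mask, spacing = as.numeric(spacing),
                 subject_id = as.character(subject_id),
                 scanner_id = as.character(scanner_id)),
            class = "masked_image")
}

#' @export
print.masked_image <- function(x, ...) {
  cat(sprintf("masked_image %dx%d (%.1fx%.1f mm), %s / %s, %d foreground px\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              x$subject_id, x$scanner_id, sum(x$mask)))
  invisible(x)
}

#' Normalize a masked image to the unit interval
#'
#' Rescales the foreground intensities to `[0, 1]` by min-max over foreground
#' pixels only, and sets the background to 0. MRI intensities are relative
#' rather than absolute, so scaling is per scan; background values never
#' influence the range. The operation is idempotent.
#'
#' @param img A [masked_image()].
#' @return The normalized [masked_image()].
#' @export
normalize_image <- function(img) {
  stopifnot(inherits(img, "masked_image"))
  fg <- img$mask == 1
  if (!any(fg)) {
    stop_drcheck("Mask has no foreground pixels.", "drcheck_invalid_input")
  }
  r <- range(img$pixels[fg])
  out <- img
  if (r[1] == r[2]) {
    warn("Constant foreground intensity; all foreground mapped to 0.")
    out$pixels[fg] <- 0
  } else {
    out$pixels[fg] <- (img$pixels[fg] - r[1]) / (r[2] - r[1])
  }
  out$pixels[!fg] <- 0
  out
}

# Linear indices of valid patch centers: foreground middle pixel, patch fully
# inside the image (no padding; border patches are excluded).
valid_patch_centers <- function(img, k) {
  h <- (k - 1L) %/% 2L
  nr <- nrow(img$pixels)
  nc <- ncol(img$pixels)
  ok <- img$mask == 1
  ok[c(seq_len(h), nr - seq_len(h) + 1L), ] <- FALSE
  ok[, c(seq_len(h), nc - seq_len(h) + 1L)] <- FALSE
  which(ok)
}

check_patch_size <- function(img, k) {
  if (k %% 2L != 1L || k < 1L) {
    stop_drcheck("Patch size `k` must be odd (a middle pixel must exist).",
                 "drcheck_invalid_input")
  }
  if (k > min(dim(img$pixels))) {
    stop_drcheck("Patch size `k` exceeds the image dimensions.",
                 "drcheck_invalid_input")
  }
}

# Extract k x k patches centered at the given linear indices, flattened in
# row-major (C) order so unflatten_patch() round-trips.
extract_at_centers <- function(img, k, centers) {
  h <- (k - 1L) %/% 2L
  nr <- nrow(img$pixels)
  rows <- ((centers - 1L) %% nr) + 1L
  cols <- ((centers - 1L) %/% nr) + 1L
  # row-major flattening: iterate dr fastest within each row of offsets
  off <- as.matrix(expand.grid(dc = -h:h, dr = -h:h))[, c("dr", "dc")]
  lin_off <- off[, "dr"] + off[, "dc"] * nr
  feats <- matrix(img$pixels[outer(centers, lin_off, `+`)],
                  nrow = length(centers))
  tibble::tibble(center_row = rows, center_col = cols,
                 subject_id = img$subject_id, scanner_id = img$scanner_id,
                 features = feats)
}

#' Decompose a masked image into patches
#'
#' Extracts every k x k patch (stride 1) whose middle pixel is foreground and
#' which lies fully inside the image. Patches whose center pixel is
#' background are filtered out: the background carries no information about
#' scan separability.
#'
#' @param img A [masked_image()].
#' @param k Odd patch side length (default 15).
#' @return A tibble of class `patch_set` with `center_row`, `center_col`,
#'   `subject_id`, `scanner_id` and a `features` matrix column of row-major
#'   flattened intensities. Zero valid centers yield an empty patch set, not
#'   an error.
#' @export
extract_patches <- function(img, k = 15) {
  stopifnot(inherits(img, "masked_image"))
  check_patch_size(img, k)
  centers <- valid_patch_centers(img, k)
  out <- if (length(centers) == 0L) {
    tibble::tibble(center_row = integer(), center_col = integer(),
                   subject_id = character(), scanner_id = character(),
                   features = matrix(numeric(), 0, k * k))
  } else {
    extract_at_centers(img, k, centers)
  }
  attr(out, "patch_size") <- k
  class(out) <- c("patch_set", class(out))
  out
}

#' Sample patches uniformly without replacement
#'
#' @param ps A `patch_set`.
#' @param n Number of patches to draw (>= 1). If `n` exceeds the number
#'   available, all patches are returned with a warning.
#' @param seed Integer seed; sampling is deterministic given it.
#' @return A `patch_set` of at most `n` rows.
#' @export
sample_patches <- function(ps, n, seed = 1) {
  stopifnot(inherits(ps, "patch_set"))
  if (nrow(ps) == 0L) {
    stop_drcheck("Cannot sample from an empty patch set.",
                 "drcheck_invalid_input")
  }
  if (!is.numeric(n) || n < 1) {
    stop_drcheck("`n` must be at least 1.", "drcheck_invalid_input")
  }
  if (n > nrow(ps)) {
    warn(sprintf("Requested %d patches but only %d available; returning all.",
                 n, nrow(ps)))
    n <- nrow(ps)
  }
  idx <- with_seed(seed, sample(nrow(ps), n))
  out <- ps[idx, , drop = FALSE]
  class(out) <- c("patch_set", setdiff(class(out), "patch_set"))
  attr(out, "patch_size") <- attr(ps, "patch_size")
  out
}

#' Sample patch features directly from an image
#'
#' Equivalent to `sample_patches(extract_patches(img, k), n, seed)` but only
#' materializes the sampled patches, which matters for full-resolution scans.
#'
#' @inheritParams extract_patches
#' @inheritParams sample_patches
#' @return A `patch_set` tibble.
#' @export
sample_patch_features <- function(img, k = 15, n = 500, seed = 1) {
  stopifnot(inherits(img, "masked_image"))
  check_patch_size(img, k)
  centers <- valid_patch_centers(img, k)
  if (length(centers) == 0L) {
    stop_drcheck("Image has no valid patch centers.", "drcheck_invalid_input")
  }
  if (n > length(centers)) {
    warn(sprintf("Requested %d patches but only %d available; returning all.",
                 n, length(centers)))
    n <- length(centers)
  }
  pick <- with_seed(seed, sample(length(centers), n))
  out <- extract_at_centers(img, k, centers[pick])
  attr(out, "patch_size") <- k
  class(out) <- c("patch_set", class(out))
  out
}

#' Reshape a flattened patch back to a k x k matrix
#'
#' Inverts the row-major flattening used by [extract_patches()].
#'
#' @param v Numeric vector of length `k^2`.
#' @param k Patch side length.
#' @return A `k x k` matrix.
#' @export
unflatten_patch <- function(v, k = sqrt(length(v))) {
  k <- as.integer(k)
  stopifnot(length(v) == k * k)
  matrix(v, k, k, byrow = TRUE)
}
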