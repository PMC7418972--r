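# Image and manifest plumbing: PNG and NIfTI readers/writers, manifest CSV,
# YAML run configs.

#' Write a masked image and its mask to disk
#'
#' PNG files store intensities rescaled to `[0, 1]` (8-bit); NIfTI files
#' (`.nii`/`.nii.gz`) store the raw values. The mask is written as a sidecar
#' file with suffix `_mask`.
#'
#' @param img A [masked_image()].
#' @param path Output path ending in `.png`, `.nii` or `.nii.gz`.
#' @return Invisibly, a character vector `c(image = path, mask = mask_path)`.
#' @export
write_scan <- function(img, path) {
  stopifnot(inherits(img, "masked_image"))
  mask_path <- mask_path_for(path)
  if (grepl("\\.png$", path)) {
    px <- img$pixels
    r <- range(px)
    if (r[2] > r[1]) px <- (px - r[1]) / (r[2] - r[1])
    png::writePNG(px, path)
    png::writePNG(img$mask + 0, mask_path)
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(RNifti::asNifti(img$pixels,
                                       pixdim = c(img$spacing, 1)), path)
    RNifti::writeNifti(RNifti::asNifti(img$mask,
                                       pixdim = c(img$spacing, 1)), mask_path)
  } else {
    stop_drcheck(sprintf("Unsupported image format: %s", path),
                 "drcheck_io_error")
  }
  invisible(c(image = path, mask = mask_path))
}

mask_path_for <- function(path) {
  sub("(\\.png|\\.nii(\\.gz)?)$", "_mask\\1", path)
}

#' Read a masked image written by [write_scan()]
#'
#' @param path Image path; the mask is looked up as the `_mask` sidecar
#'   unless `mask_path` is given.
#' @param mask_path Optional explicit mask path.
#' @param subject_id,scanner_id Identifiers to attach.
#' @return A [masked_image()].
#' @export
read_scan <- function(path, mask_path = mask_path_for(path),
                      subject_id = "subject", scanner_id = "scanner") {
  if (!file.exists(path)) {
    stop_drcheck(sprintf("Image file not found: %s", path),
                 "drcheck_io_error")
  }
  if (!file.exists(mask_path)) {
    stop_drcheck(sprintf("Mask file not found: %s", mask_path),
                 "drcheck_io_error")
  }
  load_one <- function(p) {
    if (grepl("\\.png$", p)) {
      m <- png::readPNG(p)
      if (length(dim(m)) == 3L) m <- m[, , 1]
      m
    } else if (grepl("\\.nii(\\.gz)?$", p)) {
      m <- as.array(RNifti::readNifti(p))
      if (length(dim(m)) > 2L) m <- m[, , 1]
      m
    } else {
      stop_drcheck(sprintf("Unsupported image format: %s", p),
                   "drcheck_io_error")
    }
  }
  px <- load_one(path)
  mk <- round(load_one(mask_path))
  masked_image(px, mk, subject_id = subject_id, scanner_id = scanner_id)
}

write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop_drcheck(sprintf("Manifest not found: %s", path), "drcheck_io_error")
  }
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

# Load every scan of one scanner from a manifest, with geometry validation.
load_manifest_scans <- function(manifest, scanner, dir = ".") {
  rows <- manifest[manifest$scanner_id == scanner, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop_drcheck(sprintf("Manifest has no scans for scanner '%s'.", scanner),
                 "drcheck_config_error")
  }
  scans <- purrr::pmap(rows, function(file, mask_file, subject_id,
                                      scanner_id, ...) {
    read_scan(file.path(dir, file), file.path(dir, mask_file),
              subject_id = subject_id, scanner_id = scanner_id)
  })
  dims <- purrr::map(scans, ~ dim(.x$pixels))
  if (length(unique(purrr::map_chr(dims, paste, collapse = "x"))) > 1L) {
    stop_drcheck("Scans in the manifest have mismatched geometries.",
                 "drcheck_config_error")
  }
  scans
}

#' Read a YAML run configuration
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_drcheck(sprintf("Config file not found: %s", path),
                 "drcheck_config_error")
  }
  yaml::read_yaml(path)
}

provenance_block <- function(config, seed) {
  list(package = "drcheck",
       version = as.character(utils::packageVersion("drcheck")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       seed = seed,
       config_hash = config_fingerprint(config))
}
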