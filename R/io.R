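#' Read and write label volumes as multi-page TIFF
#'
#' Labels are stored as 16-bit multi-page TIFF (one page per z-slice) with
#' a JSON sidecar recording the voxel size.
#'
#' @param vol A [label_volume()].
#' @param path TIFF file path; the sidecar is `<path>.json`.
#' @return `read_labels()` returns a [label_volume()]; `write_labels()`
#'   returns `path` invisibly.
#' @export
write_labels <- function(vol, path) {
  mx <- max(vol$voxels)
  if (mx > 65535) rlang::abort("Labels exceed 16-bit TIFF range.")
  pages <- lapply(seq_len(dim(vol$voxels)[3]),
                  function(k) vol$voxels[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(list(voxel_size_um = vol$voxel_size),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_labels
#' @param voxel_size Voxel size override (um); by default read from the
#'   sidecar.
#' @export
read_labels <- function(path, voxel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) {
    arr[, , k] <- as.integer(round(pages[[k]] * 65535))
  }
  if (is.null(voxel_size)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      rlang::abort("No voxel size given and no JSON sidecar found.")
    }
    voxel_size <- jsonlite::read_json(sidecar)$voxel_size_um
  }
  label_volume(arr, voxel_size)
}

#' Read and write axis annotations as JSON
#'
#' @param annotation List with `interface_points`, `tip_point`,
#'   `edge_points` (see [determine_axis()]).
#' @param path JSON file path.
#' @return `read_annotations()` returns the annotation list;
#'   `write_annotations()` returns `path` invisibly.
#' @export
write_annotations <- function(annotation, path) {
  jsonlite::write_json(
    list(interface_points = unname(as.matrix(annotation$interface_points)),
         tip_point = as.numeric(annotation$tip_point),
         edge_points = unname(as.matrix(annotation$edge_points))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(interface_points = rbind(rec$interface_points),
       tip_point = as.numeric(rec$tip_point),
       edge_points = rbind(rec$edge_points))
}
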