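# File round-tripping for 2-D maps: NIfTI-1 (via RNifti, float64) and CSV.
# Every write drops a JSON sidecar (<path>.json) carrying the exact grid
# geometry and any unit metadata, and reads prefer the sidecar, so physical
# pixel sizes survive round trips bit-exactly.

#' Write a 2-D field to NIfTI-1 or CSV
#'
#' @param field A package field object (e.g. [conductivity_image()]) or a
#'   plain numeric matrix.
#' @param path Output path; format chosen by extension (`.nii`/`.nii.gz` for
#'   NIfTI-1, `.csv` for comma-separated values).
#' @param grid Required when `field` is a bare matrix.
#' @param meta Named list of extra metadata stored in the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_image <- function(field, path, grid = NULL, meta = list()) {
  if (inherits(field, "mreit_field")) {
    values <- field$values
    grid <- field$grid
    meta <- c(meta, list(class = class(field)[1]))
    if (!is.null(field$noise_std)) meta$noise_std <- field$noise_std
    if (!is.null(field$tc_s) && !is.na(field$tc_s)) meta$tc_s <- field$tc_s
  } else {
    values <- as.matrix(field)
    if (is.null(grid)) stop("grid is required for bare matrices",
                            call. = FALSE)
  }
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::asNifti(structure(values,
                                     pixdim = rep(grid$pixel_size * 1e3, 2)),
                           datatype = "double")
    RNifti::writeNifti(img, path)
  } else if (ext == "csv") {
    utils::write.table(values, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    stop(sprintf("unsupported image format '.%s' (use .nii or .csv)", ext),
         call. = FALSE)
  }
  sidecar <- list(n_rows = grid$n_rows, n_cols = grid$n_cols,
                  pixel_size_m = grid$pixel_size)
  sidecar <- c(sidecar, meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a 2-D field written by [write_image()]
#'
#' @param path `.nii`/`.nii.gz` or `.csv` file. A `<path>.json` sidecar, when
#'   present, supplies the exact pixel size and metadata; otherwise the NIfTI
#'   header's pixdim (mm) is used and CSV files get `pixel_size = NA`.
#' @return List with `values` (matrix), `grid` (an [mreit_grid()] or `NULL`
#'   if the spacing is unknown) and `meta`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::readNifti(path)
    values <- matrix(as.numeric(img), dim(img)[1], dim(img)[2])
    pixel_size <- RNifti::pixdim(img)[1] * 1e-3
  } else if (ext == "csv") {
    nf <- utils::count.fields(path, sep = ",")
    if (length(unique(nf)) != 1L) {
      stop(sprintf("malformed CSV '%s': rows have %s fields", path,
                   paste(unique(nf), collapse = "/")), call. = FALSE)
    }
    values <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
    dimnames(values) <- NULL
    if (!is.numeric(values)) {
      stop(sprintf("malformed CSV '%s': non-numeric entries", path),
           call. = FALSE)
    }
    pixel_size <- NA_real_
  } else {
    stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
  }
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$pixel_size_m)) pixel_size <- meta$pixel_size_m
    if (!is.null(meta$n_rows) &&
        (meta$n_rows != nrow(values) || meta$n_cols != ncol(values))) {
      stop(sprintf("sidecar of '%s' disagrees with the data dimensions",
                   path), call. = FALSE)
    }
  }
  grid <- if (is.finite(pixel_size)) {
    mreit_grid(nrow(values), ncol(values), pixel_size = pixel_size)
  }
  list(values = values, grid = grid, meta = meta)
}
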