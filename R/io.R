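#' NIfTI stack I/O
#'
#' Thin wrappers around RNifti for the package's image conventions: dynamic
#' series and masks are stored one slice per file as (x, y, frame) volumes;
#' masks are 0/1. `read_mask_nifti()` returns a logical matrix (first frame
#' if the file is 3-D).
#'
#' @param stack numeric array (2-D or 3-D).
#' @param path output/input file (`.nii` or `.nii.gz`).
#' @param pixel_spacing in-plane pixel size, mm, written into the header.
#' @return `read_stack_nifti()`: numeric array; `read_mask_nifti()`: logical
#'   matrix.
#' @export
write_stack_nifti <- function(stack, path, pixel_spacing = c(1, 1)) {
  img <- RNifti::asNifti(stack,
                         pixdim = c(rep_len(pixel_spacing, 2), 1)[seq_len(
                           max(2L, length(dim(stack))))])
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_stack_nifti
#' @export
read_stack_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path, call. = FALSE)
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' @rdname write_stack_nifti
#' @export
read_mask_nifti <- function(path) {
  arr <- read_stack_nifti(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  arr > 0.5
}

#' Write and read numeric result tables
#'
#' CSV writers/readers for the package's result tables. All numeric columns
#' are written with 12 significant digits so a write/read round trip
#' preserves values to better than 1e-9 relative error; output is fully
#' deterministic (no locale- or platform-dependent formatting).
#'
#' @param df a data frame.
#' @param path CSV path.
#' @return `read_results()`: a data frame with numeric columns restored.
#' @export
write_results <- function(df, path) {
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), "NA", sprintf("%.12g", x))
  })
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path,
                               call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE)
}
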