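#' Construct a feature table
#'
#' A feature table is the common currency between all stages of the
#' pipeline: a numeric samples-by-features matrix with unique column
#' names, an integer-coded class label per row, and a modality tag
#' (`"morph"` or `"spectral"`) per column.
#'
#' @param x numeric matrix (samples x features) with column names.
#' @param y class labels; coerced to a factor. Integer-coded labels
#'   `0..K-1` are the convention used throughout.
#' @param modality character vector of per-feature modality tags,
#'   recycled to `ncol(x)`.
#' @param sample_id optional sample identifiers (default: rownames or
#'   `s1..sn`).
#' @return An object of class `feature_table`: a list with elements
#'   `x`, `y`, `modality`, `sample_id`.
#' @examples
#' ft <- feature_table(matrix(rnorm(20), 10, 2,
#'                            dimnames = list(NULL, c("a", "b"))),
#'                     rep(0:1, each = 5))
#' ft
#' @export
feature_table <- function(x, y, modality = "morph", sample_id = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x)))
    stop("feature names must be unique")
  if (!is.factor(y)) y <- factor(y)
  if (length(y) != nrow(x))
    stop("length(y) must equal nrow(x)")
  modality <- rep_len(as.character(modality), ncol(x))
  if (is.null(sample_id)) {
    sample_id <- rownames(x)
    if (is.null(sample_id)) sample_id <- paste0("s", seq_len(nrow(x)))
  }
  structure(list(x = x, y = y, modality = modality,
                 sample_id = as.character(sample_id)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s: %d", names(table(x$modality)),
                            as.integer(table(x$modality))),
                    collapse = ", ")))
  cat(sprintf("  classes: %s\n",
              paste(levels(x$y), collapse = " ")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$x)

ft_subset_rows <- function(ft, idx) {
  feature_table(ft$x[idx, , drop = FALSE], ft$y[idx],
                ft$modality, ft$sample_id[idx])
}

#' Construct a spectral set
#'
#' Reflectance spectra on a shared, strictly increasing wavelength grid.
#'
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param reflectance numeric matrix, samples x bands.
#' @param sample_id optional sample identifiers.
#' @return An object of class `spectral_set`.
#' @export
spectral_set <- function(wavelengths, reflectance, sample_id = NULL) {
  reflectance <- as.matrix(reflectance)
  if (ncol(reflectance) != length(wavelengths))
    stop("ncol(reflectance) must equal length(wavelengths)")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (is.null(sample_id)) sample_id <- paste0("s", seq_len(nrow(reflectance)))
  colnames(reflectance) <- as.character(wavelengths)
  structure(list(wavelengths = as.numeric(wavelengths),
                 reflectance = reflectance,
                 sample_id = as.character(sample_id)),
            class = "spectral_set")
}

#' @export
print.spectral_set <- function(x, ...) {
  cat(sprintf("<spectral_set> %d spectra, %d bands (%g-%g nm)\n",
              nrow(x$reflectance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Convert a spectral set to a feature table
#'
#' @param s a [spectral_set()].
#' @param y class labels, one per spectrum.
#' @return A `feature_table` with modality `"spectral"`; column names
#'   are the wavelengths in nm.
#' @export
spectra_to_features <- function(s, y) {
  feature_table(s$reflectance, y, modality = "spectral",
                sample_id = s$sample_id)
}
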