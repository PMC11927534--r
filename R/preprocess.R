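#' Savitzky-Golay smoothing of spectra
#'
#' Per-sample polynomial convolution smoothing along the wavelength
#' axis. Defaults (window 11, order 2) follow standard NIR practice:
#' wide enough to suppress band-to-band noise, low enough order to
#' preserve the peak/valley structure.
#'
#' @param s a [spectral_set()].
#' @param window odd filter window length (bands).
#' @param polyorder polynomial order, `< window`.
#' @return A `spectral_set` on the same wavelength grid.
#' @export
sg_smooth <- function(s, window = 11, polyorder = 2) {
  stopifnot(inherits(s, "spectral_set"))
  if (window %% 2 == 0) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  if (window > length(s$wavelengths)) stop("window exceeds band count")
  sm <- t(apply(s$reflectance, 1, signal::sgolayfilt,
                p = polyorder, n = window))
  if (anyNA(sm)) stop("smoothing produced NA values")
  spectral_set(s$wavelengths, sm, s$sample_id)
}

#' Min-max normalization with ranges learned on a fit subset
#'
#' Each feature is mapped by `(x - min) / (max - min)` with the range
#' learned on `fit_rows` only (training rows), so held-out samples may
#' legitimately fall outside `[0, 1]`. Constant features map to 0.
#'
#' @param ft a `feature_table`.
#' @param ranges optional ranges (as returned in the `"ranges"`
#'   attribute of a previous call) to apply instead of fitting.
#' @param fit_rows rows used to learn the ranges (default: all).
#' @return The normalized `feature_table` with a `"ranges"` attribute
#'   (2 x features matrix, rows `min`/`max`).
#' @export
minmax_normalize <- function(ft, ranges = NULL,
                             fit_rows = seq_len(nrow(ft$x))) {
  stopifnot(inherits(ft, "feature_table"))
  if (is.null(ranges)) {
    if (length(fit_rows) == 0) stop("fit_rows must be non-empty")
    xf <- ft$x[fit_rows, , drop = FALSE]
    ranges <- rbind(min = apply(xf, 2, min), max = apply(xf, 2, max))
  }
  span <- ranges["max", ] - ranges["min", ]
  const <- span <= 0
  span[const] <- 1
  xn <- sweep(sweep(ft$x, 2, ranges["min", ], `-`), 2, span, `/`)
  xn[, const] <- 0
  n_out <- sum(xn < 0 | xn > 1)
  if (n_out > 0)
    message(n_out, " value(s) outside [0,1] after applying fitted ranges")
  out <- feature_table(xn, ft$y, ft$modality, ft$sample_id)
  attr(out, "ranges") <- ranges
  out
}

#' Feature-level fusion of two modalities
#'
#' Column-wise concatenation (morphological block first), preserving
#' modality tags. Sample identities and labels must agree.
#'
#' @param morph,spec `feature_table`s with identical sample ordering.
#' @return The fused `feature_table`.
#' @export
fuse_features <- function(morph, spec) {
  stopifnot(inherits(morph, "feature_table"))
  if (is.null(spec) || ncol(spec$x) == 0) return(morph)
  stopifnot(inherits(spec, "feature_table"))
  if (!identical(as.character(morph$y), as.character(spec$y)) ||
      !identical(morph$sample_id, spec$sample_id))
    stop("sample/label alignment mismatch between modalities")
  feature_table(cbind(morph$x, spec$x), morph$y,
                c(morph$modality, spec$modality), morph$sample_id)
}

#' Stratified train/test split
#'
#' Rows are sampled within each class so that class proportions are
#' preserved exactly up to rounding; `floor(train_frac * n_k)` rows of
#' class `k` go to the training set.
#'
#' @param ft a `feature_table`.
#' @param train_frac training proportion in (0, 1) (default 0.7).
#' @param seed integer seed for the row sampling.
#' @return A list with `train` and `test` feature tables.
#' @export
split_stratified <- function(ft, train_frac = 0.7, seed = 1) {
  stopifnot(inherits(ft, "feature_table"))
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must be in (0, 1)")
  set.seed(seed)
  tr <- integer(0)
  for (k in levels(ft$y)) {
    idx <- which(ft$y == k)
    if (length(idx) < 2) stop("class ", k, " has fewer than 2 samples")
    n_tr <- floor(train_frac * length(idx))
    tr <- c(tr, sample(idx, n_tr))
  }
  tr <- sort(tr)
  list(train = ft_subset_rows(ft, tr),
       test = ft_subset_rows(ft, setdiff(seq_len(nrow(ft$x)), tr)))
}

# Stratified fold assignment: returns an integer fold id per row.
stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (k in levels(y)) {
    idx <- sample(which(y == k))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}
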