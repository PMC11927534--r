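#' Configuration for the synthetic multimodal seed-data generator
#'
#' The generator emulates the statistical structure of a multimodal
#' seed-variety study: smooth NIR reflectance curves (350-2500 nm at
#' 1 nm) sharing a common peak/valley morphology with class-dependent
#' offsets and peak amplitudes, and a 52-column morphological block
#' with class-dependent means on an informative subset and deliberately
#' heterogeneous feature scales.
#'
#' @param n_classes number of varieties (default 11).
#' @param n_per_class spectra/kernels per variety (default 150).
#' @param wavelength_start,wavelength_end,wavelength_step wavelength
#'   grid in nm (defaults 350, 2500, 1; 2151 bands).
#' @param peak_centers,valley_centers nm positions of the shared
#'   reflectance peaks and valleys.
#' @param class_shift_sd sd (reflectance units) of the class-level
#'   offset/slope effects; also scales the class-specific peak
#'   amplitude variation.
#' @param noise_sd sd of i.i.d. per-band measurement noise.
#' @param n_morph number of morphological features (default 52).
#' @param n_informative how many of the named morphological features
#'   carry class signal.
#' @param morph_effect_size standardized between-class mean separation
#'   of informative morphological features.
#' @param seed integer seed; all generator randomness derives from it
#'   by fixed offsets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_classes = 11, n_per_class = 150,
                       wavelength_start = 350, wavelength_end = 2500,
                       wavelength_step = 1,
                       peak_centers = c(863, 1105, 1295, 1680, 2015),
                       valley_centers = c(980, 1175, 1450, 1780, 1915),
                       class_shift_sd = 0.002, noise_sd = 0.01,
                       n_morph = 52, n_informative = 10,
                       morph_effect_size = 0.45, seed = 1) {
  if (n_classes < 1 || n_per_class < 1 || wavelength_step <= 0)
    stop("counts and wavelength step must be positive")
  if (wavelength_end <= wavelength_start)
    stop("wavelength_end must exceed wavelength_start")
  nm <- .morph_names(n_morph, n_informative)  # validates n_morph
  cfg <- list(n_classes = as.integer(n_classes),
              n_per_class = as.integer(n_per_class),
              wavelength_start = wavelength_start,
              wavelength_end = wavelength_end,
              wavelength_step = wavelength_step,
              peak_centers = peak_centers,
              valley_centers = valley_centers,
              class_shift_sd = class_shift_sd, noise_sd = noise_sd,
              n_morph = as.integer(n_morph),
              n_informative = as.integer(n_informative),
              morph_effect_size = morph_effect_size,
              seed = as.integer(seed), morph_names = nm)
  class(cfg) <- "sim_config"
  cfg
}

# Named morphological features mirroring the geometric/texture/color
# families reported for seed kernels; the remainder are filler noise
# columns m00..mNN.
.morph_named <- c("E", "r", "A", "P", "contrast", "hist0", "Hu2",
                  "energy", "a_mean", "g_dev", "a_dev", "s_dev",
                  "h_mean", "g_mean", "b_mean", "l_mean")

.morph_names <- function(n_morph, n_informative) {
  if (n_informative > length(.morph_named))
    stop("n_informative exceeds the number of named features (",
         length(.morph_named), ")")
  if (n_morph < length(.morph_named))
    stop("n_morph must be at least ", length(.morph_named))
  extra <- n_morph - length(.morph_named)
  c(.morph_named,
    if (extra > 0) sprintf("m%02d", seq_len(extra) - 1L))
}

.sim_wavelengths <- function(cfg) {
  seq(cfg$wavelength_start, cfg$wavelength_end, by = cfg$wavelength_step)
}

# Shared smooth base curve: linear baseline plus Gaussian bumps at the
# peak centers minus bumps at the valley centers (width ~40 nm).
.base_curve <- function(wl, peaks, valleys, width = 40) {
  b <- 0.35 + 1.2e-4 * (wl - min(wl))
  for (p in peaks)   b <- b + 0.12 * exp(-(wl - p)^2 / (2 * width^2))
  for (v in valleys) b <- b - 0.10 * exp(-(wl - v)^2 / (2 * width^2))
  b
}

#' Simulate hyperspectral reflectance curves
#'
#' Each spectrum is the shared base curve plus a class-specific
#' low-amplitude offset/slope, class-specific amplitude scaling of the
#' peak bumps (localized class signal for band selection), and i.i.d.
#' per-band noise.
#'
#' @param cfg a [sim_config()].
#' @return A list with `spectra` (a [spectral_set()]) and `y`
#'   (factor labels `0..n_classes-1`).
#' @export
sim_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  wl <- .sim_wavelengths(cfg)
  base <- .base_curve(wl, cfg$peak_centers, cfg$valley_centers)
  K <- cfg$n_classes; n <- cfg$n_per_class
  wid <- 40
  # class-level effects (offset, slope, per-peak amplitude multiplier)
  set.seed(cfg$seed + 2000L)
  off   <- stats::rnorm(K, 0, cfg$class_shift_sd)
  slope <- stats::rnorm(K, 0, cfg$class_shift_sd)
  amp   <- matrix(stats::rnorm(K * length(cfg$peak_centers), 0,
                               3 * cfg$class_shift_sd),
                  K, length(cfg$peak_centers))
  wln <- (wl - mean(wl)) / (max(wl) - min(wl))
  bumps <- sapply(cfg$peak_centers,
                  function(p) exp(-(wl - p)^2 / (2 * wid^2)))
  set.seed(cfg$seed + 3000L)
  refl <- matrix(0, K * n, length(wl))
  y <- integer(K * n)
  for (k in seq_len(K)) {
    cls <- base + off[k] + slope[k] * wln +
      as.numeric(bumps %*% amp[k, ])
    rows <- (k - 1L) * n + seq_len(n)
    noise <- matrix(stats::rnorm(n * length(wl), 0, cfg$noise_sd),
                    n, length(wl))
    refl[rows, ] <- matrix(cls, n, length(wl), byrow = TRUE) + noise
    y[rows] <- k - 1L
  }
  ids <- sprintf("s%04d", seq_len(K * n))
  list(spectra = spectral_set(wl, refl, ids),
       y = factor(y, levels = 0:(K - 1)))
}

#' Simulate the morphological feature block
#'
#' The first `n_informative` named features receive class-dependent
#' means (standardized separation `morph_effect_size`); all columns
#' have deliberately heterogeneous scales so that downstream
#' normalization is exercised.
#'
#' @param cfg a [sim_config()].
#' @return A `feature_table` with modality `"morph"`.
#' @export
sim_morphology <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  K <- cfg$n_classes; n <- cfg$n_per_class; p <- cfg$n_morph
  set.seed(cfg$seed + 1000L)
  scales <- 10^stats::runif(p, -2, 3)          # heterogeneous units
  delta <- matrix(0, K, p)
  ninf <- cfg$n_informative
  delta[, seq_len(ninf)] <- stats::rnorm(K * ninf)
  set.seed(cfg$seed + 4000L)
  x <- matrix(0, K * n, p)
  y <- integer(K * n)
  for (k in seq_len(K)) {
    rows <- (k - 1L) * n + seq_len(n)
    mu <- cfg$morph_effect_size * delta[k, ]
    x[rows, ] <- matrix(stats::rnorm(n * p), n, p) +
      matrix(mu, n, p, byrow = TRUE)
    y[rows] <- k - 1L
  }
  x <- sweep(x, 2, scales, `*`)
  colnames(x) <- cfg$morph_names
  feature_table(x, factor(y, levels = 0:(K - 1)), modality = "morph",
                sample_id = sprintf("s%04d", seq_len(K * n)))
}

#' Simulate a paired multimodal dataset
#'
#' Wraps [sim_spectra()] and [sim_morphology()] with aligned sample
#' identities, optionally writing CSV fixtures.
#'
#' @param cfg a [sim_config()].
#' @param dir optional directory; when given, `morph.csv` and
#'   `spectra.csv` are written there (first column `sample_id`, second
#'   `label`, remaining columns features; spectral headers are
#'   wavelengths in nm).
#' @return A list with `morph` (feature table), `spectra`
#'   (spectral set), `y` (labels) and `cfg`.
#' @export
sim_seed_dataset <- function(cfg, dir = NULL) {
  sp <- sim_spectra(cfg)
  mo <- sim_morphology(cfg)
  if (nrow(mo$x) != nrow(sp$spectra$reflectance))
    stop("internal error: modality sample counts differ")
  stopifnot(identical(mo$sample_id, sp$spectra$sample_id))
  out <- list(morph = mo, spectra = sp$spectra, y = sp$y, cfg = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_csv(mo, file.path(dir, "morph.csv"))
    write_feature_csv(spectra_to_features(sp$spectra, sp$y),
                      file.path(dir, "spectra.csv"))
  }
  out
}

#' Write / read a feature table as CSV
#'
#' Layout: `sample_id`, `label` (integer), then one column per feature.
#'
#' @param ft a `feature_table`.
#' @param path file path.
#' @rdname feature_csv
#' @export
write_feature_csv <- function(ft, path) {
  df <- data.frame(sample_id = ft$sample_id,
                   label = as.integer(as.character(ft$y)),
                   ft$x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param modality modality tag to assign on read.
#' @rdname feature_csv
#' @export
read_feature_csv <- function(path, modality = "morph") {
  df <- utils::read.csv(path, check.names = FALSE)
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  feature_table(x, factor(df$label), modality = modality,
                sample_id = df$sample_id)
}
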