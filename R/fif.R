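# Fluorescence intensity fluctuation (FIF) spectrometry: molecular
# brightness of membrane receptors from photon-counting confocal images.

#' Tile a membrane image into square regions of interest
#'
#' Divides a single-channel photon-count image into non-overlapping
#' `roi_size` x `roi_size` blocks starting from the top-left corner. Partial
#' blocks at the right/bottom border are discarded. If a mask is supplied
#' (nonzero/`TRUE` = membrane), only blocks lying entirely inside the mask
#' are kept.
#'
#' @param image numeric matrix of non-negative photon counts.
#' @param mask optional logical or numeric matrix of the same dimensions;
#'   nonzero marks membrane pixels.
#' @param roi_size side length of the square regions, in pixels.
#' @param image_id identifier carried through to outputs.
#' @return An object of class `roi_grid`: list with `image_id`, `roi_size`,
#'   `rois` (list of `roi_size` x `roi_size` matrices), `mask_applied`.
#' @examples
#' g <- segment_membrane(matrix(5, 45, 45))
#' length(g$rois)  # 9
#' @export
segment_membrane <- function(image, mask = NULL, roi_size = 15L,
                             image_id = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (any(image < 0)) stop("image has negative pixel values", call. = FALSE)
  roi_size <- as.integer(roi_size)
  if (roi_size < 1L) stop("roi_size must be >= 1", call. = FALSE)
  if (nrow(image) < roi_size || ncol(image) < roi_size) {
    stop("image too small: no complete region of interest fits",
         call. = FALSE)
  }
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(image))) {
      stop("mask dimensions differ from image", call. = FALSE)
    }
    mask <- matrix(as.logical(mask != 0), nrow(image), ncol(image))
  }
  nr <- nrow(image) %/% roi_size
  nc <- ncol(image) %/% roi_size
  rois <- list()
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      ri <- ((i - 1L) * roi_size + 1L):(i * roi_size)
      ci <- ((j - 1L) * roi_size + 1L):(j * roi_size)
      if (!is.null(mask) && !all(mask[ri, ci])) next
      rois[[length(rois) + 1L]] <- image[ri, ci]
    }
  }
  structure(list(image_id = image_id, roi_size = roi_size, rois = rois,
                 mask_applied = !is.null(mask)),
            class = "roi_grid")
}

#' Molecular brightness of one region of interest
#'
#' The molecular brightness is the variance-to-mean ratio of the photon
#' counts in the region, minus one: `epsilon = var(I)/mean(I) - 1`. For an
#' ideal photon-counting detector, immobile background gives epsilon ~ 0
#' (Poisson), and for mobile fluorophore-tagged receptors epsilon is
#' proportional to the average oligomer size.
#'
#' @param roi numeric matrix or vector of photon counts.
#' @return epsilon (dimensionless, >= -1).
#' @examples
#' molecular_brightness(matrix(7, 15, 15))  # -1: zero variance
#' @export
molecular_brightness <- function(roi) {
  x <- as.numeric(roi)
  if (length(x) == 0L) stop("empty ROI", call. = FALSE)
  if (any(x < 0)) stop("negative photon counts", call. = FALSE)
  m <- mean(x)
  if (m <= 0) stop("empty ROI: mean intensity is zero", call. = FALSE)
  # population variance, as a moment of the intensity distribution
  v <- mean((x - m)^2)
  v / m - 1
}

#' Brightness sample for one experimental condition
#'
#' Bundles per-ROI brightness values with the number of cells they came
#' from. `n_cells` is metadata (the replication unit for the Z-test), not
#' inferred from the ROI count.
#'
#' @param epsilon_values numeric vector of per-ROI brightness values.
#' @param condition label, e.g. ligand + concentration.
#' @param n_cells number of cells analyzed (>= 1).
#' @return object of class `brightness_sample`.
#' @export
brightness_sample <- function(epsilon_values, condition = "condition",
                              n_cells = 1L) {
  epsilon_values <- as.numeric(epsilon_values)
  if (any(!is.finite(epsilon_values))) {
    stop("non-finite brightness values", call. = FALSE)
  }
  if (any(epsilon_values < -1)) {
    stop("brightness values below -1 are impossible", call. = FALSE)
  }
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L) stop("n_cells must be >= 1", call. = FALSE)
  structure(list(condition = condition, epsilon_values = epsilon_values,
                 n_cells = n_cells),
            class = "brightness_sample")
}

#' Per-ROI brightness values of one image
#'
#' Convenience wrapper: segment, then compute epsilon per region.
#'
#' @inheritParams segment_membrane
#' @return numeric vector of epsilon values (one per kept region).
#' @export
image_brightness <- function(image, mask = NULL, roi_size = 15L) {
  grid <- segment_membrane(image, mask = mask, roi_size = roi_size)
  vapply(grid$rois, molecular_brightness, numeric(1))
}

#' Gaussian fit of the log-brightness distribution
#'
#' Brightness distributions of membrane receptors are close to log-normal,
#' so log10(epsilon) is histogrammed, the counts normalized to a maximum of
#' 1, and a Gaussian fitted by least squares. Non-positive epsilon values
#' cannot be log-transformed and are discarded; the discarded fraction is
#' reported on the returned object.
#'
#' @param sample a [brightness_sample()], or a bare numeric vector of
#'   epsilon values (then `n_cells` must be given).
#' @param bin_width histogram bin width on the log10 scale; `NULL` for
#'   Freedman-Diaconis.
#' @param n_cells used only when `sample` is a bare vector.
#' @return a `gaussian_fit` (see [fit_gaussian_histogram()]) with extra
#'   fields `condition` and `frac_discarded`.
#' @export
fit_log_gaussian <- function(sample, bin_width = NULL, n_cells = NULL) {
  if (inherits(sample, "brightness_sample")) {
    eps <- sample$epsilon_values
    n_cells <- sample$n_cells
    condition <- sample$condition
  } else {
    eps <- as.numeric(sample)
    if (is.null(n_cells)) stop("n_cells required for a bare vector",
                               call. = FALSE)
    condition <- "condition"
  }
  pos <- eps[eps > 0]
  if (length(pos) < 50L) {
    stop("need at least 50 positive brightness values", call. = FALSE)
  }
  fit <- fit_gaussian_histogram(log10(pos), bin_width = bin_width,
                                n_cells = n_cells)
  fit$condition <- condition
  fit$frac_discarded <- 1 - length(pos) / length(eps)
  fit
}

#' Z-statistic comparing two fitted brightness distributions
#'
#' `Z = |m1 - m2| / sqrt(q1^2 + q2^2)` where `m` is the Gaussian mean of
#' each log-brightness distribution and `q` its standard deviation divided
#' by the square root of the number of cells analyzed. Z > 2 is read as the
#' two populations being different.
#'
#' @param fit1,fit2 `gaussian_fit` objects (from [fit_log_gaussian()]).
#' @return list with `z`, `different` (logical, Z > 2), `m1`, `m2`, `q1`,
#'   `q2`.
#' @export
z_statistic <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "gaussian_fit"), inherits(fit2, "gaussian_fit"))
  q1 <- fit1$q
  q2 <- fit2$q
  if (!is.finite(q1) || !is.finite(q2) || (q1 == 0 && q2 == 0)) {
    stop("degenerate comparison: both q are zero or undefined",
         call. = FALSE)
  }
  z <- abs(fit1$m - fit2$m) / sqrt(q1^2 + q2^2)
  list(z = z, different = z > 2, m1 = fit1$m, m2 = fit2$m, q1 = q1, q2 = q2)
}

#' Receptor surface density from mean image intensity
#'
#' Converts the background-subtracted mean photon count per pixel to
#' receptors per square micron using the detector calibration
#' (counts per fluorophore) and the pixel area.
#'
#' @param image numeric matrix of photon counts.
#' @param mask optional membrane mask (nonzero = membrane).
#' @param counts_per_fluorophore calibration, counts per fluorophore (> 0).
#' @param pixel_area_um2 area of one pixel in square microns (> 0).
#' @param background mean background counts per pixel to subtract
#'   (default 0).
#' @return receptors per square micron (>= 0).
#' @examples
#' estimate_density(matrix(50, 30, 30), counts_per_fluorophore = 0.5,
#'                  pixel_area_um2 = 0.1)  # 1000
#' @export
estimate_density <- function(image, mask = NULL, counts_per_fluorophore,
                             pixel_area_um2, background = 0) {
  stop_if_not_scalar_number(counts_per_fluorophore, "counts_per_fluorophore")
  stop_if_not_scalar_number(pixel_area_um2, "pixel_area_um2")
  if (counts_per_fluorophore <= 0) {
    stop("counts_per_fluorophore must be > 0", call. = FALSE)
  }
  if (pixel_area_um2 <= 0) stop("pixel_area_um2 must be > 0", call. = FALSE)
  px <- as.numeric(image)
  if (!is.null(mask)) px <- px[as.logical(mask != 0)]
  dens <- (mean(px) - background) / (counts_per_fluorophore * pixel_area_um2)
  max(dens, 0)
}

#' Read a single-channel grayscale TIFF as a photon-count matrix
#'
#' Integer TIFFs are returned on their native count scale (`as.is`), float
#' TIFFs as stored. Multi-channel images are rejected.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_fif_image <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L) stop("expected a single-channel image",
                                call. = FALSE)
    img <- img[, , 1L]
  }
  storage.mode(img) <- "double"
  img
}

#' Summarize brightness samples as a data frame
#'
#' One row per condition with the Gaussian fit parameters and the
#' comparison error q, matching the layout written by the pipeline stage.
#'
#' @param fits list of `gaussian_fit` objects from [fit_log_gaussian()].
#' @return data.frame with columns condition, a, m, s, se_m, se_s, n_cells,
#'   q, frac_discarded, converged.
#' @export
brightness_fit_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(condition = f$condition %||% NA_character_,
               a = f$a, m = f$m, s = f$s, se_m = f$se_m, se_s = f$se_s,
               n_cells = f$n_cells, q = f$q,
               frac_discarded = f$frac_discarded %||% NA_real_,
               converged = f$converged)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
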