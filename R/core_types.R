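#' Single-channel microscopy field
#'
#' Container for one grayscale field: a pixel matrix plus the plate
#' coordinates that identify it. Intensities are arbitrary fluorescence
#' units (16-bit integer range when read from TIFF, float after
#' processing); `(well_id, site_index, timepoint, channel)` uniquely
#' identifies an image within a dataset.
#'
#' @param pixels numeric matrix of non-negative, finite intensities.
#' @param channel one of `"PRE"`, `"POST"`, `"TRANS"`.
#' @param well_id plate coordinate, e.g. `"B07"`.
#' @param site_index imaging site within the well, integer >= 1.
#' @param timepoint acquisition label, e.g. `"baseline"` or `"72h"`.
#' @param pixel_size_um micrometres per pixel, > 0.
#' @return object of class `field_image`.
#' @export
field_image <- function(pixels, channel = c("PRE", "POST", "TRANS"),
                        well_id = "A01", site_index = 1L,
                        timepoint = "baseline", pixel_size_um = 0.35) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop("pixels must be finite")
  if (any(pixels < 0))
    stop("pixels must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  site_index <- as.integer(site_index)
  if (is.na(site_index) || site_index < 1L)
    stop("site_index must be an integer >= 1")
  structure(
    list(pixels = pixels, channel = channel, well_id = as.character(well_id),
         site_index = site_index, timepoint = as.character(timepoint),
         pixel_size_um = as.numeric(pixel_size_um)),
    class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image> %s site %d %s [%s] %dx%d px @ %.3g um/px\n",
              x$well_id, x$site_index, x$timepoint, x$channel,
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um))
  invisible(x)
}

#' @export
dim.field_image <- function(x) dim(x$pixels)

# Accept either a field_image or a bare matrix in image operations.
as_pixels <- function(x) {
  if (inherits(x, "field_image")) x$pixels
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected a field_image or a numeric matrix")
}

#' Area of a field in square micrometres
#'
#' @param x a `field_image`.
#' @return `width_px * height_px * pixel_size_um^2`.
#' @export
field_area_um2 <- function(x) {
  stopifnot(inherits(x, "field_image"))
  prod(dim(x$pixels)) * x$pixel_size_um^2
}

#' Puncta-detection pipeline parameters
#'
#' Bundles every tunable of the detection chain. Defaults follow the
#' published screening protocol: background flattening at vendor pixel
#' size 5, no-neighbors deconvolution with filter size 10, scaling factor
#' 0.97 and noise suppression on, top-hat with a 50 px^2 area budget,
#' contrast enhancement saturating 0.3% of pixels, maximum-entropy
#' auto-thresholding, and particles of 2 to 50 px (inclusive) counted.
#'
#' The vendor "Flatten Background, pixel size = 5" operation is realised
#' as subtraction of a morphological opening whose disc radius is
#' `flatten_size_px * flatten_scale_px` (default 5 x 3 = 15 px, about five
#' punctum radii), which removes soma blobs and illumination structure
#' while passing <= 50 px^2 puncta.
#'
#' @param flatten_size_px background-flattening size parameter (>= 1).
#' @param flatten_scale_px punctum-scale multiplier converting
#'   `flatten_size_px` into the opening disc radius.
#' @param deconv_filter_size_px no-neighbors blur size; the haze estimate
#'   is a Gaussian blur of sigma `deconv_filter_size_px / 2`.
#' @param deconv_scaling fraction of the haze estimate subtracted, in
#'   (0, 1].
#' @param deconv_suppress_noise logical; pre-smooth with a sigma-1
#'   Gaussian before haze subtraction.
#' @param tophat_area_px2 area budget of the top-hat structuring element;
#'   the largest disc with at most this many pixels is used.
#' @param saturated_fraction percentage of pixels saturated by contrast
#'   enhancement (split between the two tails), in (0, 100).
#' @param threshold_method `"MAXENTROPY"` or `"OTSU"`.
#' @param min_size_px,max_size_px inclusive particle-size bounds in px.
#' @param connectivity pixel connectivity for component labeling, 4 or 8.
#' @param noise_floor_mads sparse-image robustness floor: the
#'   auto-threshold is never taken below this many median absolute
#'   deviations of the processed image, preventing histogram thresholds
#'   from collapsing into the noise on fields with few or no puncta.
#'   Set to 0 to disable.
#' @return object of class `detection_params`.
#' @export
detection_params <- function(flatten_size_px = 5L, flatten_scale_px = 3L,
                             deconv_filter_size_px = 10L,
                             deconv_scaling = 0.97,
                             deconv_suppress_noise = TRUE,
                             tophat_area_px2 = 50L,
                             saturated_fraction = 0.3,
                             threshold_method = c("MAXENTROPY", "OTSU"),
                             min_size_px = 2L, max_size_px = 50L,
                             connectivity = 8L, noise_floor_mads = 6) {
  threshold_method <- match.arg(threshold_method)
  p <- list(flatten_size_px = as.integer(flatten_size_px),
            flatten_scale_px = as.integer(flatten_scale_px),
            deconv_filter_size_px = as.integer(deconv_filter_size_px),
            deconv_scaling = as.numeric(deconv_scaling),
            deconv_suppress_noise = isTRUE(deconv_suppress_noise),
            tophat_area_px2 = as.integer(tophat_area_px2),
            saturated_fraction = as.numeric(saturated_fraction),
            threshold_method = threshold_method,
            min_size_px = as.integer(min_size_px),
            max_size_px = as.integer(max_size_px),
            connectivity = as.integer(connectivity),
            noise_floor_mads = as.numeric(noise_floor_mads))
  if (p$min_size_px <= 0L || p$min_size_px > p$max_size_px)
    stop("require 0 < min_size_px <= max_size_px")
  if (p$flatten_size_px < 1L || p$deconv_filter_size_px < 1L ||
      p$tophat_area_px2 < 1L)
    stop("flatten_size_px, deconv_filter_size_px, tophat_area_px2 must be >= 1")
  if (p$saturated_fraction <= 0 || p$saturated_fraction >= 100)
    stop("saturated_fraction must be in (0, 100)")
  if (p$deconv_scaling <= 0 || p$deconv_scaling > 1)
    stop("deconv_scaling must be in (0, 1]")
  if (!p$connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8")
  class(p) <- "detection_params"
  p
}

#' @export
print.detection_params <- function(x, ...) {
  cat("<detection_params>\n")
  for (nm in names(unclass(x))) cat(sprintf("  %-22s %s\n", nm, x[[nm]]))
  invisible(x)
}

#' Detected puncta for one field/channel
#'
#' @param label_mask integer matrix; 0 = background, k = punctum k. Labels
#'   are consecutive 1..n in raster (row-major) order of first occurrence.
#' @param puncta data frame with columns `id`, `centroid_row`,
#'   `centroid_col` (0-based pixel coordinates) and `area_px`.
#' @param source optional list identifying the originating field
#'   (well/site/timepoint/channel).
#' @param provenance optional list recording the threshold and parameters
#'   that produced the set.
#' @return object of class `puncta_set` with count `n`.
#' @export
puncta_set <- function(label_mask, puncta, source = NULL, provenance = NULL) {
  if (!is.matrix(label_mask)) stop("label_mask must be a matrix")
  labs <- sort(unique(as.integer(label_mask[label_mask > 0])))
  if (nrow(puncta) != length(labs) ||
      (nrow(puncta) && !setequal(puncta$id, labs)))
    stop("puncta records must match the nonzero labels of label_mask")
  structure(list(label_mask = label_mask, puncta = puncta,
                 n = nrow(puncta), source = source, provenance = provenance),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> n = %d puncta in %dx%d field\n",
              x$n, nrow(x$label_mask), ncol(x$label_mask)))
  invisible(x)
}

#' 96-well plate map
#'
#' @param wells data frame with columns `well` (e.g. "B07"), `condition`
#'   (label), `dose` (numeric, `NA` for controls/blanks), `dose_unit`
#'   (character, may be `NA`) and `role` (`"TREATED"`, `"NTC"` or
#'   `"BLANK"`).
#' @param sites_per_well imaging sites per well (default 5).
#' @param timepoints ordered character vector of acquisition labels; the
#'   first is the designated baseline.
#' @return object of class `plate_layout`.
#' @export
plate_layout <- function(wells, sites_per_well = 5L,
                         timepoints = c("baseline", "24h")) {
  req <- c("well", "condition", "role")
  if (!all(req %in% names(wells)))
    stop("wells must have columns well, condition, role")
  if (!"dose" %in% names(wells)) wells$dose <- NA_real_
  if (!"dose_unit" %in% names(wells)) wells$dose_unit <- NA_character_
  if (!all(wells$role %in% c("TREATED", "NTC", "BLANK")))
    stop("role must be TREATED, NTC or BLANK")
  if (anyDuplicated(wells$well)) stop("duplicate well ids in layout")
  if (any(wells$role == "TREATED") && !any(wells$role == "NTC"))
    stop("layout with TREATED wells must contain at least one NTC well")
  if (length(timepoints) < 1L || anyDuplicated(timepoints))
    stop("timepoints must be a non-empty list of distinct labels")
  structure(list(wells = wells[, c("well", "condition", "dose",
                                   "dose_unit", "role")],
                 sites_per_well = as.integer(sites_per_well),
                 timepoints = as.character(timepoints),
                 baseline = as.character(timepoints[[1L]])),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf(
    "<plate_layout> %d wells (%d NTC), %d sites/well, timepoints: %s\n",
    nrow(x$wells), sum(x$wells$role == "NTC"), x$sites_per_well,
    paste(x$timepoints, collapse = " -> ")))
  invisible(x)
}

#' Puncta density per square micrometre
#'
#' Converts a per-image punctum count into a density, the unit in which
#' developmental plateau values are usually quoted (about 0.03/um^2
#' presynaptic, 0.014/um^2 postsynaptic, 0.011/um^2 colocalized in mature
#' hippocampal cultures).
#'
#' @param count per-image punctum count (>= 0).
#' @param image_area_um2 field area in square micrometres (> 0).
#' @return puncta per um^2.
#' @export
puncta_density <- function(count, image_area_um2) {
  if (!is.numeric(image_area_um2) || any(!is.finite(image_area_um2)) ||
      any(image_area_um2 <= 0))
    stop("image_area_um2 must be positive and finite")
  if (any(count < 0)) stop("count must be non-negative")
  count / image_area_um2
}
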