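# The four-stage punctum detection chain: flatten background ->
# no-neighbors deconvolution -> top-hat -> contrast normalization ->
# histogram auto-threshold -> size-filtered component counting. All
# stages operate on plain numeric matrices (or field_images) and are
# scale-equivariant up to the final normalization, so the binary mask is
# invariant to positive rescaling of a float input.

# Morphology and blurs use edge-replicated padding: openings computed
# against a zero (or wrapped) exterior leave a bright frame at the field
# border that the threshold then picks up as spurious particles.
pad_replicate <- function(x, r) {
  H <- nrow(x); W <- ncol(x)
  x[c(rep(1L, r), seq_len(H), rep(H, r)),
    c(rep(1L, r), seq_len(W), rep(W, r)), drop = FALSE]
}

# EBImage grayscale morphology operates on the [0, 1] range (values
# outside are clamped), so the image is rescaled by its maximum around
# the opening. Rescaling commutes with min/max filters exactly.
opening_replicate <- function(x, brush) {
  r <- (nrow(brush) - 1L) %/% 2L
  m <- max(x)
  if (m <= 0) return(x)
  p <- pad_replicate(x, r) / m
  op <- EBImage::opening(p, brush) * m
  if (r == 0L) return(op)
  op[(r + 1L):(r + nrow(x)), (r + 1L):(r + ncol(x)), drop = FALSE]
}

gauss_blur <- function(x, sigma) {
  radius <- 2L * ceiling(3 * sigma) + 1L
  if (radius > min(dim(x)))  # fall back for tiny arrays
    radius <- max(3L, min(dim(x)) - (min(dim(x)) + 1L) %% 2L)
  EBImage::gblur(x, sigma = sigma, radius = radius, boundary = "replicate")
}

# Largest odd disc brush with at most `area` pixels (at least the 1-px
# "disc").
disc_for_area <- function(area) {
  best <- matrix(1, 1, 1)
  size <- 3L
  repeat {
    b <- EBImage::makeBrush(size, shape = "disc")
    if (sum(b) > area) break
    best <- b
    size <- size + 2L
  }
  best
}

restore_field <- function(template, px) {
  if (inherits(template, "field_image")) { template$pixels <- px; template }
  else px
}


#' Flatten the image background
#'
#' Subtracts a smooth background estimate - the morphological opening by
#' a disc of radius `radius_px` - and clamps at zero. Structures wider
#' than the disc in every direction (soma blobs, illumination structure)
#' are treated as background and removed; puncta pass. A spatially
#' constant image maps to zero everywhere.
#'
#' @param image `field_image` or numeric matrix.
#' @param radius_px opening disc radius; the default corresponds to the
#'   protocol's flatten size 5 times a 3 px punctum scale.
#' @return background-subtracted image, same type as the input.
#' @export
flatten_background <- function(image, radius_px = 15L) {
  px <- as_pixels(image)
  if (radius_px < 1L) stop("radius_px must be >= 1")
  side <- 2L * as.integer(radius_px) + 1L
  if (side > min(dim(px)))
    stop("flatten kernel larger than the image")
  bg <- opening_replicate(px, EBImage::makeBrush(side, shape = "disc"))
  restore_field(image, pmax(px - bg, 0))
}

#' No-neighbors deconvolution (haze removal)
#'
#' Single-plane approximation of nearest-neighbor deconvolution: a scaled
#' Gaussian-blurred copy of the plane stands in for the out-of-focus haze
#' and is subtracted, with clamping at zero. High-spatial-frequency
#' structure (puncta) retains greater relative amplitude than smooth
#' structure. With `suppress_noise` the plane is pre-smoothed with a
#' sigma-1 Gaussian.
#'
#' @param image `field_image` or numeric matrix.
#' @param filter_size_px haze blur size; the blur sigma is
#'   `filter_size_px / 2`.
#' @param scaling fraction of the haze estimate subtracted, in `[0, 1]`;
#'   0 leaves the image unchanged.
#' @param suppress_noise logical pre-smoothing switch.
#' @return deconvolved image, same type as input, non-negative.
#' @export
deconvolve_no_neighbors <- function(image, filter_size_px = 10L,
                                    scaling = 0.97,
                                    suppress_noise = TRUE) {
  px <- as_pixels(image)
  if (scaling < 0 || scaling > 1) stop("scaling must be in [0, 1]")
  if (filter_size_px < 1L) stop("filter_size_px must be >= 1")
  k <- nn_kernel(filter_size_px, scaling, suppress_noise)
  out <- if (!is.null(k) && nrow(k) <= min(dim(px))) {
    # single composite convolution (smoothing and haze subtraction fused)
    EBImage::filter2(px, k, boundary = "replicate")
  } else {
    y <- if (suppress_noise) gauss_blur(px, sigma = 1) else px
    if (scaling > 0) y - scaling * gauss_blur(y, sigma = filter_size_px / 2)
    else y
  }
  restore_field(image, pmax(out, 0))
}

# Composite no-neighbors kernel: smooth * (identity - scaling * haze blur),
# cached per parameter set.
.nn_cache <- new.env(parent = emptyenv())
nn_kernel <- function(filter_size_px, scaling, suppress_noise) {
  if (scaling <= 0) return(NULL)
  key <- paste(filter_size_px, scaling, suppress_noise)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  sig <- filter_size_px / 2
  g5 <- EBImage::makeBrush(2L * ceiling(3 * sig) + 1L, "Gaussian", sigma = sig)
  g1 <- if (suppress_noise) EBImage::makeBrush(7L, "Gaussian", sigma = 1)
        else matrix(1, 1, 1)
  n1 <- nrow(g1); n5 <- nrow(g5)
  big <- matrix(0, n5 + n1 - 1L, n5 + n1 - 1L)
  for (i in seq_len(n1)) for (j in seq_len(n1))
    big[i:(i + n5 - 1L), j:(j + n5 - 1L)] <-
      big[i:(i + n5 - 1L), j:(j + n5 - 1L)] + g1[i, j] * g5
  k <- -scaling * big
  ctr <- (n5 - 1L) %/% 2L
  k[(ctr + 1L):(ctr + n1), (ctr + 1L):(ctr + n1)] <-
    k[(ctr + 1L):(ctr + n1), (ctr + 1L):(ctr + n1)] + g1
  .nn_cache[[key]] <- k
  k
}

#' White top-hat filter
#'
#' Image minus its morphological opening by the largest disc containing
#' at most `tophat_area_px2` pixels. Bright structures larger than the
#' disc in every direction are suppressed to about zero; smaller
#' structures (puncta) pass at full contrast.
#'
#' @param image `field_image` or numeric matrix.
#' @param tophat_area_px2 pixel budget of the structuring element.
#' @return filtered image, same type as input.
#' @export
tophat <- function(image, tophat_area_px2 = 50L) {
  px <- as_pixels(image)
  el <- disc_for_area(tophat_area_px2)
  out <- px - opening_replicate(px, el)
  restore_field(image, pmax(out, 0))
}

#' Percentile contrast enhancement with normalization
#'
#' Finds cut intensities such that `saturated_fraction / 2` percent of
#' pixels fall below/above them, then linearly rescales `[low, high]` to
#' `[0, 1]`, clipping outside. Pixel order is preserved among non-clipped
#' pixels. The number of pixels clipped at each end is
#' `ceiling(n * saturated_fraction / 200)`.
#'
#' @param image `field_image` or numeric matrix.
#' @param saturated_fraction percentage of pixels saturated, split
#'   between the two tails.
#' @return rescaled image in `[0, 1]`, same type as input.
#' @export
enhance_contrast <- function(image, saturated_fraction = 0.3) {
  px <- as_pixels(image)
  cuts <- contrast_cuts(px, saturated_fraction)
  out <- (px - cuts[1]) / (cuts[2] - cuts[1])
  restore_field(image, pmin(pmax(out, 0), 1))
}

contrast_cuts <- function(px, saturated_fraction) {
  n <- length(px)
  k <- ceiling(n * saturated_fraction / 200)
  xs <- sort.int(as.numeric(px))
  lo <- xs[min(k + 1L, n)]; hi <- xs[max(n - k, 1L)]
  if (hi <= lo)
    stop("degenerate input: contrast window is empty")
  c(lo, hi)
}

# Shared 256-bin histogram machinery for the auto-thresholds: bins span
# [min, max] of the image (8-bit auto-threshold semantics after
# normalization). Returns the chosen bin T (0-based); the mask is
# bin(x) > T.
hist_bins <- function(px, n_bins = 256L) {
  lo <- min(px); hi <- max(px)
  if (!(hi > lo)) stop("degenerate input: image has a single intensity")
  b <- pmin(floor((px - lo) / (hi - lo) * n_bins), n_bins - 1L)
  list(bin = b, lo = lo, hi = hi, n_bins = n_bins,
       counts = tabulate(as.integer(b) + 1L, nbins = n_bins))
}

threshold_from_bin <- function(hb, T)
  hb$lo + (T + 1) * (hb$hi - hb$lo) / hb$n_bins

#' Maximum-entropy (Kapur) auto-threshold
#'
#' Builds a 256-bin histogram over the image range and returns the bin
#' `T` maximizing the sum of Shannon entropies of the normalized
#' background (bins `<= T`) and foreground (bins `> T`) class
#' histograms. Ties are broken by the lowest `T`. The mask is
#' `bin(image) > T`.
#'
#' @param image `field_image` or numeric matrix with at least two
#'   distinct intensities.
#' @param n_bins histogram resolution (default 256).
#' @return list with `threshold` (intensity at the lower edge of the
#'   first foreground bin), `bin` (0-based `T`), `mask` (logical matrix)
#'   and `method`.
#' @export
threshold_maxentropy <- function(image, n_bins = 256L) {
  px <- as_pixels(image)
  hb <- hist_bins(px, n_bins)
  p <- hb$counts / sum(hb$counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P1 <- cumsum(p); S1 <- cumsum(plogp)
  Ptot <- P1[n_bins]; Stot <- S1[n_bins]
  Ts <- 0:(n_bins - 2L)
  P_bg <- P1[Ts + 1L]; P_fg <- Ptot - P_bg
  valid <- P_bg > 0 & P_fg > 0
  Hb <- log(P_bg) - S1[Ts + 1L] / P_bg
  Hf <- log(P_fg) - (Stot - S1[Ts + 1L]) / P_fg
  crit <- ifelse(valid, Hb + Hf, -Inf)
  T <- Ts[which.max(crit)]        # which.max takes the first (lowest T)
  mask <- matrix(hb$bin > T, nrow(px), ncol(px))
  list(threshold = threshold_from_bin(hb, T), bin = T, mask = mask,
       method = "MAXENTROPY")
}

#' Otsu auto-threshold
#'
#' Same 256-bin histogram contract as [threshold_maxentropy()], choosing
#' the bin that maximizes the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`; ties broken by the lowest bin.
#'
#' @inheritParams threshold_maxentropy
#' @return same structure as [threshold_maxentropy()].
#' @export
threshold_otsu <- function(image, n_bins = 256L) {
  px <- as_pixels(image)
  hb <- hist_bins(px, n_bins)
  p <- hb$counts / sum(hb$counts)
  i <- 0:(n_bins - 1L)
  w0 <- cumsum(p); m <- cumsum(p * i); mt <- m[n_bins]
  Ts <- 0:(n_bins - 2L)
  w0T <- w0[Ts + 1L]; w1T <- 1 - w0T
  valid <- w0T > 0 & w1T > 0
  mu0 <- m[Ts + 1L] / w0T; mu1 <- (mt - m[Ts + 1L]) / w1T
  crit <- ifelse(valid, w0T * w1T * (mu0 - mu1)^2, -Inf)
  T <- Ts[which.max(crit)]
  mask <- matrix(hb$bin > T, nrow(px), ncol(px))
  list(threshold = threshold_from_bin(hb, T), bin = T, mask = mask,
       method = "OTSU")
}

#' Size-filtered particle detection on a binary mask
#'
#' Labels connected components and keeps those with `min_size_px <=
#' area <= max_size_px` (bounds inclusive, the particle-analyzer
#' convention); edge-touching components are kept. Survivors are
#' relabeled 1..n preserving raster order.
#'
#' @param mask logical or 0/1 matrix.
#' @param min_size_px,max_size_px inclusive area bounds in pixels.
#' @param connectivity 4 or 8 (default 8, the common spot-counting
#'   choice).
#' @param source,provenance passed through to the [puncta_set()].
#' @return a `puncta_set`.
#' @export
detect_puncta <- function(mask, min_size_px = 2L, max_size_px = 50L,
                          connectivity = 8L, source = NULL,
                          provenance = NULL) {
  if (min_size_px <= 0L || min_size_px > max_size_px)
    stop("require 0 < min_size_px <= max_size_px")
  lab <- label_components(mask, connectivity)
  st <- component_stats(lab)
  keep <- st$area_px >= min_size_px & st$area_px <= max_size_px
  st <- st[keep, , drop = FALSE]
  relab <- integer(max(lab, 1L))
  if (nrow(st)) relab[st$id] <- seq_len(nrow(st))
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0L
  out[pos] <- relab[lab[pos]]
  st$id <- seq_len(nrow(st))
  rownames(st) <- NULL
  puncta_set(out, st, source = source, provenance = provenance)
}

#' Run the full punctum detection chain on a raw field
#'
#' Composes flatten background, no-neighbors deconvolution, top-hat,
#' contrast enhancement, auto-threshold (maximum entropy or Otsu) and
#' size-filtered component counting, in that order. Deterministic; the
#' threshold actually used, the method and a parameter fingerprint are
#' recorded in the result's provenance.
#'
#' @param raw a `field_image` (or numeric matrix).
#' @param params a [detection_params()].
#' @return a `puncta_set` with provenance.
#' @export
run_detection <- function(raw, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  px <- as_pixels(raw)
  # canonical intensity scale: all later stages see the same numbers for
  # any positively rescaled copy of the input, making the final mask
  # exactly scale-invariant
  m <- max(px)
  if (m > 0) px <- px / m
  x <- flatten_background(px, params$flatten_size_px * params$flatten_scale_px)
  x <- deconvolve_no_neighbors(x, params$deconv_filter_size_px,
                               params$deconv_scaling,
                               params$deconv_suppress_noise)
  x <- tophat(x, params$tophat_area_px2)
  # noise scale of the filtered image, from the half-normal distribution
  # of its positive values (the clamped-at-zero background noise);
  # robust to the sparse bright punctum pixels
  pos <- x[x > 0]
  sigma_hat <- if (length(pos)) stats::median(pos) / 0.6745 else 0
  cuts <- contrast_cuts(x, params$saturated_fraction)
  x <- restore_field(NULL, pmin(pmax((x - cuts[1]) / (cuts[2] - cuts[1]),
                                     0), 1))
  th <- switch(params$threshold_method,
               MAXENTROPY = threshold_maxentropy(x),
               OTSU = threshold_otsu(x))
  # sparse-image guard: histogram thresholds collapse into the noise when
  # few or no puncta are present; never threshold below the noise floor
  floor_thr <- (params$noise_floor_mads * sigma_hat - cuts[1]) /
               (cuts[2] - cuts[1])
  thr_used <- max(th$threshold, floor_thr)
  mask <- if (thr_used > th$threshold) x > thr_used else th$mask
  src <- if (inherits(raw, "field_image"))
    raw[c("well_id", "site_index", "timepoint", "channel")] else NULL
  detect_puncta(mask, params$min_size_px, params$max_size_px,
                params$connectivity, source = src,
                provenance = list(threshold = thr_used,
                                  threshold_bin = th$bin,
                                  floor_applied = thr_used > th$threshold,
                                  method = th$method,
                                  params_hash = config_hash(unclass(params))))
}
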