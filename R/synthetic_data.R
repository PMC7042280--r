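# Synthetic two-channel field generator with ground truth. Emulates the
# nuisance structure the detection chain is designed to remove: punctate
# spots on neurite-like curvilinear ridges, diffuse soma blobs, a smooth
# illumination gradient, and Poisson+Gaussian camera noise, quantized to
# 16 bits last. Ground truth records every punctum centroid, the
# pre/post colocalization pairing, applied stage shifts and treatment
# loss fractions.

#' Specification of a synthetic two-channel field
#'
#' Defaults encode mature-culture plateau conditions: presynaptic density
#' 0.03/um^2, postsynaptic 0.014/um^2, and a colocalized fraction of
#' 11/14 of postsynaptic puncta (colocalized density about 0.011/um^2).
#' The field geometry is a desk-scale 224 x 224 px tile at 0.35 um/px
#' (about 6.1e3 um^2, an expected ~184 presynaptic puncta).
#'
#' @param width_px,height_px field size in pixels.
#' @param pixel_size_um micrometres per pixel.
#' @param density_pre,density_post channel densities in puncta per um^2.
#' @param coloc_fraction fraction of postsynaptic puncta placed within
#'   `coloc_radius_px` of a presynaptic punctum, in `[0, 1]`.
#' @param punctum_radius_px length-2 range of punctum radii (px).
#' @param psf_sigma_px Gaussian point-spread sigma added in quadrature to
#'   the punctum radius when rendering.
#' @param coloc_radius_px colocalized post puncta are offset from their
#'   pre partner uniformly in a disk of this radius.
#' @param min_sep_px minimum centre separation enforced between
#'   non-colocalized puncta and any opposite-channel punctum (and between
#'   same-channel puncta); must be at least twice the maximum punctum
#'   radius.
#' @param snr punctum amplitude over background, in units of the
#'   background noise standard deviation.
#' @param n_somata number of large diffuse soma blobs.
#' @param n_neurites number of neurite-like random-walk ridges.
#' @param background list: `offset` (camera baseline + diffuse
#'   fluorescence), `gradient` (peak-to-peak illumination ramp),
#'   `neurite` (ridge amplitude), `soma` (blob amplitude), all in ADU.
#' @param noise list: `poisson_gain` (ADU per photoelectron) and
#'   `gaussian_sd` (read noise, ADU).
#' @param stage_jitter_px maximum absolute integer stage shift drawn per
#'   follow-up acquisition when simulating plates.
#' @param seed integer; all scene structure and noise derive from it.
#' @return object of class `field_spec`.
#' @export
field_spec <- function(width_px = 224L, height_px = 224L,
                       pixel_size_um = 0.35,
                       density_pre = 0.03, density_post = 0.014,
                       coloc_fraction = 11 / 14,
                       punctum_radius_px = c(1.6, 2.4),
                       psf_sigma_px = 0.8, coloc_radius_px = 2,
                       min_sep_px = 6, snr = 6,
                       n_somata = 2L, n_neurites = 6L,
                       background = list(offset = 300, gradient = 120,
                                         neurite = 35, soma = 250),
                       noise = list(poisson_gain = 2, gaussian_sd = 10),
                       stage_jitter_px = 6L, seed = 1L) {
  if (density_pre < 0 || density_post < 0) stop("densities must be >= 0")
  if (coloc_fraction < 0 || coloc_fraction > 1)
    stop("coloc_fraction must be in [0, 1]")
  if (length(punctum_radius_px) != 2L || any(punctum_radius_px <= 0))
    stop("punctum_radius_px must be a positive length-2 range")
  if (min_sep_px < 2 * max(punctum_radius_px))
    stop("min_sep_px must be >= 2 * max punctum radius")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um,
                 density_pre = density_pre, density_post = density_post,
                 coloc_fraction = coloc_fraction,
                 punctum_radius_px = punctum_radius_px,
                 psf_sigma_px = psf_sigma_px,
                 coloc_radius_px = coloc_radius_px,
                 min_sep_px = min_sep_px, snr = snr,
                 n_somata = as.integer(n_somata),
                 n_neurites = as.integer(n_neurites),
                 background = background, noise = noise,
                 stage_jitter_px = as.integer(stage_jitter_px),
                 seed = as.integer(seed)),
            class = "field_spec")
}

spec_area_um2 <- function(spec)
  spec$width_px * spec$height_px * spec$pixel_size_um^2

# Hard-core rejection sampler: n points uniform in [m, H-1-m] x [m, W-1-m]
# (0-based), at least sep from `avoid` points and from each other.
place_points <- function(n, h, w, margin, sep, avoid = NULL,
                         max_tries = 400L) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  lo_r <- margin; hi_r <- h - 1 - margin
  lo_c <- margin; hi_c <- w - 1 - margin
  if (hi_r <= lo_r || hi_c <= lo_c)
    stop("field too small for the requested margins")
  av_r <- if (is.null(avoid)) numeric(0) else avoid[, 1]
  av_c <- if (is.null(avoid)) numeric(0) else avoid[, 2]
  pts <- matrix(NA_real_, n, 2)
  sep2 <- sep^2
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      pr <- runif(1, lo_r, hi_r); pc <- runif(1, lo_c, hi_c)
      clash <- (i > 1L &&
                min((pts[seq_len(i - 1L), 1] - pr)^2 +
                    (pts[seq_len(i - 1L), 2] - pc)^2) < sep2) ||
               (length(av_r) &&
                min((av_r - pr)^2 + (av_c - pc)^2) < sep2)
      if (!clash) { pts[i, ] <- c(pr, pc); ok <- TRUE; break }
    }
    if (!ok)
      stop("infeasible punctum packing: density too high for min_sep_px = ",
           sep, " (placed ", i - 1L, " of ", n, ")")
  }
  pts
}

# Scene: geometric content of one field before rendering. Both channels
# share the cell morphology (neurites, somata, gradient direction).
build_scene <- function(spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(spec$seed, "scene"))
  h <- spec$height_px; w <- spec$width_px
  area <- spec_area_um2(spec)
  rmax <- max(spec$punctum_radius_px)
  margin <- ceiling(2 * rmax + 2 * spec$psf_sigma_px) + spec$coloc_radius_px

  n_pre <- rpois(1, spec$density_pre * area)
  n_post <- rpois(1, spec$density_post * area)
  pre_xy <- place_points(n_pre, h, w, margin, spec$min_sep_px)

  coloc <- if (n_post) as.logical(rbinom(n_post, 1, spec$coloc_fraction))
           else logical(0)
  if (n_pre == 0L) coloc[] <- FALSE    # nothing to appose to
  n_coloc <- sum(coloc)
  if (n_coloc > n_pre)
    stop("infeasible colocalization: ", n_coloc,
         " colocalized post puncta requested but only ", n_pre,
         " pre puncta available")
  partner <- rep(NA_integer_, n_post)
  if (n_coloc) partner[coloc] <- sample.int(n_pre, n_coloc)

  post_xy <- matrix(NA_real_, n_post, 2)
  if (n_coloc) {
    rr <- spec$coloc_radius_px * sqrt(runif(n_coloc))
    th <- runif(n_coloc, 0, 2 * pi)
    post_xy[coloc, ] <- pre_xy[partner[coloc], , drop = FALSE] +
      cbind(rr * sin(th), rr * cos(th))
  }
  if (n_post - n_coloc > 0) {
    free <- place_points(n_post - n_coloc, h, w, margin, spec$min_sep_px,
                         avoid = pre_xy)
    post_xy[!coloc, ] <- free
  }

  mkdf <- function(xy) {
    n <- nrow(xy)
    data.frame(id = seq_len(n),
               row = if (n) xy[, 1] else numeric(0),
               col = if (n) xy[, 2] else numeric(0),
               radius = runif(n, spec$punctum_radius_px[1],
                              spec$punctum_radius_px[2]),
               amp_fac = runif(n, 0.9, 1.25))
  }
  pre <- mkdf(pre_xy); post <- mkdf(post_xy)
  post$coloc <- coloc; post$partner <- partner

  neurites <- lapply(seq_len(spec$n_neurites), function(i) {
    # smoothed random walk entering from a random border point
    start <- c(runif(1, 0, h - 1), runif(1, 0, w - 1))
    ang <- runif(1, 0, 2 * pi)
    nstep <- ceiling(1.5 * (h + w) / 2)
    dang <- cumsum(rnorm(nstep, 0, 0.22))
    steps <- cbind(sin(ang + dang), cos(ang + dang)) * 2.0
    pts <- sweep(apply(steps, 2, cumsum), 2, start, `+`)
    pts[pts[, 1] >= -5 & pts[, 1] <= h + 4 &
        pts[, 2] >= -5 & pts[, 2] <= w + 4, , drop = FALSE]
  })
  somata <- data.frame(row = runif(spec$n_somata, 0.15 * h, 0.85 * h),
                       col = runif(spec$n_somata, 0.15 * w, 0.85 * w),
                       sigma = runif(spec$n_somata, 9, 14),
                       amp_fac = runif(spec$n_somata, 0.7, 1.2))
  grad_dir <- runif(1, 0, 2 * pi)

  list(spec = spec, pre = pre, post = post,
       coloc_pairs = data.frame(pre_id = partner[coloc],
                                post_id = which(coloc)),
       neurites = neurites, somata = somata, grad_dir = grad_dir,
       cache = new.env(parent = emptyenv()))
}

# Save/restore the global RNG state so generators are self-seeding
# without disturbing the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Sum of isotropic Gaussians rendered on an h x w canvas (0-based
# centers, possibly off-canvas). Single-scope accumulation keeps the
# canvas modification in place.
accumulate_gaussians <- function(h, w, rows, cols, amps, sigmas) {
  img <- matrix(0, h, w)
  for (i in seq_along(rows)) {
    sigma <- sigmas[i]
    ext <- ceiling(4 * sigma)
    r0 <- max(0L, floor(rows[i]) - ext); r1 <- min(h - 1L, ceiling(rows[i]) + ext)
    c0 <- max(0L, floor(cols[i]) - ext); c1 <- min(w - 1L, ceiling(cols[i]) + ext)
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    gr <- exp(-((rr - rows[i])^2) / (2 * sigma^2))
    gc <- exp(-((cc - cols[i])^2) / (2 * sigma^2))
    img[rr + 1L, cc + 1L] <- img[rr + 1L, cc + 1L] + amps[i] * outer(gr, gc)
  }
  img
}

# Shared non-punctate content of a scene (illumination gradient,
# neurite ridges, somata), identical for both channels; cached per scene.
render_stroma <- function(scene) {
  if (!is.null(scene$cache$stroma)) return(scene$cache$stroma)
  spec <- scene$spec
  h <- spec$height_px; w <- spec$width_px
  bg <- spec$background

  lin <- outer((0:(h - 1)) * sin(scene$grad_dir),
               (0:(w - 1)) * cos(scene$grad_dir), `+`)
  lin <- if (diff(range(lin)) > 0) (lin - min(lin)) / diff(range(lin))
         else matrix(0.5, h, w)
  img <- bg$offset + bg$gradient * lin

  ridge <- matrix(0, h, w)
  for (pl in scene$neurites) {
    if (!nrow(pl)) next
    ri <- round(pl[, 1]); ci <- round(pl[, 2])
    keep <- ri >= 0 & ri < h & ci >= 0 & ci < w
    if (!any(keep)) next
    idx <- unique(cbind(ri[keep], ci[keep]) %*% c(1, h) + 1)  # col-major
    ridge[idx] <- ridge[idx] + bg$neurite
  }
  # neurite shafts carry dim, diffuse out-of-focus label: several px wide
  # so the top-hat opening can reconstruct (and hence remove) them
  if (length(scene$neurites)) ridge <- EBImage::gblur(ridge, sigma = 2.6)
  img <- img + ridge

  if (nrow(scene$somata))
    img <- img + accumulate_gaussians(h, w, scene$somata$row,
                                      scene$somata$col,
                                      bg$soma * scene$somata$amp_fac,
                                      scene$somata$sigma)
  if (!is.null(scene$cache)) scene$cache$stroma <- img
  img
}

# Deterministic noiseless rendering of one channel of a scene.
render_clean <- function(scene, channel = c("PRE", "POST")) {
  channel <- match.arg(channel)
  spec <- scene$spec
  noise_sd <- sqrt(spec$noise$poisson_gain * spec$background$offset +
                   spec$noise$gaussian_sd^2)
  spots <- if (channel == "PRE") scene$pre else scene$post
  img <- render_stroma(scene)
  if (nrow(spots))
    img <- img + accumulate_gaussians(
      spec$height_px, spec$width_px, spots$row, spots$col,
      spec$snr * noise_sd * spots$amp_fac,
      sqrt((0.65 * spots$radius)^2 + spec$psf_sigma_px^2))
  img
}

# Camera model: shot noise at gain g plus Gaussian read noise, clamped
# and quantized to the 16-bit range last.
apply_noise <- function(clean, spec, rng_label) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(spec$seed, "noise", rng_label))
  g <- spec$noise$poisson_gain
  shot <- if (g > 0) rpois(length(clean), clean / g) * g else clean
  out <- shot + rnorm(length(clean), 0, spec$noise$gaussian_sd)
  out <- matrix(out, nrow(clean), ncol(clean))
  round(pmin(pmax(out, 0), 65535))
}

render_channel <- function(scene, channel, timepoint, well_id = "A01",
                           site_index = 1L) {
  spec <- scene$spec
  px <- apply_noise(render_clean(scene, channel), spec,
                    paste(channel, timepoint, sep = "_"))
  field_image(px, channel = channel, well_id = well_id,
              site_index = site_index, timepoint = timepoint,
              pixel_size_um = spec$pixel_size_um)
}

scene_truth <- function(scene) {
  list(pre_centroids = scene$pre[, c("id", "row", "col")],
       post_centroids = scene$post[, c("id", "row", "col")],
       coloc_pairs = scene$coloc_pairs)
}

#' Generate one synthetic two-channel field with ground truth
#'
#' Deterministic for a fixed `spec$seed`: two calls return bit-identical
#' images. Expected puncta counts equal density x area (Poisson draws);
#' colocalized post puncta are centred within `coloc_radius_px` of their
#' pre partner; non-colocalized puncta are at least `min_sep_px` from any
#' opposite-channel punctum.
#'
#' @param spec a [field_spec()].
#' @param well_id,site_index,timepoint identity stamped on the images.
#' @return list with elements `pre`, `post` (field_image), `truth`
#'   (centroids + coloc pairs) and `scene` (internal geometry, reusable
#'   by [generate_timepoint_pair()]).
#' @export
generate_field <- function(spec, well_id = "A01", site_index = 1L,
                           timepoint = "baseline") {
  stopifnot(inherits(spec, "field_spec"))
  scene <- build_scene(spec)
  list(pre = render_channel(scene, "PRE", timepoint, well_id, site_index),
       post = render_channel(scene, "POST", timepoint, well_id, site_index),
       truth = scene_truth(scene), scene = scene)
}

# Apply survival + rigid translation to a scene. Colocalized pre puncta
# share the fate of their post partner unless decoupled.
evolve_scene <- function(scene, loss_pre, loss_post, shift_px,
                         decouple = FALSE, rng_label = "loss") {
  spec <- scene$spec
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(spec$seed, rng_label))
  post <- scene$post; pre <- scene$pre
  post_keep <- if (nrow(post)) runif(nrow(post)) >= loss_post else logical(0)
  pre_keep <- if (nrow(pre)) runif(nrow(pre)) >= loss_pre else logical(0)
  if (!decouple && nrow(post)) {
    cp <- post$coloc & !is.na(post$partner)
    pre_keep[post$partner[cp]] <- post_keep[cp]
  }
  s2 <- scene
  s2$pre <- pre[pre_keep, , drop = FALSE]
  s2$post <- post[post_keep, , drop = FALSE]
  s2$coloc_pairs <- scene$coloc_pairs[
    scene$coloc_pairs$pre_id %in% s2$pre$id &
    scene$coloc_pairs$post_id %in% s2$post$id, , drop = FALSE]
  dy <- shift_px[1]; dx <- shift_px[2]
  s2$pre$row <- s2$pre$row + dy; s2$pre$col <- s2$pre$col + dx
  s2$post$row <- s2$post$row + dy; s2$post$col <- s2$post$col + dx
  s2$neurites <- lapply(s2$neurites, function(p)
    sweep(p, 2, c(dy, dx), `+`))
  s2$somata$row <- s2$somata$row + dy; s2$somata$col <- s2$somata$col + dx
  s2$cache <- new.env(parent = emptyenv())   # stroma moved with the stage
  s2
}

#' Generate a baseline / follow-up field pair
#'
#' The follow-up scene removes each baseline punctum independently with
#' its channel's loss probability (a colocalized pre punctum is removed
#' jointly with its post partner unless `decouple = TRUE`), translates
#' the surviving scene rigidly by `shift_px`, and regenerates camera
#' noise. Illumination (offset + gradient) does not move with the stage.
#'
#' @param spec a [field_spec()].
#' @param loss_pre,loss_post per-punctum removal probabilities in `[0, 1]`.
#' @param shift_px integer `(dy, dx)` stage shift of the follow-up.
#' @param decouple if `TRUE`, presynaptic survival is independent of the
#'   post partner.
#' @param timepoints labels for the two acquisitions.
#' @param channels channels to render (rendering only `"PRE"` roughly
#'   halves the cost of registration studies).
#' @param well_id,site_index identity stamped on the images.
#' @return list with `baseline` and `followup` (each a list of rendered
#'   channels) and `truth` holding both scenes' centroids, the applied
#'   shift and the loss fractions.
#' @export
generate_timepoint_pair <- function(spec, loss_pre = 0, loss_post = 0,
                                    shift_px = c(0L, 0L), decouple = FALSE,
                                    timepoints = c("baseline", "followup"),
                                    channels = c("PRE", "POST"),
                                    well_id = "A01", site_index = 1L) {
  stopifnot(inherits(spec, "field_spec"))
  if (any(abs(shift_px) >= c(spec$height_px, spec$width_px)))
    stop("|shift_px| must be smaller than the field size")
  if (loss_pre < 0 || loss_pre > 1 || loss_post < 0 || loss_post > 1)
    stop("loss fractions must be in [0, 1]")
  scene <- build_scene(spec)
  scene2 <- evolve_scene(scene, loss_pre, loss_post, shift_px, decouple,
                         rng_label = paste("loss", timepoints[2], sep = "_"))
  render_tp <- function(sc, tp) {
    out <- list()
    if ("PRE" %in% channels)
      out$pre <- render_channel(sc, "PRE", tp, well_id, site_index)
    if ("POST" %in% channels)
      out$post <- render_channel(sc, "POST", tp, well_id, site_index)
    out
  }
  list(baseline = render_tp(scene, timepoints[1]),
       followup = render_tp(scene2, timepoints[2]),
       truth = list(baseline = scene_truth(scene),
                    followup = scene_truth(scene2),
                    applied_shift_px = as.integer(shift_px),
                    loss_pre = loss_pre, loss_post = loss_post))
}

#' Loss tiers of the glutamate positive-control preset
#'
#' Encodes the dose-response tiers reported for glutamate excitotoxicity
#' on colocalized synapse counts: more than 80% of synapses lost at
#' >= 25 uM, about 50-70% at 2.5 uM, under 30% at 250 and 25 nM, and
#' minimal to no loss at 2.5 nM. Postsynaptic puncta are hit somewhat
#' harder than presynaptic ones.
#'
#' @param dose_uM glutamate dose in micromolar.
#' @return named vector `c(loss_pre, loss_post)` of removal fractions.
#' @export
glutamate_effect <- function(dose_uM) {
  loss <- if (is.na(dose_uM) || dose_uM <= 0) 0
          else if (dose_uM >= 25) 0.85
          else if (dose_uM >= 2.5) 0.6
          else if (dose_uM >= 0.025) 0.2
          else if (dose_uM >= 0.0025) 0.02
          else 0
  c(loss_pre = 0.8 * loss, loss_post = loss)
}

#' Triplicate dose-series layout for the glutamate preset
#'
#' @param doses_uM dose series in micromolar.
#' @param n_replicates wells per dose (and NTC wells).
#' @param sites_per_well imaging sites per well.
#' @param timepoints acquisition labels, baseline first.
#' @return a [plate_layout()].
#' @export
glutamate_layout <- function(doses_uM = c(2500, 250, 25, 2.5, 0.25,
                                          0.025, 0.0025),
                             n_replicates = 3L, sites_per_well = 5L,
                             timepoints = c("baseline", "24h")) {
  conds <- c(sprintf("glut_%guM", doses_uM), "NTC")
  doses <- c(doses_uM, NA_real_)
  roles <- c(rep("TREATED", length(doses_uM)), "NTC")
  rows <- LETTERS[seq_along(conds)]
  wells <- do.call(rbind, lapply(seq_along(conds), function(i) {
    data.frame(well = sprintf("%s%02d", rows[i], seq_len(n_replicates)),
               condition = conds[i], dose = doses[i], dose_unit = "uM",
               role = roles[i], stringsAsFactors = FALSE)
  }))
  plate_layout(wells, sites_per_well = sites_per_well,
               timepoints = timepoints)
}

resolve_effect <- function(effect_map, condition, dose, role) {
  if (role %in% c("NTC", "BLANK")) return(c(loss_pre = 0, loss_post = 0))
  eff <- if (is.function(effect_map)) effect_map(condition, dose)
         else effect_map[[condition]]
  if (is.null(eff))
    stop("no treatment effect defined for condition ", condition)
  eff <- unlist(eff)
  c(loss_pre = unname(eff[["loss_pre"]]),
    loss_post = unname(eff[["loss_post"]]))
}

#' Generate a whole-plate time-series dataset on disk
#'
#' Writes one 16-bit TIFF per (well, site, timepoint, channel) under
#' `dir`, plus `manifest.csv` recording ground-truth counts, applied
#' losses and stage shifts. NTC and blank wells receive loss 0; blank
#' wells are rendered without cells (both densities 0).
#'
#' @param layout a [plate_layout()].
#' @param effect_map either a named list `condition -> c(loss_pre,
#'   loss_post)` or a function `(condition, dose) ->` the same.
#' @param spec a [field_spec()] shared by all sites (its seed is
#'   overridden per site).
#' @param seed master seed for the plate.
#' @param dir output directory, created if needed.
#' @return the manifest data frame, invisibly.
#' @export
generate_plate <- function(layout, effect_map, spec = field_spec(),
                           seed = 1L, dir) {
  stopifnot(inherits(layout, "plate_layout"))
  if (missing(dir)) stop("an output dir is required")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tps <- layout$timepoints
  followups <- tps[-1L]
  rows <- list()
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))

  for (i in seq_len(nrow(layout$wells))) {
    wl <- layout$wells[i, ]
    eff <- resolve_effect(effect_map, wl$condition, wl$dose, wl$role)
    for (s in seq_len(layout$sites_per_well)) {
      site_seed <- derive_seed(seed, wl$well, s)
      sspec <- spec
      sspec$seed <- site_seed
      if (wl$role == "BLANK") {
        sspec$density_pre <- 0; sspec$density_post <- 0
        sspec$n_neurites <- 0L; sspec$n_somata <- 0L
      }
      scene <- build_scene(sspec)
      emit <- function(sc, tp, loss, shift) {
        for (ch in c("PRE", "POST")) {
          fi <- render_channel(sc, ch, tp, wl$well, s)
          fn <- field_filename(wl$well, s, tp, ch)
          write_field_tiff(fi, file.path(dir, fn))
          tr <- if (ch == "PRE") sc$pre else sc$post
          n_in <- if (nrow(tr)) sum(tr$row >= 0 & tr$row < sspec$height_px &
                                    tr$col >= 0 & tr$col < sspec$width_px)
                  else 0L
          rows[[length(rows) + 1L]] <<- data.frame(
            well = wl$well, site = s, timepoint = tp, channel = ch,
            path = fn, n_truth = n_in,
            loss_applied = unname(loss[[if (ch == "PRE") "loss_pre"
                                        else "loss_post"]]),
            shift_dy = shift[1], shift_dx = shift[2], seed = site_seed,
            stringsAsFactors = FALSE)
        }
      }
      emit(scene, tps[1L], c(loss_pre = 0, loss_post = 0), c(0L, 0L))
      set.seed(derive_seed(site_seed, "jitter"))
      for (tp in followups) {
        shift <- as.integer(round(runif(2, -spec$stage_jitter_px,
                                        spec$stage_jitter_px)))
        sc2 <- evolve_scene(scene, eff[["loss_pre"]], eff[["loss_post"]],
                            shift, rng_label = paste("loss", tp, sep = "_"))
        emit(sc2, tp, eff, shift)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
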