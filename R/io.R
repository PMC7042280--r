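# Dataset-on-disk conventions: one 16-bit grayscale TIFF per
# (well, site, timepoint, channel), named {well}_{site}_{timepoint}_{channel}.tif.
# Timepoint labels may themselves contain underscores; well is the first
# token, site the second, channel the last.

#' File name for a field image
#' @param well,site,timepoint,channel identity of the field.
#' @return basename of the TIFF, e.g. `"B07_1_24h_PRE.tif"`.
#' @export
field_filename <- function(well, site, timepoint, channel) {
  sprintf("%s_%d_%s_%s.tif", well, as.integer(site), timepoint, channel)
}

parse_field_filename <- function(path) {
  b <- tools::file_path_sans_ext(basename(path))
  parts <- strsplit(b, "_", fixed = TRUE)[[1L]]
  if (length(parts) < 4L)
    stop("cannot parse field filename: ", basename(path))
  list(well = parts[[1L]], site = as.integer(parts[[2L]]),
       timepoint = paste(parts[3:(length(parts) - 1L)], collapse = "_"),
       channel = parts[[length(parts)]])
}

#' Write a field image as a 16-bit grayscale TIFF
#'
#' Intensities are clamped to `[0, 65535]` and rounded; the stored file is
#' single-plane 16-bit.
#'
#' @param field a `field_image`.
#' @param path output file; parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "field_image"))
  px <- pmin(pmax(round(field$pixels), 0), 65535)
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a field image from a 16-bit grayscale TIFF
#'
#' Field identity (well, site, timepoint, channel) is taken from the file
#' name unless supplied explicitly.
#'
#' @param path TIFF file written by [write_field_tiff()] (or any
#'   single-plane grayscale TIFF).
#' @param pixel_size_um micrometres per pixel of the acquisition.
#' @param well,site,timepoint,channel optional identity overrides.
#' @return a `field_image` with integer intensities in `[0, 65535]`.
#' @export
read_field_tiff <- function(path, pixel_size_um = 0.35, well = NULL,
                            site = NULL, timepoint = NULL, channel = NULL) {
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  storage.mode(px) <- "double"
  id <- tryCatch(parse_field_filename(path), error = function(e) NULL)
  field_image(px,
              channel = channel %||% id$channel %||% "PRE",
              well_id = well %||% id$well %||% "A01",
              site_index = site %||% id$site %||% 1L,
              timepoint = timepoint %||% id$timepoint %||% "baseline",
              pixel_size_um = pixel_size_um)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a plate layout to YAML
#' @param layout a `plate_layout`.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_plate_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  wl <- lapply(seq_len(nrow(layout$wells)), function(i) {
    w <- layout$wells[i, ]
    list(well = w$well, condition = w$condition,
         dose = if (is.na(w$dose)) NULL else w$dose,
         dose_unit = if (is.na(w$dose_unit)) NULL else w$dose_unit,
         role = w$role)
  })
  yaml::write_yaml(list(sites_per_well = layout$sites_per_well,
                        timepoints = as.list(layout$timepoints),
                        wells = wl), path)
  invisible(path)
}

#' Read a plate layout from YAML
#' @param path YAML file written by [write_plate_layout()].
#' @return a `plate_layout`.
#' @export
read_plate_layout <- function(path) {
  y <- yaml::read_yaml(path)
  wells <- do.call(rbind, lapply(y$wells, function(w) {
    data.frame(well = w$well, condition = w$condition,
               dose = if (is.null(w$dose)) NA_real_ else as.numeric(w$dose),
               dose_unit = if (is.null(w$dose_unit)) NA_character_
                           else w$dose_unit,
               role = w$role, stringsAsFactors = FALSE)
  }))
  plate_layout(wells, sites_per_well = y$sites_per_well,
               timepoints = unlist(y$timepoints))
}

# 32-bit FNV-1a hash of a character scalar, as 8 hex digits. Used both to
# derive reproducible sub-stream seeds and to fingerprint configurations.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    # xor affects only the low byte (inputs are < 256 after folding)
    lowb <- h %% 256
    h <- h - lowb + bitwXor(lowb, b %% 256)
    # 32-bit multiply by 16777619 without overflow: split into halves
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  h
}

# Deterministic sub-seed in [0, 2^31 - 2] from a base seed plus labels.
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "|")
  as.integer(fnv1a32(key) %% 2147483646)
}

config_hash <- function(x) {
  h <- fnv1a32(paste(deparse(x, control = "all"), collapse = ""))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
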