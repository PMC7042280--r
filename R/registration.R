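# Integer-pixel alignment of serial acquisitions of one imaging site by
# normalized cross-correlation template matching: the central crop of the
# moving image is searched within the reference over a bounded shift
# window. Subpixel refinement is deliberately absent - downstream
# counting is binary-mask based and the acquisitions are revisits of
# approximately the same stage position.

# Cross-correlation of `ref` with kernel `tpl` at every valid placement
# (top-left corners), via zero-padded FFTs. Returns an
# (H-h+1) x (W-w+1) matrix of raw correlation sums.
xcorr_valid <- function(ref, tpl) {
  H <- nrow(ref); W <- ncol(ref); h <- nrow(tpl); w <- ncol(tpl)
  pad <- function(m) { out <- matrix(0, H, W); out[1:nrow(m), 1:ncol(m)] <- m; out }
  cc <- Re(stats::fft(stats::fft(pad(ref)) * Conj(stats::fft(pad(tpl))),
                      inverse = TRUE)) / (H * W)
  cc[1:(H - h + 1), 1:(W - w + 1), drop = FALSE]
}

# Sliding-window sums of `x` over h x w windows, exact via cumsum
# integral images; same layout as xcorr_valid.
window_sums <- function(x, h, w) {
  cs <- apply(apply(x, 2, cumsum), 1, cumsum)  # transposed double cumsum
  cs <- t(cs)
  cs <- rbind(0, cbind(0, cs))
  H <- nrow(x); W <- ncol(x)
  r <- 1:(H - h + 1); c <- 1:(W - w + 1)
  cs[r + h, c + w, drop = FALSE] - cs[r, c + w, drop = FALSE] -
    cs[r + h, c, drop = FALSE] + cs[r, c, drop = FALSE]
}

#' Estimate the integer shift between two acquisitions of one field
#'
#' The central 50% crop of `moving` is matched within `reference` by
#' normalized cross-correlation, searched over `|dy|, |dx| <=
#' max_shift_px`. The returned `(dy, dx)` is the displacement of the
#' moving image's content relative to the reference (moving pixel
#' `(r, c)` corresponds to reference pixel `(r - dy, c - dx)`). Ties are
#' broken by the smallest Euclidean shift magnitude, then row-major
#' order. The score is the peak normalized correlation in `[-1, 1]`.
#'
#' @param reference,moving `field_image`s or numeric matrices of equal
#'   shape.
#' @param max_shift_px search half-window; must be below half the
#'   smallest image dimension.
#' @return list `(dy, dx, score)`.
#' @export
estimate_shift <- function(reference, moving, max_shift_px = 50L) {
  ref <- as_pixels(reference); mov <- as_pixels(moving)
  if (!all(dim(ref) == dim(mov))) stop("images must have the same shape")
  H <- nrow(ref); W <- ncol(ref)
  if (max_shift_px >= min(H, W) / 2)
    stop("max_shift_px must be below half the smallest image dimension")

  h <- floor(H / 2); w <- floor(W / 2)
  r0 <- floor(H / 4) + 1L; c0 <- floor(W / 4) + 1L   # template top-left (1-based)
  tpl <- mov[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]
  tmean <- mean(tpl); tnorm <- sqrt(sum((tpl - tmean)^2))
  if (tnorm < .Machine$double.eps^0.5 * max(1, abs(tmean)) || tnorm == 0)
    stop("degenerate input: the alignment template has zero variance")

  num_raw <- xcorr_valid(ref, tpl - tmean)
  s1 <- window_sums(ref, h, w)
  s2 <- window_sums(ref^2, h, w)
  varw <- pmax(s2 - s1^2 / (h * w), 0)
  denom <- sqrt(varw) * tnorm
  score <- ifelse(denom > 0, num_raw / denom, -Inf)

  # placement (i, j) (1-based top-left in ref) corresponds to shift
  # dy = r0 - i, dx = c0 - j
  ii <- r0 - seq_len(nrow(score))        # dy per row
  jj <- c0 - seq_len(ncol(score))        # dx per col
  ok_r <- which(abs(ii) <= max_shift_px)
  ok_c <- which(abs(jj) <= max_shift_px)
  if (!length(ok_r) || !length(ok_c)) stop("empty shift search window")
  sub <- score[ok_r, ok_c, drop = FALSE]
  dys <- ii[ok_r]; dxs <- jj[ok_c]

  best <- max(sub)
  cand <- which(sub >= best - 1e-9, arr.ind = TRUE)
  dy <- dys[cand[, 1]]; dx <- dxs[cand[, 2]]
  ord <- order(dy^2 + dx^2, dy, dx)
  pick <- ord[1L]
  list(dy = as.integer(dy[pick]), dx = as.integer(dx[pick]),
       score = sub[cand[pick, 1], cand[pick, 2]])
}

#' Align a per-timepoint series of acquisitions of one site
#'
#' Shifts are estimated pairwise against the first timepoint on one
#' designated channel; the region of interest is the maximal axis-aligned
#' rectangle visible in every aligned frame. The same shifts and ROI are
#' meant to be applied to both channels of the site.
#'
#' @param images list of `field_image`s (or matrices), one per timepoint,
#'   in acquisition order; the first is the reference.
#' @param max_shift_px search half-window passed to [estimate_shift()].
#' @param min_roi_fraction minimum admissible ROI area as a fraction of
#'   the field; below it alignment fails with an error naming the site.
#' @return object of class `alignment_result`: `shifts` (list of integer
#'   `(dy, dx)`, first is `(0, 0)`), `scores`, and `roi` = `(row0, col0,
#'   height, width)` in 0-based reference coordinates.
#' @export
align_series <- function(images, max_shift_px = 50L,
                         min_roi_fraction = 0.5) {
  if (length(images) == 0L) stop("empty image series")
  ref <- as_pixels(images[[1L]])
  H <- nrow(ref); W <- ncol(ref)
  shifts <- list(c(0L, 0L)); scores <- 1.0
  if (length(images) > 1L) {
    for (k in 2:length(images)) {
      est <- estimate_shift(images[[1L]], images[[k]], max_shift_px)
      shifts[[k]] <- c(est$dy, est$dx); scores[k] <- est$score
    }
  }
  dys <- vapply(shifts, `[`, integer(1), 1L)
  dxs <- vapply(shifts, `[`, integer(1), 2L)
  # reference pixel (r, c) [0-based] is visible in frame k iff
  # 0 <= r + dy_k < H: intersect over frames
  row0 <- max(0L, max(-dys)); row1 <- (H - 1L) - max(0L, max(dys))
  col0 <- max(0L, max(-dxs)); col1 <- (W - 1L) - max(0L, max(dxs))
  if (row1 < row0 || col1 < col0)
    stop("alignment failure: empty frame intersection")
  roi <- c(row0 = row0, col0 = col0,
           height = row1 - row0 + 1L, width = col1 - col0 + 1L)
  src <- if (inherits(images[[1L]], "field_image"))
    sprintf("%s site %d", images[[1L]]$well_id, images[[1L]]$site_index)
    else "series"
  if (roi[["height"]] * roi[["width"]] < min_roi_fraction * H * W)
    stop(sprintf(
      "alignment failure at %s: ROI covers %.0f%% of the field (min %.0f%%)",
      src, 100 * roi[["height"]] * roi[["width"]] / (H * W),
      100 * min_roi_fraction))
  structure(list(shifts = shifts, scores = scores, roi = roi),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  sh <- paste(vapply(x$shifts, function(s)
    sprintf("(%d,%d)", s[1], s[2]), ""), collapse = " ")
  cat(sprintf("<alignment_result> shifts %s, roi %dx%d at (%d,%d)\n",
              sh, x$roi[["height"]], x$roi[["width"]],
              x$roi[["row0"]], x$roi[["col0"]]))
  invisible(x)
}

#' Crop one aligned frame to the common region of interest
#'
#' Output pixel `(0, 0)` corresponds to the ROI origin of the reference
#' frame; for frame shift `(dy, dx)` the content is read from
#' `(roi_row0 + dy, roi_col0 + dx)` of the frame itself.
#'
#' @param image `field_image` or matrix.
#' @param shift integer `(dy, dx)` of this frame from [align_series()].
#' @param roi named vector `(row0, col0, height, width)`, 0-based.
#' @return same type as `image`, with ROI dimensions.
#' @export
crop_to_roi <- function(image, shift, roi) {
  px <- as_pixels(image)
  r0 <- roi[["row0"]] + shift[1L] + 1L
  c0 <- roi[["col0"]] + shift[2L] + 1L
  r1 <- r0 + roi[["height"]] - 1L; c1 <- c0 + roi[["width"]] - 1L
  if (r0 < 1L || c0 < 1L || r1 > nrow(px) || c1 > ncol(px))
    stop("roi + shift falls outside the image")
  out <- px[r0:r1, c0:c1, drop = FALSE]
  if (inherits(image, "field_image")) {
    image$pixels <- out
    image
  } else out
}
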