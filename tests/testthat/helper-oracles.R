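# Independent brute-force oracles, deliberately written with different
# algorithms than the package internals.

# Flood-fill component labeling with an explicit stack.
oracle_flood_fill <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nbr <- if (connectivity == 4L)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(rep(-1:1, each = 3), rep(-1:1, 3))[-5, , drop = FALSE]
  cur <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {    # row-major scan
    if (!mask[r, c] || lab[r, c] != 0L) next
    cur <- cur + 1L
    stack <- list(c(r, c)); lab[r, c] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nbr))) {
        rr <- p[1] + nbr[k, 1]; cc <- p[2] + nbr[k, 2]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Survivors of a size filter applied to oracle labeling: sorted areas and
# count, enough to compare detections independent of label numbering.
oracle_particles <- function(mask, min_size, max_size, connectivity = 8L) {
  lab <- oracle_flood_fill(mask, connectivity)
  if (max(lab) == 0L) return(list(n = 0L, areas = integer()))
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_size & areas <= max_size)
  list(n = length(keep), areas = sort(areas[keep]))
}

# Exhaustive Kapur maximum-entropy scan: recomputes both class entropies
# from scratch for every candidate bin.
oracle_kapur_bin <- function(px, n_bins = 256L) {
  lo <- min(px); hi <- max(px)
  b <- pmin(floor((px - lo) / (hi - lo) * n_bins), n_bins - 1L)
  counts <- tabulate(as.integer(b) + 1L, nbins = n_bins)
  p <- counts / sum(counts)
  best <- -Inf; bestT <- NA_integer_
  for (T in 0:(n_bins - 2L)) {
    pb <- p[1:(T + 1L)]; pf <- p[(T + 2L):n_bins]
    Pb <- sum(pb); Pf <- sum(pf)
    if (Pb <= 0 || Pf <= 0) next
    hb <- -sum(ifelse(pb > 0, (pb / Pb) * log(pb / Pb), 0))
    hf <- -sum(ifelse(pf > 0, (pf / Pf) * log(pf / Pf), 0))
    if (hb + hf > best + 1e-12) { best <- hb + hf; bestT <- T }
  }
  bestT
}

# Exhaustive Otsu scan maximizing between-class variance from scratch.
oracle_otsu_bin <- function(px, n_bins = 256L) {
  lo <- min(px); hi <- max(px)
  b <- pmin(floor((px - lo) / (hi - lo) * n_bins), n_bins - 1L)
  counts <- tabulate(as.integer(b) + 1L, nbins = n_bins)
  p <- counts / sum(counts)
  i <- 0:(n_bins - 1L)
  best <- -Inf; bestT <- NA_integer_
  for (T in 0:(n_bins - 2L)) {
    w0 <- sum(p[1:(T + 1L)]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:(T + 1L)] * i[1:(T + 1L)]) / w0
    mu1 <- sum(p[(T + 2L):n_bins] * i[(T + 2L):n_bins]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best + 1e-12) { best <- v; bestT <- T }
  }
  bestT
}

# Direct normalized cross-correlation over the shift window, looped.
oracle_ncc_shift <- function(ref, mov, max_shift) {
  H <- nrow(ref); W <- ncol(ref)
  h <- floor(H / 2); w <- floor(W / 2)
  r0 <- floor(H / 4) + 1L; c0 <- floor(W / 4) + 1L
  tpl <- mov[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]
  tz <- tpl - mean(tpl)
  best <- -Inf; bdy <- NA; bdx <- NA
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    i <- r0 - dy; j <- c0 - dx
    if (i < 1 || j < 1 || i + h - 1 > H || j + w - 1 > W) next
    win <- ref[i:(i + h - 1L), j:(j + w - 1L)]
    wz <- win - mean(win)
    den <- sqrt(sum(wz^2) * sum(tz^2))
    if (den == 0) next
    sc <- sum(wz * tz) / den
    better <- sc > best + 1e-9
    tie <- abs(sc - best) <= 1e-9 &&
      (dy^2 + dx^2 < bdy^2 + bdx^2 ||
       (dy^2 + dx^2 == bdy^2 + bdx^2 &&
        (dy < bdy || (dy == bdy && dx < bdx))))
    if (better || tie) { best <- sc; bdy <- dy; bdx <- dx }
  }
  c(dy = bdy, dx = bdx, score = best)
}

# Random test images with bimodal-ish structure for threshold oracles.
random_test_image <- function(seed, n = 64L) {
  set.seed(seed)
  kind <- seed %% 3L
  n0 <- floor(n * n * 0.8)
  if (kind == 0L) matrix(rnorm(n * n, 100, 30), n, n)
  else if (kind == 1L) matrix(c(rnorm(n0, 50, 12),
                                rnorm(n * n - n0, 180, 25)), n, n)
  else matrix(rpois(n * n, 40) + runif(n * n) * 60, n, n)
}

# A textured, wrap-free translatable image for registration tests.
textured_image <- function(seed, n = 96L) {
  set.seed(seed)
  base <- matrix(rnorm(n * n), n, n)
  k <- EBImage::makeBrush(9, "Gaussian", sigma = 1.5)
  100 + 40 * EBImage::filter2(base, k, boundary = "replicate")
}

translate_padded <- function(img, dy, dx) {
  # content moved by (dy, dx); vacated pixels filled with the image mean
  H <- nrow(img); W <- ncol(img)
  out <- matrix(mean(img), H, W)
  src_r <- seq_len(H) - dy; src_c <- seq_len(W) - dx
  ok_r <- src_r >= 1 & src_r <= H; ok_c <- src_c >= 1 & src_c <= W
  out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c]]
  out
}
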