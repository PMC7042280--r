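# Ground-truth evaluation utilities for the synthetic generator:
# one-to-one greedy matching of detected centroids to true centroids and
# the derived recall/precision.

#' Match detected puncta to ground-truth centroids
#'
#' Greedy one-to-one matching by ascending centroid distance; a detected
#' punctum matches a true punctum if their centroids are within
#' `max_dist_px`.
#'
#' @param truth data frame with columns `row`, `col` (0-based true
#'   centroids).
#' @param detected a `puncta_set` or data frame with `centroid_row`,
#'   `centroid_col`.
#' @param max_dist_px match radius in pixels (default 3).
#' @return list `n_truth`, `n_detected`, `n_matched`, `recall`,
#'   `precision`, and the matched index `pairs`.
#' @export
match_puncta <- function(truth, detected, max_dist_px = 3) {
  det <- if (inherits(detected, "puncta_set")) detected$puncta else detected
  nt <- nrow(truth); nd <- nrow(det)
  if (nt == 0L || nd == 0L)
    return(list(n_truth = nt, n_detected = nd, n_matched = 0L,
                recall = ifelse(nt == 0L, NA_real_, 0),
                precision = ifelse(nd == 0L, NA_real_, 0),
                pairs = data.frame(truth_idx = integer(),
                                   det_idx = integer())))
  d2 <- outer(truth$row, det$centroid_row, `-`)^2 +
        outer(truth$col, det$centroid_col, `-`)^2
  hit <- which(d2 <= max_dist_px^2, arr.ind = TRUE)
  ord <- order(d2[hit])
  hit <- hit[ord, , drop = FALSE]
  used_t <- logical(nt); used_d <- logical(nd)
  tp <- integer(0); dp <- integer(0)
  for (i in seq_len(nrow(hit))) {
    a <- hit[i, 1]; b <- hit[i, 2]
    if (!used_t[a] && !used_d[b]) {
      used_t[a] <- TRUE; used_d[b] <- TRUE
      tp <- c(tp, a); dp <- c(dp, b)
    }
  }
  list(n_truth = nt, n_detected = nd, n_matched = length(tp),
       recall = length(tp) / nt, precision = length(tp) / nd,
       pairs = data.frame(truth_idx = tp, det_idx = dp))
}

#' Power simulation for synapse-loss screening
#'
#' Simulates complete before/after plates in memory - treated and
#' control wells, several imaging sites each, stage jitter between
#' acquisitions - runs the full pipeline (align, crop, detect both
#' channels, colocalize) on every field, expresses colocalized counts as
#' percent of each well's baseline and tests treated vs control with
#' Dunnett adjustment. Returns one adjusted p-value per simulated plate.
#'
#' @param n_sims number of simulated plates.
#' @param loss_post removal probability of postsynaptic (and, jointly,
#'   colocalized) puncta in treated wells.
#' @param loss_pre removal probability of non-colocalized presynaptic
#'   puncta (default 0.8 x `loss_post`, the preset ratio).
#' @param n_treated,n_ntc wells per group.
#' @param sites imaging sites per well.
#' @param spec field specification shared by all sites (its seed is
#'   overridden per site); the default is a reduced 160 px tile to keep
#'   whole-plate simulation affordable.
#' @param seed master seed.
#' @param max_shift_px alignment search half-window.
#' @return data frame with one row per simulation: `sim`, `p_adj`,
#'   `pct_treated`, `pct_ntc`.
#' @export
simulate_loss_screen <- function(n_sims = 100, loss_post = 0.8,
                                 loss_pre = 0.8 * loss_post,
                                 n_treated = 3, n_ntc = 3, sites = 5,
                                 spec = field_spec(width_px = 160L,
                                                   height_px = 160L),
                                 seed = 1L, max_shift_px = 20L) {
  out <- vector("list", n_sims)
  for (sim in seq_len(n_sims)) {
    pct <- vapply(seq_len(n_treated + n_ntc), function(wi) {
      treated <- wi <= n_treated
      base <- 0; fol <- 0
      for (s in seq_len(sites)) {
        sseed <- derive_seed(seed, sim, wi, s)
        sp <- spec; sp$seed <- sseed
        old <- .Random.seed_save()
        set.seed(derive_seed(sseed, "shift"))
        sh <- as.integer(round(runif(2, -spec$stage_jitter_px,
                                     spec$stage_jitter_px)))
        .Random.seed_restore(old)
        tp <- generate_timepoint_pair(sp,
                                      loss_pre = if (treated) loss_pre else 0,
                                      loss_post = if (treated) loss_post else 0,
                                      shift_px = sh)
        al <- align_series(list(tp$baseline$pre, tp$followup$pre),
                           max_shift_px)
        det <- function(img, k)
          run_detection(crop_to_roi(img, al$shifts[[k]], al$roi))
        base <- base + colocalize(det(tp$baseline$pre, 1),
                                  det(tp$baseline$post, 1))$n_coloc
        fol <- fol + colocalize(det(tp$followup$pre, 2),
                                det(tp$followup$post, 2))$n_coloc
      }
      100 * fol / base
    }, numeric(1))
    groups <- rep(c("treated", "NTC"), c(n_treated, n_ntc))
    dn <- dunnett_vs_control(pct, groups, "NTC")
    out[[sim]] <- data.frame(sim = sim, p_adj = dn$p_adj,
                             pct_treated = mean(pct[seq_len(n_treated)]),
                             pct_ntc = mean(pct[-seq_len(n_treated)]))
  }
  do.call(rbind, out)
}
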