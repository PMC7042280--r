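# Site -> well -> condition aggregation and the screening statistics:
# the experimental unit is the well (site values are averaged first,
# avoiding pseudo-replication), synapse loss is expressed as percent of
# each well's own baseline, and treated conditions are tested against
# no-treatment controls with multiplicity adjustment.

#' Summarize per-site counts to wells
#'
#' Groups per-field counts by (well, timepoint, readout) and computes
#' the mean and sample standard deviation over imaging sites. Wells with
#' a single site are flagged (`sd` is `NA` there) rather than silently
#' used; wells missing sites relative to `expected_sites` trigger a
#' warning.
#'
#' @param counts data frame with columns `well`, `site`, `timepoint`,
#'   `readout` and `value` (one row per field and readout).
#' @param expected_sites optional expected number of sites per well.
#' @return data frame of class `well_summary`: `well`, `timepoint`,
#'   `readout`, `mean`, `sd`, `n_sites`, `flag_single_site`.
#' @export
summarize_wells <- function(counts, expected_sites = NULL) {
  req <- c("well", "site", "timepoint", "readout", "value")
  if (!all(req %in% names(counts)))
    stop("counts must have columns ", paste(req, collapse = ", "))
  ag <- aggregate(value ~ well + timepoint + readout, data = counts,
                  FUN = function(v) c(mean = mean(v), sd = sd(v),
                                      n = length(v)))
  out <- data.frame(well = ag$well, timepoint = ag$timepoint,
                    readout = ag$readout,
                    mean = ag$value[, "mean"], sd = ag$value[, "sd"],
                    n_sites = as.integer(ag$value[, "n"]),
                    stringsAsFactors = FALSE)
  out$flag_single_site <- out$n_sites == 1L
  if (!is.null(expected_sites) && any(out$n_sites < expected_sites))
    warning(sum(out$n_sites < expected_sites),
            " well/timepoint/readout groups have fewer than ",
            expected_sites, " sites")
  class(out) <- c("well_summary", class(out))
  out
}

#' Percent of baseline
#'
#' `100 * followup / baseline`, the per-well synapse-survival statistic
#' ("80% lost" corresponds to a value of 20). Scale-free: multiplying
#' all counts by a positive constant leaves it unchanged.
#'
#' @param followup_mean,baseline_mean per-well mean counts (vectorized).
#' @return percentages.
#' @export
percent_of_baseline <- function(followup_mean, baseline_mean) {
  if (any(!is.finite(baseline_mean)) || any(baseline_mean <= 0))
    stop("baseline mean must be positive")
  100 * followup_mean / baseline_mean
}

#' Intra- and inter-plate variability metrics
#'
#' Intra-plate: the average over wells of the site-to-site standard
#' deviation and of the site-level coefficient of variation (sd/mean).
#' Inter-plate: the coefficient of variation of per-plate grand means
#' (requires a `plate` column with at least two plates).
#'
#' @param well_summaries data frame with columns `mean`, `sd` (per well)
#'   and optionally `plate`.
#' @return list `intra_mean_sd`, `intra_mean_cv`, `inter_cv` (NA when
#'   fewer than two plates are present).
#' @export
variability_metrics <- function(well_summaries) {
  ws <- well_summaries
  if (!all(c("mean", "sd") %in% names(ws)))
    stop("need columns mean and sd")
  usable <- is.finite(ws$sd) & is.finite(ws$mean) & ws$mean > 0
  intra_sd <- mean(ws$sd[usable])
  intra_cv <- mean(ws$sd[usable] / ws$mean[usable])
  inter <- NA_real_
  if ("plate" %in% names(ws) && length(unique(ws$plate)) >= 2L) {
    pm <- tapply(ws$mean, ws$plate, mean)
    inter <- sd(pm) / mean(pm)
  }
  list(intra_mean_sd = intra_sd, intra_mean_cv = intra_cv,
       inter_cv = inter)
}

#' Agreement between automated and manual counts
#'
#' Pearson correlation of paired per-image counts, plus the least-squares
#' fit `manual ~ automated` (automation typically yields slightly higher
#' absolute numbers, i.e. a slope below 1 with high correlation).
#'
#' @param automated,manual paired numeric vectors.
#' @return list `r`, `slope`, `intercept`, `n`.
#' @export
automated_vs_manual_agreement <- function(automated, manual) {
  if (length(automated) != length(manual))
    stop("paired vectors must have equal length")
  ok <- is.finite(automated) & is.finite(manual)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  fit <- lm(manual[ok] ~ automated[ok])
  list(r = cor(automated[ok], manual[ok]),
       slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       n = sum(ok))
}
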