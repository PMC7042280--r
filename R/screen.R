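# Dataset-level orchestration: simulate a plate to disk, run the
# screening pipeline (align -> crop -> detect -> colocalize -> aggregate
# -> test) over every site, and emit result tables plus a QC report.
# Sites whose alignment fails are excluded and enumerated in QC, never
# silently dropped.

#' Assemble a run configuration
#'
#' Collects every knob of a screening run in one list; [write_run_config()]
#' / [read_run_config()] serialize it to YAML. The configuration hash is
#' stamped on every output table so outputs from different configurations
#' are detectable.
#'
#' @param dataset_dir directory of TIFFs (+ manifest.csv).
#' @param layout a [plate_layout()] or path to its YAML.
#' @param detection a [detection_params()].
#' @param align_channel channel used for alignment (default `"PRE"`, the
#'   brighter, earlier-expressed marker).
#' @param max_shift_px alignment search half-window.
#' @param min_roi_fraction minimum admissible ROI fraction.
#' @param coloc_criterion,coloc_param see [colocalize()].
#' @param control control condition label.
#' @param alpha significance level.
#' @param pixel_size_um micrometres per pixel of the dataset.
#' @param out_dir output directory (optional).
#' @param seed seed recorded in outputs.
#' @return list of class `run_config`.
#' @export
run_config <- function(dataset_dir = ".", layout = NULL,
                       detection = detection_params(),
                       align_channel = "PRE", max_shift_px = 20L,
                       min_roi_fraction = 0.5,
                       coloc_criterion = "PIXEL_OVERLAP", coloc_param = 1,
                       control = "NTC", alpha = 0.05,
                       pixel_size_um = 0.35, out_dir = NULL, seed = 1L) {
  cfg <- list(dataset_dir = dataset_dir, layout = layout,
              detection = detection, align_channel = align_channel,
              max_shift_px = as.integer(max_shift_px),
              min_roi_fraction = min_roi_fraction,
              coloc_criterion = coloc_criterion, coloc_param = coloc_param,
              control = control, alpha = alpha,
              pixel_size_um = pixel_size_um, out_dir = out_dir,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$detection <- unclass(x$detection)
  if (inherits(x$layout, "plate_layout")) {
    lp <- paste0(tools::file_path_sans_ext(path), "_layout.yaml")
    write_plate_layout(cfg$layout, lp)
    x$layout <- lp
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$detection <- do.call(detection_params, x$detection)
  do.call(run_config, x)
}

#' Simulate a plate dataset to disk with provenance
#'
#' Thin wrapper over [generate_plate()] that also writes a
#' machine-readable provenance file (configuration, seed, package
#' version).
#'
#' @param layout a [plate_layout()].
#' @param effect_map condition-to-loss map, see [generate_plate()].
#' @param spec a [field_spec()].
#' @param seed master seed.
#' @param dir output directory.
#' @return manifest data frame, invisibly.
#' @export
simulate_plate <- function(layout, effect_map, spec = field_spec(),
                           seed = 1L, dir) {
  manifest <- generate_plate(layout, effect_map, spec, seed, dir)
  prov <- list(seed = as.integer(seed),
               spec = unclass(spec),
               sites_per_well = layout$sites_per_well,
               timepoints = as.list(layout$timepoints),
               version = as.character(utils::packageVersion("synaptoscreen")))
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  invisible(manifest)
}

read_site_stack <- function(dir, well, site, timepoints, channels,
                            pixel_size_um) {
  out <- list()
  for (tp in timepoints) for (ch in channels) {
    fn <- file.path(dir, field_filename(well, site, tp, ch))
    if (!file.exists(fn)) stop("missing image: ", basename(fn))
    out[[paste(tp, ch, sep = ".")]] <-
      read_field_tiff(fn, pixel_size_um = pixel_size_um, well = well,
                      site = site, timepoint = tp, channel = ch)
  }
  out
}

#' Run the screening pipeline over a plate dataset
#'
#' For every site: align the timepoints on one channel, crop all images
#' to the common ROI, detect puncta on both channels at every timepoint,
#' and colocalize. Counts are aggregated site -> well, expressed as
#' percent of each well's baseline, and every treated condition is
#' compared against the control with Dunnett adjustment, per follow-up
#' timepoint and readout. Alignment failures are logged in the QC table
#' and their sites excluded.
#'
#' @param cfg a [run_config()]; `cfg$layout` must be a `plate_layout` or
#'   a YAML path.
#' @return list with `per_field`, `well_summary`, `well_percent`,
#'   `report`, `qc`, `alignments` data frames and `config_hash`; also
#'   written as CSVs under `cfg$out_dir` when set.
#' @export
screen_plate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  layout <- cfg$layout
  if (is.character(layout)) layout <- read_plate_layout(layout)
  stopifnot(inherits(layout, "plate_layout"))
  tps <- layout$timepoints
  hash <- config_hash(list(unclass(cfg$detection), cfg$align_channel,
                           cfg$max_shift_px, cfg$min_roi_fraction,
                           cfg$coloc_criterion, cfg$coloc_param,
                           cfg$control, cfg$alpha, cfg$seed))
  per_field <- list(); qc <- list(); aligns <- list()

  for (i in seq_len(nrow(layout$wells))) {
    wl <- layout$wells[i, ]
    for (s in seq_len(layout$sites_per_well)) {
      res <- tryCatch({
        stack <- read_site_stack(cfg$dataset_dir, wl$well, s, tps,
                                 c("PRE", "POST"), cfg$pixel_size_um)
        al_imgs <- lapply(tps, function(tp)
          stack[[paste(tp, cfg$align_channel, sep = ".")]])
        al <- align_series(al_imgs, cfg$max_shift_px, cfg$min_roi_fraction)
        rows <- list()
        for (k in seq_along(tps)) {
          tp <- tps[k]
          dets <- lapply(c(PRE = "PRE", POST = "POST"), function(ch) {
            img <- crop_to_roi(stack[[paste(tp, ch, sep = ".")]],
                               al$shifts[[k]], al$roi)
            run_detection(img, cfg$detection)
          })
          cl <- colocalize(dets$PRE, dets$POST, cfg$coloc_criterion,
                           cfg$coloc_param)
          for (rd in c("pre", "post", "coloc")) {
            v <- switch(rd, pre = dets$PRE$n, post = dets$POST$n,
                        coloc = cl$n_coloc)
            thr <- switch(rd, pre = dets$PRE$provenance$threshold,
                          post = dets$POST$provenance$threshold,
                          coloc = NA_real_)
            rows[[length(rows) + 1L]] <- data.frame(
              well = wl$well, site = s, timepoint = tp, readout = rd,
              value = v, threshold = thr,
              shift_dy = al$shifts[[k]][1], shift_dx = al$shifts[[k]][2],
              align_score = al$scores[k], stringsAsFactors = FALSE)
          }
        }
        list(rows = rows, align = al)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        qc[[length(qc) + 1L]] <- data.frame(
          well = wl$well, site = s, status = "excluded",
          reason = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        per_field <- c(per_field, res$rows)
        aligns[[length(aligns) + 1L]] <- data.frame(
          well = wl$well, site = s, timepoint = tps,
          shift_dy = vapply(res$align$shifts, `[`, integer(1), 1),
          shift_dx = vapply(res$align$shifts, `[`, integer(1), 2),
          score = res$align$scores,
          roi_row0 = res$align$roi[["row0"]],
          roi_col0 = res$align$roi[["col0"]],
          roi_height = res$align$roi[["height"]],
          roi_width = res$align$roi[["width"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  per_field <- do.call(rbind, per_field)
  if (is.null(per_field) || !nrow(per_field))
    stop("total failure: no site could be processed")
  qc <- if (length(qc)) do.call(rbind, qc)
        else data.frame(well = character(), site = integer(),
                        status = character(), reason = character())
  aligns <- do.call(rbind, aligns)

  ws <- summarize_wells(per_field[, c("well", "site", "timepoint",
                                      "readout", "value")],
                        expected_sites = layout$sites_per_well)

  # per-well percent of baseline for every follow-up timepoint
  base <- ws[ws$timepoint == layout$baseline, ]
  wp <- list()
  for (tp in setdiff(tps, layout$baseline)) {
    fol <- ws[ws$timepoint == tp, ]
    m <- merge(fol, base, by = c("well", "readout"),
               suffixes = c("", "_base"))
    usable <- m$mean_base > 0
    m$pct_of_baseline <- NA_real_
    m$pct_of_baseline[usable] <-
      percent_of_baseline(m$mean[usable], m$mean_base[usable])
    wp[[tp]] <- data.frame(well = m$well, timepoint = tp,
                           readout = m$readout,
                           mean = m$mean, mean_base = m$mean_base,
                           pct_of_baseline = m$pct_of_baseline,
                           stringsAsFactors = FALSE)
  }
  wp <- do.call(rbind, wp)
  wp <- merge(wp, layout$wells, by = "well")

  # NTC-normalized alternative (percent of the mean NTC percent)
  report <- list()
  for (tp in unique(wp$timepoint)) for (rd in unique(wp$readout)) {
    sub <- wp[wp$timepoint == tp & wp$readout == rd &
              wp$role != "BLANK" & is.finite(wp$pct_of_baseline), ]
    if (!nrow(sub)) next
    ntc_mean <- mean(sub$pct_of_baseline[sub$role == "NTC"])
    sub$pct_of_ntc <- 100 * sub$pct_of_baseline / ntc_mean
    dn <- tryCatch(
      dunnett_vs_control(sub$pct_of_baseline, sub$condition, cfg$control,
                         cfg$alpha),
      error = function(e) NULL)
    for (cond in unique(sub$condition)) {
      sc <- sub[sub$condition == cond, ]
      p <- if (cond == cfg$control) 1
           else if (!is.null(dn) && cond %in% dn$condition)
             dn$p_adj[dn$condition == cond] else NA_real_
      report[[length(report) + 1L]] <- data.frame(
        condition = cond, dose = sc$dose[1], timepoint = tp, readout = rd,
        n_wells = nrow(sc),
        pct_of_baseline_mean = mean(sc$pct_of_baseline),
        pct_sd = sd(sc$pct_of_baseline),
        pct_of_ntc_mean = mean(sc$pct_of_ntc),
        p_adj = p, stars = if (is.na(p)) NA_character_ else p_stars(p),
        stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, report)

  out <- list(per_field = per_field, well_summary = ws,
              well_percent = wp, report = report, qc = qc,
              alignments = aligns, config_hash = hash)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("per_field", "well_summary", "well_percent", "report",
                 "qc", "alignments")) {
      df <- out[[nm]]
      df$config_hash <- rep(hash, nrow(df))
      write.csv(df, file.path(cfg$out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
    }
  }
  out
}

#' Summarize a finished screening run
#'
#' Reads the CSV outputs of [screen_plate()] from a results directory and
#' returns per-condition percent-of-baseline tables plus QC summaries
#' (alignment scores, thresholds, well CVs). Optionally draws a simple
#' dose-response plot to PDF.
#'
#' @param results_dir directory holding `report.csv` etc.
#' @param plot_file optional PDF path for a percent-of-baseline plot.
#' @return list `report`, `qc`, `alignment_summary`, `threshold_summary`,
#'   `well_cv`.
#' @export
report_screen <- function(results_dir, plot_file = NULL) {
  rp <- file.path(results_dir, "report.csv")
  if (!dir.exists(results_dir) || !file.exists(rp))
    stop("no screening results found in ", results_dir)
  report <- read.csv(rp, stringsAsFactors = FALSE)
  qc <- read.csv(file.path(results_dir, "qc.csv"),
                 stringsAsFactors = FALSE)
  al <- read.csv(file.path(results_dir, "alignments.csv"),
                 stringsAsFactors = FALSE)
  pf <- read.csv(file.path(results_dir, "per_field.csv"),
                 stringsAsFactors = FALSE)
  ws <- read.csv(file.path(results_dir, "well_summary.csv"),
                 stringsAsFactors = FALSE)
  alsum <- data.frame(min_score = min(al$score), mean_score = mean(al$score),
                      max_abs_shift = max(abs(c(al$shift_dy, al$shift_dx))))
  thr <- pf[is.finite(pf$threshold), ]
  thrsum <- aggregate(threshold ~ readout + timepoint, data = thr, FUN = mean)
  wcv <- ws[is.finite(ws$sd) & ws$mean > 0, ]
  wcv <- aggregate(cbind(cv = wcv$sd / wcv$mean),
                   by = list(timepoint = wcv$timepoint,
                             readout = wcv$readout), FUN = mean)
  if (!is.null(plot_file)) {
    grDevices::pdf(plot_file, width = 6, height = 4)
    on.exit(grDevices::dev.off())
    sub <- report[report$readout == "coloc", ]
    graphics::barplot(sub$pct_of_baseline_mean,
                      names.arg = sub$condition, las = 2,
                      ylab = "% of baseline (coloc)")
  }
  list(report = report, qc = qc, alignment_summary = alsum,
       threshold_summary = thrsum, well_cv = wcv)
}
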