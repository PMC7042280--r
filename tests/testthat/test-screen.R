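tiny_layout <- function() {
  wells <- data.frame(well = c("A01", "A02", "B01", "B02"),
                      condition = c("glut", "glut", "NTC", "NTC"),
                      dose = c(25, 25, NA, NA),
                      dose_unit = c("uM", "uM", NA, NA),
                      role = c("TREATED", "TREATED", "NTC", "NTC"))
  plate_layout(wells, sites_per_well = 2,
               timepoints = c("baseline", "24h"))
}

make_dataset <- function(dir, seed = 3) {
  simulate_plate(tiny_layout(),
                 function(cond, dose) glutamate_effect(dose),
                 spec = field_spec(width_px = 128L, height_px = 128L),
                 seed = seed, dir = dir)
}

test_that("screen_plate runs the pipeline end-to-end and writes tables", {
  dir <- withr::local_tempdir()
  out <- withr::local_tempdir()
  man <- make_dataset(dir)
  expect_identical(nrow(man), 4L * 2L * 2L * 2L)
  expect_true(file.exists(file.path(dir, "provenance.yaml")))

  cfg <- run_config(dataset_dir = dir, layout = tiny_layout(),
                    out_dir = out, pixel_size_um = 0.35)
  res <- screen_plate(cfg)

  # per-field table: 4 wells x 2 sites x 2 timepoints x 3 readouts
  expect_identical(nrow(res$per_field), 48L)
  expect_identical(nrow(res$qc), 0L)
  expect_setequal(unique(res$per_field$readout), c("pre", "post", "coloc"))

  # recovered stage shifts match the generator's manifest
  man24 <- unique(man[man$timepoint == "24h",
                      c("well", "site", "shift_dy", "shift_dx")])
  al24 <- res$alignments[res$alignments$timepoint == "24h", ]
  m <- merge(man24, al24, by = c("well", "site"))
  dev <- pmax(abs(m$shift_dy.x - m$shift_dy.y),
              abs(m$shift_dx.x - m$shift_dx.y))
  expect_true(all(dev <= 1))          # heavy-loss sites may be off by 1 px
  expect_gte(sum(dev == 0), 6L)

  # report: condition x timepoint x readout rows with consistent stars
  rep <- res$report
  expect_identical(nrow(rep), 2L * 1L * 3L)
  expect_true(all(rep$p_adj[rep$condition == "NTC"] == 1))
  ok <- is.finite(rep$p_adj)
  expect_identical(rep$stars[ok], p_stars(rep$p_adj[ok]))

  # the 85%-loss condition shows strong colocalized synapse loss
  glut <- rep[rep$condition == "glut" & rep$readout == "coloc", ]
  ntc <- rep[rep$condition == "NTC" & rep$readout == "coloc", ]
  expect_lt(glut$pct_of_baseline_mean, 40)
  expect_gt(ntc$pct_of_baseline_mean, 85)
  expect_lt(glut$p_adj, 0.05)

  # outputs on disk with the config hash stamped
  for (f in c("per_field", "well_summary", "well_percent", "report",
              "qc", "alignments"))
    expect_true(file.exists(file.path(out, paste0(f, ".csv"))))
  pf <- read.csv(file.path(out, "per_field.csv"))
  expect_true(all(pf$config_hash == res$config_hash))
})

test_that("screening a dataset twice is deterministic", {
  dir <- withr::local_tempdir()
  make_dataset(dir)
  cfg <- run_config(dataset_dir = dir, layout = tiny_layout())
  r1 <- screen_plate(cfg)
  r2 <- screen_plate(cfg)
  expect_identical(r1$per_field, r2$per_field)
  expect_identical(r1$report, r2$report)
})

test_that("report_screen summarizes results and rejects empty dirs", {
  dir <- withr::local_tempdir()
  out <- withr::local_tempdir()
  make_dataset(dir)
  cfg <- run_config(dataset_dir = dir, layout = tiny_layout(),
                    out_dir = out)
  screen_plate(cfg)
  rep <- report_screen(out)
  expect_true(all(c("report", "qc", "alignment_summary",
                    "threshold_summary", "well_cv") %in% names(rep)))
  expect_gte(rep$alignment_summary$min_score, 0.5)
  expect_error(report_screen(withr::local_tempdir()), "no screening")
})

test_that("run_config round-trips through YAML", {
  dir <- withr::local_tempdir()
  cfg <- run_config(dataset_dir = "data", layout = tiny_layout(),
                    detection = detection_params(threshold_method = "OTSU"),
                    max_shift_px = 12, seed = 9)
  path <- file.path(dir, "config.yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_identical(back$detection$threshold_method, "OTSU")
  expect_identical(back$max_shift_px, 12L)
  expect_identical(back$seed, 9L)
  lay <- read_plate_layout(back$layout)
  expect_equal(lay$wells, tiny_layout()$wells)
})

test_that("missing images surface as QC exclusions, not crashes", {
  dir <- withr::local_tempdir()
  make_dataset(dir)
  # remove one site's follow-up image
  unlink(file.path(dir, field_filename("A01", 1, "24h", "PRE")))
  cfg <- run_config(dataset_dir = dir, layout = tiny_layout())
  res <- suppressWarnings(screen_plate(cfg))   # fewer-sites warning expected
  expect_identical(nrow(res$qc), 1L)
  expect_match(res$qc$reason, "missing image")
  expect_identical(res$qc$well, "A01")
  # remaining sites still analyzed
  expect_identical(nrow(res$per_field), 42L)
})
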