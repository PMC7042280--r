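small_spec <- function(seed, ...) {
  field_spec(width_px = 128L, height_px = 128L, seed = seed, ...)
}

test_that("generation is bit-deterministic in the seed", {
  a <- generate_field(small_spec(5))
  b <- generate_field(small_spec(5))
  expect_identical(a$pre$pixels, b$pre$pixels)
  expect_identical(a$post$pixels, b$post$pixels)
  expect_identical(a$truth, b$truth)
  c <- generate_field(small_spec(6))
  expect_false(identical(a$pre$pixels, c$pre$pixels))
})

test_that("zero presynaptic density leaves only background structure", {
  f <- generate_field(small_spec(2, density_pre = 0))
  expect_identical(nrow(f$truth$pre_centroids), 0L)
  expect_identical(nrow(f$truth$coloc_pairs), 0L)
  expect_gt(sd(f$pre$pixels), 0)     # noise and stroma still present
})

test_that("puncta counts follow Poisson(density x area)", {
  # expected count 300 on a 1e4 um^2 field at 0.03/um^2
  sp <- field_spec(width_px = 286L, height_px = 286L, pixel_size_um = 0.35,
                   density_post = 0.005, seed = 1)
  area <- sp$width_px * sp$height_px * sp$pixel_size_um^2
  mu <- 0.03 * area
  expect_equal(mu, 300, tolerance = 0.01)
  counts <- vapply(1:8, function(s) {
    sp$seed <- s
    nrow(synaptoscreen:::build_scene(sp)$pre)
  }, numeric(1))
  expect_true(all(abs(counts - mu) < 4 * sqrt(mu)))
  expect_lt(abs(mean(counts) - mu), 2.5 * sqrt(mu / 8))
})

test_that("colocalized and free puncta respect the placement geometry", {
  for (s in 1:4) {
    f <- generate_field(small_spec(s))
    tr <- f$truth
    h <- 128; w <- 128
    all_xy <- rbind(as.matrix(tr$pre_centroids[, c("row", "col")]),
                    as.matrix(tr$post_centroids[, c("row", "col")]))
    expect_true(all(all_xy >= 0 & all_xy <= h - 1))  # fully inside

    sp <- small_spec(s)
    pre <- tr$pre_centroids; post <- tr$post_centroids
    if (nrow(tr$coloc_pairs)) {
      d <- sqrt((pre$row[tr$coloc_pairs$pre_id] -
                 post$row[tr$coloc_pairs$post_id])^2 +
                (pre$col[tr$coloc_pairs$pre_id] -
                 post$col[tr$coloc_pairs$post_id])^2)
      expect_true(all(d <= sp$coloc_radius_px + 1e-9))
    }
    free <- setdiff(post$id, tr$coloc_pairs$post_id)
    if (length(free) && nrow(pre)) {
      dmin <- vapply(free, function(i)
        min(sqrt((pre$row - post$row[i])^2 + (pre$col - post$col[i])^2)),
        numeric(1))
      expect_true(all(dmin >= sp$min_sep_px - 1e-9))
      expect_true(all(dmin >= 2 * max(sp$punctum_radius_px)))
    }
  }
})

test_that("infeasible packing is rejected with a diagnostic", {
  expect_error(
    generate_field(field_spec(width_px = 48L, height_px = 48L,
                              density_pre = 2, min_sep_px = 6, seed = 1)),
    "infeasible")
})

test_that("timepoint pairs apply loss, joint coloc removal, and rigid shift", {
  # zero loss, zero shift: identical ground truth, fresh noise
  tp <- generate_timepoint_pair(small_spec(3))
  expect_equal(tp$truth$baseline$pre_centroids,
               tp$truth$followup$pre_centroids)
  expect_false(identical(tp$baseline$pre$pixels, tp$followup$pre$pixels))

  # heavy postsynaptic loss: survivors binomial around 0.2 x baseline
  surv <- vapply(1:6, function(s) {
    tp <- generate_timepoint_pair(small_spec(s), loss_post = 0.8)
    c(nrow(tp$truth$followup$post_centroids),
      nrow(tp$truth$baseline$post_centroids))
  }, numeric(2))
  p_hat <- sum(surv[1, ]) / sum(surv[2, ])
  se <- sqrt(0.2 * 0.8 / sum(surv[2, ]))
  expect_lt(abs(p_hat - 0.2), 4 * se)

  # colocalized pre puncta are removed jointly with their post partner
  tp <- generate_timepoint_pair(small_spec(4), loss_post = 0.9)
  base <- tp$truth$baseline; fol <- tp$truth$followup
  surv_post <- fol$post_centroids$id
  for (k in seq_len(nrow(base$coloc_pairs))) {
    pre_id <- base$coloc_pairs$pre_id[k]
    post_id <- base$coloc_pairs$post_id[k]
    expect_identical(pre_id %in% fol$pre_centroids$id,
                     post_id %in% surv_post)
  }

  # exact rigid translation of every surviving centroid
  tp <- generate_timepoint_pair(small_spec(5), shift_px = c(3L, -2L))
  b <- tp$truth$baseline$pre_centroids
  f <- tp$truth$followup$pre_centroids
  expect_equal(f$row, b$row[match(f$id, b$id)] + 3)
  expect_equal(f$col, b$col[match(f$id, b$id)] - 2)

  expect_error(generate_timepoint_pair(small_spec(1),
                                       shift_px = c(128L, 0L)), "shift")
  expect_error(generate_timepoint_pair(small_spec(1), loss_post = 1.2))
})

test_that("generate_plate writes the full dataset with a faithful manifest", {
  dir <- withr::local_tempdir()
  wells <- data.frame(well = c("A01", "B01"), condition = c("glut", "NTC"),
                      dose = c(25, NA), dose_unit = c("uM", NA),
                      role = c("TREATED", "NTC"))
  layout <- plate_layout(wells, sites_per_well = 2,
                         timepoints = c("baseline", "24h"))
  spec <- field_spec(width_px = 96L, height_px = 96L)
  man <- generate_plate(layout, list(glut = c(loss_pre = 0.5,
                                              loss_post = 0.6)),
                        spec, seed = 7, dir = dir)
  # 2 wells x 2 sites x 2 timepoints x 2 channels
  tifs <- list.files(dir, pattern = "\\.tif$")
  expect_identical(length(tifs), 16L)
  expect_identical(nrow(man), 16L)
  expect_true(all(file.exists(file.path(dir, man$path))))
  expect_true(all(man$loss_applied[man$well == "B01"] == 0))
  expect_true(all(man$loss_applied[man$well == "A01" &
                                   man$timepoint == "24h" &
                                   man$channel == "POST"] == 0.6))
  expect_true(all(man$shift_dy[man$timepoint == "baseline"] == 0))

  # same seed reproduces the manifest byte-for-byte
  dir2 <- withr::local_tempdir()
  generate_plate(layout, list(glut = c(loss_pre = 0.5, loss_post = 0.6)),
                 spec, seed = 7, dir = dir2)
  expect_identical(readLines(file.path(dir, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
})

test_that("glutamate preset encodes the reported dose-response tiers", {
  expect_equal(glutamate_effect(2500)[["loss_post"]], 0.85)
  expect_equal(glutamate_effect(25)[["loss_post"]], 0.85)
  expect_equal(glutamate_effect(2.5)[["loss_post"]], 0.6)
  expect_equal(glutamate_effect(0.25)[["loss_post"]], 0.2)
  expect_equal(glutamate_effect(0.025)[["loss_post"]], 0.2)
  expect_lte(glutamate_effect(0.0025)[["loss_post"]], 0.05)
  expect_equal(glutamate_effect(NA)[["loss_post"]], 0)
  # presynaptic loss is milder than postsynaptic at every dose
  for (d in c(2500, 2.5, 0.25, 0.0025))
    expect_lt(glutamate_effect(d)[["loss_pre"]],
              glutamate_effect(d)[["loss_post"]] + 1e-12)
  lay <- glutamate_layout()
  expect_identical(sum(lay$wells$role == "NTC"), 3L)
  expect_identical(nrow(lay$wells), 24L)
})
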