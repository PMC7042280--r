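test_that("flatten_background removes smooth structure, keeps spots", {
  expect_equal(flatten_background(matrix(37, 40, 40), 5),
               matrix(0, 40, 40))

  # bright 3x3 spot on constant background survives at its contrast
  img <- matrix(10, 21, 21); img[10:12, 10:12] <- 110
  out <- flatten_background(img, 5)
  expect_equal(out[11, 11], 100)
  expect_equal(max(out[img == 10]), 0)

  # shallow ramp: opening residual bounded by slope x kernel width
  slope <- 0.5
  ramp <- matrix(rep(slope * (0:39), each = 40), 40, 40)
  out <- flatten_background(ramp, 5)
  expect_lte(max(out), slope * (2 * 5 + 1))

  expect_error(flatten_background(matrix(1, 10, 10), 20), "larger")
})

test_that("no-neighbors deconvolution removes haze, keeps high frequency", {
  cc <- matrix(200, 48, 48)
  expect_equal(deconvolve_no_neighbors(cc, 10, 0.97, TRUE),
               matrix(0.03 * 200, 48, 48), tolerance = 1e-6)
  x <- matrix(runif(48 * 48, 10, 20), 48, 48)
  expect_equal(deconvolve_no_neighbors(x, 10, 0, FALSE), x)

  # isolated Gaussian spot on an offset: peak-to-background ratio grows
  g <- outer(-15:15, -15:15, function(r, c) exp(-(r^2 + c^2) / (2 * 1.5^2)))
  img <- 50 + 100 * g
  pad <- matrix(50, 64, 64); pad[17:47, 17:47] <- img
  out <- deconvolve_no_neighbors(pad, 10, 0.97, FALSE)
  ratio_in <- max(pad) / pad[1, 1]
  ratio_out <- max(out) / max(out[1, 1], 1e-9)
  expect_gt(ratio_out, ratio_in)
})

test_that("white top-hat passes small structures and levels large ones", {
  expect_equal(tophat(matrix(5, 20, 20), 50), matrix(0, 20, 20))

  img <- matrix(0, 15, 15); img[7, 7:8] <- 9   # 2-px dot
  out <- tophat(img, 50)
  expect_equal(out[7, 7:8], c(9, 9))

  img <- matrix(0, 40, 40); img[6:35, 6:35] <- 100  # 30x30 square
  out <- tophat(img, 49)
  expect_equal(max(out[10:31, 10:31]), 0)   # interior reconstructed
})

test_that("contrast enhancement saturates the prescribed pixel fraction", {
  # image already spanning [0, 1] with no saturation requested: unchanged
  img <- matrix(seq(0, 1, length.out = 64), 8, 8)
  expect_equal(enhance_contrast(img, saturated_fraction = 0), img)

  two <- matrix(c(10, 20), 10, 10)
  out <- enhance_contrast(two, 0.3)
  expect_identical(sort(unique(as.numeric(out))), c(0, 1))

  ramp <- matrix(seq_len(1000), 40, 25)
  out <- enhance_contrast(ramp, 0.3)     # ceiling(1.5) = 2 clipped per end
  lo_anchor <- max(ramp[out == 0])       # anchor itself maps to exactly 0
  hi_anchor <- min(ramp[out == 1])
  expect_identical(sum(ramp < lo_anchor), 2L)
  expect_identical(sum(ramp > hi_anchor), 2L)
  # monotone among non-clipped pixels
  mid <- out > 0 & out < 1
  expect_true(all(diff(out[mid][order(ramp[mid])]) > 0))

  expect_error(enhance_contrast(matrix(3, 5, 5), 0.3), "degenerate")
})

test_that("maximum-entropy threshold matches its exhaustive oracle", {
  half <- matrix(c(rep(0, 50), rep(255, 50)), 10, 10)
  th <- threshold_maxentropy(half)
  expect_identical(th$mask, half == 255)

  for (s in 1:10) {
    img <- random_test_image(s)
    expect_identical(threshold_maxentropy(img)$bin, oracle_kapur_bin(img))
  }

  set.seed(42)
  mix <- matrix(c(rnorm(2048, 50, 10), rnorm(2048, 200, 10)), 64, 64)
  th <- threshold_maxentropy(mix)
  truth <- matrix(c(rep(FALSE, 2048), rep(TRUE, 2048)), 64, 64)
  expect_gte(mean(th$mask == truth), 0.99)

  expect_error(threshold_maxentropy(matrix(9, 5, 5)), "degenerate")
})

test_that("Otsu threshold matches its exhaustive oracle", {
  two <- matrix(c(rep(10, 60), rep(200, 40)), 10, 10)
  th <- threshold_otsu(two)
  expect_identical(th$mask, two == 200)

  for (s in 1:10) {
    img <- random_test_image(s + 50)
    expect_identical(threshold_otsu(img)$bin, oracle_otsu_bin(img))
  }

  set.seed(43)
  mix <- matrix(c(rnorm(2000, 50, 10), rnorm(2096, 200, 10)), 64, 64)
  truth <- matrix(c(rep(FALSE, 2000), rep(TRUE, 2096)), 64, 64)
  expect_gte(mean(threshold_otsu(mix)$mask == truth), 0.99)
})

test_that("detect_puncta applies the inclusive 2-50 px size filter", {
  expect_identical(detect_puncta(matrix(0, 10, 10))$n, 0L)

  # components of areas 1, 2, 50, 51: only 2 and 50 survive
  m <- matrix(0, 30, 40)
  m[2, 2] <- 1                       # area 1
  m[5, 5:6] <- 1                     # area 2
  m[10:14, 10:19] <- 1               # area 50
  m[20:22, 20:36] <- 1               # area 51
  ps <- detect_puncta(m, 2, 50)
  expect_identical(ps$n, 2L)
  expect_identical(sort(ps$puncta$area_px), c(2L, 50L))

  # labels are consecutive in raster order with exact centroids
  expect_identical(ps$puncta$id, 1:2)
  expect_equal(ps$puncta$centroid_row[1], 4)   # 0-based
  expect_equal(ps$puncta$centroid_col[1], 4.5)
})

test_that("component labeling agrees with a flood-fill oracle", {
  for (s in 1:10) {
    set.seed(s)
    m <- matrix(runif(40 * 40) < 0.35, 40, 40)
    for (conn in c(4L, 8L)) {
      mine <- detect_puncta(m, 2, 50, connectivity = conn)
      orc <- oracle_particles(m, 2, 50, conn)
      expect_identical(mine$n, orc$n)
      expect_identical(sort(mine$puncta$area_px), orc$areas)
      # full labeling agrees up to numbering
      lab <- label_components(m, conn)
      ref <- oracle_flood_fill(m, conn)
      expect_identical(max(lab), max(ref))
      # both row-major first-occurrence orders: identical partitions
      expect_identical(lab, ref)
    }
  }
})

test_that("the full chain detects generated puncta with high fidelity", {
  f <- generate_field(field_spec(seed = 11))
  for (ch in c("pre", "post")) {
    ps <- run_detection(f[[ch]])
    truth <- f$truth[[paste0(ch, "_centroids")]]
    m <- match_puncta(truth, ps)
    expect_gte(m$recall, 0.9)
    expect_gte(m$precision, 0.9)
    expect_true(all(ps$puncta$area_px >= 2 & ps$puncta$area_px <= 50))
    expect_lte(ps$n, sum(ps$label_mask > 0) / 2)
    expect_false(is.null(ps$provenance$threshold))
  }
})

test_that("detection counts are empty on blank fields", {
  zeros <- vapply(1:4, function(s) {
    f <- generate_field(field_spec(seed = 300 + s, density_pre = 0,
                                   density_post = 0, n_somata = 0L))
    run_detection(f$pre)$n
  }, integer(1))
  expect_true(all(zeros == 0L))
})

test_that("the final mask is invariant to positive intensity scaling", {
  f <- generate_field(field_spec(width_px = 160L, height_px = 160L,
                                 seed = 21))
  base <- run_detection(f$pre$pixels)
  for (c in c(0.5, 2.5)) {
    scaled <- run_detection(f$pre$pixels * c)
    expect_identical(scaled$label_mask, base$label_mask)
    expect_identical(scaled$n, base$n)
  }
})

test_that("detected counts fall in proportion to applied loss", {
  ratios <- vapply(c(0, 0.3, 0.6, 0.9), function(l) {
    tp <- generate_timepoint_pair(field_spec(seed = 42), loss_pre = l,
                                  decouple = TRUE, channels = "PRE")
    run_detection(tp$followup$pre)$n / run_detection(tp$baseline$pre)$n
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))                # monotone
  expect_true(all(abs(ratios - c(1, 0.7, 0.4, 0.1)) < 0.15))
})
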