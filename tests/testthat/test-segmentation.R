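cfg <- segmentation_config()

test_that("background flattening restores constants and removes slow ramps", {
  expect_true(all(flatten_background(matrix(150, 50, 50)) == 90))
  expect_true(all(flatten_background(matrix(40, 30, 30)) == 90))
  # adding a slow ramp changes nothing beyond quantization-scale error
  set.seed(1)
  base <- matrix(runif(80 * 80, 100, 140), 80, 80)
  ramp <- outer(seq(0, 8, length.out = 80), rep(1, 80))
  f1 <- flatten_background(base, cfg)
  f2 <- flatten_background(base + ramp, cfg)
  expect_lt(max(abs(f1 - f2)), 1.5)
  expect_error(flatten_background(matrix(1, 3, 3),
                                  segmentation_config(flatten_kernel_px = 9)),
               "kernel")
})

test_that("flattening reduces background spread on a gradient scene", {
  sc <- scene_spec(image_size_px = 200, colonies = list(),
                   background_gradient_amplitude = 30, noise_sd = 2, seed = 5)
  img <- render_scene(sc)$image
  expect_lt(stats::sd(flatten_background(img, cfg)), stats::sd(img))
})

test_that("noise reduction removes components strictly below 2046 px and is idempotent", {
  m <- matrix(FALSE, 300, 300)
  m[1:10, 1:10] <- TRUE                  # 100 px speck
  expect_equal(sum(reduce_noise(m, cfg)), 0)
  m2 <- matrix(FALSE, 300, 300)
  m2[1:33, 1:62] <- TRUE                 # exactly 2046 px
  expect_equal(sum(reduce_noise(m2, cfg)), 2046)
  m3 <- matrix(FALSE, 400, 400)
  m3[1:20, 1:25] <- TRUE                 # 500
  m3[100:129, 100:199] <- TRUE           # 3000
  m3[200:399, 201:400] <- TRUE           # 40000
  out <- reduce_noise(m3, cfg)
  expect_equal(sum(out), 3000 + 40000)
  expect_identical(reduce_noise(out, cfg), out)
})

test_that("8-connected foreground survives noise reduction as one object", {
  # diagonal chain: one 8-connected component, many 4-connected ones
  m <- matrix(FALSE, 3000, 3000)
  for (i in 1:2500) m[i, i] <- TRUE
  m[1:45, 1:45] <- TRUE  # make it 2025 + rest of diagonal
  expect_gt(sum(reduce_noise(m, cfg)), 0)
})

test_that("object filling closes small holes only, and bookkeeping is exact", {
  disk <- matrix(FALSE, 120, 120)
  idx <- expand.grid(r = 1:120, c = 1:120)
  disk[as.matrix(idx[(idx$r - 60)^2 + (idx$c - 60)^2 <= 45^2, ])] <- TRUE
  small <- disk; small[58:60, 58:62] <- FALSE       # 15-px hole
  filled <- fill_objects(small, cfg)
  expect_identical(filled, disk)
  big <- disk
  big[40:75, 40:55] <- FALSE                        # 576-px hole
  expect_identical(fill_objects(big, cfg), big)
  # area increases exactly by the filled hole area; never decreases
  expect_equal(sum(filled) - sum(small), 15)
  expect_true(all(filled | !small))
})

test_that("colony extraction applies the strict 30000-px gate in raster order", {
  m <- matrix(FALSE, 700, 700)
  m[2:151, 2:201] <- TRUE        # 30000 exactly -> excluded
  expect_equal(nrow(extract_colonies(m, cfg)), 0)
  m2 <- matrix(FALSE, 700, 700)
  m2[2:201, 2:201] <- TRUE       # 40000
  m2[300:499, 350:549] <- TRUE   # 40000
  out <- extract_colonies(m2, cfg, image_id = "im")
  expect_equal(nrow(out), 2)
  expect_equal(out$area_px, c(40000, 40000))
  expect_equal(out$label, 1:2)
  # raster-scan order: first pixel of component 1 comes first reading rowwise
  expect_lt(out$centroid_row[1], out$centroid_row[2])
  expect_equal(nrow(extract_colonies(matrix(FALSE, 10, 10), cfg)), 0)
  # manual cleansing by exclusion list
  expect_equal(extract_colonies(m2, cfg, exclude_labels = 1L)$label, 2L)
})

test_that("maturity gate uses the strict 1 mm equivalent-diameter rule", {
  mk <- function(area) tibble::tibble(
    image_id = "x", label = 1L, area_px = area, centroid_row = 1,
    centroid_col = 1, border_touch = FALSE, pixels = list(integer(0)),
    dim = list(c(10L, 10L)))
  # the 1 mm boundary at 2 um/px is pi * 250^2 = 196349.5 px: one pixel
  # below is excluded, one pixel above clears the strict inequality
  expect_equal(nrow(select_mature(mk(196349), 2, cfg)), 0)
  expect_equal(nrow(select_mature(mk(196350), 2, cfg)), 1)
  out <- select_mature(mk(250000), 2, cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$equivalent_diameter_um, 2 * sqrt(250000 * 4 / pi),
               tolerance = 1e-10)
  expect_equal(nrow(select_mature(mk(196350)[0, ], 2, cfg)), 0)
})

test_that("texture training selects the best of the candidate patterns", {
  tr1 <- training_scene(21, "esc_like", 0.05, 0.1, 60, 12, noise_sd = 0,
                        debris = 0)
  img <- flatten_background(tr1$image, cfg)
  msk <- tr1$truth$label_image > 0
  mdl <- train_texture_model(img, msk, n_candidates = 5, seed = 2,
                             n_pixels_per_class = 1500)
  expect_gte(max(mdl$training_report$heldout_accuracy), 0.99)
  expect_equal(which(mdl$training_report$selected),
               which.max(mdl$training_report$heldout_accuracy))
  # single candidate = the plain full fit
  m1 <- train_texture_model(img, msk, n_candidates = 1, seed = 2,
                            n_pixels_per_class = 1500)
  expect_equal(nrow(m1$training_report), 1)
  expect_length(m1$feature_names, 7)
  # inverted masks flip the decision, accuracy is symmetric
  minv <- train_texture_model(img, !msk, n_candidates = 1, seed = 2,
                              n_pixels_per_class = 1500)
  expect_gte(max(minv$training_report$heldout_accuracy), 0.99)
  expect_error(train_texture_model(img, msk & FALSE, seed = 1),
               "both foreground and background")
})

test_that("recognition reproduces ground truth on clean fixtures and round-trips via JSON", {
  mdl <- fixture_model()
  te <- training_scene(31, "esc_like", 0.05, 0.1, 60, 12)
  flat <- flatten_background(te$image, cfg)
  mask <- recognize(flat, mdl)
  gt <- te$truth$label_image > 0
  expect_gte(sum(mask & gt) / sum(mask | gt), 0.9)
  # empty scene: nothing survives noise reduction
  empty <- render_scene(scene_spec(image_size_px = 300, colonies = list(),
                                   debris_count = 3, noise_sd = 4, seed = 8))
  m_empty <- reduce_noise(recognize(flatten_background(empty$image, cfg), mdl),
                          cfg)
  expect_equal(sum(m_empty), 0)
  # persisted model predicts identically
  tmp <- withr::local_tempfile(fileext = ".json")
  write_texture_model(mdl, tmp)
  mdl2 <- read_texture_model(tmp)
  expect_equal(recognize(flat, mdl2), mask)
})

test_that("the full pipeline finds exactly one colony with accurate area on clean scenes", {
  mdl <- fixture_model()
  bench <- make_two_population_benchmark(1, effect = 1, seed = 44,
                                         debris_count = 0)
  for (i in 1:2) {
    col <- segment_image(bench$image[[i]], mdl, cfg,
                         image_id = bench$scene_id[i])
    expect_equal(nrow(col), 1)
    gt_area <- sum(bench$truth[[i]]$label_image > 0)
    expect_lt(abs(col$area_px - gt_area) / gt_area, 0.05)
  }
})

test_that("increasing the size gate never increases the colony count", {
  m <- matrix(FALSE, 700, 700)
  m[2:201, 2:201] <- TRUE
  m[300:479, 350:529] <- TRUE  # 32400
  n1 <- nrow(extract_colonies(m, segmentation_config(colony_min_px = 30000)))
  n2 <- nrow(extract_colonies(m, segmentation_config(colony_min_px = 35000)))
  n3 <- nrow(extract_colonies(m, segmentation_config(colony_min_px = 50000)))
  expect_true(n1 >= n2 && n2 >= n3)
})
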