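cfg <- segmentation_config()

# a filled shape from a radial function r(theta), centred in a frame
radial_mask <- function(n, r_fun) {
  ctr <- (n + 1) / 2
  dr <- outer(seq_len(n) - ctr, rep(1, n))
  dc <- t(dr)
  rad <- sqrt(dr^2 + dc^2)
  rad <= r_fun(atan2(dc, dr))
}

mask_to_colony <- function(mask, id = "m") {
  tibble::tibble(image_id = id, label = 1L, area_px = sum(mask),
                 centroid_row = 0, centroid_col = 0, border_touch = FALSE,
                 pixels = list(which(mask)), dim = list(dim(mask)))
}

test_that("the canonical panel has 120 parameters in three families", {
  reg <- morph_parameters()
  expect_equal(nrow(reg), 120)
  expect_setequal(unique(reg$family), c("volume", "shape", "frequency"))
  expect_equal(anyDuplicated(reg$parameter), 0)
})

test_that("a discretized disk is recognised as circular, solid and spectrally flat", {
  mask <- radial_mask(260, function(th) 110)
  prof <- compute_profiles(mask_to_colony(mask), matrix(100, 260, 260))
  expect_gte(prof$circularity, 0.95)
  expect_lte(prof$circularity, 1.05)
  expect_gte(prof$solidity, 0.98)
  expect_lt(prof$high_band_energy, 0.005)
  expect_equal(prof$fibrous_point_count, 0)
  expect_equal(prof$eccentricity, 0, tolerance = 0.05)
  expect_equal(prof$mean_radius_px, 110, tolerance = 2)
})

test_that("shape and frequency families ignore intensity; volume intensities scale", {
  set.seed(2)
  mask <- radial_mask(200, function(th) 80 * (1 + 0.1 * cos(3 * th)))
  img <- matrix(runif(200 * 200, 50, 120), 200, 200)
  col <- mask_to_colony(mask)
  p1 <- compute_profiles(col, img)
  p2 <- compute_profiles(col, img * 2)
  reg <- morph_parameters()
  geom <- reg$parameter[reg$family %in% c("shape", "frequency")]
  expect_equal(as.numeric(p1[1, geom]), as.numeric(p2[1, geom]),
               tolerance = 1e-12)
  expect_equal(p2$interior_mean_intensity, 2 * p1$interior_mean_intensity,
               tolerance = 1e-12)
  expect_equal(p2$integrated_intensity, 2 * p1$integrated_intensity,
               tolerance = 1e-12)
})

test_that("spiky outlines score higher on fibrous points and lower on circularity", {
  disk <- radial_mask(300, function(th) 100)
  star <- radial_mask(300, function(th) 100 * (1 + 0.3 * cos(8 * th)))
  img <- matrix(100, 300, 300)
  pd <- compute_profiles(mask_to_colony(disk), img)
  ps <- compute_profiles(mask_to_colony(star), img)
  expect_gt(ps$fibrous_point_count, pd$fibrous_point_count)
  expect_equal(ps$fibrous_point_count, 8)
  expect_lt(ps$circularity, pd$circularity)
  expect_gt(ps$fibrous_score, pd$fibrous_score)
  expect_gt(ps$harmonic_amp_8, 0.25)
  expect_lt(pd$harmonic_amp_8, 0.01)
})

test_that("every parameter is exactly invariant under 180-degree rotation", {
  sc <- scene_spec(image_size_px = 700,
                   colonies = list(colony_spec(c(350, 350), 260,
                                               edge_irregularity = 0.25,
                                               fibrousness = 1.5,
                                               morph_class = "collapsed_edge")),
                   noise_sd = 0, background_gradient_amplitude = 10, seed = 9)
  out <- render_scene(sc)
  mask <- out$truth$label_image > 0
  p1 <- compute_profiles(extract_colonies(mask, cfg, "a"), out$image)
  rot_mask <- mask[700:1, 700:1]
  rot_img <- out$image[700:1, 700:1]
  p2 <- compute_profiles(extract_colonies(rot_mask, cfg, "a"), rot_img)
  pc <- parameter_columns(p1)
  expect_equal(as.numeric(p1[1, pc]), as.numeric(p2[1, pc]),
               tolerance = 1e-9)
})

test_that("border-touching colonies are flagged", {
  mask <- matrix(FALSE, 300, 300)
  mask[1:200, 50:250] <- TRUE
  col <- extract_colonies(mask, cfg, "b")
  expect_true(col$border_touch)
  prof <- compute_profiles(col, matrix(80, 300, 300))
  expect_true(prof$border_touch)
})

test_that("exact duplicates and known correlation structures are filtered correctly", {
  set.seed(7)
  n <- 40
  base <- rnorm(n)
  # pair (p1, p2) at r = 1 (duplicate); (p3, p4) correlated > 0.98;
  # (p5, p6) correlated ~ 0.97 -> both kept
  p3 <- rnorm(n)
  p4 <- p3 + rnorm(n, 0, sqrt(1 / 0.99^2 - 1) * sd(p3))
  p5 <- rnorm(n)
  p6 <- 0.97 * p5 + sqrt(1 - 0.97^2) * rnorm(n)
  stopifnot(abs(cor(p3, p4)) > 0.98, abs(cor(p5, p6)) < 0.98)
  prof <- tibble::tibble(a1 = base, a2 = base, a3 = p3, a4 = p4,
                         a5 = p5, a6 = p6)
  rep <- filter_correlated(prof)
  expect_setequal(rep$kept, c("a1", "a3", "a5", "a6"))
  expect_equal(
    rep$dropped_correlated$representative[rep$dropped_correlated$dropped == "a2"],
    "a1")
  # all pairwise |r| <= 0.5 -> identity
  low <- tibble::as_tibble(matrix(rnorm(40 * 3), 40,
                                  dimnames = list(NULL, c("x", "y", "z"))))
  expect_equal(filter_correlated(low)$kept, c("x", "y", "z"))
  # zero-variance parameter never triggers the correlation filter
  prof$const <- 5
  expect_true("const" %in% filter_correlated(prof)$kept)
})

test_that("the greedy correlation filter matches exhaustive evaluation", {
  set.seed(11)
  for (rep_i in 1:20) {
    k <- sample(4:8, 1)
    X <- matrix(rnorm(30 * k), 30)
    # inject some near-duplicates
    for (j in seq_len(k)) if (runif(1) < 0.4 && j > 1)
      X[, j] <- X[, j - 1] + rnorm(30, 0, 0.05 * sd(X[, j - 1]))
    colnames(X) <- paste0("p", seq_len(k))
    prof <- tibble::as_tibble(X)
    got <- filter_correlated(prof, r_max = 0.98)$kept
    # oracle: literal greedy over the correlation matrix
    cm <- abs(cor(X))
    kept <- character(0)
    for (p in colnames(X)) {
      if (!length(kept) || all(cm[p, kept] <= 0.98)) kept <- c(kept, p)
    }
    expect_identical(got, kept)
  }
})

test_that("the CV filter drops high-CV parameters and is scale invariant", {
  set.seed(3)
  n <- 60
  mk_col <- function(mean, sd) mean + sd * scale(rnorm(n))[, 1]
  prof <- tibble::tibble(high = mk_col(10, 4),   # CV 40 -> dropped
                         low = mk_col(10, 2),    # CV 20 -> kept
                         const = rep(5, n),      # CV 0  -> kept
                         zero = scale(rnorm(n))[, 1])  # mean 0 -> dropped
  rep <- filter_high_cv(prof)
  expect_setequal(rep$kept, c("low", "const"))
  expect_setequal(rep$dropped_high_cv$dropped, c("high", "zero"))
  # positive rescaling changes nothing
  prof2 <- dplyr::mutate(prof, high = high * 17.3, low = low * 0.002)
  expect_identical(filter_high_cv(prof2)$kept, rep$kept)
})

test_that("the composed filter runs correlation then CV and is idempotent", {
  set.seed(5)
  n <- 50
  a <- rnorm(n, 10, 1)
  prof <- tibble::tibble(a = a, b = a * 1.0001 + rnorm(n, 0, 1e-4),
                         noisy = rnorm(n, 10, 5),
                         good = rnorm(n, 20, 2))
  rep <- select_parameters(prof)
  expect_setequal(rep$kept, c("a", "good"))
  expect_equal(rep$dropped_correlated$dropped, "b")
  expect_equal(rep$dropped_high_cv$dropped, "noisy")
  sub <- apply_filter(prof, rep)
  rep2 <- select_parameters(sub)
  expect_identical(rep2$kept, rep$kept)
  expect_equal(nrow(tidy(rep)), 4)
})
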