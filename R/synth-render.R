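# Scene rendering.
#
# All randomness of a scene (boundary harmonics, spike placement, interior
# texture, debris, pixel noise) is drawn from a stream seeded by the scene
# seed, in a fixed order, so an identical spec renders bit-identically.
# Pixel noise is drawn last: the 180-degree re-imaging variant re-uses the
# deterministic noiseless core and then draws its noise from the same stream
# position, emulating re-acquisition of the rotated plate.

# rendering constants (8-bit intensity units)
.render_const <- list(
  background_level = 120,   # mean illumination
  interior_depth   = 25,    # interior sits this far below local background
  rim_width_px     = 5,     # halo band width inside the boundary
  debris_gain      = 80,    # debris brightness above background
  max_occlusion    = 0.25   # rejected above this per-colony occluded fraction
)

#' Minimum guaranteed foreground contrast of a rendered colony
#'
#' In a noise-free render every colony pixel differs from the local
#' background by at least this amount: the interior sits `interior_depth`
#' below background with bounded uniform texture of half-range
#' `sqrt(3) * interior_texture_sd`, and the rim sits `halo_strength` above.
#'
#' @param cspec a [colony_spec()].
#' @return scalar minimum absolute contrast in intensity units.
#' @export
min_contrast <- function(cspec) {
  interior <- .render_const$interior_depth - sqrt(3) * cspec$interior_texture_sd
  min(interior, cspec$halo_strength)
}

# Draw the boundary randomness for one colony from the current RNG stream
# and return a vectorised radius function r(theta).
# r(theta) = r0 * (1 + sum_{k=2..6} a_k cos(k theta + phi_k)) + spikes
# with sum(a_k) = edge_irregularity; fibrousness adds sparse narrow
# Gaussian bumps in angle (outward protrusions -> high-curvature points).
boundary_radius_fun <- function(cspec) {
  r0 <- cspec$base_radius_px
  ks <- 2:6
  w <- stats::runif(length(ks), 0.3, 1)
  a <- cspec$edge_irregularity * w / sum(w)
  phi <- stats::runif(length(ks), 0, 2 * pi)
  fib <- min(cspec$fibrousness, 3)
  n_spikes <- if (fib > 0) 3L + as.integer(round(5 * fib)) else 0L
  sp_theta <- if (n_spikes > 0) stats::runif(n_spikes, 0, 2 * pi) else numeric(0)
  sp_amp <- 0.08 * fib * r0
  sp_width <- 0.06  # radians
  function(theta) {
    r <- rep(r0, length(theta))
    for (i in seq_along(ks))
      r <- r + r0 * a[i] * cos(ks[i] * theta + phi[i])
    for (t0 in sp_theta) {
      d <- abs(theta - t0)
      d <- pmin(d, 2 * pi - d)
      r <- r + sp_amp * exp(-d^2 / (2 * sp_width^2))
    }
    r
  }
}

# Deterministic per-colony seed for the boundary randomness. Boundary
# geometry is a property of the colony spec (and its position in the list),
# not of the scene seed: re-imaging the same colonies with another seed
# redraws noise, texture and debris but never the ground-truth outlines.
colony_boundary_seed <- function(cs, i) {
  v <- round(c(i, cs$center_px, cs$base_radius_px,
               cs$edge_irregularity, cs$fibrousness) * 1e4)
  as.integer(sum(v * c(1000003, 7919, 104729, 31, 193, 389)) %% 2147483647L)
}

# Noiseless render: background + colonies + debris, plus ground truth.
render_core <- function(spec) {
  nr <- spec$image_size_px[1]; nc <- spec$image_size_px[2]
  cst <- .render_const
  # boundary geometry first, from per-colony seeds (seed-invariant truth)
  rfuns <- lapply(seq_along(spec$colonies), function(i) {
    set.seed(colony_boundary_seed(spec$colonies[[i]], i))
    boundary_radius_fun(spec$colonies[[i]])
  })
  set.seed(spec$seed)
  # smooth planar illumination gradient with a random orientation
  alpha <- stats::runif(1, 0, 2 * pi)
  gx <- (seq_len(nr) - (nr + 1) / 2) / max(nr, 1)
  gy <- (seq_len(nc) - (nc + 1) / 2) / max(nc, 1)
  bg <- cst$background_level +
    spec$background_gradient_amplitude * (cos(alpha) * outer(gx, rep(1, nc)) +
                                          sin(alpha) * outer(rep(1, nr), gy))
  img <- bg
  lab <- matrix(0L, nr, nc)
  n_own <- integer(length(spec$colonies))
  for (i in seq_along(spec$colonies)) {
    cs <- spec$colonies[[i]]
    rfun <- rfuns[[i]]
    rmax <- max(rfun(seq(0, 2 * pi, length.out = 720)))
    cr <- cs$center_px[1]; cc <- cs$center_px[2]
    i1 <- max(1L, floor(cr - rmax)); i2 <- min(nr, ceiling(cr + rmax))
    j1 <- max(1L, floor(cc - rmax)); j2 <- min(nc, ceiling(cc + rmax))
    if (i1 > i2 || j1 > j2) next
    dr <- (i1:i2) - cr; dc <- (j1:j2) - cc
    DR <- outer(dr, rep(1, length(dc))); DC <- outer(rep(1, length(dr)), dc)
    rad <- sqrt(DR^2 + DC^2)
    rb <- matrix(rfun(atan2(DC, DR)), nrow(rad), ncol(rad))
    inside <- rad <= rb
    n_in <- sum(inside)
    n_own[i] <- n_in
    if (n_in == 0) next
    # interior texture: bounded uniform with the requested SD
    half <- sqrt(3) * cs$interior_texture_sd
    tex <- stats::runif(n_in, -half, half)
    sub_bg <- bg[i1:i2, j1:j2, drop = FALSE]
    sub_img <- img[i1:i2, j1:j2, drop = FALSE]
    val <- sub_bg[inside] - cst$interior_depth + tex
    rim <- rad >= rb - cst$rim_width_px & inside
    sub_img[inside] <- val
    sub_img[rim] <- sub_bg[rim] + cs$halo_strength
    img[i1:i2, j1:j2] <- sub_img
    sub_lab <- lab[i1:i2, j1:j2, drop = FALSE]
    sub_lab[inside] <- i
    lab[i1:i2, j1:j2] <- sub_lab
  }
  # occlusion check: later colonies overwrite earlier ones
  if (length(spec$colonies)) {
    vis <- tabulate(lab[lab > 0L], nbins = length(spec$colonies))
    occ <- ifelse(n_own > 0, 1 - vis / n_own, 0)
    bad <- which(occ > cst$max_occlusion)
    if (length(bad))
      stop(sprintf("colony %d is occluded by later colonies beyond the %.0f%% limit (%.0f%% hidden)",
                   bad[1], 100 * cst$max_occlusion, 100 * occ[bad[1]]),
           call. = FALSE)
  }
  # debris: small bright specks on background only, below the noise gate
  if (spec$debris_count > 0) {
    for (d in seq_len(spec$debris_count)) {
      ctr <- c(stats::runif(1, 1, nr), stats::runif(1, 1, nc))
      rd <- stats::runif(1, 1.5, 5)
      i1 <- max(1L, floor(ctr[1] - rd)); i2 <- min(nr, ceiling(ctr[1] + rd))
      j1 <- max(1L, floor(ctr[2] - rd)); j2 <- min(nc, ceiling(ctr[2] + rd))
      dr <- (i1:i2) - ctr[1]; dc <- (j1:j2) - ctr[2]
      hit <- outer(dr^2, rep(1, length(dc))) + outer(rep(1, length(dr)), dc^2) <= rd^2
      hit <- hit & lab[i1:i2, j1:j2, drop = FALSE] == 0L
      sub <- img[i1:i2, j1:j2, drop = FALSE]
      sub[hit] <- bg[i1:i2, j1:j2, drop = FALSE][hit] + cst$debris_gain
      img[i1:i2, j1:j2] <- sub
    }
  }
  # consecutive labels for colonies actually visible in frame
  keep <- which(tabulate(lab[lab > 0L], nbins = max(1L, length(spec$colonies))) > 0)
  remap <- integer(length(spec$colonies))
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  classes <- vapply(spec$colonies[keep], `[[`, character(1), "morph_class")
  names(classes) <- as.character(seq_along(keep))
  truth <- structure(
    list(label_image = lab,
         class_of_label = classes,
         specs = spec$colonies[keep]),
    class = "ground_truth")
  list(image = img, truth = truth)
}

quantize_8bit <- function(img) {
  img <- round(img)
  img[img < 0] <- 0; img[img > 255] <- 255
  img
}

#' Render a synthetic phase-contrast scene
#'
#' Renders the scene described by a [scene_spec()]: smooth background
#' gradient, colonies (bright rim halo, darker textured interior), debris
#' specks, additive Gaussian noise and 8-bit quantisation. Returns the image
#' together with its ground truth (label raster, class map, colony specs).
#' Overlap is tolerated up to a 25% per-colony occluded fraction; beyond
#' that the spec is rejected with a diagnostic.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (numeric matrix, 0-255) and `truth`
#'   (`ground_truth`: `label_image`, `class_of_label`, `specs`).
#' @examples
#' sc <- scene_spec(image_size_px = 200, colonies = list(
#'   colony_spec(c(100, 100), 60)), noise_sd = 2, seed = 7)
#' out <- render_scene(sc)
#' range(out$image)
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  core <- render_core(spec)
  img <- core$image
  if (spec$noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
  list(image = quantize_8bit(img), truth = core$truth)
}

rot180 <- function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]

#' Render the same scene after a 180-degree plate rotation
#'
#' Emulates physically rotating the culture vessel and re-imaging: the
#' deterministic scene content is rotated 180 degrees and pixel noise is
#' drawn fresh, so colony geometry (and ground truth, up to the rotation
#' map) is identical while the pixel noise realisation is not.
#'
#' @param spec a [scene_spec()].
#' @param half_turn if `FALSE`, identical to [render_scene()].
#' @return as [render_scene()].
#' @export
render_rotated <- function(spec, half_turn = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!half_turn) return(render_scene(spec))
  core <- render_core(spec)
  img <- rot180(core$image)
  if (spec$noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
  truth <- core$truth
  truth$label_image <- rot180(truth$label_image)
  list(image = quantize_8bit(img), truth = truth)
}

#' Generate a balanced two-morphology benchmark
#'
#' Produces `2 * n_per_class` single-colony scenes alternating between the
#' healthy round phenotype (`esc_like`) and the unstable collapsed-edge
#' phenotype, with `effect` scaling the between-class separation in edge
#' irregularity, fibrousness, halo strength and interior texture. At
#' `effect = 0` the two generative arms coincide (only the class label
#' differs). Colonies are drawn large enough to pass the maturity gate
#' (>1 mm equivalent diameter at 2 um/px).
#'
#' @param n_per_class scenes per class (>= 1).
#' @param effect separation scale (>= 0); 1 is the calibrated benchmark.
#' @param seed integer seed.
#' @param image_size_px tile size (default 768).
#' @param debris_count debris specks per scene (default 3).
#' @param noise_sd pixel noise SD (default 4).
#' @return tibble with columns `scene_id`, `morph_class`, `spec`, `image`,
#'   `truth` (the last three are list-columns).
#' @export
make_two_population_benchmark <- function(n_per_class, effect = 1, seed = 1L,
                                          image_size_px = 856,
                                          debris_count = 3, noise_sd = 4) {
  stopifnot(n_per_class >= 1, effect >= 0)
  set.seed(seed)
  n <- 2L * as.integer(n_per_class)
  classes <- rep(c("esc_like", "collapsed_edge"), n_per_class)
  scene_seeds <- sample.int(.Machine$integer.max - 1L, n)
  mid <- image_size_px / 2
  rows <- lapply(seq_len(n), function(i) {
    # size is a controlled nuisance: tight radius band keeps the contrast
    # morphological, and the worst-case outline (full harmonic excursion
    # plus spikes) still clears the tile border
    r0 <- stats::runif(1, 255, 280)
    ctr <- mid + stats::runif(2, -8, 8)
    irr <- stats::runif(1, 0.03, 0.08)
    fib <- stats::runif(1, 0, 0.3)
    halo <- 60; tex <- 12
    if (classes[i] == "collapsed_edge") {
      irr <- irr + effect * 0.22
      fib <- fib + effect * 1.4
      halo <- max(5, halo - effect * 30)
      tex <- max(2, tex - effect * 3)
    }
    cs <- colony_spec(ctr, r0, edge_irregularity = min(irr, 1),
                      fibrousness = fib, halo_strength = halo,
                      interior_texture_sd = tex, morph_class = classes[i],
                      check_floor = FALSE)
    scene_spec(image_size_px = image_size_px, colonies = list(cs),
               debris_count = debris_count, noise_sd = noise_sd,
               seed = scene_seeds[i])
  })
  rendered <- lapply(rows, render_scene)
  tibble::tibble(
    scene_id = sprintf("scene_%03d", seq_len(n)),
    morph_class = classes,
    spec = rows,
    image = lapply(rendered, `[[`, "image"),
    truth = lapply(rendered, `[[`, "truth"))
}

#' Write a rendered scene to disk
#'
#' Writes the 8-bit grayscale image as PNG, the ground-truth label raster as
#' an 8-bit grayscale PNG (supporting up to 255 colonies per tile), and a
#' sidecar tab-separated table of per-label class and generative parameters.
#'
#' @param rendered list with `image` and `truth` as returned by
#'   [render_scene()].
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
write_scene <- function(rendered, dir, prefix = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(prefix, ".png"))
  lab_path <- file.path(dir, paste0(prefix, "_labels.png"))
  tab_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
  png::writePNG(rendered$image / 255, img_path)
  lab <- rendered$truth$label_image
  if (max(lab) > 255)
    stop("label raster has more than 255 colonies; PNG export is 8-bit",
         call. = FALSE)
  storage.mode(lab) <- "double"
  png::writePNG(lab / 255, lab_path)
  specs <- rendered$truth$specs
  tab <- tibble::tibble(
    label = seq_along(specs),
    morph_class = unname(rendered$truth$class_of_label),
    center_row = vapply(specs, function(s) s$center_px[1], numeric(1)),
    center_col = vapply(specs, function(s) s$center_px[2], numeric(1)),
    base_radius_px = vapply(specs, `[[`, numeric(1), "base_radius_px"),
    edge_irregularity = vapply(specs, `[[`, numeric(1), "edge_irregularity"),
    fibrousness = vapply(specs, `[[`, numeric(1), "fibrousness"),
    halo_strength = vapply(specs, `[[`, numeric(1), "halo_strength"),
    interior_texture_sd = vapply(specs, `[[`, numeric(1), "interior_texture_sd"))
  utils::write.table(tab, tab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(image = img_path, labels = lab_path, truth = tab_path))
}

#' Read an 8-bit grayscale PNG as an intensity matrix (0-255)
#' @param path PNG file path.
#' @return numeric matrix on the 0-255 scale.
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x * 255
}
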