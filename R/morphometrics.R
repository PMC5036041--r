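# Morphometric description of a colony: a 120-parameter panel organised in
# three families.
#
#   volume    -- size and intensity measures (areas, axes, interior and
#                rim-band intensities, texture magnitudes)
#   shape     -- dimensionless outline descriptors (circularity, solidity,
#                convexity, eccentricity, ...)
#   frequency -- boundary-spectrum descriptors from an equal-arclength
#                radius series: per-harmonic amplitudes, band energies
#                (outline waviness = low-harmonic energy; fibrous points =
#                high-harmonic energy plus curvature-peak count) and
#                boundary-curvature statistics
#
# The boundary is the traced outer contour, resampled to 256 equal-arclength
# points anchored at the boundary point farthest from the centroid (so the
# sampling is equivariant under image rotation whenever that point is
# unique), lightly smoothed, and described by the radius-about-centroid
# series and its discrete Fourier magnitudes. All parameters are
# translation invariant; shape and frequency parameters are intensity
# invariant; everything is exactly invariant under 180-degree rotation up to
# the anchoring tie-break.

N_CONTOUR <- 256L
CURV_PEAK_THRESHOLD <- 3  # dimensionless curvature (disk == 1)

#' The canonical morphometric parameter registry
#'
#' @return tibble with columns `parameter` and `family`
#'   (`volume`/`shape`/`frequency`), in canonical order; 120 rows.
#' @export
morph_parameters <- function() {
  volume <- c(
    "area_px", "perimeter_px", "equivalent_diameter_px",
    "convex_area_px", "convex_perimeter_px",
    "bbox_height_px", "bbox_width_px",
    "major_axis_px", "minor_axis_px",
    "mean_radius_px", "sd_radius_px", "max_radius_px", "min_radius_px",
    "integrated_intensity",
    "interior_mean_intensity", "interior_sd_intensity",
    "interior_median_intensity", "interior_q10_intensity",
    "interior_q25_intensity", "interior_q75_intensity",
    "interior_q90_intensity", "interior_iqr_intensity",
    "interior_mad_intensity",
    "rim_mean_intensity_w4", "rim_mean_intensity_w8", "rim_mean_intensity_w16",
    "rim_sd_intensity_w4", "rim_sd_intensity_w8", "rim_sd_intensity_w16",
    "rim_contrast_w4", "rim_contrast_w8", "rim_contrast_w16",
    "core_mean_intensity",
    "texture_sd_scale5", "texture_sd_scale11",
    "texture_grad_mean", "boundary_grad_mean", "interior_skewness")
  shape <- c(
    "circularity", "solidity", "convexity", "eccentricity", "extent",
    "aspect_ratio", "elongation", "radius_cv", "radius_span",
    "compactness", "convex_circularity", "equiv_diameter_ratio")
  frequency <- c(
    paste0("harmonic_amp_", 2:60),
    "outline_waviness", "mid_band_energy", "high_band_energy",
    "fibrous_point_count", "fibrous_score",
    "curvature_mean", "curvature_sd", "curvature_max", "curvature_min",
    "curvature_abs_mean", "spectral_centroid")
  tibble::tibble(
    parameter = c(volume, shape, frequency),
    family = c(rep("volume", length(volume)),
               rep("shape", length(shape)),
               rep("frequency", length(frequency))))
}

# --- boundary machinery ---------------------------------------------------

# traced outer contour of a single-object mask, as an n x 2 matrix of
# (row, col) boundary-pixel centres in traversal order
trace_contour <- function(mask) {
  lab <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  oc <- EBImage::ocontour(lab)
  pts <- oc[[1]] + 1  # 0-based -> 1-based
  colnames(pts) <- c("row", "col")
  pts
}

# closed-polygon resampling at n equal arclengths, anchored at the vertex
# farthest from `center` (ties: first in traversal order)
resample_contour <- function(pts, center, n = N_CONTOUR) {
  d2 <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2
  a <- which.max(d2)
  m <- nrow(pts)
  ord <- c(a:m, seq_len(a - 1))
  p <- pts[ord, , drop = FALSE]
  p <- rbind(p, p[1, ])  # close
  seg <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  if (L == 0) return(matrix(rep(p[1, ], n), n, 2, byrow = TRUE))
  s <- seq(0, L, length.out = n + 1)[-(n + 1)]
  r_out <- stats::approx(cum, p[, 1], xout = s, ties = "ordered")$y
  c_out <- stats::approx(cum, p[, 2], xout = s, ties = "ordered")$y
  cbind(r_out, c_out)
}

# circular moving average, window 3
smooth_closed <- function(x) {
  n <- length(x)
  (x + x[c(n, 1:(n - 1))] + x[c(2:n, 1)]) / 3
}

# discrete curvature of a closed curve, scaled by mean radius so a circle
# has dimensionless curvature 1
closed_curvature <- function(p, r_bar) {
  n <- nrow(p)
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  x <- p[, 1]; y <- p[, 2]
  dx <- (x[ip] - x[im]) / 2; dy <- (y[ip] - y[im]) / 2
  ddx <- x[ip] - 2 * x + x[im]; ddy <- y[ip] - 2 * y + y[im]
  denom <- (dx^2 + dy^2)^1.5
  k <- ifelse(denom > 0, (dx * ddy - dy * ddx) / denom, 0)
  k * r_bar
}

count_peaks <- function(x, threshold) {
  n <- length(x)
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  sum(x > threshold & x >= x[im] & x >= x[ip] & x > x[im])  # strict on one side: plateaus counted once-ish
}

polygon_area <- function(p) {
  n <- nrow(p)
  ip <- c(2:n, 1)
  abs(sum(p[, 1] * p[ip, 2] - p[ip, 1] * p[, 2])) / 2
}
polygon_perimeter <- function(p) {
  n <- nrow(p)
  ip <- c(2:n, 1)
  sum(sqrt((p[ip, 1] - p[, 1])^2 + (p[ip, 2] - p[, 2])^2))
}

# binary erosion by a (2w+1)-sided box
erode_box <- function(mask, w) {
  if (w <= 0) return(mask)
  box_min(mask * 1, 2L * w + 1L) >= 1
}

# --- the profile ----------------------------------------------------------

#' Compute the morphometric profile of one colony
#'
#' Evaluates the canonical 120-parameter panel (see [morph_parameters()])
#' for a single colony mask and its source image.
#'
#' @param colony a one-row colony tibble (from [extract_colonies()]) or any
#'   list with `pixels` (linear indices) and `dim` entries.
#' @param image the grayscale source image (0-255 matrix).
#' @return named numeric vector of length 120 in canonical order, with a
#'   `border_touch` attribute.
#' @export
compute_profile <- function(colony, image) {
  px <- colony$pixels[[1]]; dm <- colony$dim[[1]]
  stopifnot(all(dim(image) == dm))
  nr <- dm[1]
  r <- ((px - 1L) %% nr) + 1L
  c <- ((px - 1L) %/% nr) + 1L
  border <- any(r == 1L | r == nr | c == 1L | c == dm[2])
  # work on a padded crop for the geometric parts
  pad <- 2L
  r0 <- min(r) - pad; c0 <- min(c) - pad
  mh <- max(r) - min(r) + 1L + 2L * pad
  mw <- max(c) - min(c) + 1L + 2L * pad
  mask <- matrix(FALSE, mh, mw)
  mask[cbind(r - r0 + 1L, c - c0 + 1L)] <- TRUE
  ctr <- c(mean(r - r0 + 1L), mean(c - c0 + 1L))

  area <- length(px)
  pts <- trace_contour(mask)
  rs <- resample_contour(pts, ctr)
  sm <- cbind(smooth_closed(rs[, 1]), smooth_closed(rs[, 2]))
  # curvature needs a slightly coarser scale: pixel staircase on small
  # colonies otherwise leaves spurious curvature peaks
  smc <- cbind(smooth_closed(sm[, 1]), smooth_closed(sm[, 2]))
  rad <- sqrt((sm[, 1] - ctr[1])^2 + (sm[, 2] - ctr[2])^2)
  r_bar <- mean(rad)
  perim <- polygon_perimeter(sm)
  hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  conv_area <- polygon_area(hull)
  conv_perim <- polygon_perimeter(hull)
  bbox_h <- diff(range(r)) + 1; bbox_w <- diff(range(c)) + 1
  # second moments of the pixel set
  cv <- stats::cov(cbind(r, c)) * (area - 1) / area
  ev <- eigen(cv, symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])

  # Fourier spectrum of the radius series, amplitudes relative to the mean
  # radius; harmonic k describes k-fold outline undulation
  co <- stats::fft(rad) / length(rad)
  amp <- 2 * Mod(co[2:(length(rad) / 2)]) / r_bar  # k = 1 .. 127
  harm <- function(k) amp[k]
  band <- function(k1, k2) sqrt(sum(harm(k1:k2)^2))
  waviness <- band(2, 8)
  mid_band <- band(9, 15)
  high_band <- band(16, 64)
  curv <- closed_curvature(smc, r_bar)
  n_peaks <- count_peaks(curv, CURV_PEAK_THRESHOLD)
  spec_cent <- {
    k <- seq_along(amp)
    e <- amp^2
    if (sum(e) > 0) sum(k * e) / sum(e) else 0
  }

  # intensity measures on the full frame
  vals <- image[px]
  mu <- mean(vals); sdv <- stats::sd(vals)
  qs <- stats::quantile(vals, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  rim_stats <- function(w) {
    er <- erode_box(mask, w)
    band_px <- which(mask & !er)
    if (!length(band_px)) return(c(mu, 0))
    rr <- ((band_px - 1L) %% mh) + 1L + r0 - 1L
    cc <- ((band_px - 1L) %/% mh) + 1L + c0 - 1L
    v <- image[cbind(rr, cc)]
    c(mean(v), if (length(v) > 1) stats::sd(v) else 0)
  }
  rim4 <- rim_stats(4L); rim8 <- rim_stats(8L); rim16 <- rim_stats(16L)
  core <- erode_box(mask, 16L)
  core_px <- which(core)
  core_mean <- if (length(core_px)) {
    rr <- ((core_px - 1L) %% mh) + 1L + r0 - 1L
    cc <- ((core_px - 1L) %/% mh) + 1L + c0 - 1L
    mean(image[cbind(rr, cc)])
  } else mu
  # local texture magnitudes over the colony footprint
  crop <- image[pmin(pmax((min(r) - pad):(max(r) + pad), 1L), nr),
                pmin(pmax((min(c) - pad):(max(c) + pad), 1L), dm[2]),
                drop = FALSE]
  in_crop <- which(mask)
  tex5 <- box_mean(crop^2, 5L) - box_mean(crop, 5L)^2
  tex11 <- box_mean(crop^2, 11L) - box_mean(crop, 11L)^2
  g <- grad_mag(crop)
  er4 <- erode_box(mask, 4L)
  band4 <- which(mask & !er4)
  skew <- if (sdv > 0) mean(((vals - mu) / sdv)^3) else 0

  out <- c(
    area_px = area, perimeter_px = perim,
    equivalent_diameter_px = 2 * sqrt(area / pi),
    convex_area_px = conv_area, convex_perimeter_px = conv_perim,
    bbox_height_px = bbox_h, bbox_width_px = bbox_w,
    major_axis_px = major, minor_axis_px = minor,
    mean_radius_px = r_bar, sd_radius_px = stats::sd(rad),
    max_radius_px = max(rad), min_radius_px = min(rad),
    integrated_intensity = sum(vals),
    interior_mean_intensity = mu, interior_sd_intensity = sdv,
    interior_median_intensity = qs[3], interior_q10_intensity = qs[1],
    interior_q25_intensity = qs[2], interior_q75_intensity = qs[4],
    interior_q90_intensity = qs[5], interior_iqr_intensity = qs[4] - qs[2],
    interior_mad_intensity = stats::mad(vals),
    rim_mean_intensity_w4 = rim4[1], rim_mean_intensity_w8 = rim8[1],
    rim_mean_intensity_w16 = rim16[1],
    rim_sd_intensity_w4 = rim4[2], rim_sd_intensity_w8 = rim8[2],
    rim_sd_intensity_w16 = rim16[2],
    rim_contrast_w4 = rim4[1] - mu, rim_contrast_w8 = rim8[1] - mu,
    rim_contrast_w16 = rim16[1] - mu,
    core_mean_intensity = core_mean,
    texture_sd_scale5 = mean(sqrt(pmax(tex5[in_crop], 0))),
    texture_sd_scale11 = mean(sqrt(pmax(tex11[in_crop], 0))),
    texture_grad_mean = mean(g[in_crop]),
    boundary_grad_mean = if (length(band4)) mean(g[band4]) else 0,
    interior_skewness = skew,
    circularity = 4 * pi * area / perim^2,
    solidity = area / conv_area,
    convexity = conv_perim / perim,
    eccentricity = if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0,
    extent = area / (bbox_h * bbox_w),
    aspect_ratio = if (minor > 0) major / minor else 1,
    elongation = if (major > 0) 1 - minor / major else 0,
    radius_cv = stats::sd(rad) / r_bar,
    radius_span = (max(rad) - min(rad)) / r_bar,
    compactness = perim^2 / area,
    convex_circularity = 4 * pi * conv_area / conv_perim^2,
    equiv_diameter_ratio = if (major > 0) 2 * sqrt(area / pi) / major else 1)
  hk <- harm(2:60)
  names(hk) <- paste0("harmonic_amp_", 2:60)
  out <- c(out, hk,
           outline_waviness = waviness, mid_band_energy = mid_band,
           high_band_energy = high_band,
           fibrous_point_count = n_peaks,
           fibrous_score = high_band + n_peaks / 32,
           curvature_mean = mean(curv), curvature_sd = stats::sd(curv),
           curvature_max = max(curv), curvature_min = min(curv),
           curvature_abs_mean = mean(abs(curv)),
           spectral_centroid = spec_cent)
  stopifnot(identical(names(out), morph_parameters()$parameter))
  attr(out, "border_touch") <- border
  out
}

#' Profile every colony of a segmentation table
#'
#' @param colonies colony tibble (see [extract_colonies()]); may span
#'   several images.
#' @param images a single grayscale matrix, or a named list of matrices
#'   keyed by `image_id`.
#' @return tibble with `colony_id`, `image_id`, `label`, `border_touch` and
#'   the 120 canonical parameter columns.
#' @export
compute_profiles <- function(colonies, images) {
  if (is.matrix(images)) {
    ids <- unique(colonies$image_id)
    stopifnot(length(ids) <= 1)
    images <- stats::setNames(list(images), if (length(ids)) ids else "image")
  }
  rows <- lapply(seq_len(nrow(colonies)), function(i) {
    cl <- colonies[i, ]
    prof <- compute_profile(cl, images[[cl$image_id]])
    tibble::tibble(colony_id = sprintf("%s_c%02d", cl$image_id, cl$label),
                   image_id = cl$image_id, label = cl$label,
                   border_touch = attr(prof, "border_touch"),
                   !!!as.list(prof))
  })
  dplyr::bind_rows(rows)
}

# meta columns that are never treated as morphometric parameters
.meta_cols <- c("colony_id", "image_id", "label", "border_touch",
                "centroid_row", "centroid_col", "equivalent_diameter_um",
                "scene_id", "morph_class", "line_id", "cluster")

# parameter columns of a profile tibble, in canonical order where known
parameter_columns <- function(profiles) {
  num <- names(profiles)[vapply(profiles, is.numeric, logical(1))]
  cand <- setdiff(num, .meta_cols)
  reg <- morph_parameters()$parameter
  if (all(cand %in% reg)) reg[reg %in% cand] else cand
}
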