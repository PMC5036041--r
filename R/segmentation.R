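# Colony recognition: the six-step pipeline from raw grayscale image to
# size-gated colony objects.
#
#   1. background flattening (local morphological background, restored to a
#      fixed grey level)
#   2. texture-trained per-pixel recognition   (see texture-model.R)
#   3. noise reduction  (drop components < 2046 px)
#   4. object filling   (fill enclosed holes <= 30 px)
#   5. manual cleansing (an exclusion list of labels, never automated)
#   6. size gate        (> 30000 px), then an optional maturity gate
#      (> 1 mm equivalent diameter)

#' Segmentation configuration
#'
#' Defaults follow the pipeline's reference settings: a 7-px flattening
#' kernel restored to grey level 90, a 2046-px noise-reduction area
#' threshold (components strictly smaller are removed), 30-px hole filling,
#' a strict 30000-px colony size gate and a 1 mm maturity diameter.
#'
#' @param flatten_kernel_px side of the square structuring element for
#'   background estimation.
#' @param flatten_grey grey level the flattened background is restored to.
#' @param noise_min_px smallest component area that survives noise reduction.
#' @param fill_hole_px largest enclosed-hole area that gets filled.
#' @param colony_min_px colony size gate (strict `>`).
#' @param mature_min_diameter_um maturity gate on equivalent-circle diameter
#'   (strict `>`), in micrometres.
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(flatten_kernel_px = 7, flatten_grey = 90,
                                noise_min_px = 2046, fill_hole_px = 30,
                                colony_min_px = 30000,
                                mature_min_diameter_um = 1000) {
  stopifnot(flatten_kernel_px > 0, flatten_grey >= 0,
            noise_min_px > 0, fill_hole_px > 0, colony_min_px > 0,
            mature_min_diameter_um > 0,
            fill_hole_px < noise_min_px, noise_min_px < colony_min_px)
  structure(list(flatten_kernel_px = as.integer(flatten_kernel_px),
                 flatten_grey = as.numeric(flatten_grey),
                 noise_min_px = as.integer(noise_min_px),
                 fill_hole_px = as.integer(fill_hole_px),
                 colony_min_px = as.integer(colony_min_px),
                 mature_min_diameter_um = as.numeric(mature_min_diameter_um)),
            class = "segmentation_config")
}

# --- separable box min / max filters with edge replication ----------------
# k is the side of the square structuring element; implemented as k shifts
# and pmin/pmax per axis, exact and dependency-free.
shift_rows <- function(m, by) {
  nr <- nrow(m)
  idx <- pmin(pmax(seq_len(nr) - by, 1L), nr)
  m[idx, , drop = FALSE]
}
shift_cols <- function(m, by) {
  nc <- ncol(m)
  idx <- pmin(pmax(seq_len(nc) - by, 1L), nc)
  m[, idx, drop = FALSE]
}
box_extreme <- function(m, k, fun) {
  half <- (k - 1L) %/% 2L
  offs <- (-half):(k - 1L - half)
  acc <- m
  for (o in offs) if (o != 0) acc <- fun(acc, shift_rows(m, o))
  m2 <- acc
  acc <- m2
  for (o in offs) if (o != 0) acc <- fun(acc, shift_cols(m2, o))
  acc
}
box_min <- function(m, k) box_extreme(m, k, pmin)
box_max <- function(m, k) box_extreme(m, k, pmax)

#' Flatten the image background
#'
#' Estimates the local background with a grayscale morphological opening
#' (erosion then dilation with a `flatten_kernel_px`-sided square), subtracts
#' it, and restores the result to the configured grey level, clipped to the
#' 8-bit range. A constant image maps to a constant image at
#' `flatten_grey`; illumination ramps that vary slower than the kernel
#' scale are removed within quantisation.
#'
#' @param image numeric matrix, 0-255 grayscale.
#' @param cfg a [segmentation_config()].
#' @return numeric matrix, same dimensions.
#' @export
flatten_background <- function(image, cfg = segmentation_config()) {
  stopifnot(is.matrix(image))
  k <- cfg$flatten_kernel_px
  if (k > min(dim(image)))
    stop("flattening kernel (", k, " px) larger than the image", call. = FALSE)
  bg <- box_max(box_min(image, k), k)  # grayscale opening
  out <- image - bg + cfg$flatten_grey
  out[out < 0] <- 0; out[out > 255] <- 255
  out
}

label_components <- function(mask, connectivity) {
  storage.mode(mask) <- "logical"
  cc_label(mask, as.integer(connectivity))
}

#' Remove small foreground components
#'
#' Deletes every 8-connected foreground component whose area is strictly
#' smaller than `noise_min_px`; components at or above the threshold are
#' untouched. Idempotent.
#'
#' @param mask logical matrix.
#' @param cfg a [segmentation_config()].
#' @return logical matrix.
#' @export
reduce_noise <- function(mask, cfg = segmentation_config()) {
  lab <- label_components(mask, 8L)
  n <- max(lab)
  if (n == 0) return(mask & FALSE)
  sizes <- cc_sizes(lab, n)
  keep <- sizes >= cfg$noise_min_px
  out <- lab > 0L
  out[lab > 0L] <- keep[lab[lab > 0L]]
  out
}

#' Fill small enclosed holes in foreground objects
#'
#' Background regions (4-connected) fully enclosed by foreground and of area
#' at most `fill_hole_px` are converted to foreground; larger holes and
#' background touching the image border are preserved.
#'
#' @inheritParams reduce_noise
#' @return logical matrix.
#' @export
fill_objects <- function(mask, cfg = segmentation_config()) {
  holes <- !mask
  lab <- label_components(holes, 4L)
  n <- max(lab)
  if (n == 0) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  sizes <- cc_sizes(lab, n)
  fill <- sizes <= cfg$fill_hole_px
  fill[border] <- FALSE
  out <- mask
  sel <- lab > 0L
  out[sel] <- mask[sel] | fill[lab[sel]]
  out
}

#' Extract colony objects from a segmented mask
#'
#' Connected components (8-connected) with area strictly greater than
#' `colony_min_px` become colony records. Labels are assigned in raster-scan
#' order (row-major, top-left origin) of each component's first pixel.
#' Manual cleansing is expressed as `exclude_labels`: the listed labels (as
#' assigned by this function) are dropped from the output, never guessed
#' automatically.
#'
#' @param mask logical matrix (after noise reduction and filling).
#' @param cfg a [segmentation_config()].
#' @param image_id identifier recorded with each colony.
#' @param exclude_labels integer labels to remove (manual cleansing).
#' @return tibble with one row per colony: `image_id`, `label`, `area_px`,
#'   `centroid_row`, `centroid_col`, `border_touch`, and list-columns
#'   `pixels` (linear indices into the frame) and `dim` (frame dimensions).
#' @export
extract_colonies <- function(mask, cfg = segmentation_config(),
                             image_id = "image", exclude_labels = integer(0)) {
  lab <- label_components(mask, 8L)
  n <- max(lab)
  empty <- tibble::tibble(image_id = character(0), label = integer(0),
                          area_px = integer(0), centroid_row = numeric(0),
                          centroid_col = numeric(0), border_touch = logical(0),
                          pixels = list(), dim = list())
  if (n == 0) return(empty)
  sizes <- cc_sizes(lab, n)
  keep <- which(sizes > cfg$colony_min_px)
  if (!length(keep)) return(empty)
  nr <- nrow(lab)
  rows <- lapply(seq_along(keep), function(i) {
    px <- which(lab == keep[i])
    r <- ((px - 1L) %% nr) + 1L
    c <- ((px - 1L) %/% nr) + 1L
    tibble::tibble(image_id = image_id, label = i,
                   area_px = length(px),
                   centroid_row = mean(r), centroid_col = mean(c),
                   border_touch = any(r == 1L | r == nr | c == 1L | c == ncol(lab)),
                   pixels = list(px), dim = list(dim(lab)))
  })
  out <- dplyr::bind_rows(rows)
  if (length(exclude_labels))
    out <- dplyr::filter(out, !.data$label %in% exclude_labels)
  out
}

#' Keep mature colonies
#'
#' Retains colonies whose equivalent-circle diameter
#' \eqn{2\sqrt{A \cdot \mathrm{umpp}^2 / \pi}} strictly exceeds the maturity
#' threshold (default 1 mm): smaller colonies are too young to have a
#' representative morphology.
#'
#' @param colonies tibble from [extract_colonies()].
#' @param um_per_px physical scale.
#' @param cfg a [segmentation_config()].
#' @return the filtered tibble with an added `equivalent_diameter_um` column.
#' @export
select_mature <- function(colonies, um_per_px = 2,
                          cfg = segmentation_config()) {
  stopifnot(um_per_px > 0)
  colonies |>
    dplyr::mutate(equivalent_diameter_um =
                    2 * sqrt(.data$area_px * um_per_px^2 / pi)) |>
    dplyr::filter(.data$equivalent_diameter_um > cfg$mature_min_diameter_um)
}

#' Rebuild a colony's full-frame logical mask
#' @param colony one row of an [extract_colonies()] tibble (or a list with
#'   `pixels` and `dim`).
#' @return logical matrix.
#' @export
colony_mask <- function(colony) {
  px <- colony$pixels[[1]]; dm <- colony$dim[[1]]
  m <- matrix(FALSE, dm[1], dm[2])
  m[px] <- TRUE
  m
}

#' Run the full recognition pipeline on one image
#'
#' Flattening, texture recognition, noise reduction, object filling,
#' size gating with the manual exclusion list, and (optionally) the
#' maturity gate.
#'
#' @param image numeric matrix, 0-255 grayscale.
#' @param model a trained [train_texture_model()] recogniser.
#' @param cfg a [segmentation_config()].
#' @param image_id identifier for the output table.
#' @param um_per_px physical scale used by the maturity gate.
#' @param exclude_labels manual-cleansing label list.
#' @param mature_only apply the maturity gate (default `TRUE`).
#' @return colony tibble (see [extract_colonies()]).
#' @export
segment_image <- function(image, model, cfg = segmentation_config(),
                          image_id = "image", um_per_px = 2,
                          exclude_labels = integer(0), mature_only = TRUE) {
  flat <- flatten_background(image, cfg)
  mask <- recognize(flat, model)
  mask <- reduce_noise(mask, cfg)
  mask <- fill_objects(mask, cfg)
  out <- extract_colonies(mask, cfg, image_id = image_id,
                          exclude_labels = exclude_labels)
  if (mature_only) out <- select_mature(out, um_per_px, cfg)
  out
}
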