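#' Describe a single synthetic colony
#'
#' A colony is modelled as a radius-modulated closed curve around a centre,
#' \deqn{r(\theta) = r_0 (1 + \sum_k a_k \cos(k\theta + \phi_k)) + \mathrm{spikes}(\theta),}
#' where `edge_irregularity` scales the low-harmonic amplitudes (wavy,
#' collapsed outlines) and `fibrousness` controls sparse high-curvature
#' protrusions (fibrous points). With both at zero the boundary is an exact
#' circle. The rendered appearance is a bright phase halo along the rim and
#' a darker, textured interior; colonies with the `collapsed_edge` class are
#' expected to have `edge_irregularity` at or above the documented floor of
#' 0.12 (their defining trait is a visibly collapsed, irregular outline).
#'
#' @param center_px numeric length-2, (row, col) centre in pixels
#'   (0-based raster convention is not used here; centres are 1-based like R
#'   matrix indices).
#' @param base_radius_px base radius \eqn{r_0} in pixels, > 0.
#' @param edge_irregularity dimensionless in \[0, 1\]: amplitude of low-order
#'   boundary harmonics (outline waviness).
#' @param fibrousness dimensionless >= 0: density/amplitude of sparse
#'   high-curvature boundary spikes.
#' @param halo_strength intensity units added along the rim band (8-bit scale).
#' @param interior_texture_sd standard deviation of interior texture
#'   (intensity units; the texture is bounded uniform so the interior never
#'   crosses the background level for default settings).
#' @param morph_class `"esc_like"` (round, sharp halo) or `"collapsed_edge"`
#'   (irregular collapsed outline, weak halo).
#' @param check_floor enforce the collapsed-edge irregularity floor
#'   (default `TRUE`). Generators that interpolate continuously between the
#'   two classes disable the check and keep the generative-arm label.
#' @return an object of class `colony_spec`.
#' @export
colony_spec <- function(center_px, base_radius_px,
                        edge_irregularity = 0.05, fibrousness = 0,
                        halo_strength = 60, interior_texture_sd = 12,
                        morph_class = c("esc_like", "collapsed_edge"),
                        check_floor = TRUE) {
  morph_class <- match.arg(morph_class)
  stopifnot(length(center_px) == 2, is.finite(center_px),
            is.numeric(base_radius_px), base_radius_px > 0,
            edge_irregularity >= 0, edge_irregularity <= 1,
            fibrousness >= 0, halo_strength >= 0, interior_texture_sd >= 0)
  if (check_floor && morph_class == "collapsed_edge" &&
      edge_irregularity < collapsed_edge_floor()) {
    stop("collapsed_edge colonies require edge_irregularity >= ",
         collapsed_edge_floor(), call. = FALSE)
  }
  structure(
    list(center_px = as.numeric(center_px),
         base_radius_px = as.numeric(base_radius_px),
         edge_irregularity = as.numeric(edge_irregularity),
         fibrousness = as.numeric(fibrousness),
         halo_strength = as.numeric(halo_strength),
         interior_texture_sd = as.numeric(interior_texture_sd),
         morph_class = morph_class),
    class = "colony_spec")
}

#' Documented irregularity floor for collapsed-edge colonies
#' @return a scalar, the minimum `edge_irregularity` a colony declared
#'   `collapsed_edge` must have.
#' @export
collapsed_edge_floor <- function() 0.12

#' Describe a synthetic phase-contrast well image
#'
#' The generator emulates the imaging geometry of an automated
#' incubator-microscope: square 8-bit tiles, by default 1000 x 1000 px
#' covering 2000 x 2000 um (2 um/px). The rendered scene is a smooth
#' background gradient plus per-colony optics (bright rim halo, darker
#' textured interior), optional small bright debris specks, additive
#' Gaussian pixel noise and 8-bit quantisation. Identical specs (including
#' the seed) render to bit-identical images and ground truth.
#'
#' @param image_size_px integer pair (rows, cols); a single value is square.
#' @param um_per_px physical scale (default 2 um/px).
#' @param colonies list of [colony_spec()] objects.
#' @param debris_count number of small bright specks (each far below the
#'   noise-reduction area threshold) scattered over background.
#' @param background_gradient_amplitude peak-to-peak amplitude of a smooth
#'   planar illumination gradient (intensity units).
#' @param noise_sd additive Gaussian pixel noise SD (intensity units).
#' @param seed integer seed; all randomness of the scene derives from it.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_size_px = c(1000, 1000), um_per_px = 2,
                       colonies = list(), debris_count = 0,
                       background_gradient_amplitude = 20, noise_sd = 4,
                       seed = 1L) {
  if (length(image_size_px) == 1) image_size_px <- rep(image_size_px, 2)
  stopifnot(length(image_size_px) == 2, all(image_size_px > 0),
            um_per_px > 0, noise_sd >= 0, debris_count >= 0,
            background_gradient_amplitude >= 0)
  if (!all(vapply(colonies, inherits, logical(1), "colony_spec")))
    stop("`colonies` must be a list of colony_spec objects", call. = FALSE)
  structure(
    list(image_size_px = as.integer(round(image_size_px)),
         um_per_px = as.numeric(um_per_px),
         colonies = colonies,
         debris_count = as.integer(debris_count),
         background_gradient_amplitude = as.numeric(background_gradient_amplitude),
         noise_sd = as.numeric(noise_sd),
         seed = as.integer(seed)),
    class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %d x %d px (%.1f um/px), %d colonies, %d debris, noise_sd %.1f, seed %d\n",
              x$image_size_px[1], x$image_size_px[2], x$um_per_px,
              length(x$colonies), x$debris_count, x$noise_sd, x$seed))
  invisible(x)
}

#' @export
print.colony_spec <- function(x, ...) {
  cat(sprintf("<colony_spec> %s at (%.0f, %.0f), r0 %.0f px, irregularity %.2f, fibrousness %.2f\n",
              x$morph_class, x$center_px[1], x$center_px[2],
              x$base_radius_px, x$edge_irregularity, x$fibrousness))
  invisible(x)
}

# JSON (de)serialisation of scene specs, used by the command-line interface.

#' Write / read a scene spec as JSON
#' @param spec a `scene_spec`.
#' @param path file path.
#' @return `read_scene_spec` returns a `scene_spec`; `write_scene_spec`
#'   returns `path` invisibly.
#' @export
write_scene_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  x <- unclass(spec)
  x$colonies <- lapply(spec$colonies, unclass)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  colonies <- lapply(seq_len(NROW(x$colonies)), function(i) {
    ci <- if (is.data.frame(x$colonies)) as.list(x$colonies[i, ]) else x$colonies[[i]]
    colony_spec(center_px = unlist(ci$center_px),
                base_radius_px = ci$base_radius_px,
                edge_irregularity = ci$edge_irregularity,
                fibrousness = ci$fibrousness,
                halo_strength = ci$halo_strength,
                interior_texture_sd = ci$interior_texture_sd,
                morph_class = ci$morph_class,
                check_floor = FALSE)
  })
  scene_spec(image_size_px = unlist(x$image_size_px), um_per_px = x$um_per_px,
             colonies = colonies, debris_count = x$debris_count,
             background_gradient_amplitude = x$background_gradient_amplitude,
             noise_sd = x$noise_sd, seed = x$seed)
}
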