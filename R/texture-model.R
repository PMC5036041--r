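# Texture-trained per-pixel colony recogniser.
#
# The original recogniser in the reference pipeline is a proprietary
# texture-learning step; here it is an openly documented equivalent: a
# fixed per-pixel feature panel (local mean, local SD, smoothed gradient
# magnitude at two window scales, plus a local intensity entropy) feeding a
# logistic pixel classifier. The selection loop is preserved: `n_candidates`
# randomised classifier configurations are fitted and the one with the
# highest held-out pixel accuracy wins (default 50 candidates).

# box mean via integral image with edge replication
box_mean <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  h1 <- (k - 1L) %/% 2L; h2 <- k - 1L - h1
  ri <- pmin(pmax(seq.int(1L - h1, nr + h2), 1L), nr)
  ci <- pmin(pmax(seq.int(1L - h1, nc + h2), 1L), nc)
  p <- m[ri, ci, drop = FALSE]
  s <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed integral image
  s <- t(s)
  s <- rbind(0, cbind(0, s))
  i <- seq_len(nr); j <- seq_len(nc)
  (s[i + k, j + k, drop = FALSE] - s[i, j + k, drop = FALSE] -
     s[i + k, j, drop = FALSE] + s[i, j, drop = FALSE]) / (k * k)
}

# central-difference gradient magnitude
grad_mag <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gr <- (m[pmin(seq_len(nr) + 1L, nr), , drop = FALSE] -
           m[pmax(seq_len(nr) - 1L, 1L), , drop = FALSE]) / 2
  gc <- (m[, pmin(seq_len(nc) + 1L, nc), drop = FALSE] -
           m[, pmax(seq_len(nc) - 1L, 1L), drop = FALSE]) / 2
  sqrt(gr^2 + gc^2)
}

#' Per-pixel texture features
#'
#' Computes the documented recogniser feature panel: local mean and local
#' standard deviation in square windows at each scale, box-smoothed
#' gradient magnitude at each scale, and a local intensity entropy
#' (histogram over `entropy_bins` equal-width bins in a window of side
#' `entropy_scale`). All windows use edge replication, and every feature is
#' symmetric under a 180-degree rotation of the image.
#'
#' @param image numeric matrix (0-255).
#' @param scales integer window sides (default `c(5, 11)`).
#' @param entropy_scale window side for the entropy feature (default 9).
#' @param entropy_bins histogram bins for the entropy feature (default 8).
#' @return numeric matrix with one row per pixel (column-major order) and
#'   one named column per feature.
#' @export
texture_features <- function(image, scales = c(5L, 11L),
                             entropy_scale = 9L, entropy_bins = 8L) {
  feats <- list()
  for (s in scales) {
    mu <- box_mean(image, s)
    mu2 <- box_mean(image^2, s)
    feats[[paste0("mean", s)]] <- mu
    feats[[paste0("sd", s)]] <- sqrt(pmax(mu2 - mu^2, 0))
  }
  g <- grad_mag(image)
  for (s in scales)
    feats[[paste0("grad", s)]] <- box_mean(g, s)
  if (entropy_bins > 1) {
    bin <- pmin(pmax(floor(image / (256 / entropy_bins)), 0), entropy_bins - 1)
    H <- 0
    for (b in seq_len(entropy_bins) - 1) {
      p <- box_mean((bin == b) * 1, entropy_scale)
      H <- H - ifelse(p > 0, p * log(p), 0)
    }
    feats[[paste0("entropy", entropy_scale)]] <- H
  }
  out <- vapply(feats, as.vector, numeric(length(image)))
  colnames(out) <- names(feats)
  out
}

#' Train the texture recogniser
#'
#' Samples labelled pixels from the training images, extracts the texture
#' feature panel, and fits `n_candidates` randomised logistic-classifier
#' configurations (random feature subsets and training subsamples); the
#' candidate with the highest accuracy on a shared held-out pixel set is
#' returned. The first candidate always uses the full feature set and all
#' training pixels, so `n_candidates = 1` is the plain fit. Deterministic
#' given `seed`.
#'
#' @param images list of grayscale matrices (a single matrix is accepted).
#' @param masks list of logical ground-truth masks aligned with `images`.
#' @param n_candidates number of randomised training patterns (default 50).
#' @param seed integer seed.
#' @param n_pixels_per_class pixels sampled per class across all images.
#' @param scales,entropy_scale,entropy_bins passed to [texture_features()].
#' @return an object of class `texture_model` with elements
#'   `feature_names`, `coef`, `threshold`, the feature configuration and a
#'   `training_report` tibble (per-candidate held-out accuracy).
#' @export
train_texture_model <- function(images, masks, n_candidates = 50L, seed = 1L,
                                n_pixels_per_class = 4000L,
                                scales = c(5L, 11L), entropy_scale = 9L,
                                entropy_bins = 8L) {
  if (is.matrix(images)) images <- list(images)
  if (is.matrix(masks)) masks <- list(masks)
  stopifnot(length(images) == length(masks), n_candidates >= 1)
  y_all <- unlist(lapply(masks, as.vector))
  if (all(y_all) || !any(y_all))
    stop("training data must contain both foreground and background pixels",
         call. = FALSE)
  set.seed(seed)
  X <- do.call(rbind, lapply(images, texture_features, scales = scales,
                             entropy_scale = entropy_scale,
                             entropy_bins = entropy_bins))
  fg <- which(y_all); bg <- which(!y_all)
  fg <- sort(sample(fg, min(n_pixels_per_class, length(fg))))
  bg <- sort(sample(bg, min(n_pixels_per_class, length(bg))))
  idx <- c(fg, bg)
  Xs <- X[idx, , drop = FALSE]
  ys <- y_all[idx]
  n <- length(ys)
  val <- sort(sample(n, floor(n / 2)))
  trn <- setdiff(seq_len(n), val)
  fit_candidate <- function(feat_idx, rows) {
    Xf <- cbind(1, Xs[rows, feat_idx, drop = FALSE])
    fit <- suppressWarnings(
      stats::glm.fit(Xf, ys[rows] * 1, family = stats::binomial()))
    co <- fit$coefficients
    co[!is.finite(co)] <- 0
    eta <- cbind(1, Xs[val, feat_idx, drop = FALSE]) %*% co
    acc <- mean((eta >= 0) == ys[val])
    list(coef = co, acc = acc)
  }
  p <- ncol(Xs)
  cands <- vector("list", n_candidates)
  feat_sets <- vector("list", n_candidates)
  for (c in seq_len(n_candidates)) {
    if (c == 1L) {
      fi <- seq_len(p); rows <- trn
    } else {
      repeat {
        fi <- which(stats::runif(p) < 0.7)
        if (length(fi) >= 2) break
      }
      rows <- sort(sample(trn, ceiling(0.7 * length(trn))))
    }
    feat_sets[[c]] <- fi
    cands[[c]] <- fit_candidate(fi, rows)
  }
  accs <- vapply(cands, `[[`, numeric(1), "acc")
  best <- which.max(accs)
  fi <- feat_sets[[best]]
  co <- cands[[best]]$coef
  names(co) <- c("(intercept)", colnames(Xs)[fi])
  structure(
    list(feature_names = colnames(Xs)[fi],
         coef = co,
         threshold = 0.5,
         scales = scales,
         entropy_scale = entropy_scale,
         entropy_bins = entropy_bins,
         training_report = tibble::tibble(
           candidate = seq_len(n_candidates),
           n_features = lengths(feat_sets),
           heldout_accuracy = accs,
           selected = seq_len(n_candidates) == best)),
    class = "texture_model")
}

#' @export
print.texture_model <- function(x, ...) {
  cat(sprintf("<texture_model> %d features, held-out accuracy %.4f (best of %d candidates)\n",
              length(x$feature_names),
              max(x$training_report$heldout_accuracy),
              nrow(x$training_report)))
  invisible(x)
}

#' Foreground probability / decision for every pixel
#'
#' Applies the trained recogniser; pixels with foreground probability at or
#' above the model threshold (0.5 by default) are foreground.
#'
#' @param image grayscale matrix (typically after [flatten_background()]).
#' @param model a `texture_model`.
#' @param probabilities return the probability raster instead of the
#'   decision mask.
#' @return logical matrix (or numeric matrix of probabilities).
#' @export
recognize <- function(image, model, probabilities = FALSE) {
  stopifnot(inherits(model, "texture_model"))
  X <- texture_features(image, scales = model$scales,
                        entropy_scale = model$entropy_scale,
                        entropy_bins = model$entropy_bins)
  X <- X[, model$feature_names, drop = FALSE]
  eta <- cbind(1, X) %*% model$coef
  pr <- matrix(stats::plogis(eta), nrow(image), ncol(image))
  if (probabilities) pr else pr >= model$threshold
}

#' Persist / restore a texture model
#'
#' Models are written as versioned JSON so a reloaded model reproduces its
#' predictions exactly.
#'
#' @param model a `texture_model`.
#' @param path file path.
#' @return `read_texture_model` returns the model; `write_texture_model`
#'   returns `path` invisibly.
#' @export
write_texture_model <- function(model, path) {
  stopifnot(inherits(model, "texture_model"))
  x <- unclass(model)
  x$format_version <- 1L
  x$coef <- as.list(x$coef)
  x$training_report <- as.list(x$training_report)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_texture_model
#' @export
read_texture_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- unlist(x$coef)
  structure(
    list(feature_names = x$feature_names,
         coef = co,
         threshold = x$threshold,
         scales = x$scales,
         entropy_scale = x$entropy_scale,
         entropy_bins = x$entropy_bins,
         training_report = tibble::as_tibble(x$training_report)),
    class = "texture_model")
}
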