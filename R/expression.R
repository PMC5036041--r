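# Statistical validation of morphology clusters against single-colony
# expression profiles: percentile-shift sample normalisation,
# cluster-versus-rest differential testing with Benjamini-Hochberg control,
# fold-change screens, expression clustering with the same average-linkage
# uncentred-correlation engine as the colony database, and PCA.
#
# Expression matrices are plain numeric matrices, probes x colonies, with
# dimnames; values are log2-scale intensities unless declared otherwise.

#' Percentile-shift sample normalisation
#'
#' Subtracts from each colony (column) its own `percentile`-th percentile
#' (linear interpolation between order statistics), so that after
#' normalisation every colony's percentile equals 0 exactly. The operation
#' is shift invariant and idempotent. Values must be on the log scale; raw
#' positive intensities are log2-transformed first when
#' `log_scale = FALSE`.
#'
#' @param matrix numeric matrix, probes x colonies.
#' @param percentile percentile used as the per-sample anchor (default 75).
#' @param log_scale are values already log scale? (default `TRUE`).
#' @return normalised matrix (log2 scale), with attribute
#'   `normalized = TRUE`.
#' @export
percentile_shift_normalize <- function(matrix, percentile = 75,
                                       log_scale = TRUE) {
  stopifnot(is.matrix(matrix), percentile > 0, percentile < 100)
  if (!log_scale) {
    if (any(matrix <= 0))
      stop("raw-scale values must be strictly positive before log transform",
           call. = FALSE)
    matrix <- log2(matrix)
  }
  const <- apply(matrix, 2, function(x) diff(range(x)) == 0)
  if (any(const))
    stop("constant expression column(s): ",
         paste(colnames(matrix)[const], collapse = ", "), call. = FALSE)
  shifts <- apply(matrix, 2, stats::quantile, probs = percentile / 100,
                  names = FALSE)  # type 7: linear interpolation
  out <- sweep(matrix, 2, shifts)
  attr(out, "normalized") <- TRUE
  out
}

# vectorised two-sample t-tests across probe rows
row_t_tests <- function(x_in, x_out, var_equal = FALSE) {
  n1 <- ncol(x_in); n2 <- ncol(x_out)
  m1 <- rowMeans(x_in); m2 <- rowMeans(x_out)
  v1 <- apply(x_in, 1, stats::var); v2 <- apply(x_out, 1, stats::var)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- ifelse(se > 0, (m1 - m2) / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t), df), 1)
  list(t = t, p = p, mean_in = m1, mean_out = m2)
}

#' Cluster-versus-rest differential expression
#'
#' Per-probe two-sample t-test of the target cluster's colonies against all
#' others (Welch's unequal-variance form by default, pooled-variance
#' selectable), with Benjamini-Hochberg adjustment across all tested probes
#' and significance at `p_adjusted < alpha`. Fold change is the ratio of
#' linear-scale group means (values de-logged base 2), so values above 1
#' mean higher expression in the target cluster.
#'
#' @param matrix normalised log2 expression matrix, probes x colonies.
#' @param cluster_of named vector, colony id -> cluster label (must cover
#'   the matrix columns).
#' @param target the cluster compared against the rest.
#' @param alpha significance level (default 0.05).
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return tibble (class `diff_exp`) with `probe_id`, `mean_in`,
#'   `mean_out`, `fold_change`, `p_raw`, `p_adjusted`, `significant`.
#' @export
cluster_vs_rest <- function(matrix, cluster_of, target, alpha = 0.05,
                            var_equal = FALSE) {
  stopifnot(is.matrix(matrix), !is.null(colnames(matrix)))
  cl <- cluster_of[colnames(matrix)]
  if (anyNA(cl))
    stop("cluster labels missing for some colonies", call. = FALSE)
  in_grp <- cl == target
  if (sum(in_grp) < 2 || sum(!in_grp) < 2)
    stop("each group needs at least 2 colonies (",
         sum(in_grp), " vs ", sum(!in_grp), ")", call. = FALSE)
  tt <- row_t_tests(matrix[, in_grp, drop = FALSE],
                    matrix[, !in_grp, drop = FALSE], var_equal = var_equal)
  p_adj <- stats::p.adjust(tt$p, method = "BH")
  lin_in <- rowMeans(2^matrix[, in_grp, drop = FALSE])
  lin_out <- rowMeans(2^matrix[, !in_grp, drop = FALSE])
  out <- tibble::tibble(
    probe_id = rownames(matrix) %||% sprintf("probe_%05d", seq_len(nrow(matrix))),
    mean_in = unname(tt$mean_in), mean_out = unname(tt$mean_out),
    fold_change = unname(lin_in / lin_out),
    p_raw = unname(tt$p), p_adjusted = unname(p_adj),
    significant = unname(p_adj < alpha))
  class(out) <- c("diff_exp", class(out))
  attr(out, "target") <- target
  attr(out, "alpha") <- alpha
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen significant probes by fold change
#'
#' Splits significant probes by direction at linear fold change strictly
#' above `min_fold` (higher in the target cluster) or strictly below
#' `1 / min_fold` (lower). A screen at a larger `min_fold` is always a
#' subset of a screen at a smaller one.
#'
#' @param results a `diff_exp` tibble from [cluster_vs_rest()].
#' @param min_fold fold-change threshold (> 1).
#' @return list with `higher` and `lower` tibbles and `n_higher`,
#'   `n_lower` counts.
#' @export
fold_change_screen <- function(results, min_fold) {
  if (min_fold <= 1) stop("min_fold must be > 1", call. = FALSE)
  sig <- dplyr::filter(results, .data$significant)
  higher <- dplyr::filter(sig, .data$fold_change > min_fold)
  lower <- dplyr::filter(sig, .data$fold_change < 1 / min_fold)
  list(higher = higher, lower = lower,
       n_higher = nrow(higher), n_lower = nrow(lower))
}

#' Cluster colonies on an expression probe subset
#'
#' Same clustering engine as the colony database (average linkage,
#' uncentred correlation), applied to colony expression vectors restricted
#' to `probe_subset`. Optionally median-centres each probe first (baseline
#' shift; default on, selectable off).
#'
#' @param matrix normalised log2 expression matrix.
#' @param probe_subset probe ids (default: all probes).
#' @param baseline_shift per-probe median centring before clustering.
#' @return a `cluster_tree` over colonies.
#' @export
cluster_expression <- function(matrix, probe_subset = rownames(matrix),
                               baseline_shift = TRUE) {
  stopifnot(length(probe_subset) >= 1)
  m <- matrix[probe_subset, , drop = FALSE]
  if (baseline_shift)
    m <- sweep(m, 1, apply(m, 1, stats::median))
  build_tree(t(m), similarity = "uncentred")
}

#' Principal-component projection of colonies
#'
#' Per-probe centred singular-value decomposition of the expression matrix;
#' returns colony scores on the leading components and explained-variance
#' fractions. Component signs are fixed so the largest-magnitude probe
#' loading of each component is positive.
#'
#' @param matrix normalised log2 expression matrix, probes x colonies.
#' @param k number of components (default `min(dim) - 1`, at least 1).
#' @return list with `scores` (tibble: `colony_id`, `PC1`, ...),
#'   `explained` (variance fractions) and `loadings`.
#' @export
pca_project <- function(matrix, k = NULL) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 2)
  x <- t(matrix)  # colonies x probes
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  kmax <- sum(pc$sdev > 0)
  if (is.null(k)) k <- max(1L, min(ncol(pc$x), ncol(matrix) - 1L))
  k <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
    if (pc$sdev[j] == 0) { scores[, j] <- 0 }
  }
  list(scores = tibble::as_tibble(scores, .name_repair = "minimal") |>
         dplyr::mutate(colony_id = colnames(matrix), .before = 1),
       explained = if (tot > 0) pc$sdev[seq_len(k)]^2 / tot
                   else rep(0, k),
       loadings = load)
}

#' Synthesise a single-colony expression experiment
#'
#' Log2-scale matrix with per-probe baseline means, optional spiked probes
#' whose mean is shifted by `log2(fold)` in the first-named group, and
#' Gaussian noise. Deterministic given `seed`.
#'
#' @param n_probes number of probes.
#' @param groups named integer vector, group label -> number of colonies;
#'   the first group carries the spike.
#' @param spike list with `n_spiked` and `fold` (linear); `fold = 1` means
#'   no group structure.
#' @param noise_sd per-value Gaussian noise SD (log2 units, default 0.5).
#' @param base_mean mean log2 baseline (default 8).
#' @param seed integer seed.
#' @return list with `matrix` (probes x colonies, dimnames set),
#'   `cluster_of` (named vector) and `truth` (tibble: `probe_id`,
#'   `spiked`).
#' @export
synth_expression <- function(n_probes, groups, spike = list(n_spiked = 0, fold = 1),
                             noise_sd = 0.5, base_mean = 8, seed = 1L) {
  stopifnot(n_probes >= 1, all(groups >= 1), spike$n_spiked <= n_probes,
            spike$fold > 0, noise_sd >= 0)
  set.seed(seed)
  n_col <- sum(groups)
  labels <- rep(names(groups), groups)
  colony_ids <- sprintf("colony_%03d", seq_len(n_col))
  probe_ids <- sprintf("probe_%05d", seq_len(n_probes))
  base <- stats::rnorm(n_probes, base_mean, 1.5)
  m <- base %o% rep(1, n_col)
  spiked <- seq_len(spike$n_spiked)
  if (length(spiked) && spike$fold != 1) {
    target_cols <- labels == names(groups)[1]
    m[spiked, target_cols] <- m[spiked, target_cols] + log2(spike$fold)
  }
  if (noise_sd > 0)
    m <- m + stats::rnorm(length(m), 0, noise_sd)
  dimnames(m) <- list(probe_ids, colony_ids)
  list(matrix = m,
       cluster_of = stats::setNames(labels, colony_ids),
       truth = tibble::tibble(probe_id = probe_ids,
                              spiked = seq_len(n_probes) %in% spiked))
}

#' Read / write an expression matrix as TSV
#'
#' Probes x colonies, header row of colony ids, first column `probe_id`.
#'
#' @param matrix expression matrix.
#' @param path file path.
#' @return `read_expression_tsv` returns the matrix.
#' @export
write_expression_tsv <- function(matrix, path) {
  utils::write.table(data.frame(probe_id = rownames(matrix), matrix,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}
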