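# broom-style tidiers for the package's fitted objects.

#' Tidy a colony database
#'
#' One row per colony: id, assigned cluster, major flag and (when
#' annotated) cell line.
#'
#' @param x a `colony_db`.
#' @param ... unused.
#' @return tibble.
#' @export
tidy.colony_db <- function(x, ...) {
  out <- tibble::tibble(colony_id = x$colony_ids,
                        cluster = unname(x$cluster_of[x$colony_ids]),
                        is_major = unname(x$cluster_of[x$colony_ids]) %in%
                          x$major_labels)
  if (!is.null(x$line_of))
    out$line <- unname(x$line_of[x$colony_ids])
  out
}

#' One-line summary of a colony database
#' @param x a `colony_db`.
#' @param ... unused.
#' @return one-row tibble: colony/parameter counts, pruning threshold,
#'   cluster counts.
#' @export
glance.colony_db <- function(x, ...) {
  tibble::tibble(n_colonies = length(x$colony_ids),
                 n_parameters = length(x$parameter_names),
                 r_star = x$r_star,
                 alpha = x$alpha,
                 n_clusters = nrow(x$cluster_table),
                 n_major = length(x$major_labels),
                 count_threshold = x$count_threshold)
}

#' Tidy a cluster tree's merge list
#' @param x a `cluster_tree`.
#' @param ... unused.
#' @return tibble: `step`, `left`, `right` (hclust convention: negative =
#'   leaf index), `similarity`.
#' @export
tidy.cluster_tree <- function(x, ...) {
  tibble::tibble(step = seq_len(nrow(x$merge)),
                 left = x$merge[, 1], right = x$merge[, 2],
                 similarity = x$similarity)
}

#' Tidy a filter report
#' @param x a `filter_report`.
#' @param ... unused.
#' @return tibble with `parameter`, `status` (`kept`/`dropped_correlated`/
#'   `dropped_high_cv`) and drop details.
#' @export
tidy.filter_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(parameter = x$kept, status = "kept",
                   representative = NA_character_, r = NA_real_,
                   cv = NA_real_),
    tibble::tibble(parameter = x$dropped_correlated$dropped,
                   status = "dropped_correlated",
                   representative = x$dropped_correlated$representative,
                   r = x$dropped_correlated$r, cv = NA_real_),
    tibble::tibble(parameter = x$dropped_high_cv$dropped,
                   status = "dropped_high_cv",
                   representative = NA_character_, r = NA_real_,
                   cv = x$dropped_high_cv$cv))
}

#' One-line summary of a differential-expression result
#' @param x a `diff_exp` tibble.
#' @param ... unused.
#' @return one-row tibble: probes tested, significant counts, target, alpha.
#' @export
glance.diff_exp <- function(x, ...) {
  tibble::tibble(n_probes = nrow(x),
                 n_significant = sum(x$significant),
                 n_higher = sum(x$significant & x$fold_change > 1),
                 n_lower = sum(x$significant & x$fold_change < 1),
                 target = attr(x, "target") %||% NA_character_,
                 alpha = attr(x, "alpha") %||% NA_real_)
}
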