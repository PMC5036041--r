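# Nearest-correlation classification of new live colonies against the
# colony database: a query profile is standardised with the database
# statistics and assigned the cluster of the database colony with the
# highest centred Pearson correlation. (The database tree itself is built
# under uncentred similarity; matching deliberately uses centred Pearson,
# mirroring the asymmetry of the reference pipeline.)

query_vector <- function(profile, db) {
  if (is.data.frame(profile)) {
    miss <- setdiff(db$parameter_names, names(profile))
    if (length(miss))
      stop("query profile is missing parameter(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    as.numeric(profile[1, db$parameter_names])
  } else {
    miss <- setdiff(db$parameter_names, names(profile))
    if (length(miss))
      stop("query profile is missing parameter(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    as.numeric(profile[db$parameter_names])
  }
}

#' Classify one colony against the database
#'
#' Standardises the query with the database's per-parameter statistics and
#' returns the cluster of the database colony with the highest Pearson
#' correlation (ties broken by database order), together with the runner-up
#' for audit.
#'
#' @param profile named numeric vector or one-row tibble containing at
#'   least the database's selected parameters (raw scale).
#' @param db a `colony_db`.
#' @param query_id identifier for the result row.
#' @param min_r optional warning threshold: if the best correlation falls
#'   below it a warning is emitted (no assignment is rejected).
#' @return one-row tibble: `query_id`, `best_match_colony_id`, `best_r`,
#'   `assigned_cluster`, `is_major`, `runner_up_id`, `runner_up_r`.
#' @export
classify_colony <- function(profile, db, query_id = "query", min_r = NULL) {
  stopifnot(inherits(db, "colony_db"))
  q <- query_vector(profile, db)
  z <- (q - db$standardization$mean) / db$standardization$sd
  if (stats::sd(z) == 0)
    stop("query vector has zero variance after standardization", call. = FALSE)
  r <- as.vector(stats::cor(t(db$standardized_matrix), z))
  best <- which.max(r)  # which.max takes the first maximum: ties by DB order
  ru <- if (length(r) > 1) order(r, decreasing = TRUE)[2] else NA_integer_
  if (!is.null(min_r) && r[best] < min_r)
    warning(sprintf("best correlation %.3f below min_r = %.3f for %s",
                    r[best], min_r, query_id), call. = FALSE)
  cl <- unname(db$cluster_of[db$colony_ids[best]])
  tibble::tibble(
    query_id = query_id,
    best_match_colony_id = db$colony_ids[best],
    best_r = r[best],
    assigned_cluster = cl,
    is_major = cl %in% db$major_labels,
    runner_up_id = if (is.na(ru)) NA_character_ else db$colony_ids[ru],
    runner_up_r = if (is.na(ru)) NA_real_ else r[ru])
}

#' Classify a batch of colonies
#'
#' Applies [classify_colony()] to every row of a profile tibble. Per-colony
#' failures (missing parameters, degenerate vectors) are reported as
#' flagged rows with an `error` message; the batch never aborts.
#'
#' @param profiles profile tibble with a `colony_id` column (or row order
#'   ids are generated).
#' @param db a `colony_db`.
#' @param min_r see [classify_colony()].
#' @return tibble of classification results with an `error` column
#'   (`NA` on success).
#' @export
classify_batch <- function(profiles, db, min_r = NULL) {
  ids <- if ("colony_id" %in% names(profiles)) profiles$colony_id
         else sprintf("query_%03d", seq_len(nrow(profiles)))
  if (!length(ids))
    return(tibble::tibble(query_id = character(0),
                          best_match_colony_id = character(0),
                          best_r = numeric(0),
                          assigned_cluster = character(0),
                          is_major = logical(0),
                          runner_up_id = character(0),
                          runner_up_r = numeric(0),
                          error = character(0)))
  rows <- lapply(seq_along(ids), function(i) {
    tryCatch(
      dplyr::mutate(
        classify_colony(profiles[i, ], db, query_id = ids[i], min_r = min_r),
        error = NA_character_),
      error = function(e)
        tibble::tibble(query_id = ids[i], best_match_colony_id = NA_character_,
                       best_r = NA_real_, assigned_cluster = NA_character_,
                       is_major = NA, runner_up_id = NA_character_,
                       runner_up_r = NA_real_, error = conditionMessage(e)))
  })
  dplyr::bind_rows(rows)
}

#' Summarise a classification batch
#'
#' Per-cluster counts and fractions over successfully classified colonies;
#' includes every database cluster so screening fractions (e.g. the
#' cluster-A fraction of a new line) are reported even when zero.
#'
#' @param results tibble from [classify_batch()].
#' @param db the `colony_db` the batch was classified against.
#' @return tibble with `cluster`, `is_major`, `n`, `fraction`.
#' @export
classification_summary <- function(results, db) {
  ok <- dplyr::filter(results, is.na(.data$error))
  n_tot <- nrow(ok)
  all_cl <- sort(unique(unname(db$cluster_of)))
  counts <- table(factor(ok$assigned_cluster, levels = all_cl))
  tibble::tibble(cluster = all_cl,
                 is_major = all_cl %in% db$major_labels,
                 n = as.integer(counts),
                 fraction = if (n_tot > 0) as.numeric(counts) / n_tot else 0)
}
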