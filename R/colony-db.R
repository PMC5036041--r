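# The clustered colony database.
#
# Selected parameters are z-standardised (sample SD), colonies are
# clustered by average-linkage agglomeration under uncentred-correlation
# distance (1 - sum(x*y)/(|x||y|)), the dendrogram is pruned at the
# no-correlation-test threshold r* (so every within-cluster merge is more
# similar than chance correlation at level alpha for the number of selected
# parameters), and clusters above the 5% membership rule become "major".

#' Z-standardise a colony-by-parameter matrix
#'
#' Each parameter is centred and scaled to unit sample SD (n-1 convention)
#' across database colonies. When `stats` is supplied (classification of new
#' colonies against an existing database) those statistics are applied
#' unchanged.
#'
#' @param x numeric matrix (colonies x parameters) with column names.
#' @param stats optional tibble with `parameter`, `mean`, `sd` columns.
#' @return matrix with a `standardization` attribute carrying the stats.
#' @export
standardize <- function(x, stats = NULL) {
  x <- as.matrix(x)
  if (is.null(stats)) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    bad <- names(which(sdv == 0))
    if (length(bad))
      stop("zero-SD parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    stats <- tibble::tibble(parameter = colnames(x), mean = unname(mu),
                            sd = unname(sdv))
  } else {
    stats <- stats[match(colnames(x), stats$parameter), ]
    if (anyNA(stats$parameter))
      stop("standardization stats missing for some parameters", call. = FALSE)
  }
  z <- sweep(sweep(x, 2, stats$mean), 2, stats$sd, `/`)
  attr(z, "standardization") <- stats
  z
}

#' Uncentred correlation of two vectors
#'
#' The cosine-type similarity \eqn{\sum x_i y_i / (\|x\| \|y\|)} used by the
#' clustering engine; the corresponding distance is one minus this value.
#'
#' @param x,y numeric vectors of equal length (>= 2), nonzero norm.
#' @return scalar in \[-1, 1\].
#' @export
uncentred_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("uncentred correlation undefined for a zero-norm vector",
         call. = FALSE)
  sum(x * y) / (nx * ny)
}

similarity_matrix <- function(x, similarity = c("uncentred", "pearson")) {
  similarity <- match.arg(similarity)
  if (similarity == "uncentred") {
    nrm <- sqrt(rowSums(x^2))
    if (any(nrm == 0))
      stop("zero-norm row(s) in similarity computation", call. = FALSE)
    s <- tcrossprod(x) / outer(nrm, nrm)
  } else {
    s <- suppressWarnings(stats::cor(t(x)))
    s[!is.finite(s)] <- 0
  }
  s[s > 1] <- 1; s[s < -1] <- -1
  s
}

#' Average-linkage tree under correlation similarity
#'
#' Agglomerative average-linkage clustering of the rows of `x` with
#' distance `1 - similarity` (uncentred correlation by default, centred
#' Pearson selectable). The returned tree records the merge list in
#' agglomeration order together with the average-linkage similarity at each
#' merge.
#'
#' @param x numeric matrix (colonies x parameters), >= 2 rows; row names are
#'   used as leaf ids.
#' @param similarity `"uncentred"` (default) or `"pearson"`.
#' @return an object of class `cluster_tree`: `merge` (hclust convention),
#'   `similarity` (per merge), `labels`, `similarity_type` and the
#'   underlying `hclust` fit.
#' @export
build_tree <- function(x, similarity = c("uncentred", "pearson")) {
  similarity <- match.arg(similarity)
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2)
  if (is.null(rownames(x))) rownames(x) <- paste0("colony_", seq_len(nrow(x)))
  s <- similarity_matrix(x, similarity)
  d <- stats::as.dist(1 - s)
  hc <- stats::hclust(d, method = "average")
  structure(list(merge = hc$merge,
                 similarity = 1 - hc$height,
                 labels = rownames(x),
                 similarity_type = similarity,
                 hclust = hc),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d leaves, %s similarity, merge similarities %.3f .. %.3f\n",
              length(x$labels), x$similarity_type,
              max(x$similarity), min(x$similarity)))
  invisible(x)
}

#' Export a cluster tree to Newick
#' @param tree a `cluster_tree`.
#' @param path optional file; if omitted the Newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
tree_to_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree$hclust)
  if (is.null(path)) ape::write.tree(phy)
  else { ape::write.tree(phy, file = path); invisible(path) }
}

#' Critical correlation of the no-correlation test
#'
#' Inverts the test of no correlation, \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}}:
#' with `n_params` selected parameters and two-sided level `alpha`, the
#' Student-t critical value \eqn{t^*} at `n_params - 2` degrees of freedom
#' gives the pruning threshold \eqn{r^* = t^*/\sqrt{df + t^{*2}}}. Any pair
#' of colonies merged above \eqn{r^*} is more similar than chance
#' correlation at that level; with 27 parameters and alpha 0.05 this yields
#' r* = 0.380863 (t* = 2.059539).
#'
#' @param n_params number of parameters describing each colony (>= 3).
#' @param alpha two-sided significance level (default 0.05).
#' @return scalar r*, with the critical t as attribute `t_critical`.
#' @export
critical_r <- function(n_params, alpha = 0.05) {
  stopifnot(n_params >= 3, alpha > 0, alpha < 1)
  df <- n_params - 2
  t_star <- stats::qt(1 - alpha / 2, df)
  r <- t_star / sqrt(df + t_star^2)
  attr(r, "t_critical") <- t_star
  r
}

#' Prune a cluster tree at a correlation threshold
#'
#' Clusters are the maximal subtrees all of whose internal merge
#' similarities strictly exceed `r_threshold`; every leaf receives exactly
#' one label. A higher threshold always refines the partition of a lower
#' one.
#'
#' @param tree a `cluster_tree`.
#' @param r_threshold similarity threshold in (-1, 1), typically
#'   [critical_r()].
#' @return named character vector, leaf id -> cluster label (`"K1"`,
#'   `"K2"`, ... in order of each cluster's first leaf).
#' @export
prune_tree <- function(tree, r_threshold) {
  stopifnot(inherits(tree, "cluster_tree"),
            r_threshold > -1, r_threshold < 1)
  n <- length(tree$labels)
  merge <- tree$merge; sim <- tree$similarity
  valid <- logical(n - 1)
  for (i in seq_len(n - 1)) {
    a <- merge[i, 1]; b <- merge[i, 2]
    ok_a <- a < 0 || valid[a]
    ok_b <- b < 0 || valid[b]
    valid[i] <- ok_a && ok_b && sim[i] > r_threshold
  }
  grp <- seq_len(n)  # union-find over leaves
  find <- function(i) { while (grp[i] != i) { grp[i] <<- grp[grp[i]]; i <- grp[i] }; i }
  node_rep <- integer(n - 1)
  for (i in seq_len(n - 1)) {
    a <- merge[i, 1]; b <- merge[i, 2]
    ra <- if (a < 0) -a else node_rep[a]
    rb <- if (b < 0) -b else node_rep[b]
    if (valid[i]) {
      ra <- find(ra); rb <- find(rb)
      grp[max(ra, rb)] <- min(ra, rb)
      node_rep[i] <- min(ra, rb)
    } else {
      node_rep[i] <- ra  # representative only; no merge
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  first_leaf <- match(unique(roots), roots)
  lab_of_root <- stats::setNames(paste0("K", seq_along(first_leaf)),
                                 roots[first_leaf])
  stats::setNames(unname(lab_of_root[as.character(roots)]), tree$labels)
}

#' Designate major and minor clusters
#'
#' A cluster is major when it contains strictly more than
#' `floor(frac * n_total)` colonies; with 303 colonies and the default 5%
#' rule the count threshold is 15, so a 16-colony cluster is major and a
#' 15-colony cluster is minor.
#'
#' @param labels vector (or named vector) of cluster labels, one per colony.
#' @param n_total total number of labelled colonies (defaults to
#'   `length(labels)`).
#' @param frac membership fraction rule (default 0.05).
#' @return list with `major` and `minor` character vectors of cluster labels.
#' @export
designate_major <- function(labels, n_total = length(labels), frac = 0.05) {
  sizes <- table(labels)
  threshold <- floor(frac * n_total)
  major <- names(sizes)[sizes > threshold]
  list(major = major, minor = setdiff(names(sizes), major),
       count_threshold = threshold)
}

#' Order clusters into letters A, B, ...
#'
#' Clusters are sorted by the composite key used to name the signature
#' cluster first: (1) clusters whose within-line existence ratio is higher
#' in the aberrant line than in the reference line come first (the
#' aberrant-enriched morphology gets letter A), then (2) major before
#' minor, then (3) descending mean colony area. At most 20 letters (A-T)
#' are available; more clusters is an error.
#'
#' @param cluster_of named vector, colony id -> cluster label.
#' @param mean_area_of named vector, cluster label -> mean colony area.
#' @param major_labels character vector of major cluster labels.
#' @param line_of optional named vector, colony id -> cell-line id.
#' @param reference_line,aberrant_line line ids compared by the enrichment
#'   key (ignored when `line_of` is `NULL`).
#' @return tibble with `cluster`, `letter`, `enriched`, `major`,
#'   `mean_area` in letter order.
#' @export
order_clusters <- function(cluster_of, mean_area_of, major_labels,
                           line_of = NULL, reference_line = NULL,
                           aberrant_line = NULL) {
  labs <- sort(unique(unname(cluster_of)))
  enriched <- stats::setNames(rep(FALSE, length(labs)), labs)
  if (!is.null(line_of) && !is.null(reference_line) && !is.null(aberrant_line)) {
    line_of <- line_of[names(cluster_of)]
    n_ref <- sum(line_of == reference_line)
    n_ab <- sum(line_of == aberrant_line)
    for (l in labs) {
      in_l <- cluster_of == l
      r_ref <- if (n_ref > 0) sum(in_l & line_of == reference_line) / n_ref else 0
      r_ab <- if (n_ab > 0) sum(in_l & line_of == aberrant_line) / n_ab else 0
      enriched[l] <- r_ab > r_ref
    }
  }
  tab <- tibble::tibble(cluster = labs,
                        enriched = unname(enriched[labs]),
                        major = labs %in% major_labels,
                        mean_area = unname(mean_area_of[labs]))
  tab <- dplyr::arrange(tab, dplyr::desc(.data$enriched),
                        dplyr::desc(.data$major),
                        dplyr::desc(.data$mean_area))
  if (nrow(tab) > 20)
    stop("more than 20 clusters; letters beyond T are not assigned (",
         nrow(tab), " clusters)", call. = FALSE)
  tab$letter <- LETTERS[seq_len(nrow(tab))]
  tab[, c("cluster", "letter", "enriched", "major", "mean_area")]
}

#' Build the clustered colony database
#'
#' Runs the full database construction on a profile tibble: border-touching
#' colonies are excluded, the two-stage parameter filter selects the
#' analysis panel, parameters are z-standardised, the average-linkage
#' uncentred-correlation tree is built and pruned at
#' `critical_r(n_selected, alpha)`, clusters above the 5% rule become major
#' and all clusters are lettered A, B, ... (the aberrant-enriched cluster
#' first when line annotations are given).
#'
#' @param profiles profile tibble from [compute_profiles()].
#' @param line_of optional named vector, colony id -> cell-line id.
#' @param reference_line,aberrant_line line ids for the enrichment ordering.
#' @param alpha significance level of the no-correlation pruning test.
#' @param r_max,cv_max parameter-filter thresholds (see
#'   [select_parameters()]).
#' @param scale z-standardise parameters before clustering (default `TRUE`;
#'   turn off for strict-replication runs on pre-scaled data).
#' @param similarity tree similarity, `"uncentred"` (default) or
#'   `"pearson"`.
#' @param major_frac major-cluster membership rule (default 0.05).
#' @param include_border keep border-touching colonies (default `FALSE`).
#' @return an object of class `colony_db`.
#' @export
build_colony_db <- function(profiles, line_of = NULL, reference_line = NULL,
                            aberrant_line = NULL, alpha = 0.05,
                            r_max = 0.98, cv_max = 30, scale = TRUE,
                            similarity = c("uncentred", "pearson"),
                            major_frac = 0.05, include_border = FALSE) {
  similarity <- match.arg(similarity)
  if (!include_border && "border_touch" %in% names(profiles))
    profiles <- dplyr::filter(profiles, !.data$border_touch)
  stopifnot(nrow(profiles) >= 2)
  ids <- if ("colony_id" %in% names(profiles)) profiles$colony_id
         else paste0("colony_", seq_len(nrow(profiles)))
  report <- select_parameters(profiles, r_max = r_max, cv_max = cv_max)
  x <- as.matrix(profiles[, report$kept, drop = FALSE])
  rownames(x) <- ids
  z <- standardize(x)
  stats <- attr(z, "standardization")
  zm <- if (scale) z else x
  r_star <- critical_r(length(report$kept), alpha)
  tree <- build_tree(zm, similarity)
  cluster_of <- prune_tree(tree, as.numeric(r_star))
  majors <- designate_major(cluster_of, frac = major_frac)
  areas <- if ("area_px" %in% names(profiles)) profiles$area_px
           else rowMeans(x)
  mean_area_of <- tapply(areas, cluster_of[ids], mean)
  ord <- order_clusters(cluster_of, mean_area_of, majors$major,
                        line_of = line_of, reference_line = reference_line,
                        aberrant_line = aberrant_line)
  letter_of <- stats::setNames(ord$letter, ord$cluster)
  cluster_letters <- stats::setNames(unname(letter_of[cluster_of]),
                                     names(cluster_of))
  structure(
    list(colony_ids = ids,
         parameter_names = report$kept,
         matrix = x,
         standardization = stats,
         standardized_matrix = z,
         scaled = scale,
         similarity = similarity,
         tree = tree,
         r_star = as.numeric(r_star),
         alpha = alpha,
         cluster_of = cluster_letters,
         cluster_table = dplyr::mutate(
           ord, size = as.integer(table(cluster_letters)[ord$letter])),
         major_labels = sort(unname(letter_of[majors$major])),
         minor_labels = sort(unname(letter_of[majors$minor])),
         count_threshold = majors$count_threshold,
         line_of = line_of,
         filter_report = report,
         provenance = list(alpha = alpha, r_max = r_max, cv_max = cv_max,
                           scale = scale, similarity = similarity,
                           major_frac = major_frac,
                           reference_line = reference_line,
                           aberrant_line = aberrant_line)),
    class = "colony_db")
}

#' @export
print.colony_db <- function(x, ...) {
  cat(sprintf("<colony_db> %d colonies x %d parameters, r* = %.6f, %d clusters (%d major: %s)\n",
              length(x$colony_ids), length(x$parameter_names), x$r_star,
              nrow(x$cluster_table), length(x$major_labels),
              paste(x$major_labels, collapse = ", ")))
  invisible(x)
}

#' Per-cluster membership report
#'
#' Cluster sizes and, when line annotations are available, the within-line
#' existence ratio of every cluster (the fraction of each line's colonies
#' falling in the cluster).
#'
#' @param db a `colony_db`.
#' @return tibble, one row per cluster (wide in lines if annotated).
#' @export
cluster_report <- function(db) {
  stopifnot(inherits(db, "colony_db"))
  base <- db$cluster_table[, c("letter", "size", "major", "mean_area")]
  names(base)[1] <- "cluster"
  if (is.null(db$line_of)) return(base)
  lines <- db$line_of[db$colony_ids]
  tab <- table(cluster = db$cluster_of[db$colony_ids], line = lines)
  ratio <- sweep(tab, 2, colSums(tab), `/`)
  wide <- tibble::as_tibble(as.data.frame.matrix(ratio), rownames = "cluster")
  dplyr::left_join(base, wide, by = "cluster")
}

# --- persistence ----------------------------------------------------------

#' Persist / restore a colony database directory
#'
#' The database is stored as plain-text tables (raw matrix, standardisation
#' statistics, cluster labels, merge list) plus a provenance JSON, and can
#' be restored bit-identically.
#'
#' @param db a `colony_db`.
#' @param dir directory path.
#' @return `read_colony_db` returns the `colony_db`; `write_colony_db`
#'   returns `dir` invisibly.
#' @export
write_colony_db <- function(db, dir) {
  stopifnot(inherits(db, "colony_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                         quote = FALSE, row.names = FALSE)
  w(data.frame(colony_id = db$colony_ids, db$matrix, check.names = FALSE),
    "matrix.tsv")
  w(db$standardization, "standardization.tsv")
  w(data.frame(colony_id = names(db$cluster_of),
               cluster = unname(db$cluster_of),
               is_major = unname(db$cluster_of) %in% db$major_labels,
               line = if (is.null(db$line_of)) NA
                      else unname(db$line_of[names(db$cluster_of)])),
    "labels.tsv")
  w(data.frame(step = seq_len(nrow(db$tree$merge)),
               left = db$tree$merge[, 1], right = db$tree$merge[, 2],
               similarity = db$tree$similarity),
    "merges.tsv")
  w(db$cluster_table, "clusters.tsv")
  jsonlite::write_json(
    c(db$provenance,
      list(r_star = db$r_star, parameter_names = db$parameter_names,
           major_labels = db$major_labels, minor_labels = db$minor_labels,
           count_threshold = db$count_threshold, scaled = db$scaled)),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  tree_to_newick(db$tree, file.path(dir, "tree.newick"))
  invisible(dir)
}

#' @rdname write_colony_db
#' @export
read_colony_db <- function(dir) {
  r <- function(f) utils::read.table(file.path(dir, f), sep = "\t",
                                     header = TRUE, check.names = FALSE)
  mat <- r("matrix.tsv")
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  x <- as.matrix(mat[, -1, drop = FALSE])
  rownames(x) <- mat$colony_id
  labels <- r("labels.tsv")
  stats <- tibble::as_tibble(r("standardization.tsv"))
  clusters <- tibble::as_tibble(r("clusters.tsv"))
  line_of <- if (all(is.na(labels$line))) NULL
             else stats::setNames(labels$line, labels$colony_id)
  z <- standardize(x, stats)
  tree <- build_tree(if (prov$scaled) z else x, prov$similarity)
  structure(
    list(colony_ids = mat$colony_id,
         parameter_names = prov$parameter_names,
         matrix = x,
         standardization = stats,
         standardized_matrix = z,
         scaled = prov$scaled,
         similarity = prov$similarity,
         tree = tree,
         r_star = prov$r_star,
         alpha = prov$alpha,
         cluster_of = stats::setNames(labels$cluster, labels$colony_id),
         cluster_table = clusters,
         major_labels = prov$major_labels,
         minor_labels = if (length(prov$minor_labels)) prov$minor_labels
                        else character(0),
         count_threshold = prov$count_threshold,
         line_of = line_of,
         filter_report = NULL,
         provenance = prov[c("alpha", "r_max", "cv_max", "scale",
                             "similarity", "major_frac",
                             "reference_line", "aberrant_line")]),
    class = "colony_db")
}
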