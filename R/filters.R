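# Two-stage parameter selection: highly correlated parameters are
# collapsed to a single representative (|Pearson r| > 0.98), then
# parameters with a high coefficient of variation (CV > 30) are dropped as
# poor descriptors. The filters compose in that order.

new_filter_report <- function(kept, dropped_correlated, dropped_high_cv) {
  structure(list(kept = kept,
                 dropped_correlated = dropped_correlated,
                 dropped_high_cv = dropped_high_cv),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> kept %d, dropped %d correlated, %d high-CV\n",
              length(x$kept), nrow(x$dropped_correlated),
              nrow(x$dropped_high_cv)))
  invisible(x)
}

#' Collapse highly correlated parameters
#'
#' Greedy pass in canonical parameter order: a parameter is dropped when its
#' absolute Pearson correlation across colonies with any already-kept
#' parameter exceeds `r_max`; the earliest kept parameter it correlates
#' with is recorded as its representative. Correlations involving a
#' zero-variance parameter are defined as 0 (constant parameters are the CV
#' filter's business).
#'
#' @param profiles profile tibble (parameter columns plus metadata).
#' @param r_max correlation threshold (default 0.98, strict `>`).
#' @return a `filter_report`.
#' @export
filter_correlated <- function(profiles, r_max = 0.98) {
  pars <- parameter_columns(profiles)
  stopifnot(nrow(profiles) >= 3, length(pars) >= 1)
  X <- as.matrix(profiles[, pars, drop = FALSE])
  cm <- suppressWarnings(stats::cor(X))
  cm[!is.finite(cm)] <- 0
  kept <- character(0)
  dropped <- list()
  for (p in pars) {
    if (length(kept)) {
      rr <- cm[p, kept]
      hit <- which(abs(rr) > r_max)
      if (length(hit)) {
        dropped[[p]] <- tibble::tibble(dropped = p,
                                       representative = kept[hit[1]],
                                       r = unname(rr[hit[1]]))
        next
      }
    }
    kept <- c(kept, p)
  }
  new_filter_report(kept,
                    if (length(dropped)) dplyr::bind_rows(dropped)
                    else tibble::tibble(dropped = character(0),
                                        representative = character(0),
                                        r = numeric(0)),
                    tibble::tibble(dropped = character(0), cv = numeric(0)))
}

#' Drop parameters with a high coefficient of variation
#'
#' The CV is `100 * SD / |mean|` across colonies on the raw
#' (unstandardised) values; parameters with CV strictly above `cv_max` are
#' dropped, as are zero-mean parameters (infinite CV). Constant parameters
#' have CV 0 and are kept. The decision is invariant to positive rescaling
#' of a parameter.
#'
#' @param profiles profile tibble.
#' @param cv_max CV threshold (default 30, strict `>`).
#' @return a `filter_report`.
#' @export
filter_high_cv <- function(profiles, cv_max = 30) {
  pars <- parameter_columns(profiles)
  stopifnot(nrow(profiles) >= 2, length(pars) >= 1)
  X <- as.matrix(profiles[, pars, drop = FALSE])
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  cv <- ifelse(mu == 0, Inf, 100 * sdv / abs(mu))
  drop <- cv > cv_max
  new_filter_report(pars[!drop],
                    tibble::tibble(dropped = character(0),
                                   representative = character(0),
                                   r = numeric(0)),
                    tibble::tibble(dropped = pars[drop], cv = unname(cv[drop])))
}

#' Run the composed parameter-selection filter
#'
#' Correlation filter first, then the CV filter on the survivors, matching
#' the analysis order of the reference pipeline. The composition is
#' idempotent.
#'
#' @inheritParams filter_correlated
#' @inheritParams filter_high_cv
#' @return a `filter_report` whose `kept` names the analysis panel.
#' @export
select_parameters <- function(profiles, r_max = 0.98, cv_max = 30) {
  rep1 <- filter_correlated(profiles, r_max)
  sub <- profiles[, c(intersect(names(profiles), .meta_cols), rep1$kept),
                  drop = FALSE]
  rep2 <- filter_high_cv(sub, cv_max)
  new_filter_report(rep2$kept, rep1$dropped_correlated, rep2$dropped_high_cv)
}

#' Restrict a profile tibble to a filter report's kept panel
#' @param profiles profile tibble.
#' @param report a `filter_report`.
#' @return tibble with metadata columns and the kept parameters only.
#' @export
apply_filter <- function(profiles, report) {
  stopifnot(inherits(report, "filter_report"))
  profiles[, c(intersect(names(profiles), .meta_cols), report$kept),
           drop = FALSE]
}
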