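#' Per-unit summaries of raw variables
#'
#' For every best-matching unit, the mean and sample standard deviation
#' (denominator n - 1) of each variable on its original scale, over the
#' samples assigned to the unit. The standard deviation is reported as `NA`
#' for singleton units.
#'
#' @param assign `ng_assignment` from [ng_assign()].
#' @param raw data.frame with a `sample_id` column and numeric variables in
#'   their original units (e.g. the picoplankton table joined with
#'   metadata); every assigned sample must be present.
#' @return long data.frame: unit, n, variable, mean, sd.
#' @export
summarize_bmus <- function(assign, raw) {
  a <- assign$assignments
  missing <- setdiff(a$sample_id, raw$sample_id)
  if (length(missing)) {
    stop("sample(s) missing from raw table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[match(a$sample_id, raw$sample_id), , drop = FALSE]
  vars <- names(raw)[vapply(raw, is.numeric, logical(1))]
  out <- do.call(rbind, lapply(sort(unique(a$unit)), function(u) {
    rows <- raw[a$unit == u, vars, drop = FALSE]
    n <- nrow(rows)
    data.frame(unit = u, n = n, variable = vars,
               mean = vapply(rows, mean, numeric(1)),
               sd = if (n > 1L) vapply(rows, sd, numeric(1)) else NA_real_,
               row.names = NULL)
  }))
  out
}

#' Water-column map of best-matching units
#'
#' One row per sample with its station, depth and assigned unit, sorted by
#' station then depth; duplicated (station, depth) pairs stay distinct rows.
#'
#' @param assign `ng_assignment`.
#' @param meta metadata data.frame with sample_id, station, depth.
#' @return data.frame: station, depth, sample_id, unit.
#' @export
bmu_map <- function(assign, meta) {
  a <- assign$assignments
  m <- meta[match(a$sample_id, meta$sample_id), c("station", "depth")]
  out <- data.frame(station = m$station, depth = m$depth,
                    sample_id = a$sample_id, unit = a$unit, row.names = NULL)
  out[order(out$station, out$depth), , drop = FALSE]
}

#' Per-unit taxon composition profiles
#'
#' The mean relative-abundance vector of the samples assigned to each unit
#' (unweighted mean over member samples); taxa whose per-unit mean falls
#' below `other_threshold` are pooled into an `"other"` category, so each
#' profile still sums to 1. Units with no assigned samples are omitted with
#' a warning.
#'
#' @param assign `ng_assignment`.
#' @param proportions samples x taxa matrix of relative abundances (rows sum
#'   to 1); row names are sample ids.
#' @param other_threshold pooling threshold in `[0, 1)` (default 0.01).
#' @return long data.frame: unit, taxon, mean_abundance; attribute
#'   `"other_threshold"`.
#' @export
bmu_composition <- function(assign, proportions, other_threshold = 0.01) {
  stopifnot(other_threshold >= 0, other_threshold < 1)
  mode <- attr(proportions, "mode")
  if (!is.null(mode) && !identical(mode, "proportions")) {
    stop("composition profiles need a proportions table (see to_relative)",
         call. = FALSE)
  }
  a <- assign$assignments
  p <- proportions[match(a$sample_id, rownames(proportions)), , drop = FALSE]
  k <- length(assign$frequencies)
  empty <- setdiff(seq_len(k), unique(a$unit))
  if (length(empty)) {
    warning("unit(s) with no samples omitted: ", paste(empty, collapse = ", "),
            call. = FALSE)
  }
  out <- do.call(rbind, lapply(sort(unique(a$unit)), function(u) {
    prof <- colMeans(p[a$unit == u, , drop = FALSE])
    minor <- prof < other_threshold
    kept <- prof[!minor]
    if (any(minor)) kept <- c(kept, other = sum(prof[minor]))
    data.frame(unit = u, taxon = names(kept), mean_abundance = unname(kept),
               row.names = NULL)
  }))
  attr(out, "other_threshold") <- other_threshold
  out
}

#' Anomaly-direction concordance between a target and comparator features
#'
#' On a standardized feature matrix, a sample shows "opposition" when the
#' sign of the target anomaly differs from the sign of the summary of the
#' comparator anomalies and both are nonzero. The comparator summary is the
#' per-sample median (default) or, with `method = "pairwise"`, opposition
#' holds when the target sign differs from a strict majority of the
#' individual comparator signs.
#'
#' @param features standardized matrix (see [zscore_normalize()]) with
#'   feature column names and sample row names.
#' @param target name of the target feature (e.g. `"salinity"`).
#' @param comparators names of one or more comparator features.
#' @param method `"median"` (default) or `"pairwise"`.
#' @return list: `fraction` (share of samples with opposition) and `detail`
#'   data.frame (sample_id, target_anomaly, comparator_summary, opposed).
#' @export
anomaly_concordance <- function(features, target, comparators,
                                method = c("median", "pairwise")) {
  method <- match.arg(method)
  stopifnot(target %in% colnames(features), length(comparators) >= 1L,
            all(comparators %in% colnames(features)))
  tv <- features[, target]
  if (all(tv == 0)) stop("target feature has zero variance", call. = FALSE)
  cm <- features[, comparators, drop = FALSE]
  if (method == "median") {
    summ <- apply(cm, 1L, median)
    opposed <- sign(tv) != sign(summ) & tv != 0 & summ != 0
  } else {
    opp_count <- rowSums(sign(cm) != 0 & sign(cm) != sign(tv) & tv != 0)
    summ <- opp_count / ncol(cm)
    opposed <- opp_count > ncol(cm) / 2
  }
  detail <- data.frame(
    sample_id = if (is.null(rownames(features)))
      as.character(seq_len(nrow(features))) else rownames(features),
    target_anomaly = unname(tv), comparator_summary = unname(summ),
    opposed = unname(opposed), row.names = NULL)
  list(fraction = mean(opposed), detail = detail)
}
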