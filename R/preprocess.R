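#' Remove non-bacterial and organelle ASVs
#'
#' Drops ASVs whose domain is not "Bacteria", or that carry a "Chloroplast" /
#' "Mitochondria" / "Mitochondrion" label at any rank (case-insensitive; the
#' SILVA taxonomy places chloroplasts at order and mitochondria at family
#' level). Samples are kept even if all their reads are removed.
#'
#' @param counts ASV table matrix (samples x ASVs).
#' @param tax taxonomy data.frame as returned by [read_taxonomy()].
#' @return filtered ASV table; attribute `"removed"` lists dropped ASV ids.
#' @export
taxonomic_filter <- function(counts, tax) {
  counts <- as_asv_table(counts)
  ids <- colnames(counts)
  missing <- setdiff(ids, tax$asv_id)
  if (length(missing)) {
    stop("ASV(s) absent from taxonomy: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tx <- tax[match(ids, tax$asv_id), , drop = FALSE]
  is_bact <- !is.na(tx$domain) & tolower(tx$domain) == "bacteria"
  organelle <- c("chloroplast", "mitochondria", "mitochondrion")
  rank_mat <- tolower(as.matrix(tx[, TAX_RANKS, drop = FALSE]))
  has_org <- apply(rank_mat, 1L, function(r) any(r %in% organelle, na.rm = TRUE))
  keep <- is_bact & !has_org
  out <- counts[, keep, drop = FALSE]
  emptied <- rownames(out)[rowSums(out) == 0 & rowSums(counts) > 0]
  if (length(emptied)) {
    warning("sample(s) emptied by taxonomic filter: ",
            paste(emptied, collapse = ", "), call. = FALSE)
  }
  attr(out, "removed") <- ids[!keep]
  out
}

#' Prevalence filter for ASV tables
#'
#' Keeps ASV j iff it is seen with at least `min_count` reads in at least
#' `ceiling(min_fraction * n_samples)` samples; the complement — ASVs seen
#' fewer than `min_count` times in the required share of samples — is removed.
#'
#' @param counts ASV table matrix (samples x ASVs).
#' @param min_count minimum per-sample read count (default 3).
#' @param min_fraction minimum fraction of samples (default 0.2).
#' @return filtered ASV table; attribute `"filter_log"` is a data.frame with
#'   per-ASV `n_passing` and `kept`.
#' @export
prevalence_filter <- function(counts, min_count = 3L, min_fraction = 0.2) {
  counts <- as_asv_table(counts)
  stopifnot(min_count >= 1L, min_fraction > 0, min_fraction <= 1)
  n <- nrow(counts)
  need <- ceiling(min_fraction * n)
  n_passing <- colSums(counts >= min_count)
  keep <- n_passing >= need
  log <- data.frame(asv_id = colnames(counts), n_passing = as.integer(n_passing),
                    kept = unname(keep), row.names = NULL)
  out <- counts[, keep, drop = FALSE]
  attr(out, "filter_log") <- log
  out
}

#' Agglomerate ASV counts to a taxonomic rank
#'
#' Counts are summed over ASVs sharing the label at `rank`. ASVs without a
#' label at that rank are pooled under the finest available ancestor label
#' suffixed `"_unclassified"` (or `"unclassified"` when no rank is assigned
#' at all). Per-sample read totals are conserved exactly.
#'
#' @param counts ASV table matrix (samples x ASVs).
#' @param tax taxonomy data.frame.
#' @param rank one of domain, phylum, class, order, family, genus.
#' @return integer matrix, samples x taxa, with attribute `"mode" = "counts"`.
#' @export
agglomerate_taxa <- function(counts, tax, rank = "genus") {
  counts <- as_asv_table(counts)
  rank <- match.arg(rank, TAX_RANKS)
  ids <- colnames(counts)
  missing <- setdiff(ids, tax$asv_id)
  if (length(missing)) {
    stop("ASV(s) absent from taxonomy: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tx <- tax[match(ids, tax$asv_id), , drop = FALSE]
  ri <- match(rank, TAX_RANKS)
  labels <- vapply(seq_along(ids), function(k) {
    lab <- tx[[rank]][k]
    if (!is.na(lab)) return(lab)
    for (j in rev(seq_len(ri - 1L))) {       # finest ancestor first
      anc <- tx[[TAX_RANKS[j]]][k]
      if (!is.na(anc)) return(paste0(anc, "_unclassified"))
    }
    "unclassified"
  }, character(1))
  groups <- factor(labels, levels = unique(labels))
  out <- t(rowsum(t(counts), groups))
  storage.mode(out) <- "integer"
  attr(out, "mode") <- "counts"
  out
}

#' Convert a count table to per-sample relative abundances
#'
#' @param counts samples x taxa count matrix; every sample total must be > 0.
#' @return numeric matrix of proportions; rows sum to 1. Attribute
#'   `"mode" = "proportions"`.
#' @export
to_relative <- function(counts) {
  mode <- attr(counts, "mode")
  if (!is.null(mode) && identical(mode, "proportions")) {
    stop("table is already in proportions mode", call. = FALSE)
  }
  totals <- rowSums(counts)
  zero <- rownames(counts)[totals == 0]
  if (length(zero)) {
    stop("sample(s) with zero total count: ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  out <- counts / totals
  attr(out, "mode") <- "proportions"
  out
}

#' Standardize each feature to zero mean and unit variance
#'
#' Each column is independently centered and scaled (sample standard
#' deviation, denominator n - 1), so values are signed standardized anomalies.
#' Constant columns become all zeros, with a warning and a record in the
#' `"constant_features"` attribute. Applying the operation twice leaves the
#' matrix unchanged.
#'
#' @param m numeric matrix, samples x features, no missing values.
#' @return numeric matrix with attributes `"centers"`, `"scales"` and
#'   `"constant_features"`.
#' @export
zscore_normalize <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 samples to standardize", call. = FALSE)
  if (anyNA(m)) stop("missing values in feature matrix", call. = FALSE)
  centers <- colMeans(m)
  scales <- apply(m, 2L, sd)
  constant <- scales < .Machine$double.eps^0.5
  if (any(constant)) {
    warning("constant feature(s) set to zero: ",
            paste(colnames(m)[constant], collapse = ", "), call. = FALSE)
    scales[constant] <- 1
  }
  out <- sweep(sweep(m, 2L, centers, "-"), 2L, scales, "/")
  out[, constant] <- 0
  attr(out, "centers") <- centers
  attr(out, "scales") <- scales
  attr(out, "constant_features") <- colnames(m)[constant]
  out
}

#' Classify nutrient limitation from inorganic stoichiometry
#'
#' Phosphorus limitation: SRP < 0.1 umol/L and TIN/SRP > 22 and SiO4/SRP > 22.
#' Nitrogen limitation: TIN < 1 umol/L. When SRP = 0 the ratios are +Inf and
#' the inequalities are applied as stated. The extended nitrogen criterion
#' (TIN < 1 and TIN/SRP < 10 and Si/TIN > 1) is reported as a separate column
#' and never folded into `n_limited`.
#'
#' @param meta data.frame with columns sample_id, tin, srp, sio4.
#' @return data.frame: sample_id, n_p, si_p, si_tin, p_limited, n_limited,
#'   n_limited_ext.
#' @export
classify_limitation <- function(meta) {
  need <- c("sample_id", "tin", "srp", "sio4")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata misses column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tin <- meta$tin; srp <- meta$srp; sio4 <- meta$sio4
  n_p <- ifelse(srp > 0, tin / srp, Inf)
  si_p <- ifelse(srp > 0, sio4 / srp, Inf)
  si_tin <- ifelse(tin > 0, sio4 / tin, Inf)
  data.frame(
    sample_id = meta$sample_id,
    n_p = n_p, si_p = si_p, si_tin = si_tin,
    p_limited = srp < 0.1 & n_p > 22 & si_p > 22,
    n_limited = tin < 1,
    n_limited_ext = tin < 1 & n_p < 10 & si_tin > 1,
    row.names = NULL
  )
}
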