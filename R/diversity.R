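#' Shannon diversity index
#'
#' `H' = -sum(p_i * log(p_i))` over taxa with positive counts, with
#' `p_i = count_i / total`. Computed via [vegan::diversity()].
#'
#' @param counts non-negative count vector with at least one positive entry.
#' @param base logarithm base (default `exp(1)`, i.e. nats).
#' @return Shannon entropy.
#' @export
shannon_index <- function(counts, base = exp(1)) {
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) stop("all-zero count vector", call. = FALSE)
  unname(vegan::diversity(counts, index = "shannon", base = base))
}

#' Pielou's evenness
#'
#' `J' = H' / log(S_obs)`, where `S_obs` is the number of taxa with positive
#' counts. Undefined (NA, with a warning) for single-taxon samples.
#'
#' @inheritParams shannon_index
#' @return evenness in `[0, 1]`, or `NA` when `S_obs < 2`.
#' @export
pielou_evenness <- function(counts, base = exp(1)) {
  s_obs <- sum(counts > 0)
  if (s_obs < 2L) {
    warning("Pielou evenness undefined for a single-taxon sample",
            call. = FALSE)
    return(NA_real_)
  }
  shannon_index(counts, base) / log(s_obs, base = base)
}

#' Per-sample diversity table
#'
#' Observed richness, Shannon H', Pielou J' and total reads for every sample
#' of a count table. Following the source pipeline, indices are meant to be
#' computed on the untransformed, unrarefied (but filtered) ASV table; the
#' table used is up to the caller and recorded in the attribute `"table"`.
#'
#' @param counts samples x taxa count matrix.
#' @param base logarithm base (default nats).
#' @param table_label free-text label of which table was used (default
#'   `"filtered"`).
#' @return data.frame: sample_id, s_obs, shannon, pielou, total_reads.
#' @export
diversity_table <- function(counts, base = exp(1), table_label = "filtered") {
  out <- data.frame(
    sample_id = rownames(counts),
    s_obs = as.integer(rowSums(counts > 0)),
    shannon = apply(counts, 1L, shannon_index, base = base),
    pielou = vapply(seq_len(nrow(counts)), function(i) {
      if (sum(counts[i, ] > 0) < 2L) NA_real_
      else suppressWarnings(pielou_evenness(counts[i, ], base))
    }, numeric(1)),
    total_reads = unname(rowSums(counts)),
    row.names = NULL)
  attr(out, "table") <- table_label
  out
}

#' Expected rarefaction curve
#'
#' Exact hypergeometric expectation of observed richness in a uniform random
#' subsample of `n` reads:
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))`,
#' evaluated with log-binomial arithmetic via [vegan::rarefy()].
#'
#' @param counts non-negative integer count vector.
#' @param depths subsample sizes, each between 1 and `sum(counts)`.
#' @return numeric vector of expected richness, one value per depth.
#' @export
rarefaction_curve <- function(counts, depths) {
  n_tot <- sum(counts)
  if (any(depths < 1) || any(depths > n_tot)) {
    stop("subsample depths must lie in [1, total reads]", call. = FALSE)
  }
  vapply(depths, function(n) {
    unname(suppressWarnings(
      vegan::rarefy(matrix(as.integer(counts), nrow = 1), sample = n)))
  }, numeric(1))
}

#' Monte-Carlo rarefaction
#'
#' Average observed richness over repeated subsampling without replacement;
#' a stochastic cross-check of [rarefaction_curve()].
#'
#' @param counts non-negative integer count vector.
#' @param depth subsample size.
#' @param draws number of Monte-Carlo draws (default 1000).
#' @return list with `mean` richness and its standard error `se`.
#' @export
rarefaction_mc <- function(counts, depth, draws = 1000L) {
  n_tot <- sum(counts)
  stopifnot(depth >= 1, depth <= n_tot)
  pool <- rep.int(seq_along(counts), counts)
  s <- vapply(seq_len(draws), function(i) {
    length(unique(pool[sample.int(n_tot, depth)]))
  }, numeric(1))
  list(mean = mean(s), se = sd(s) / sqrt(draws))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks are used for ties; p-values use the t-distribution
#' approximation (no multiplicity correction). Constant input yields `NA`
#' with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return data.frame: r, n, p.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined", call. = FALSE)
    return(data.frame(r = NA_real_, n = length(x), p = NA_real_))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  data.frame(r = unname(ct$estimate), n = length(x), p = ct$p.value)
}
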