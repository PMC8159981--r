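# Variables entering the picoplankton (PIC) feature space: abundances of the
# main functional groups, the HNA/LNA shares and bacterial production.
PIC_FEATURES <- c("tp", "syn", "prochl", "pe", "hnf", "aap",
                  "hna_pct", "lna_pct", "bp")

#' Picoplankton feature matrix
#'
#' Extracts the nine variables of the picoplankton analysis (tp, syn, prochl,
#' pe, hnf, aap, hna_pct, lna_pct, bp) as a numeric matrix with sample ids as
#' row names, ready for [zscore_normalize()].
#'
#' @param pico picoplankton data.frame (see [read_pico_table()]).
#' @return numeric matrix, samples x 9.
#' @export
pico_feature_matrix <- function(pico) {
  miss <- setdiff(PIC_FEATURES, names(pico))
  if (length(miss)) stop("picoplankton table misses: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  m <- as.matrix(pico[, PIC_FEATURES])
  rownames(m) <- pico$sample_id
  m
}

stage_dir <- function(run_dir, idx, name) {
  p <- file.path(run_dir, sprintf("%02d_%s", idx, name))
  dir.create(p, recursive = TRUE, showWarnings = FALSE)
  p
}

#' Run the full analysis pipeline
#'
#' Orchestrates one analysis mode end to end and writes every intermediate
#' table plus a manifest to a run directory:
#'
#' * `"BCC"` (bacterial community composition): taxonomic filter ->
#'   prevalence filter -> genus agglomeration -> relative abundances ->
#'   per-genus standardization -> neural gas -> composition profiles, BMU
#'   depth map, diversity indices and their Spearman correlation with the
#'   chlorophyll-fluorescence proxy.
#' * `"PIC"` (picoplankton): nine standardized picoplankton variables ->
#'   neural gas -> per-unit summaries of raw variables and metadata, BMU
#'   depth map, salinity anomaly-direction concordance, nutrient-limitation
#'   classification.
#'
#' The number of units is either fixed (`k`) or chosen by the SSIntra
#' coefficient of variation over `k_grid`. Reruns with identical inputs and
#' configuration produce byte-identical outputs.
#'
#' @param counts ASV table matrix (BCC mode).
#' @param taxonomy taxonomy data.frame (BCC mode).
#' @param metadata sample metadata data.frame (both modes).
#' @param pico picoplankton data.frame (PIC mode).
#' @param mode `"PIC"` or `"BCC"`.
#' @param out_dir run directory (created; refuses to overwrite an existing
#'   manifest unless `overwrite = TRUE`).
#' @param k fixed number of units, or `NULL` to select over `k_grid`.
#' @param k_grid,restarts model-selection grid and restarts per K.
#' @param epochs,eps_init,eps_final,lambda_init,lambda_final training
#'   schedule (see [ng_train()]).
#' @param min_count,min_fraction prevalence-filter parameters.
#' @param rank agglomeration rank (BCC mode).
#' @param other_threshold composition pooling threshold.
#' @param seed integer seed driving training and model selection.
#' @param overwrite allow overwriting an existing run directory.
#' @return (invisibly) list with the model, assignment, selection table (if
#'   any), per-stage outputs and the manifest.
#' @export
run_pipeline <- function(counts = NULL, taxonomy = NULL, metadata = NULL,
                         pico = NULL, mode = c("PIC", "BCC"),
                         out_dir, k = NULL, k_grid = 2:8, restarts = 10L,
                         epochs = 500L, eps_init = 0.5, eps_final = 0.005,
                         lambda_init = 2.5, lambda_final = 0.01,
                         min_count = 3L, min_fraction = 0.2, rank = "genus",
                         other_threshold = 0.01, seed = 1L,
                         overwrite = FALSE) {
  mode <- match.arg(mode)
  if (is.null(metadata)) stop("metadata is required", call. = FALSE)
  if (mode == "BCC" && (is.null(counts) || is.null(taxonomy))) {
    stop("BCC mode requires counts and taxonomy", call. = FALSE)
  }
  if (mode == "PIC" && is.null(pico)) {
    stop("PIC mode requires the picoplankton table", call. = FALSE)
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop("run directory already contains a manifest; use overwrite = TRUE",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  outputs <- character(0)
  res <- list(mode = mode)

  if (mode == "BCC") {
    d1 <- stage_dir(out_dir, 1, "filter")
    n_before <- ncol(counts)
    filt_tax <- taxonomic_filter(counts, taxonomy)
    n_after_tax <- ncol(filt_tax)
    filt <- prevalence_filter(filt_tax, min_count, min_fraction)
    n_after_prev <- ncol(filt)
    message(sprintf("taxonomic filter: %d -> %d ASVs; prevalence filter: %d -> %d ASVs",
                    n_before, n_after_tax, n_after_tax, n_after_prev))
    outputs <- c(outputs, write_asv_table(filt, file.path(d1, "filtered_asv.tsv")),
                 write_tsv(attr(filt, "filter_log"),
                           file.path(d1, "prevalence_log.tsv")))
    stages$filter <- list(asvs_input = n_before, asvs_after_taxonomic = n_after_tax,
                          asvs_after_prevalence = n_after_prev,
                          reads_after = sum(filt))

    d2 <- stage_dir(out_dir, 2, "genus")
    genus <- agglomerate_taxa(filt, taxonomy, rank)
    rel <- to_relative(genus)
    outputs <- c(outputs, write_tsv(
      data.frame(sample_id = rownames(rel), as.data.frame(rel),
                 check.names = FALSE),
      file.path(d2, "genus_proportions.tsv")))
    stages$genus <- list(rank = rank, n_taxa = ncol(genus))
    features <- zscore_normalize(rel)
    res$filtered <- filt; res$proportions <- rel
  } else {
    features <- zscore_normalize(pico_feature_matrix(pico))
    stages$features <- list(n_features = ncol(features))
  }
  res$features <- features

  d3 <- stage_dir(out_dir, if (mode == "BCC") 3L else 1L, "model")
  if (is.null(k)) {
    sel <- ng_select_k(features, k_grid, restarts = restarts, base_seed = seed,
                       epochs = epochs, eps_init = eps_init,
                       eps_final = eps_final, lambda_init = lambda_init,
                       lambda_final = lambda_final)
    outputs <- c(outputs, write_tsv(sel$table, file.path(d3, "k_selection.tsv")))
    k_used <- sel$chosen_k
    stages$select_k <- list(k_grid = k_grid, restarts = restarts,
                            chosen_k = k_used)
    res$selection <- sel
  } else {
    k_used <- as.integer(k)
  }
  model <- ng_train(features, k_used, epochs = epochs, eps_init = eps_init,
                    eps_final = eps_final, lambda_init = lambda_init,
                    lambda_final = lambda_final, seed = seed)
  assign <- ng_assign(features, model)
  outputs <- c(outputs,
               write_tsv(as.data.frame(model$codebook),
                         file.path(d3, "codebook.tsv")),
               write_tsv(assign$assignments, file.path(d3, "assignments.tsv")),
               write_tsv(data.frame(unit = seq_along(assign$frequencies),
                                    frequency = unname(assign$frequencies)),
                         file.path(d3, "unit_frequencies.tsv")))
  stages$model <- list(k = k_used, epochs = epochs,
                       final_ss_intra = model$final_ss_intra)
  res$model <- model; res$assignment <- assign

  d4 <- stage_dir(out_dir, if (mode == "BCC") 4L else 2L, "characterize")
  map <- bmu_map(assign, metadata)
  outputs <- c(outputs, write_tsv(map, file.path(d4, "bmu_map.tsv")))
  if (mode == "BCC") {
    comp <- bmu_composition(assign, res$proportions, other_threshold)
    outputs <- c(outputs, write_tsv(comp, file.path(d4, "bmu_composition.tsv")))
    res$composition <- comp

    d5 <- stage_dir(out_dir, 5L, "diversity")
    div <- diversity_table(res$filtered)
    m <- metadata[match(div$sample_id, metadata$sample_id), ]
    cors <- do.call(rbind, lapply(c("shannon", "pielou", "s_obs"), function(v) {
      cbind(index = v, spearman_cor(div[[v]], m$chl_fluor))
    }))
    outputs <- c(outputs, write_tsv(div, file.path(d5, "diversity.tsv")),
                 write_tsv(cors, file.path(d5, "chl_correlations.tsv")))
    res$diversity <- div; res$correlations <- cors
    stages$diversity <- list(covariate = "chl_fluor")
  } else {
    raw <- merge(pico, metadata, by = "sample_id", sort = FALSE)
    summ <- summarize_bmus(assign, raw)
    conc <- anomaly_concordance(
      zscore_normalize(as.matrix(
        cbind(metadata[match(rownames(features), metadata$sample_id),
                       "salinity", drop = FALSE],
              pico[match(rownames(features), pico$sample_id), BIOTIC_BLOCK]))),
      target = "salinity", comparators = BIOTIC_BLOCK)
    lim <- classify_limitation(metadata)
    outputs <- c(outputs,
                 write_tsv(summ, file.path(d4, "cluster_summary.tsv")),
                 write_tsv(conc$detail, file.path(d4, "salinity_concordance.tsv")),
                 write_tsv(lim, file.path(d4, "nutrient_limitation.tsv")))
    res$summary <- summ; res$concordance <- conc; res$limitation <- lim
    stages$characterize <- list(salinity_concordance = conc$fraction)
  }

  manifest <- list(
    package = "picogas",
    version = as.character(utils::packageVersion("picogas")),
    mode = mode,
    config = list(k = if (is.null(k)) NULL else as.integer(k),
                  k_grid = as.integer(k_grid), restarts = as.integer(restarts),
                  epochs = as.integer(epochs), eps_init = eps_init,
                  eps_final = eps_final, lambda_init = lambda_init,
                  lambda_final = lambda_final, min_count = as.integer(min_count),
                  min_fraction = min_fraction, rank = rank,
                  other_threshold = other_threshold, seed = as.integer(seed)),
    n_samples = nrow(features),
    stages = stages,
    checksums = as.list(setNames(
      unname(tools::md5sum(sort(outputs))),
      substring(sort(outputs), nchar(out_dir) + 2L)))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}
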