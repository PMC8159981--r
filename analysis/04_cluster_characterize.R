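#!/usr/bin/env Rscript
# Stage 4: train the neural-gas models and characterize the clusters.
#
# Both blocks are quantized with four best-matching units (the planted
# community-type number, which the PIC selection in stage 3 also picks) via
# best-of-10-restart training. Outputs: sample -> BMU assignments and unit
# frequencies, per-BMU summaries of the raw variables, the station x depth
# BMU map, per-BMU genus composition profiles with "other" pooling, the
# salinity anomaly-opposition fraction, and recovery of the planted labels.

library(picogas)

out <- "results/characterize"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L
k <- 4L
comparators <- c("tp", "syn", "prochl", "pe", "hnf", "aap", "bp")

pico <- read_pico_table("results/data/picoplankton.tsv")
meta <- read_sample_metadata("results/data/metadata.tsv")
truth <- read.delim("results/data/planted_truth.tsv")
genus <- read.delim("results/preprocess/genus_proportions.tsv",
                    check.names = FALSE)
rel <- as.matrix(genus[, -1]); rownames(rel) <- genus$sample_id
attr(rel, "mode") <- "proportions"

pic_feats <- zscore_normalize(pico_feature_matrix(pico))
bcc_feats <- zscore_normalize(rel)

pic_fit <- ng_train_best(pic_feats, k, restarts = 10, base_seed = seed)
bcc_fit <- ng_train_best(bcc_feats, k, restarts = 10, base_seed = seed)
pic_assign <- ng_assign(pic_feats, pic_fit)
bcc_assign <- ng_assign(bcc_feats, bcc_fit)

ari <- function(a) mclust::adjustedRandIndex(a$assignments$unit, truth$cluster)
cat(sprintf("PIC: final SSIntra %.2f, unit frequencies %s, ARI vs truth %.2f\n",
            pic_fit$final_ss_intra,
            paste(sprintf("%.0f%%", 100 * pic_assign$frequencies), collapse = "/"),
            ari(pic_assign)))
cat(sprintf("BCC: final SSIntra %.2f, ARI vs truth %.2f\n",
            bcc_fit$final_ss_intra, ari(bcc_assign)))

summ <- summarize_bmus(pic_assign, merge(pico, meta, by = "sample_id",
                                         sort = FALSE))
comp <- bmu_composition(bcc_assign, rel, other_threshold = 0.02)
conc <- anomaly_concordance(
  zscore_normalize(as.matrix(cbind(meta["salinity"], pico[, comparators]))),
  target = "salinity", comparators = comparators)
cat(sprintf("salinity anomaly opposition: %.0f%% of samples\n",
            100 * conc$fraction))

write_tsv(pic_assign$assignments, file.path(out, "pic_assignments.tsv"))
write_tsv(bcc_assign$assignments, file.path(out, "bcc_assignments.tsv"))
write_tsv(summ, file.path(out, "pic_cluster_summary.tsv"))
write_tsv(bmu_map(pic_assign, meta), file.path(out, "pic_bmu_map.tsv"))
write_tsv(comp, file.path(out, "bcc_composition.tsv"))
write_tsv(conc$detail, file.path(out, "salinity_concordance.tsv"))
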