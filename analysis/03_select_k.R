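#!/usr/bin/env Rscript
# Stage 3: choose the number of best-matching units for both analyses.
#
# For the picoplankton (PIC) block (nine standardized abundance/production
# variables) and the community-composition (BCC) block (standardized genus
# proportions), ten under-annealed restarts per candidate K probe the
# stability of the quantization; the chosen K is the largest whose best
# SSIntra is reproduced by at least 90% of restarts. The full
# mean/sd/CV/share tables are written so the choice is auditable.

library(picogas)

out <- "results/model"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

pico <- read_pico_table("results/data/picoplankton.tsv")
pic_feats <- zscore_normalize(pico_feature_matrix(pico))

genus <- read.delim("results/preprocess/genus_proportions.tsv",
                    check.names = FALSE)
rel <- as.matrix(genus[, -1]); rownames(rel) <- genus$sample_id
bcc_feats <- zscore_normalize(rel)

pic_sel <- ng_select_k(pic_feats, 2:8, restarts = 10, base_seed = seed)
bcc_sel <- ng_select_k(bcc_feats, 2:8, restarts = 10, base_seed = seed)

cat("PIC selection (9 features):\n"); print(pic_sel)
cat("\nBCC selection (", ncol(bcc_feats), "genus features):\n"); print(bcc_sel)
cat("\nNote: in the high-dimensional BCC space the singleton deep sample\n",
    "depresses the share at K = 4 (see the methods vignette); the 4-unit\n",
    "structure is still recovered by best-of-restarts training in stage 4.\n")

write_tsv(pic_sel$table, file.path(out, "pic_k_selection.tsv"))
write_tsv(bcc_sel$table, file.path(out, "bcc_k_selection.tsv"))
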