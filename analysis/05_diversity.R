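#!/usr/bin/env Rscript
# Stage 5: alpha diversity on the filtered (untransformed, unrarefied) table.
#
# Per-sample observed richness, Shannon H' (nats) and Pielou J', exact
# hypergeometric rarefaction curves for the shallowest/deepest sample of
# each station, and Spearman correlations of the indices against the
# chlorophyll-fluorescence proxy.

library(picogas)

out <- "results/diversity"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

filt <- read_asv_table("results/preprocess/filtered_asv.tsv")
meta <- read_sample_metadata("results/data/metadata.tsv")

div <- diversity_table(filt)
m <- meta[match(div$sample_id, meta$sample_id), ]
cors <- do.call(rbind, lapply(c("shannon", "pielou", "s_obs"), function(v) {
  cbind(index = v, spearman_cor(div[[v]], m$chl_fluor))
}))
cat(sprintf("diversity over %d samples: H' %.2f-%.2f, J' %.2f-%.2f, S %d-%d\n",
            nrow(div), min(div$shannon), max(div$shannon),
            min(div$pielou, na.rm = TRUE), max(div$pielou, na.rm = TRUE),
            min(div$s_obs), max(div$s_obs)))
cat("Spearman vs chlorophyll fluorescence:\n")
print(cors, row.names = FALSE)

depths_grid <- function(n) unique(c(round(seq(1, n, length.out = 25)), n))
picks <- unlist(lapply(split(m$sample_id, m$station), function(ids) {
  d <- m$depth[match(ids, m$sample_id)]
  ids[c(which.min(d), which.max(d))]
}))
curves <- do.call(rbind, lapply(unique(picks), function(sid) {
  v <- filt[sid, ]
  g <- depths_grid(sum(v))
  data.frame(sample_id = sid, reads = g,
             expected_richness = rarefaction_curve(v, g))
}))

write_tsv(div, file.path(out, "diversity.tsv"))
write_tsv(cors, file.path(out, "chl_correlations.tsv"))
write_tsv(curves, file.path(out, "rarefaction_curves.tsv"))
cat(sprintf("rarefaction curves written for %d samples\n",
            length(unique(curves$sample_id))))
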