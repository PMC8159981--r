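#!/usr/bin/env Rscript
# Stage 2: filtering, genus agglomeration and nutrient-limitation status.
#
# Applies the two ASV filters in their canonical order (taxonomic removal of
# non-bacterial/organelle ASVs, then the >= 3 reads in >= 20% of samples
# prevalence rule), agglomerates to genus proportions, and classifies each
# sample's nutrient limitation from inorganic stoichiometry.

library(picogas)

out <- "results/preprocess"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_asv_table("results/data/asv_counts.tsv")
tax <- read_taxonomy("results/data/taxonomy.tsv")
meta <- read_sample_metadata("results/data/metadata.tsv")

filt_tax <- taxonomic_filter(counts, tax)
filt <- prevalence_filter(filt_tax, min_count = 3L, min_fraction = 0.2)
cat(sprintf("taxonomic filter: %d -> %d ASVs (removed %d)\n",
            ncol(counts), ncol(filt_tax), length(attr(filt_tax, "removed"))))
cat(sprintf("prevalence filter: %d -> %d ASVs; reads retained: %d\n",
            ncol(filt_tax), ncol(filt), sum(filt)))

genus <- agglomerate_taxa(filt, tax, rank = "genus")
rel <- to_relative(genus)
cat(sprintf("agglomerated to %d genus-level taxa\n", ncol(genus)))

lim <- classify_limitation(meta)
cat(sprintf("limitation: %d/%d samples P-limited, %d/%d N-limited\n",
            sum(lim$p_limited), nrow(lim), sum(lim$n_limited), nrow(lim)))

write_asv_table(filt, file.path(out, "filtered_asv.tsv"))
write_tsv(attr(filt, "filter_log"), file.path(out, "prevalence_log.tsv"))
write_tsv(data.frame(sample_id = rownames(rel), as.data.frame(rel),
                     check.names = FALSE),
          file.path(out, "genus_proportions.tsv"))
write_tsv(lim, file.path(out, "nutrient_limitation.tsv"))
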