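#!/usr/bin/env Rscript
# Stage 1: generate the synthetic depth-stratified survey.
#
# Emulates a 6-station late-summer survey (JP1, PS1-2, SAP1-3; 22 sequenced
# samples over 0-100 m) with four depth-bin community types, contaminant and
# rare ASVs, hydrographic depth profiles, and picoplankton vectors carrying a
# planted negative salinity association. Writes the plain-text inputs that
# the later stages read back through the package's own readers.

library(picogas)

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scenario <- community_scenario()
ds <- generate_dataset(scenario, seed = seed)

write_asv_table(ds$counts, file.path(out, "asv_counts.tsv"))
write_tsv(ds$taxonomy, file.path(out, "taxonomy.tsv"))
write_tsv(ds$metadata, file.path(out, "metadata.tsv"))
write_tsv(ds$pico, file.path(out, "picoplankton.tsv"))
write_tsv(data.frame(sample_id = ds$metadata$sample_id,
                     cluster = planted_truth(ds)$labels),
          file.path(out, "planted_truth.tsv"))

cat(sprintf("simulated %d samples x %d ASVs at %d stations (seed %d)\n",
            nrow(ds$counts), ncol(ds$counts),
            length(unique(ds$metadata$station)), seed))
cat(sprintf("mean reads per sample: %.0f (sd %.0f)\n",
            mean(rowSums(ds$counts)), sd(rowSums(ds$counts))))
cat(sprintf("planted community types by depth bin: %s\n",
            paste(table(ds$truth), collapse = " / ")))
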