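test_that("the default scenario reproduces the survey design", {
  sc <- community_scenario()
  ds <- generate_dataset(sc, seed = 1)
  expect_equal(nrow(ds$counts), 22)
  expect_identical(sort(unique(ds$metadata$station)),
                   c("JP1", "PS1", "PS2", "SAP1", "SAP2", "SAP3"))
  expect_true(all(ds$truth %in% 1:4))
  expect_equal(length(unique(ds$truth)), 4)
  # counts rows sum to the drawn read depth; reads are plausible
  expect_true(all(rowSums(ds$counts) > 2e4))
  # taxonomy covers every ASV
  expect_true(all(colnames(ds$counts) %in% ds$taxonomy$asv_id))
  # metadata invariants
  expect_true(all(ds$metadata$depth >= 0))
  expect_equal(ds$metadata$tin,
               ds$metadata$no3 + ds$metadata$no2 + ds$metadata$nh4)
  expect_true(all(abs(ds$pico$hna_pct + ds$pico$lna_pct - 100) < 1e-9))
})

test_that("generation is fully reproducible from the seed", {
  sc <- community_scenario()
  a <- generate_dataset(sc, seed = 42)
  b <- generate_dataset(sc, seed = 42)
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$pico, b$pico)
  d <- generate_dataset(sc, seed = 43)
  expect_false(identical(a$counts, d$counts))
})

test_that("without contaminants and rare ASVs the filters change nothing", {
  sc <- community_scenario(contaminant_fraction = 0, rare_asv_count = 0)
  ds <- generate_dataset(sc, seed = 1)
  f1 <- taxonomic_filter(ds$counts, ds$taxonomy)
  f2 <- prevalence_filter(f1)
  expect_identical(ncol(f2), ncol(ds$counts))
})

test_that("contaminant and rare ASVs are removed by the intended filter", {
  ds <- generate_dataset(community_scenario(), seed = 2)
  cont <- grep("^CONT", colnames(ds$counts), value = TRUE)
  rare <- grep("^RARE", colnames(ds$counts), value = TRUE)
  expect_gt(length(cont), 0)
  expect_gt(length(rare), 0)
  f1 <- taxonomic_filter(ds$counts, ds$taxonomy)
  expect_true(all(cont %in% attr(f1, "removed")))
  f2 <- prevalence_filter(f1)
  kept <- colnames(f2)
  expect_false(any(rare %in% kept))
  # rare ASVs never reach the keep threshold by construction
  expect_true(all(ds$counts[, rare] <= 2))
})

test_that("read depths hit the scenario mean and cv", {
  set.seed(99)
  rd <- draw_read_depths(1000, 93317, 23087 / 93317)
  expect_lt(abs(mean(rd) / 93317 - 1), 0.05)
  expect_lt(abs((sd(rd) / mean(rd)) / (23087 / 93317) - 1), 0.05)
})

test_that("the planted salinity correlation is realized", {
  sc <- community_scenario(stations = list(S1 = seq(0, 100, length.out = 500)))
  ds <- generate_dataset(sc, seed = 5)
  b <- rowMeans(scale(as.matrix(
    ds$pico[, c("tp", "syn", "prochl", "pe", "hnf", "aap", "bp")])))
  expect_lt(abs(cor(ds$metadata$salinity, b) - (-0.9)), 0.1)
})

test_that("planted truth aligns with the depth-bin rule", {
  sc <- community_scenario()
  ds <- generate_dataset(sc, seed = 3)
  tr <- planted_truth(ds)
  expect_identical(names(tr$labels), ds$metadata$sample_id)
  want <- findInterval(ds$metadata$depth, sc$depth_breaks) + 1L
  expect_identical(unname(tr$labels), want)
  # depth bins are left-closed at the breakpoints (25 m joins the second bin)
  expect_identical(as.vector(table(tr$labels)), c(11L, 6L, 4L, 1L))
  # K_true = 1 is all one label
  sc1 <- community_scenario(depth_breaks = numeric(0),
                            pico_means = default_pico_means(1))
  expect_true(all(planted_truth(generate_dataset(sc1, seed = 1))$labels == 1))
})

test_that("infeasible depth grids are rejected", {
  expect_error(community_scenario(stations = list(S = c(5, 10)),
                                  depth_breaks = c(25, 60, 90)),
               "infeasible")
})

test_that("planted Gaussian clusters respect the separation contract", {
  pc <- generate_planted_clusters(40, 4, 6, separation = 5, seed = 7)
  expect_equal(dim(pc$x), c(40, 6))
  expect_identical(sort(unique(pc$labels)), 1:4)
  cents <- rowsum(pc$x, pc$labels) / as.vector(table(pc$labels))
  # empirical centers sit near the planted ones, so min distance ~ separation
  expect_gt(min(dist(cents)), 3.5)
  expect_identical(generate_planted_clusters(40, 4, 6, 5, seed = 7)$x, pc$x)
})
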