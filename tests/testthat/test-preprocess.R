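test_that("taxonomic filter keeps bacteria and drops organelles at any rank", {
  counts <- random_asv_table(3, 3, seed = 1)
  tax <- data.frame(
    asv_id = colnames(counts),
    domain = c("Bacteria", "Eukaryota", "Bacteria"),
    phylum = c("Cyanobacteria", "Ochrophyta", "Cyanobacteria"),
    class = NA, order = c(NA, NA, "Chloroplast"), family = NA,
    genus = c("Synechococcus", NA, NA), stringsAsFactors = FALSE)
  out <- taxonomic_filter(counts, tax)
  expect_identical(colnames(out), "a001")
  expect_identical(attr(out, "removed"), c("a002", "a003"))

  # all-bacterial table is untouched
  tax2 <- tax
  tax2$domain <- "Bacteria"; tax2$order <- NA
  expect_identical(colnames(taxonomic_filter(counts, tax2)), colnames(counts))

  # mitochondria matched case-insensitively at family rank
  tax3 <- tax2
  tax3$family <- c(NA, "MITOCHONDRIA", "Mitochondrion")
  expect_identical(colnames(taxonomic_filter(counts, tax3)), "a001")

  expect_error(taxonomic_filter(counts, tax[-2, ]), "a002")
})

test_that("prevalence filter applies the count/fraction keep rule", {
  counts <- matrix(c(3, 3, 0, 0, 0,
                     2, 9, 0, 0, 0,
                     3, 3, 3, 3, 3), 5, 3,
                   dimnames = list(paste0("s", 1:5), c("two", "one", "all")))
  storage.mode(counts) <- "integer"
  # keep rule: count >= 3 in at least ceiling(fraction * n) samples
  out <- prevalence_filter(counts, 3L, 0.2)   # needs 1 of 5 samples
  expect_identical(colnames(out), c("two", "one", "all"))
  out4 <- prevalence_filter(counts, 3L, 0.4)  # needs 2 of 5 samples
  expect_identical(colnames(out4), c("two", "all"))
  expect_identical(attr(out4, "filter_log")$kept, c(TRUE, FALSE, TRUE))
  # boundary: min_fraction = 1 keeps an ASV present >= 3 everywhere
  expect_identical(colnames(prevalence_filter(counts, 3L, 1)), "all")
})

test_that("filters agree exactly with brute-force predicates on random tables", {
  set.seed(2024)
  for (i in 1:300) {
    counts <- random_asv_table(sample(2:20, 1), sample(2:50, 1),
                               lambda = runif(1, 0.5, 4))
    tax <- random_taxonomy(colnames(counts))
    keep_t <- oracle_taxonomic_keep(counts, tax)
    expect_identical(cn(suppressWarnings(taxonomic_filter(counts, tax))),
                     cn(counts)[keep_t])
    mc <- sample(1:5, 1); mf <- runif(1, 0.05, 1)
    keep_p <- oracle_prevalence_keep(counts, mc, mf)
    expect_identical(cn(prevalence_filter(counts, mc, mf)),
                     cn(counts)[keep_p])
  }
})

test_that("prevalence filter is monotone in its thresholds", {
  set.seed(7)
  counts <- random_asv_table(15, 40, lambda = 1.5)
  base <- colnames(prevalence_filter(counts, 2L, 0.2))
  expect_true(all(colnames(prevalence_filter(counts, 3L, 0.2)) %in% base))
  expect_true(all(colnames(prevalence_filter(counts, 2L, 0.4)) %in% base))
})

test_that("agglomeration sums counts by rank label and pools unassigned", {
  counts <- matrix(c(5L, 1L, 7L, 2L, 3L, 4L), 2, 3,
                   dimnames = list(c("s1", "s2"), c("a1", "a2", "a3")))
  tax <- data.frame(asv_id = c("a1", "a2", "a3"), domain = "Bacteria",
                    phylum = "P", class = NA, order = NA,
                    family = c(NA, NA, "F"),
                    genus = c("G", "G", NA), stringsAsFactors = FALSE)
  g <- agglomerate_taxa(counts, tax, "genus")
  expect_identical(g[, "G"], c(s1 = 12L, s2 = 3L))
  expect_identical(colnames(g), c("G", "F_unclassified"))
  expect_identical(rowSums(g), rowSums(counts))  # read conservation
  # no rank at all below domain -> pooled under the domain label
  tax$family <- NA; tax$phylum <- NA
  g2 <- agglomerate_taxa(counts, tax, "genus")
  expect_true("Bacteria_unclassified" %in% colnames(g2))
})

test_that("relative abundances sum to one and zero samples are rejected", {
  counts <- matrix(c(1L, 0L, 3L, 0L), 2, 2,
                   dimnames = list(c("s1", "s2"), c("g1", "g2")))
  expect_error(to_relative(counts), "s2")
  counts[2, 2] <- 4L
  rel <- to_relative(counts)
  expect_equal(rel["s1", ], c(g1 = 0.25, g2 = 0.75))
  expect_equal(unname(rowSums(rel)), c(1, 1))
})

test_that("z-scoring yields unit-variance anomalies and handles edge cases", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- zscore_normalize(m)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1), tolerance = 1e-12)
  # idempotence
  expect_equal(zscore_normalize(z), z, tolerance = 1e-9, ignore_attr = TRUE)
  # invariance under affine rescaling of an input feature
  m2 <- m; m2[, "b"] <- 3 * m2[, "b"] - 7
  expect_equal(zscore_normalize(m2)[, "b"], z[, "b"], tolerance = 1e-12)
  # constant feature -> zeros with a warning
  mc <- cbind(a = c(1, 2, 3), const = c(4, 4, 4))
  expect_warning(zc <- zscore_normalize(mc), "constant")
  expect_equal(unname(zc[, "const"]), c(0, 0, 0))
  expect_error(zscore_normalize(cbind(c(1, NA))), "missing")
})

test_that("nutrient limitation classification follows the stated inequalities", {
  meta <- data.frame(sample_id = c("x1", "x2", "x3"),
                     tin = c(2.2, 0.5, 1.9), srp = c(0.05, 0.2, 0.09),
                     sio4 = c(2.2, 1.0, 2.1))
  lim <- classify_limitation(meta)
  expect_equal(lim$n_p, c(44, 2.5, 1.9 / 0.09))
  expect_identical(lim$p_limited, c(TRUE, FALSE, FALSE))  # x3: N/P ~ 21.1 <= 22
  expect_identical(lim$n_limited, c(FALSE, TRUE, FALSE))
  # srp = 0 -> infinite ratios, rules still apply
  z <- classify_limitation(data.frame(sample_id = "z", tin = 0.5, srp = 0,
                                      sio4 = 1))
  expect_identical(z$n_p, Inf)
  expect_true(z$p_limited && z$n_limited)
})

test_that("limitation flags match direct evaluation on random records", {
  set.seed(11)
  for (i in 1:1000) {
    tin <- runif(1, 0, 4); srp <- sample(c(0, runif(1, 0, 0.4)), 1)
    sio4 <- runif(1, 0, 4)
    got <- classify_limitation(data.frame(sample_id = "r", tin = tin,
                                          srp = srp, sio4 = sio4))
    want <- oracle_limitation(tin, srp, sio4)
    expect_identical(c(got$p_limited, got$n_limited), unname(want))
  }
})
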