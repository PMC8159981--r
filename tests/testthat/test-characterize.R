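make_assignment <- function(units, ids = sprintf("s%02d", seq_along(units))) {
  k <- max(units)
  structure(list(
    assignments = data.frame(sample_id = ids, unit = units,
                             distance = 0, row.names = NULL),
    frequencies = setNames(tabulate(units, k) / length(units),
                           paste0("BMU", seq_len(k)))
  ), class = "ng_assignment")
}

test_that("per-unit summaries report means and sample sds on raw scales", {
  a <- make_assignment(c(1, 1, 2))
  raw <- data.frame(sample_id = c("s01", "s02", "s03"), v = c(1, 3, 10),
                    w = c(2, 2, 8))
  s <- summarize_bmus(a, raw)
  expect_equal(s$mean[s$unit == 1 & s$variable == "v"], 2)
  expect_equal(s$sd[s$unit == 1 & s$variable == "v"], sqrt(2))
  expect_true(is.na(s$sd[s$unit == 2 & s$variable == "v"]))  # singleton
  # n-weighted unit means recover the grand mean
  sv <- s[s$variable == "v", ]
  expect_equal(sum(sv$mean * sv$n) / sum(sv$n), mean(raw$v))
  expect_error(summarize_bmus(a, raw[-1, ]), "s01")
})

test_that("a single-unit summary reproduces whole-dataset statistics", {
  set.seed(3)
  raw <- data.frame(sample_id = sprintf("s%02d", 1:8), v = rnorm(8))
  s <- summarize_bmus(make_assignment(rep(1, 8)), raw)
  expect_equal(s$mean, mean(raw$v))
  expect_equal(s$sd, sd(raw$v))
})

test_that("the BMU map is sorted by station then depth with one row per sample", {
  a <- make_assignment(c(2, 1, 1, 2), ids = c("x1", "x2", "x3", "x4"))
  meta <- data.frame(sample_id = c("x1", "x2", "x3", "x4"),
                     station = c("B", "A", "A", "A"),
                     depth = c(5, 50, 5, 5))
  m <- bmu_map(a, meta)
  expect_equal(nrow(m), 4)
  expect_equal(m$station, c("A", "A", "A", "B"))
  expect_equal(m$depth, c(5, 5, 50, 5))   # duplicated (station, depth) kept
})

test_that("composition profiles average members and pool minor taxa", {
  a <- make_assignment(c(1, 1))
  p <- rbind(c(0.5, 0.5), c(0.3, 0.7))
  dimnames(p) <- list(c("s01", "s02"), c("t1", "t2"))
  attr(p, "mode") <- "proportions"
  prof0 <- bmu_composition(a, p, other_threshold = 0)
  expect_equal(prof0$mean_abundance, c(0.4, 0.6))
  prof <- bmu_composition(a, p, other_threshold = 0.45)
  expect_equal(prof$taxon, c("t2", "other"))
  expect_equal(prof$mean_abundance, c(0.6, 0.4))
  expect_equal(sum(prof$mean_abundance), 1)
})

test_that("raising the pooling threshold never adds named taxa", {
  set.seed(8)
  p <- to_relative(random_asv_table(6, 12, lambda = 3) + 1L)
  a <- make_assignment(rep(1:2, 3))
  named <- sapply(c(0, 0.02, 0.05, 0.1), function(th) {
    prof <- bmu_composition(a, p, th)
    sum(prof$taxon != "other")
  })
  expect_true(all(diff(named) <= 0))
  # empty unit warning
  a3 <- make_assignment(c(1, 1, 1, 1, 1, 1))
  a3$frequencies <- c(BMU1 = 1, BMU2 = 0)
  expect_warning(bmu_composition(a3, p, 0), "no samples")
})

test_that("anomaly opposition follows the sign rule against the comparator median", {
  z <- function(v) as.numeric(scale(v))
  n <- 8
  set.seed(10)
  base <- rnorm(n)
  f <- cbind(t = z(-base), c1 = z(base))
  rownames(f) <- paste0("s", 1:n)
  expect_equal(anomaly_concordance(f, "t", "c1")$fraction, 1)
  f2 <- cbind(t = z(base), c1 = z(base))
  rownames(f2) <- rownames(f)
  expect_equal(anomaly_concordance(f2, "t", "c1")$fraction, 0)

  # hand-enumerated mixed case: target signs (-,-,+,+), medians (+,+,+,-)
  f3 <- cbind(t = c(-1, -1, 1, 1), a = c(2, 1, 3, -1), b = c(1, 2, 1, -2),
              c = c(3, 3, 2, -3))
  rownames(f3) <- paste0("s", 1:4)
  cc <- anomaly_concordance(f3, "t", c("a", "b", "c"))
  expect_equal(cc$fraction, 0.75)
  expect_identical(cc$detail$opposed, c(TRUE, TRUE, FALSE, TRUE))
  expect_error(anomaly_concordance(cbind(t = rep(0, 4), f3[, -1]), "t", "a"),
               "zero variance")
})

test_that("concordance is invariant under positive rescaling before normalization", {
  set.seed(12)
  raw <- matrix(rexp(40), 10, 4,
                dimnames = list(paste0("s", 1:10), c("t", "a", "b", "c")))
  f1 <- zscore_normalize(raw)
  raw2 <- sweep(raw, 2, c(3, 0.5, 10, 7), "*")
  f2 <- zscore_normalize(raw2)
  expect_equal(anomaly_concordance(f1, "t", c("a", "b", "c"))$fraction,
               anomaly_concordance(f2, "t", c("a", "b", "c"))$fraction)
})
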