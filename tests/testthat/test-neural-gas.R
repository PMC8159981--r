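test_that("schedule interpolates exponentially between its endpoints", {
  expect_equal(ng_schedule(0, 100, 0.5, 0.005), 0.5)
  expect_equal(ng_schedule(100, 100, 0.5, 0.005), 0.005)
  expect_equal(ng_schedule(50, 100, 0.5, 0.005), sqrt(0.5 * 0.005))
  t <- 0:100
  expect_true(all(diff(ng_schedule(t, 100, 2.5, 0.01)) < 0))
  expect_error(ng_schedule(0, 100, 0, 0.1), "positive")
})

test_that("adaptation moves units by rank-weighted steps", {
  # K = 1: the single unit has rank 0 and moves by eps
  w <- matrix(c(0, 0), 1, 2)
  expect_equal(ng_adapt_step(c(1, 1), w, 0.5, 1), matrix(c(0.5, 0.5), 1, 2))
  # K = 2: winner moves by eps, the other by eps * exp(-1)
  w2 <- matrix(c(0, 0, 4, 0), 2, 2, byrow = TRUE)
  out <- ng_adapt_step(c(1, 0), w2, 0.5, 1)
  expect_equal(out[1, 1], 0.5)                       # 0 + 0.5 * (1 - 0)
  expect_equal(out[2, 1], 4 + 0.5 * exp(-1) * (1 - 4))
  # winner-take-all limit: only the winner moves measurably
  out3 <- ng_adapt_step(c(1, 0), w2, 0.5, 1e-9)
  expect_equal(out3[2, ], w2[2, ])
  expect_error(ng_adapt_step(c(NA, 0), w2, 0.5, 1), "non-finite")
})

test_that("rank ties break toward the lower unit index", {
  # two units equidistant from x: unit 1 takes rank 0
  w <- matrix(c(-1, 0, 1, 0), 2, 2, byrow = TRUE)
  out <- ng_adapt_step(c(0, 0), w, 0.5, 1e-9)
  expect_equal(out[1, 1], -0.5)    # winner moved
  expect_equal(out[2, 1], 1)       # rank 1, frozen in the WTA limit
})

test_that("SSIntra equals the brute-force nearest-unit scan", {
  expect_equal(ng_ss_intra(matrix(c(3, 4), 1, 2), matrix(0, 1, 2)), 25)
  w <- matrix(rnorm(6), 3, 2)
  expect_equal(ng_ss_intra(w, w), 0)
  set.seed(5)
  for (i in 1:50) {
    x <- matrix(rnorm(40), 10, 4)
    w <- matrix(rnorm(4 * sample(1:6, 1)), ncol = 4)
    brute <- sum(apply(x, 1, function(p) min(colSums((t(w) - p)^2))))
    expect_equal(ng_ss_intra(x, w), brute, tolerance = 1e-12)
    # adding a unit can never increase the error
    w2 <- rbind(w, rnorm(4))
    expect_lte(ng_ss_intra(x, w2), ng_ss_intra(x, w) + 1e-12)
  }
  expect_error(ng_ss_intra(matrix(nrow = 0, ncol = 2), w), "empty")
})

test_that("training is deterministic and converges to known fixed points", {
  set.seed(1)
  x <- cbind(rnorm(200, 1, 0.3), rnorm(200, -2, 0.3))
  m1 <- ng_train(x, 3, epochs = 50, seed = 9)
  m2 <- ng_train(x, 3, epochs = 50, seed = 9)
  expect_identical(m1$codebook, m2$codebook)
  expect_length(m1$ss_intra_history, 50)
  expect_equal(m1$final_ss_intra, ng_ss_intra(x, m1$codebook))

  # K = 1 fixed point is the sample mean
  m <- ng_train(x, 1, seed = 3)
  expect_lt(sqrt(sum((m$codebook - colMeans(x))^2)), 0.05)

  # two well-separated clusters, K = 2: one unit near each centroid
  set.seed(2)
  xx <- rbind(matrix(rnorm(20, 0, 0.5), 10, 2),
              matrix(rnorm(20, 10, 0.5), 10, 2))
  mm <- ng_train(xx, 2, seed = 4)
  cents <- rbind(colMeans(xx[1:10, ]), colMeans(xx[11:20, ]))
  d <- apply(cents, 1, function(cc)
    min(sqrt(rowSums(sweep(mm$codebook, 2, cc, "-")^2))))
  expect_true(all(d < 0.5))

  # single data point: all units collapse onto it
  ms <- ng_train(matrix(c(2, 3), 1, 2), 3, seed = 5)
  expect_lt(ms$final_ss_intra, 1e-6)
})

test_that("assignment picks the nearest unit with deterministic tie-breaks", {
  w <- matrix(c(0, 0, 5, 0, 10, 0), 3, 2, byrow = TRUE)
  x <- rbind(w, c(2.5, 0))       # last sample equidistant to units 1 and 2
  rownames(x) <- paste0("s", 1:4)
  a <- ng_assign(x, w)
  expect_equal(a$assignments$unit, c(1L, 2L, 3L, 1L))
  expect_equal(a$assignments$distance[1:3], c(0, 0, 0))
  expect_equal(sum(a$frequencies), 1)

  sizes <- c(6, 7, 6, 2, 1)
  units <- rep(seq_along(sizes), sizes)
  wu <- matrix(seq_along(sizes) * 10, ncol = 1)
  xs <- matrix(units * 10 + runif(22, -1, 1), ncol = 1)
  fa <- ng_assign(xs, wu)
  expect_equal(unname(fa$frequencies), sizes / 22)
})

test_that("model selection handles degenerate grids and reports its table", {
  set.seed(6)
  x <- matrix(rnorm(40), 10, 4)
  s1 <- ng_select_k(x, 1L, restarts = 3)
  expect_identical(s1$chosen_k, 1L)
  # K = n with sample init: near-perfect quantization, negligible cv
  sn <- ng_select_k(x, nrow(x), restarts = 3)
  expect_lt(max(sn$ss_intra), 1e-3)
  expect_lt(sn$table$cv, 0.1)
  expect_identical(names(sn$table), c("k", "mean_ss", "sd_ss", "cv", "share"))
})

test_that("best-of-restarts keeps the lowest quantization error", {
  pc <- generate_planted_clusters(22, 4, 9, separation = 5, seed = 2)
  xn <- zscore_normalize(pc$x)
  best <- ng_train_best(xn, 4, restarts = 5, base_seed = 10)
  ss <- attr(best, "restart_ss")
  expect_length(ss, 5)
  expect_equal(best$final_ss_intra, min(ss))
})
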