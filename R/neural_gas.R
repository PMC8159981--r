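#' Exponential parameter schedule
#'
#' The step size and neighbourhood range decay exponentially from their
#' initial to their final value over the adaptation run:
#' `v(t) = v_init * (v_final / v_init)^(t / t_max)`.
#'
#' @param t step index, 0..t_max.
#' @param t_max total number of adaptation steps (>= 1).
#' @param v_init,v_final positive endpoints.
#' @return interpolated value; strictly decreasing in `t` when
#'   `v_final < v_init`.
#' @export
ng_schedule <- function(t, t_max, v_init, v_final) {
  if (v_init <= 0 || v_final <= 0) stop("schedule endpoints must be positive",
                                        call. = FALSE)
  stopifnot(t_max >= 1, all(t >= 0), all(t <= t_max))
  v_init * (v_final / v_init)^(t / t_max)
}

#' One neural-gas adaptation step
#'
#' Every codebook unit moves toward the presented vector `x` with weight
#' `eps * exp(-rank / lambda)`, where `rank` is the number of units strictly
#' closer to `x` (Euclidean; ties broken so the lower unit index receives the
#' lower rank).
#'
#' @param x numeric feature vector.
#' @param codebook K x d matrix of unit positions.
#' @param eps step size in (0, 1].
#' @param lambda neighbourhood decay constant, > 0.
#' @return updated K x d codebook.
#' @export
ng_adapt_step <- function(x, codebook, eps, lambda) {
  stopifnot(is.matrix(codebook), length(x) == ncol(codebook),
            eps > 0, eps <= 1, lambda > 0)
  if (!all(is.finite(x))) stop("non-finite input vector", call. = FALSE)
  .ng_adapt_cpp(codebook, as.numeric(x), eps, lambda)
}

#' SSIntra quantization error
#'
#' Sum over samples of the squared Euclidean distance to the nearest
#' codebook unit.
#'
#' @param x numeric matrix, samples x features.
#' @param codebook K x d matrix; d must match `ncol(x)`.
#' @return non-negative scalar.
#' @export
ng_ss_intra <- function(x, codebook) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty data matrix", call. = FALSE)
  stopifnot(is.matrix(codebook), ncol(codebook) == ncol(x))
  .ng_ss_intra_cpp(x, codebook)
}

ng_init_codebook <- function(x, k, init) {
  n <- nrow(x)
  if (init == "plusplus" && k <= n) {
    # D^2-weighted spread seeding: keeps restart diversity while covering
    # well-separated regions of the data
    chosen <- sample.int(n, 1L)
    d2 <- rowSums(sweep(x, 2L, x[chosen, ], "-")^2)
    while (length(chosen) < k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      nxt <- sample.int(n, 1L, prob = p)
      chosen <- c(chosen, nxt)
      d2 <- pmin(d2, rowSums(sweep(x, 2L, x[nxt, ], "-")^2))
    }
    x[chosen, , drop = FALSE]
  } else if (init == "sample" && k <= n) {
    x[sample.int(n, k), , drop = FALSE]
  } else {
    lo <- apply(x, 2L, min)
    hi <- apply(x, 2L, max)
    w0 <- matrix(runif(k * ncol(x)), k, ncol(x))
    sweep(sweep(w0, 2L, hi - lo, "*"), 2L, lo, "+")
  }
}

#' Train a neural-gas model
#'
#' Online training: each epoch presents every sample once in a freshly
#' shuffled order; the global step counter drives the exponential schedules
#' of the step size and the neighbourhood range with
#' `t_max = epochs * n_samples`. Fully deterministic given `seed`.
#'
#' @param x numeric matrix, samples x features (a standardized feature
#'   matrix; see [zscore_normalize()]).
#' @param k number of best-matching units (codebook size), >= 1.
#' @param epochs training epochs (default 500).
#' @param eps_init,eps_final step-size schedule endpoints (defaults 0.5 and
#'   0.005).
#' @param lambda_init,lambda_final neighbourhood-range schedule endpoints
#'   (defaults 2.5 and 0.01).
#' @param seed integer seed controlling initialization and presentation
#'   order.
#' @param init `"sample"` (codebook seeded from k distinct data rows;
#'   default), `"plusplus"` (squared-distance-weighted spread seeding) or
#'   `"uniform"` (uniform in the bounding box). Falls back to uniform when
#'   `k > n`.
#' @param w0,orders optional explicit initial codebook (K x d) and
#'   presentation orders (epochs x n matrix of 1-based sample indices);
#'   override the seeded defaults, e.g. to compare against an external
#'   reference run.
#' @return an object of class `ng_model`: list with `codebook`,
#'   `ss_intra_history` (one value per epoch), `final_ss_intra` and `config`.
#' @export
ng_train <- function(x, k, epochs = 500L, eps_init = 0.5, eps_final = 0.005,
                     lambda_init = 2.5, lambda_final = 0.01,
                     seed = 1L, init = c("sample", "plusplus", "uniform"),
                     w0 = NULL, orders = NULL) {
  init <- match.arg(init)
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n < 1L) stop("empty data matrix", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  stopifnot(epochs >= 1L,
            eps_final > 0, eps_final <= eps_init, eps_init <= 1,
            lambda_final > 0, lambda_final <= lambda_init)
  if (anyNA(x) || !all(is.finite(x))) stop("non-finite data", call. = FALSE)
  set.seed(seed)
  if (is.null(w0)) w0 <- ng_init_codebook(x, k, init)
  stopifnot(is.matrix(w0), nrow(w0) == k, ncol(w0) == d)
  if (is.null(orders)) {
    orders <- matrix(vapply(seq_len(epochs), function(e) sample.int(n),
                            integer(n)),
                     nrow = epochs, byrow = TRUE)
  }
  storage.mode(orders) <- "integer"
  stopifnot(ncol(orders) == n)
  fit <- .ng_train_cpp(x, w0, orders, eps_init, eps_final,
                       lambda_init, lambda_final)
  colnames(fit$codebook) <- colnames(x)
  structure(list(
    codebook = fit$codebook,
    ss_intra_history = as.numeric(fit$ss_intra_history),
    final_ss_intra = ng_ss_intra(x, fit$codebook),
    config = list(k = as.integer(k), epochs = as.integer(epochs),
                  eps_init = eps_init, eps_final = eps_final,
                  lambda_init = lambda_init, lambda_final = lambda_final,
                  seed = as.integer(seed), init = init)
  ), class = "ng_model")
}

#' @export
print.ng_model <- function(x, ...) {
  cat(sprintf("Neural-gas model: %d units, %d features, %d epochs (seed %d)\n",
              nrow(x$codebook), ncol(x$codebook), x$config$epochs,
              x$config$seed))
  cat(sprintf("final SSIntra: %.6g\n", x$final_ss_intra))
  invisible(x)
}

#' Restarted neural-gas training keeping the best quantization
#'
#' Trains `restarts` models (seeds `base_seed + 0:(restarts-1)`) and returns
#' the one with the lowest final SSIntra. By default the restarts use the
#' same under-annealed probe schedule as [ng_select_k()] (`epochs = 100`,
#' `lambda_init = 0.5`): with full annealing every restart converges to the
#' same solution, which defeats the purpose of restarting, whereas diverse
#' under-annealed restarts explore competing quantizations and the best one
#' is kept. Each restart is still fully converged (the step size ends at
#' `eps_final`).
#'
#' @inheritParams ng_train
#' @param restarts number of restarts (default 10).
#' @param base_seed integer; restart r uses seed `base_seed + r - 1`.
#' @param ... further arguments passed to [ng_train()].
#' @return the best `ng_model`; attribute `"restart_ss"` holds all final
#'   SSIntra values.
#' @export
ng_train_best <- function(x, k, restarts = 10L, base_seed = 1L,
                          epochs = 100L, lambda_init = 0.5, ...) {
  stopifnot(restarts >= 1L)
  fits <- lapply(seq_len(restarts), function(r) {
    ng_train(x, k, seed = base_seed + r - 1L, epochs = epochs,
             lambda_init = lambda_init, ...)
  })
  ss <- vapply(fits, `[[`, numeric(1), "final_ss_intra")
  best <- fits[[which.min(ss)]]
  attr(best, "restart_ss") <- ss
  best
}

#' Assign samples to their best-matching units
#'
#' Nearest-codebook-unit assignment (Euclidean; ties go to the lower unit
#' index) plus per-unit relative frequencies.
#'
#' @param x numeric matrix, samples x features.
#' @param model `ng_model` (or a bare codebook matrix).
#' @return list of class `ng_assignment`: `assignments` data.frame
#'   (sample_id, unit, distance) and `frequencies` (per-unit relative
#'   frequency, summing to 1; units 1..K).
#' @export
ng_assign <- function(x, model) {
  codebook <- if (inherits(model, "ng_model")) model$codebook else model
  x <- as.matrix(x)
  stopifnot(ncol(x) == ncol(codebook))
  k <- nrow(codebook)
  d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(codebook) +
    outer(rep(1, nrow(x)), rowSums(codebook^2))
  d2[d2 < 0] <- 0
  unit <- max.col(-d2, ties.method = "first")
  dist <- sqrt(d2[cbind(seq_len(nrow(x)), unit)])
  freq <- tabulate(unit, nbins = k) / nrow(x)
  structure(list(
    assignments = data.frame(
      sample_id = if (is.null(rownames(x))) as.character(seq_len(nrow(x)))
                  else rownames(x),
      unit = unit, distance = dist, row.names = NULL),
    frequencies = setNames(freq, paste0("BMU", seq_len(k)))
  ), class = "ng_assignment")
}

#' Select the number of best-matching units by SSIntra restart dispersion
#'
#' For each candidate K the model is retrained `restarts` times (seeds
#' `base_seed + 0:(restarts-1)`) and the dispersion of the final SSIntra
#' quantization error over restarts is summarized by its coefficient of
#' variation (sd / mean) and by the *basin share* — the fraction of restarts
#' reproducing the best final SSIntra within relative tolerance `ss_rtol`.
#'
#' The selection restarts are deliberately under-annealed (defaults
#' `epochs = 100`, `lambda_init = 0.5`, i.e. near winner-take-all): a fully
#' annealed run converges to the same quantization from almost any start, so
#' its restart dispersion is numerical noise and carries no information
#' about K. Under weak annealing the restart ensemble probes the local
#' optimum landscape instead: at the true cluster number a single dominant
#' basin captures almost every restart, while one unit more or less opens
#' several competing split/merge optima and the restarts scatter.
#'
#' Decision rules:
#' * `"stability"` (default): the largest K whose basin share is at least
#'   `share_min`; if no K qualifies, the K with the maximal share (ties to
#'   the smaller K).
#' * `"min_cv"`: the K minimizing the CV, ties to the smaller K. With a
#'   well-annealed quantizer several K typically sit at the numerical noise
#'   floor and the argmin is arbitrary; the rule is retained for comparison.
#'
#' A zero mean SSIntra (perfect quantization in every restart) yields CV 0.
#' The full table is returned so any alternative rule can be applied.
#'
#' @param x numeric matrix, samples x features.
#' @param k_grid candidate unit counts (each between 1 and n_samples).
#' @param restarts number of restarts per K (>= 2, default 10).
#' @param base_seed integer; restart r uses seed `base_seed + r - 1`.
#' @param rule `"stability"` (default) or `"min_cv"`.
#' @param share_min stability-rule share threshold (default 0.9).
#' @param ss_rtol relative tolerance defining "same basin" (default 0.01).
#' @param epochs,lambda_init schedule of the selection restarts (see
#'   Details; the defaults differ from [ng_train()] on purpose).
#' @param ... further arguments passed to [ng_train()] (eps schedule,
#'   lambda_final, init).
#' @return list of class `ng_selection`: `table` (data.frame k, mean_ss,
#'   sd_ss, cv, share), `ss_intra` (restarts x length(k_grid) matrix of
#'   final SSIntra) and `chosen_k`.
#' @export
ng_select_k <- function(x, k_grid, restarts = 10L, base_seed = 1L,
                        rule = c("stability", "min_cv"), share_min = 0.9,
                        ss_rtol = 0.01, epochs = 100L, lambda_init = 0.5,
                        ...) {
  rule <- match.arg(rule)
  x <- as.matrix(x)
  stopifnot(length(k_grid) >= 1L, restarts >= 2L,
            all(k_grid >= 1L), all(k_grid <= nrow(x)),
            share_min > 0, share_min <= 1, ss_rtol >= 0)
  k_grid <- as.integer(k_grid)
  ss <- vapply(k_grid, function(k) {
    vapply(seq_len(restarts), function(r) {
      ng_train(x, k, seed = base_seed + r - 1L, epochs = epochs,
               lambda_init = lambda_init, ...)$final_ss_intra
    }, numeric(1))
  }, numeric(restarts))
  ss <- matrix(ss, nrow = restarts, dimnames = list(NULL, paste0("K", k_grid)))
  mean_ss <- colMeans(ss)
  sd_ss <- apply(ss, 2L, sd)
  cv <- ifelse(mean_ss > 0, sd_ss / mean_ss, 0)
  share <- apply(ss, 2L, function(v) mean(v <= min(v) * (1 + ss_rtol)))
  chosen <- if (rule == "min_cv") {
    k_grid[which.min(cv)]           # which.min ties -> first, i.e. smaller K
  } else {
    ok <- k_grid[share >= share_min]
    if (length(ok)) max(ok) else k_grid[which.max(share)]
  }
  structure(list(
    table = data.frame(k = k_grid, mean_ss = unname(mean_ss),
                       sd_ss = unname(sd_ss), cv = unname(cv),
                       share = unname(share), row.names = NULL),
    ss_intra = ss,
    chosen_k = chosen,
    rule = rule
  ), class = "ng_selection")
}

#' @export
print.ng_selection <- function(x, ...) {
  cat("SSIntra coefficient-of-variation model selection\n")
  print(x$table, row.names = FALSE)
  cat("chosen K:", x$chosen_k, "\n")
  invisible(x)
}
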