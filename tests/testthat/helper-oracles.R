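# Independent oracles and fixture builders used across the suite.

# Column names normalized so a zero-column matrix compares as character(0).
cn <- function(m) as.character(colnames(m))

# Random ASV table with sample/ASV ids.
random_asv_table <- function(n, m, lambda = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(rpois(n * m, lambda), n, m,
                   dimnames = list(sprintf("s%02d", seq_len(n)),
                                   sprintf("a%03d", seq_len(m))))
  storage.mode(counts) <- "integer"
  counts
}

# Random taxonomy covering the given ASV ids, mixing domains and organelle
# labels at the rank positions real classifications use.
random_taxonomy <- function(asv_ids) {
  n <- length(asv_ids)
  domain <- sample(c("Bacteria", "Eukaryota", "Archaea"), n, TRUE,
                   prob = c(0.7, 0.2, 0.1))
  ord <- sample(c("Flavobacteriales", "Chloroplast", "SAR11 clade", NA), n,
                TRUE, prob = c(0.5, 0.15, 0.25, 0.1))
  fam <- sample(c("Flavobacteriaceae", "Mitochondria", NA), n, TRUE,
                prob = c(0.6, 0.15, 0.25))
  data.frame(asv_id = asv_ids, domain = domain,
             phylum = sample(c("Proteobacteria", "Bacteroidota", NA), n, TRUE),
             class = sample(c("Alphaproteobacteria", NA), n, TRUE),
             order = ord, family = fam,
             genus = sample(c("GenA", "GenB", NA), n, TRUE),
             stringsAsFactors = FALSE)
}

# Brute-force per-ASV loop of the taxonomic removal rule.
oracle_taxonomic_keep <- function(counts, tax) {
  vapply(colnames(counts), function(id) {
    row <- tax[tax$asv_id == id, ]
    ranks <- tolower(unlist(row[c("domain", "phylum", "class", "order",
                                  "family", "genus")]))
    dom_ok <- !is.na(row$domain) && tolower(row$domain) == "bacteria"
    org <- any(ranks %in% c("chloroplast", "mitochondria", "mitochondrion"),
               na.rm = TRUE)
    dom_ok && !org
  }, logical(1))
}

# Brute-force per-ASV sample-counting loop of the prevalence keep rule.
oracle_prevalence_keep <- function(counts, min_count, min_fraction) {
  n <- nrow(counts)
  vapply(seq_len(ncol(counts)), function(j) {
    hits <- 0L
    for (i in seq_len(n)) if (counts[i, j] >= min_count) hits <- hits + 1L
    hits >= ceiling(min_fraction * n)
  }, logical(1))
}

# Independently coded online k-means: winner-take-all competitive learning
# with the same presentation order and exponential step-size schedule.
oracle_online_kmeans <- function(x, w0, orders_flat, eps_init, eps_final) {
  w <- w0
  t_max <- length(orders_flat)
  t <- 0
  for (idx in orders_flat) {
    eps <- eps_init * (eps_final / eps_init)^(t / t_max)
    d <- rowSums(sweep(w, 2, x[idx, ], "-")^2)
    win <- which.min(d)
    w[win, ] <- w[win, ] + eps * (x[idx, ] - w[win, ])
    t <- t + 1
  }
  w
}

nearest_unit <- function(x, w) {
  apply(x, 1, function(p) which.min(colSums((t(w) - p)^2)))
}

# Direct evaluation of the limitation inequalities.
oracle_limitation <- function(tin, srp, sio4) {
  np <- if (srp > 0) tin / srp else Inf
  sip <- if (srp > 0) sio4 / srp else Inf
  c(p = srp < 0.1 && np > 22 && sip > 22, n = tin < 1)
}

# Dense water-column scenario used for concentration-sensitive properties.
dense_scenario <- function() {
  community_scenario(stations = list(
    P1 = seq(0, 100, length.out = 40),
    P2 = seq(0, 100, length.out = 40),
    P3 = seq(0, 100, length.out = 40)))
}
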