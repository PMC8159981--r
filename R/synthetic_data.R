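#' @name synthetic-data
#' @title Synthetic depth-stratified community datasets
#' @description
#' The generator emulates the statistical structure of a late-summer,
#' depth-stratified picoplankton survey of several open-sea stations: a fixed
#' station/depth design (22 samples over 0-100 m by default), community types
#' tied deterministically to depth bins, Dirichlet-multinomial genus
#' compositions split over 1-5 ASVs per genus, lognormal sequencing depths,
#' contaminant and rare ASVs to exercise the filters, monotone environmental
#' depth profiles, and picoplankton vectors with a planted negative salinity
#' association. Ground-truth cluster labels are returned for
#' parameter-recovery tests.
NULL

# Marine genus pool with plausible higher ranks (SILVA-style labels).
GENUS_POOL <- local({
  g <- rbind(
    c("Synechococcus", "Cyanobiaceae", "Synechococcales", "Cyanobacteriia", "Cyanobacteria"),
    c("Prochlorococcus", "Cyanobiaceae", "Synechococcales", "Cyanobacteriia", "Cyanobacteria"),
    c("Cyanobium", "Cyanobiaceae", "Synechococcales", "Cyanobacteriia", "Cyanobacteria"),
    c("AEGEAN-169", "AEGEAN-169 marine group", "Rhodospirillales", "Alphaproteobacteria", "Proteobacteria"),
    c("SAR116", "Puniceispirillaceae", "Puniceispirillales", "Alphaproteobacteria", "Proteobacteria"),
    c("Ascidiaceihabitans", "Rhodobacteraceae", "Rhodobacterales", "Alphaproteobacteria", "Proteobacteria"),
    c("Erythrobacter", "Erythrobacteraceae", "Sphingomonadales", "Alphaproteobacteria", "Proteobacteria"),
    c("Paracoccus", "Rhodobacteraceae", "Rhodobacterales", "Alphaproteobacteria", "Proteobacteria"),
    c("Aurantimonas", "Aurantimonadaceae", "Rhizobiales", "Alphaproteobacteria", "Proteobacteria"),
    c("Croceicoccus", "Erythrobacteraceae", "Sphingomonadales", "Alphaproteobacteria", "Proteobacteria"),
    c("Marivivens", "Rhodobacteraceae", "Rhodobacterales", "Alphaproteobacteria", "Proteobacteria"),
    c("Methylobacterium", "Methylobacteriaceae", "Rhizobiales", "Alphaproteobacteria", "Proteobacteria"),
    c("OCS116", "OCS116 clade", "Parvibaculales", "Alphaproteobacteria", "Proteobacteria"),
    c("HIMB11", "Rhodobacteraceae", "Rhodobacterales", "Alphaproteobacteria", "Proteobacteria"),
    c("OM75", "Hyphomonadaceae", "Caulobacterales", "Alphaproteobacteria", "Proteobacteria"),
    c("Maricaulis", "Hyphomonadaceae", "Caulobacterales", "Alphaproteobacteria", "Proteobacteria"),
    c("Tistrella", "Geminicoccaceae", "Rhodospirillales", "Alphaproteobacteria", "Proteobacteria"),
    c("SAR86", "SAR86 clade", "Oceanospirillales", "Gammaproteobacteria", "Proteobacteria"),
    c("OM60", "Halieaceae", "Cellvibrionales", "Gammaproteobacteria", "Proteobacteria"),
    c("Litoricola", "Litoricolaceae", "Oceanospirillales", "Gammaproteobacteria", "Proteobacteria"),
    c("Alteromonas", "Alteromonadaceae", "Alteromonadales", "Gammaproteobacteria", "Proteobacteria"),
    c("Pseudoalteromonas", "Pseudoalteromonadaceae", "Alteromonadales", "Gammaproteobacteria", "Proteobacteria"),
    c("Pseudomonas", "Pseudomonadaceae", "Pseudomonadales", "Gammaproteobacteria", "Proteobacteria"),
    c("Woeseia", "Woeseiaceae", "Steroidobacterales", "Gammaproteobacteria", "Proteobacteria"),
    c("SUP05", "Thioglobaceae", "Thiomicrospirales", "Gammaproteobacteria", "Proteobacteria"),
    c("KI89A", "KI89A clade", "Cellvibrionales", "Gammaproteobacteria", "Proteobacteria"),
    c("HOC36", "HOC36 clade", "Oceanospirillales", "Gammaproteobacteria", "Proteobacteria"),
    c("Ca. Tenderia", "Tenderiaceae", "Tenderiales", "Gammaproteobacteria", "Proteobacteria"),
    c("NS4 marine group", "Flavobacteriaceae", "Flavobacteriales", "Bacteroidia", "Bacteroidota"),
    c("NS5 marine group", "Flavobacteriaceae", "Flavobacteriales", "Bacteroidia", "Bacteroidota"),
    c("NS9 marine group", "NS9 marine group", "Flavobacteriales", "Bacteroidia", "Bacteroidota"),
    c("NS2b marine group", "Flavobacteriaceae", "Flavobacteriales", "Bacteroidia", "Bacteroidota"),
    c("Balneola", "Balneolaceae", "Balneolales", "Rhodothermia", "Bacteroidota"),
    c("Muricauda", "Flavobacteriaceae", "Flavobacteriales", "Bacteroidia", "Bacteroidota"),
    c("Marinoscillum", "Cyclobacteriaceae", "Cytophagales", "Bacteroidia", "Bacteroidota"),
    c("Euzebyella", "Flavobacteriaceae", "Flavobacteriales", "Bacteroidia", "Bacteroidota"),
    c("Ca. Actinomarina", "Actinomarinaceae", "Actinomarinales", "Acidimicrobiia", "Actinobacteriota"),
    c("Sva0996 marine group", "Microtrichaceae", "Microtrichales", "Acidimicrobiia", "Actinobacteriota"),
    c("Curtobacterium", "Microbacteriaceae", "Micrococcales", "Actinobacteria", "Actinobacteriota"),
    c("Nocardioides", "Nocardioidaceae", "Propionibacteriales", "Actinobacteria", "Actinobacteriota"),
    c("Rhodococcus", "Nocardiaceae", "Mycobacteriales", "Actinobacteria", "Actinobacteriota"),
    c("LS-NOB", "Nitrospinaceae", "Nitrospinales", "Nitrospinia", "Nitrospinota"),
    c("SAR202", "SAR202 clade", "SAR202 clade", "Dehalococcoidia", "Chloroflexota"),
    c("Urania-1B-19", "Phycisphaeraceae", "Phycisphaerales", "Phycisphaerae", "Planctomycetota"),
    c("JL-ETNP-F27", "Phycisphaeraceae", "Phycisphaerales", "Phycisphaerae", "Planctomycetota"),
    c("Rubripirellula", "Pirellulaceae", "Pirellulales", "Planctomycetes", "Planctomycetota"),
    c("Roseibacillus", "Rubritaleaceae", "Verrucomicrobiales", "Verrucomicrobiae", "Verrucomicrobiota"),
    c("Lentimonas", "Puniceicoccaceae", "Puniceicoccales", "Verrucomicrobiae", "Verrucomicrobiota")
  )
  data.frame(genus = g[, 1], family = g[, 2], order = g[, 3], class = g[, 4],
             phylum = g[, 5], stringsAsFactors = FALSE)
})

# Station/depth design of the emulated survey: 22 sequenced samples.
DEFAULT_STATIONS <- list(
  JP1 = c(0, 5, 10, 20, 30, 50, 66, 75),
  PS1 = c(5, 25, 65),
  PS2 = c(5, 16, 50),
  SAP1 = 40,
  SAP2 = c(5, 20, 33),
  SAP3 = c(5, 20, 78, 100)
)

PICO_VARS <- c("tp", "syn", "prochl", "pe", "hnf", "aap", "aap_pct",
               "hna_pct", "lna_pct", "bp")

# Abundance-type variables carrying the planted salinity association.
BIOTIC_BLOCK <- c("tp", "syn", "prochl", "pe", "hnf", "aap", "bp")

#' Default per-bin picoplankton means
#'
#' Per-depth-bin means (rows, surface to deep) of the ten picoplankton
#' variables, calibrated to the observed ranges of the emulated system:
#' picoplankton-rich surface waters, a Synechococcus maximum around the
#' thermocline, and a deep endpoint with collapsed stocks and HNA dominance.
#' For `k != 4` the anchor rows are linearly interpolated.
#'
#' @param k number of depth bins.
#' @return k x 10 matrix with columns tp, syn, prochl, pe, hnf, aap,
#'   aap_pct, hna_pct, lna_pct, bp.
#' @export
default_pico_means <- function(k) {
  # surface / upper thermocline / DCM transition / deep; the deep bin is an
  # extreme endpoint (collapsed stocks, HNA dominance), as observed below
  # 100 m in stratified oligotrophic waters
  anchor <- rbind(
    #       tp    syn  prochl  pe   hnf   aap  aap%  hna%  lna%   bp
    c(0.26, 7.68, 1.68, 0.83, 1.13, 1.51, 5.15, 45.5, 54.5, 0.07),
    c(0.25, 12.58, 0.78, 1.07, 1.06, 0.53, 1.89, 43.6, 56.4, 0.06),
    c(0.20, 6.00, 1.20, 0.60, 0.70, 0.35, 1.40, 48.0, 52.0, 0.05),
    c(0.10, 0.20, 0.15, 0.10, 0.15, 0.08, 0.50, 58.0, 42.0, 0.03)
  )
  colnames(anchor) <- PICO_VARS
  if (k == nrow(anchor)) return(anchor)
  # interpolate rows for other bin counts
  idx <- seq(1, nrow(anchor), length.out = k)
  out <- t(vapply(idx, function(i) {
    lo <- floor(i); hi <- ceiling(i); w <- i - lo
    (1 - w) * anchor[lo, ] + w * anchor[hi, ]
  }, numeric(ncol(anchor))))
  colnames(out) <- PICO_VARS
  out
}

#' Default within-bin picoplankton standard deviations
#'
#' Set to the low end of the observed per-cluster spreads so the planted
#' bins sit at least 5 within-cluster standard deviations apart in
#' normalized feature space.
#'
#' @return named numeric vector over the ten picoplankton variables.
#' @export
default_pico_sds <- function() {
  setNames(c(0.025, 1.1, 0.22, 0.11, 0.15, 0.17, 0.45, 2.6, 2.6, 0.012),
           PICO_VARS)
}

#' Define a synthetic community scenario
#'
#' Default values mirror the emulated survey: 6 stations with 22 samples over
#' 0-100 m, four depth-bin community types (breaks at 25, 60 and 90 m),
#' sequencing depths with mean 93,317 reads and coefficient of variation
#' 23,087 / 93,317, and a salinity-vs-biotic planted correlation of -0.9.
#'
#' @param stations named list of depth vectors (m), one entry per station.
#' @param depth_breaks increasing depth breakpoints (m) separating community
#'   types; `length(depth_breaks) + 1` is the true cluster number.
#' @param n_genera size of the bacterial genus pool.
#' @param dirichlet_concentration within-cluster compositional concentration
#'   (larger = less sample-to-sample variation).
#' @param reads_mean,reads_cv lognormal sequencing-depth parameters.
#' @param contaminant_fraction expected fraction of reads in contaminant
#'   (non-bacterial / chloroplast / mitochondrial) ASVs.
#' @param n_contaminants number of contaminant ASVs (ignored when
#'   `contaminant_fraction = 0`).
#' @param rare_asv_count number of rare ASVs planted to fail the prevalence
#'   filter by construction.
#' @param pico_means k x 10 matrix of per-bin picoplankton means (columns
#'   tp, syn, prochl, pe, hnf, aap, aap_pct, hna_pct, lna_pct, bp, in the
#'   units of [read_pico_table()]).
#' @param pico_sds within-bin standard deviations (same columns).
#' @param salinity_rho planted correlation between salinity and the mean
#'   standardized abundance-type picoplankton anomaly (default -0.9).
#' @param salinity_mean,salinity_sd salinity location and scale (PSS).
#' @return list of class `community_scenario`.
#' @export
community_scenario <- function(stations = DEFAULT_STATIONS,
                               depth_breaks = c(25, 60, 90),
                               n_genera = 40L,
                               dirichlet_concentration = 200,
                               reads_mean = 93317,
                               reads_cv = 23087 / 93317,
                               contaminant_fraction = 0.05,
                               n_contaminants = 12L,
                               rare_asv_count = 30L,
                               pico_means = NULL,
                               pico_sds = default_pico_sds(),
                               salinity_rho = -0.9,
                               salinity_mean = 38.8,
                               salinity_sd = 0.05) {
  stopifnot(length(stations) >= 1L, all(lengths(stations) >= 1L),
            all(diff(depth_breaks) > 0), n_genera >= 2L,
            dirichlet_concentration > 0, reads_mean > 0, reads_cv > 0,
            contaminant_fraction >= 0, contaminant_fraction < 1,
            rare_asv_count >= 0, abs(salinity_rho) <= 1)
  k_true <- length(depth_breaks) + 1L
  depths <- unlist(stations, use.names = FALSE)
  bins <- findInterval(depths, depth_breaks) + 1L
  if (length(unique(bins)) < k_true) {
    stop("infeasible scenario: some depth bins contain no samples",
         call. = FALSE)
  }
  if (is.null(pico_means)) pico_means <- default_pico_means(k_true)
  stopifnot(nrow(pico_means) == k_true,
            identical(colnames(pico_means), PICO_VARS),
            identical(names(pico_sds), PICO_VARS))
  structure(list(
    stations = stations, depth_breaks = depth_breaks,
    k_true = k_true, n_genera = as.integer(n_genera),
    dirichlet_concentration = dirichlet_concentration,
    reads_mean = reads_mean, reads_cv = reads_cv,
    contaminant_fraction = contaminant_fraction,
    n_contaminants = as.integer(n_contaminants),
    rare_asv_count = as.integer(rare_asv_count),
    pico_means = pico_means, pico_sds = pico_sds,
    salinity_rho = salinity_rho, salinity_mean = salinity_mean,
    salinity_sd = salinity_sd
  ), class = "community_scenario")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Draw lognormal sequencing depths
#'
#' Lognormal with the requested arithmetic mean and coefficient of
#' variation, rounded to integers.
#'
#' @param n number of draws.
#' @param mean target mean read count.
#' @param cv target coefficient of variation.
#' @return integer vector of read depths.
#' @export
draw_read_depths <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  pmax(1L, as.integer(round(rlnorm(n, meanlog, sdlog))))
}

#' Generate a synthetic dataset from a scenario
#'
#' See [community_scenario()] for the model. Fully reproducible from `seed`.
#'
#' @param scenario a `community_scenario`.
#' @param seed integer seed.
#' @return list of class `synthetic_dataset`: `counts` (ASV table matrix),
#'   `taxonomy`, `metadata`, `pico` (data.frames), `truth` (integer labels
#'   1..k_true aligned with sample order) and `scenario`.
#' @export
generate_dataset <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "community_scenario"))
  set.seed(seed)
  sc <- scenario
  station <- rep(names(sc$stations), lengths(sc$stations))
  depth <- unlist(sc$stations, use.names = FALSE)
  sample_id <- make.unique(sprintf("%s_%gm", station, depth), sep = "_")
  n <- length(sample_id)
  truth <- findInterval(depth, sc$depth_breaks) + 1L
  k <- sc$k_true

  ## genus pool: names, ranks, depth preference, abundance weight
  G <- sc$n_genera
  pool <- GENUS_POOL
  if (G > nrow(pool)) {
    extra <- data.frame(genus = sprintf("Genus%03d", seq_len(G - nrow(pool))),
                        family = "Unknown family", order = "Unknown order",
                        class = "Unknown class", phylum = "Proteobacteria")
    pool <- rbind(pool, extra)
  }
  pool <- pool[sample.int(nrow(pool), G), , drop = FALSE]
  pref_bin <- sample.int(k, G, replace = TRUE,
                         prob = rev(seq_len(k)) / sum(seq_len(k)))
  weight <- rlnorm(G, sdlog = 1)
  base <- vapply(seq_len(k), function(c) {
    p <- weight * exp(-2 * abs(pref_bin - c))
    p <- p / sum(p)
    p <- pmax(p, 0.004)
    p / sum(p)
  }, numeric(G))                                   # G x k

  ## split genera into ASVs with fixed within-genus weights
  n_asv_g <- sample.int(5L, G, replace = TRUE)
  asv_genus <- rep(seq_len(G), n_asv_g)
  asv_w <- unlist(lapply(n_asv_g, function(m) {
    w <- rgamma(m, 1); w <- w / sum(w); w <- pmax(w, 0.12); w / sum(w)
  }), use.names = FALSE)
  n_bact_asv <- length(asv_genus)
  asv_ids <- sprintf("ASV%04d", seq_len(n_bact_asv))

  taxonomy <- data.frame(
    asv_id = asv_ids, domain = "Bacteria",
    phylum = pool$phylum[asv_genus], class = pool$class[asv_genus],
    order = pool$order[asv_genus], family = pool$family[asv_genus],
    genus = pool$genus[asv_genus], stringsAsFactors = FALSE)

  ## contaminant ASVs: eukaryotes, chloroplasts, mitochondria
  cf <- sc$contaminant_fraction
  n_cont <- if (cf > 0) sc$n_contaminants else 0L
  if (n_cont > 0L) {
    kind <- rep_len(c("eukaryote", "chloroplast", "mitochondria"), n_cont)
    cont_ids <- sprintf("CONT%03d", seq_len(n_cont))
    cont_tax <- data.frame(
      asv_id = cont_ids,
      domain = ifelse(kind == "eukaryote", "Eukaryota", "Bacteria"),
      phylum = ifelse(kind == "eukaryote", "Ochrophyta", "Cyanobacteria"),
      class = ifelse(kind == "eukaryote", "Bacillariophyceae",
                     ifelse(kind == "chloroplast", "Cyanobacteriia",
                            "Alphaproteobacteria")),
      order = ifelse(kind == "chloroplast", "Chloroplast",
                     ifelse(kind == "mitochondria", "Rickettsiales",
                            "Thalassiosirales")),
      family = ifelse(kind == "mitochondria", "Mitochondria", NA_character_),
      genus = NA_character_, stringsAsFactors = FALSE)
    cont_tax$class[kind == "mitochondria"] <- "Alphaproteobacteria"
    cont_tax$phylum[kind == "mitochondria"] <- "Proteobacteria"
    taxonomy <- rbind(taxonomy, cont_tax)
    cont_w <- rdirichlet1(rep(2, n_cont))
  }

  ## counts: Dirichlet-multinomial per sample at a drawn read depth
  depths_reads <- draw_read_depths(n, sc$reads_mean, sc$reads_cv)
  all_ids <- taxonomy$asv_id
  counts <- matrix(0L, n, length(all_ids),
                   dimnames = list(sample_id, all_ids))
  for (i in seq_len(n)) {
    p_g <- rdirichlet1(sc$dirichlet_concentration * base[, truth[i]])
    p_asv <- p_g[asv_genus] * asv_w
    prob <- if (n_cont > 0L) c((1 - cf) * p_asv, cf * cont_w) else p_asv
    counts[i, ] <- as.integer(rmultinom(1L, depths_reads[i], prob))
  }

  ## rare ASVs: reads moved from each sample's top ASV, so row sums are
  ## conserved and every rare ASV fails the prevalence keep-rule (counts <= 2)
  if (sc$rare_asv_count > 0L) {
    rare_ids <- sprintf("RARE%03d", seq_len(sc$rare_asv_count))
    rg <- sample.int(G, sc$rare_asv_count, replace = TRUE)
    rare_tax <- data.frame(
      asv_id = rare_ids, domain = "Bacteria", phylum = pool$phylum[rg],
      class = pool$class[rg], order = pool$order[rg],
      family = pool$family[rg], genus = pool$genus[rg],
      stringsAsFactors = FALSE)
    taxonomy <- rbind(taxonomy, rare_tax)
    rare_counts <- matrix(0L, n, sc$rare_asv_count,
                          dimnames = list(sample_id, rare_ids))
    for (j in seq_len(sc$rare_asv_count)) {
      in_samples <- sample.int(n, sample.int(4L, 1L))
      for (i in in_samples) {
        take <- sample.int(2L, 1L)
        top <- which.max(counts[i, ])
        counts[i, top] <- counts[i, top] - take
        rare_counts[i, j] <- take
      }
    }
    counts <- cbind(counts, rare_counts)
  }

  ## environmental depth profiles (monotone parametric curves + noise)
  temperature <- 13 + 9.6 * exp(-depth / 35) + rnorm(n, 0, 0.3)
  no3 <- pmax(0.01, 0.15 + 1.8 * (depth / 100)^1.5 + rnorm(n, 0, 0.08))
  no2 <- pmax(0.001, 0.04 + 0.10 * depth / 100 + rnorm(n, 0, 0.015))
  nh4 <- pmax(0.01, 0.12 + 0.35 * depth / 100 + rnorm(n, 0, 0.05))
  tin <- no3 + no2 + nh4
  srp <- pmax(0.01, 0.035 + 0.09 * (depth / 100)^1.5 + rnorm(n, 0, 0.012))
  sio4 <- pmax(0.05, 0.95 + 1.1 * depth / 100 + rnorm(n, 0, 0.1))
  oxygen_sat <- 114 - 18 * depth / 100 + rnorm(n, 0, 2)
  chl_fluor <- pmax(0.02, 0.10 + 1.2 * exp(-(depth - 70)^2 / (2 * 15^2)) +
                      rnorm(n, 0, 0.05))

  ## picoplankton vectors: per-bin means + Gaussian noise
  pico <- vapply(PICO_VARS, function(v) {
    pmax(0, sc$pico_means[truth, v] + rnorm(n, 0, sc$pico_sds[[v]]))
  }, numeric(n))
  pico <- as.data.frame(pico)
  pico$hna_pct <- pmin(95, pmax(5, pico$hna_pct))
  pico$lna_pct <- 100 - pico$hna_pct

  ## salinity: planted correlation with the mean standardized biotic anomaly
  b <- rowMeans(scale(as.matrix(pico[, BIOTIC_BLOCK])))
  b <- as.numeric(scale(b))
  rho <- sc$salinity_rho
  z_sal <- rho * b + sqrt(1 - rho^2) * rnorm(n)
  salinity <- sc$salinity_mean + sc$salinity_sd * z_sal

  metadata <- data.frame(
    sample_id = sample_id, station = station, depth = depth,
    temperature = temperature, salinity = salinity,
    oxygen_sat = oxygen_sat, no3 = no3, no2 = no2, nh4 = nh4, tin = tin,
    srp = srp, sio4 = sio4, chl_fluor = chl_fluor, stringsAsFactors = FALSE)
  pico <- cbind(data.frame(sample_id = sample_id, stringsAsFactors = FALSE),
                round(pico, 4))

  structure(list(
    counts = as_asv_table(counts),
    taxonomy = taxonomy[order(taxonomy$asv_id), , drop = FALSE],
    metadata = metadata,
    pico = pico,
    truth = truth,
    scenario = sc,
    seed = as.integer(seed)
  ), class = "synthetic_dataset")
}

#' Ground-truth labels of a synthetic dataset
#'
#' @param ds a `synthetic_dataset`.
#' @return list: `labels` (integer vector aligned with the dataset's sample
#'   order, named by sample id) and `scenario`.
#' @export
planted_truth <- function(ds) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  list(labels = setNames(ds$truth, ds$metadata$sample_id),
       scenario = ds$scenario)
}

#' Generate Gaussian planted clusters at a controlled separation
#'
#' Isotropic unit-variance Gaussian clusters whose centers are rescaled so
#' the minimum pairwise center distance equals `separation` within-cluster
#' standard deviations. Points falling nearer another planted center than
#' their own are redrawn, so the planted labels coincide with the nearest-
#' center partition: without this, at separation 5 in 9 dimensions roughly
#' one draw in eight of 22 points contains a label-inconsistent point that
#' no clustering method could recover. Used for vector-quantization
#' recovery experiments.
#'
#' @param n total number of points.
#' @param k number of clusters.
#' @param d dimensionality.
#' @param separation minimum center distance in within-cluster sd units.
#' @param seed integer seed.
#' @return list: `x` (n x d matrix), `labels` (integer vector).
#' @export
generate_planted_clusters <- function(n, k, d, separation = 5, seed = 1L) {
  stopifnot(n >= k, k >= 2L, d >= 1L, separation > 0)
  set.seed(seed)
  centers <- matrix(rnorm(k * d), k, d)
  dmin <- min(dist(centers))
  centers <- centers * (separation / dmin)
  labels <- rep_len(seq_len(k), n)
  x <- matrix(0, n, d)
  for (i in seq_len(n)) {
    repeat {
      p <- centers[labels[i], ] + rnorm(d)
      d2 <- rowSums(sweep(centers, 2L, p, "-")^2)
      if (which.min(d2) == labels[i]) break
    }
    x[i, ] <- p
  }
  rownames(x) <- sprintf("pt%03d", seq_len(n))
  colnames(x) <- sprintf("f%02d", seq_len(d))
  list(x = x, labels = labels)
}
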