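#' @useDynLib picogas, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif sd setNames cor.test quantile
#' @importFrom utils read.delim write.table
NULL

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

META_COLS <- c("sample_id", "station", "depth", "temperature", "salinity",
               "oxygen_sat", "no3", "no2", "nh4", "tin", "srp", "sio4",
               "chl_fluor")

PICO_COLS <- c("sample_id", "tp", "syn", "prochl", "pe", "hnf", "aap",
               "aap_pct", "hna_pct", "lna_pct", "bp")

delim_for <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Validate an ASV count table
#'
#' An ASV table is an integer matrix of read counts with unique sample ids as
#' row names and unique ASV ids as column names. Row order defines the sample
#' order used by every downstream step.
#'
#' @param counts matrix of non-negative integer counts (samples x ASVs).
#' @return the validated matrix (storage mode integer), invisibly unchanged.
#' @export
as_asv_table <- function(counts) {
  if (!is.matrix(counts) || length(counts) == 0L) {
    stop("ASV table must be a non-empty matrix", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("ASV table needs sample row names and ASV column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate ASV ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    stop(sprintf("invalid count at sample '%s', ASV '%s': %s",
                 rownames(counts)[i[1L]], colnames(counts)[i[2L]],
                 counts[bad[1L]]), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Read an ASV count table from TSV/CSV
#'
#' The file carries ASV ids in the header and sample ids in the first column
#' (or transposed, with `orientation = "asvs_in_rows"`). Output is always
#' oriented samples x ASVs.
#'
#' @param path file path (`.tsv`/`.csv`; delimiter inferred from extension).
#' @param orientation `"samples_in_rows"` (default) or `"asvs_in_rows"`.
#' @param delim optional delimiter override.
#' @return integer matrix, samples x ASVs (see [as_asv_table()]).
#' @export
read_asv_table <- function(path, orientation = c("samples_in_rows", "asvs_in_rows"),
                           delim = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(file.exists(path))
  df <- read.delim(path, sep = delim_for(path, delim), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty ASV table: ", path, call. = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                   !is.na(m))
    i <- arrayInd(bad[1L], dim(m))
    stop(sprintf("non-numeric count at row '%s', column '%s'",
                 ids[i[1L]], colnames(m)[i[2L]]), call. = FALSE)
  }
  rownames(m) <- ids
  if (orientation == "asvs_in_rows") m <- t(m)
  as_asv_table(m)
}

#' Write an ASV count table as TSV/CSV
#'
#' @param counts ASV table matrix (samples x ASVs).
#' @param path output path; delimiter inferred from extension.
#' @param orientation row content of the written file.
#' @export
write_asv_table <- function(counts, path,
                            orientation = c("samples_in_rows", "asvs_in_rows")) {
  orientation <- match.arg(orientation)
  m <- as_asv_table(counts)
  if (orientation == "asvs_in_rows") m <- t(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1L] <- if (orientation == "samples_in_rows") "sample_id" else "asv_id"
  write_tsv(df, path)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Expects a delimited file with an `asv_id` column plus the six rank columns
#' domain, phylum, class, order, family, genus (case-insensitive header;
#' empty cells mark unassigned ranks).
#'
#' @param path file path.
#' @param delim optional delimiter override.
#' @return data.frame with columns `asv_id` and the six ranks (character;
#'   `NA` where missing).
#' @export
read_taxonomy <- function(path, delim = NULL) {
  stopifnot(file.exists(path))
  df <- read.delim(path, sep = delim_for(path, delim), check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  names(df) <- tolower(trimws(names(df)))
  need <- c("asv_id", TAX_RANKS)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("taxonomy file misses column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df <- df[, need]
  for (j in seq_along(df)) {
    df[[j]] <- trimws(df[[j]])
    df[[j]][df[[j]] == ""] <- NA_character_
  }
  if (anyDuplicated(df$asv_id)) {
    stop("duplicate asv_id in taxonomy: ",
         paste(unique(df$asv_id[duplicated(df$asv_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df$asv_id)) stop("taxonomy contains empty asv_id", call. = FALSE)
  df
}

read_typed_table <- function(path, required, numeric_cols, delim = NULL,
                             what = "table") {
  stopifnot(file.exists(path))
  df <- read.delim(path, sep = delim_for(path, delim), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- tolower(trimws(names(df)))
  miss <- setdiff(required, names(df))
  if (length(miss)) stop(what, " misses column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df <- df[, required]
  for (cn in numeric_cols) {
    v <- df[[cn]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & trimws(as.character(v)) != "")
    if (length(bad)) {
      stop(sprintf("%s: unparseable numeric in column '%s', row %d ('%s')",
                   what, cn, bad[1L], v[bad[1L]]), call. = FALSE)
    }
    df[[cn]] <- num
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop(what, ": duplicate sample_id", call. = FALSE)
  }
  df
}

#' Read the hydrographic sample metadata table
#'
#' Columns (case-insensitive): sample_id, station, depth (m), temperature
#' (deg C), salinity (PSS), oxygen_sat (%), no3, no2, nh4, tin, srp, sio4
#' (all umol/L), chl_fluor (relative fluorescence, chlorophyll proxy).
#'
#' @param path file path.
#' @param delim optional delimiter override.
#' @return data.frame of typed records, one per sample.
#' @export
read_sample_metadata <- function(path, delim = NULL) {
  df <- read_typed_table(path, META_COLS, setdiff(META_COLS, c("sample_id", "station")),
                         delim, what = "sample metadata")
  df$station <- as.character(df$station)
  if (any(df$depth < 0, na.rm = TRUE)) stop("negative depth", call. = FALSE)
  nut <- c("no3", "no2", "nh4", "tin", "srp", "sio4")
  for (cn in nut) if (any(df[[cn]] < 0, na.rm = TRUE)) {
    stop("negative concentration in ", cn, call. = FALSE)
  }
  for (cn in c("no3", "no2")) {
    bad <- which(!is.na(df$tin) & !is.na(df[[cn]]) & df$tin < df[[cn]] - 1e-9)
    if (length(bad)) stop(sprintf("tin < %s for sample '%s'", cn,
                                  df$sample_id[bad[1L]]), call. = FALSE)
  }
  df
}

#' Read the picoplankton parameter table
#'
#' Columns: sample_id, tp (1e6 cells/mL), syn, prochl, pe, hnf (1e3 cells/mL),
#' aap (1e4 cells/mL), aap_pct, hna_pct, lna_pct (%), bp (1e4 cells/h/mL).
#' Enforces `hna_pct + lna_pct = 100` within 0.1 when both present.
#'
#' @param path file path.
#' @param delim optional delimiter override.
#' @return data.frame of typed records, one per sample.
#' @export
read_pico_table <- function(path, delim = NULL) {
  df <- read_typed_table(path, PICO_COLS, setdiff(PICO_COLS, "sample_id"),
                         delim, what = "picoplankton table")
  num <- df[, setdiff(PICO_COLS, "sample_id")]
  if (any(num < 0, na.rm = TRUE)) stop("negative picoplankton value", call. = FALSE)
  both <- !is.na(df$hna_pct) & !is.na(df$lna_pct)
  bad <- which(both & abs(df$hna_pct + df$lna_pct - 100) > 0.1)
  if (length(bad)) {
    stop(sprintf("hna_pct + lna_pct != 100 for sample '%s' (%.2f + %.2f)",
                 df$sample_id[bad[1L]], df$hna_pct[bad[1L]], df$lna_pct[bad[1L]]),
         call. = FALSE)
  }
  df
}

#' Read an ASV table from a BIOM v1 (JSON) file
#'
#' Convenience wrapper mapping the BIOM interchange format onto the same
#' contract as [read_asv_table()]. Requires the `biomformat` package.
#'
#' @param path BIOM v1 JSON file.
#' @return integer matrix, samples x ASVs.
#' @export
read_biom_table <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("the 'biomformat' package is required for BIOM import", call. = FALSE)
  }
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")  # observations x samples
  as_asv_table(t(m))
}

#' Write a data.frame as a delimited UTF-8 text file
#'
#' Delimiter inferred from the extension (`.csv` comma, otherwise tab);
#' Unix newlines, no quoting, no row names.
#'
#' @param df data.frame.
#' @param path output path.
#' @param delim optional delimiter override.
#' @export
write_tsv <- function(df, path, delim = NULL) {
  write.table(df, path, sep = delim_for(path, delim), quote = FALSE,
              row.names = FALSE, col.names = TRUE, na = "", eol = "\n",
              fileEncoding = "UTF-8")
  invisible(path)
}
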