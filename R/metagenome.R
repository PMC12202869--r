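#' Read a photosynthesis gene catalog
#'
#' A catalog is a TSV with columns `gene_id` (KO-style identifier, unique),
#' `symbol` (e.g. `psaA`), `category` (apparatus: PSI, PSII, Cytb6f, PET,
#' ATPase, PBS_APC, PBS_PC_PEC, PBS_PE, FaRLiP) and `length` (amino acids,
#' > 0).  The packaged default
#' (`system.file("extdata", "photosynthesis_gene_catalog.tsv", package =
#' "ventlight")`) is a curated, user-replaceable stand-in listing the gene
#' symbols of the cyanobacterial phototrophic apparatus with standard KEGG
#' Orthology ids where they exist and synthetic ids for the far-red
#' (FaRLiP) probe genes.
#'
#' @param path Catalog TSV path; default the packaged catalog.
#' @return A data frame of class `gene_catalog`.
#' @export
read_gene_catalog <- function(path = system.file("extdata",
                                                 "photosynthesis_gene_catalog.tsv",
                                                 package = "ventlight")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  gene_catalog(df)
}

#' @rdname read_gene_catalog
#' @param df Data frame with columns `gene_id`, `symbol`, `category`,
#'   `length`.
#' @export
gene_catalog <- function(df) {
  need <- c("gene_id", "symbol", "category", "length")
  if (!all(need %in% names(df))) {
    stop_domain("catalog needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) stop_domain("catalog gene_id must be unique")
  if (any(df$length <= 0)) stop_domain("gene lengths must be positive (aa)")
  df <- df[, need]
  class(df) <- c("gene_catalog", "data.frame")
  df
}

#' Parse a BLAST/DIAMOND tabular alignment file
#'
#' Reads a 12-column tabular file (BLAST `outfmt 6`: qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore).
#' Minus-orientation rows (`send < sstart`) are normalized so that
#' `sstart <= send`.  Malformed rows raise an error naming their line
#' numbers.
#'
#' @param path Alignment file path.
#' @return A data frame of hit records with the 12 standard columns (zero
#'   rows for an empty file).
#' @export
parse_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(.empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 12L)
  if (length(bad)) {
    stop_domain("malformed alignment rows (need 12 tab-separated columns) ",
                "at line(s): ", paste(head(bad, 10L), collapse = ", "))
  }
  m <- do.call(rbind, lapply(parts, `[`, 1:12))
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- cols
  num <- setdiff(cols, c("qseqid", "sseqid"))
  df[num] <- lapply(df[num], as.numeric)
  badnum <- which(rowSums(is.na(df[num])) > 0)
  if (length(badnum)) {
    stop_domain("non-numeric fields in alignment rows at line(s): ",
                paste(head(badnum, 10L), collapse = ", "))
  }
  flip <- df$send < df$sstart
  if (any(flip)) {
    tmp <- df$sstart[flip]
    df$sstart[flip] <- df$send[flip]
    df$send[flip] <- tmp
  }
  if (any(df$bitscore < 0)) stop_domain("negative bitscores in ", path)
  df
}

# Zero-row hit table with the outfmt-6 schema.
.empty_hits <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = numeric(0),
             mismatch = numeric(0), gapopen = numeric(0),
             qstart = numeric(0), qend = numeric(0),
             sstart = numeric(0), send = numeric(0),
             evalue = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

#' Retain best hits per read
#'
#' For each read (`qseqid`) keeps the record(s) with maximal bitscore.  Ties
#' across genes are all retained and annotated: `shared_n` is the number of
#' tied records for the read, so a tied read later contributes `1/shared_n`
#' of a hit to each gene.
#'
#' @param hits Data frame from [parse_hits()].
#' @return The retained records with an added `shared_n` column.
#' @export
best_hits <- function(hits) {
  if (!nrow(hits)) {
    hits$shared_n <- integer(0)
    return(hits)
  }
  mx <- tapply(hits$bitscore, hits$qseqid, max)
  keep <- hits$bitscore == mx[hits$qseqid]
  out <- hits[keep, , drop = FALSE]
  out$shared_n <- as.integer(table(out$qseqid)[out$qseqid])
  rownames(out) <- NULL
  out
}

#' Aggregate best hits into fractional per-gene read counts
#'
#' A read whose best hit is shared by `k` genes contributes `1/k` to each,
#' so the summed counts over all genes equal the number of mapped reads.
#'
#' @param best Data frame from [best_hits()].
#' @return Data frame with columns `gene_id` and `read_hits`.
#' @export
aggregate_read_hits <- function(best) {
  if (!nrow(best)) {
    return(data.frame(gene_id = character(0), read_hits = numeric(0)))
  }
  w <- 1 / best$shared_n
  agg <- tapply(w, best$sseqid, sum)
  data.frame(gene_id = names(agg), read_hits = as.numeric(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Breadth of coverage of one gene
#'
#' Fraction of the gene length covered by the union of alignment intervals
#' (`sstart`..`send`, 1-based inclusive), computed with
#' `IRanges::reduce()`.
#'
#' @param sstart,send Alignment subject coordinates (equal length; may be
#'   empty for no hits).
#' @param gene_length Gene length in amino acids, > 0.
#' @return Covered fraction in \[0, 1\].
#' @examples
#' covered_fraction(c(1, 41), c(50, 100), 100)  # 1
#' @export
covered_fraction <- function(sstart, send, gene_length) {
  if (!is_scalar_number(gene_length) || gene_length <= 0) {
    stop_domain("gene length must be a positive scalar (aa)")
  }
  if (!length(sstart)) return(0)
  if (length(sstart) != length(send) || any(send < sstart)) {
    stop_domain("need sstart <= send for every interval")
  }
  if (any(send > gene_length) || any(sstart < 1)) {
    stop_domain("alignment coordinates outside [1, gene_length]")
  }
  red <- IRanges::reduce(IRanges::IRanges(start = as.integer(round(sstart)),
                                          end = as.integer(round(send))))
  min(1, sum(IRanges::width(red)) / gene_length)
}

#' Per-gene coverage table for one dataset
#'
#' Combines [best_hits()], [aggregate_read_hits()] and [covered_fraction()]
#' into the per-gene table the completeness scoring consumes.  Every catalog
#' gene appears (zeros when unhit); `normalized_hits` is hits per million
#' library reads.
#'
#' @param hits Data frame from [parse_hits()] (one dataset).
#' @param catalog A [gene_catalog()].
#' @param library_size Total reads in the dataset's library, > 0.
#' @return Data frame with columns `gene_id`, `read_hits`,
#'   `normalized_hits`, `covered_fraction`.
#' @export
coverage_table <- function(hits, catalog, library_size) {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (!is_scalar_number(library_size) || library_size <= 0) {
    stop_domain("library size must be positive")
  }
  best <- best_hits(hits)
  counts <- aggregate_read_hits(best)
  out <- data.frame(gene_id = catalog$gene_id, stringsAsFactors = FALSE)
  out$read_hits <- counts$read_hits[match(out$gene_id, counts$gene_id)]
  out$read_hits[is.na(out$read_hits)] <- 0
  out$normalized_hits <- out$read_hits * 1e6 / library_size
  out$covered_fraction <- vapply(seq_len(nrow(out)), function(i) {
    g <- out$gene_id[i]
    rows <- best[best$sseqid == g, , drop = FALSE]
    covered_fraction(rows$sstart, rows$send,
                     catalog$length[catalog$gene_id == g])
  }, numeric(1))
  out
}

#' Gene presence calls from coverage
#'
#' A gene is present when its covered fraction is at least `threshold`
#' (>= convention at the boundary; default 0.8).
#'
#' @param coverage Data frame from [coverage_table()].
#' @param threshold Breadth-of-coverage threshold in (0, 1\].
#' @return Named logical vector (names are gene ids).
#' @export
gene_presence <- function(coverage, threshold = 0.8) {
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold > 1) {
    stop_domain("threshold must lie in (0, 1]")
  }
  setNames(coverage$covered_fraction >= threshold, coverage$gene_id)
}

#' Apparatus completeness matrix
#'
#' For each dataset and each apparatus category, the fraction of the
#' catalog's genes of that category called present.
#'
#' @param presence Logical matrix, datasets x gene ids (dimnames required),
#'   or a single named logical vector for one dataset.
#' @param catalog A [gene_catalog()].
#' @param vent_type Optional character vector of vent types (C1, C2, S, N,
#'   O, T1, T2), one per dataset; attached as an attribute.
#' @param categories Categories to score; default all in the catalog.
#'   Requesting a category absent from the catalog is an error.
#' @return A numeric matrix of class `completeness_matrix` (datasets x
#'   categories, cells in \[0, 1\]), with attribute `vent_type`.
#' @export
apparatus_completeness <- function(presence, catalog, vent_type = NULL,
                                   categories = NULL) {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (is.vector(presence)) {
    presence <- matrix(presence, nrow = 1,
                       dimnames = list("dataset", names(presence)))
  }
  if (is.null(categories)) categories <- unique(catalog$category)
  missing_cat <- setdiff(categories, catalog$category)
  if (length(missing_cat)) {
    stop_domain("categories absent from catalog: ",
                paste(missing_cat, collapse = ", "))
  }
  m <- matrix(0, nrow(presence), length(categories),
              dimnames = list(rownames(presence), categories))
  for (cat in categories) {
    genes <- catalog$gene_id[catalog$category == cat]
    got <- intersect(genes, colnames(presence))
    sub <- presence[, got, drop = FALSE]
    n_present <- rowSums(sub)
    m[, cat] <- n_present / length(genes)
  }
  if (!is.null(vent_type)) {
    if (length(vent_type) != nrow(m)) {
      stop_domain("need one vent type per dataset")
    }
    attr(m, "vent_type") <- setNames(as.character(vent_type), rownames(m))
  }
  class(m) <- c("completeness_matrix", class(m))
  m
}

#' Far-red photoacclimation (FaRLiP) probe check
#'
#' TRUE for a dataset iff any of the probe genes (default apcD2, apcD3,
#' apcD5) is present.
#'
#' @param presence Logical matrix (datasets x gene ids) or named vector.
#' @param catalog A [gene_catalog()]; must contain all probe symbols.
#' @param probes Probe gene symbols.
#' @return Named logical vector, one per dataset.
#' @export
farlip_check <- function(presence, catalog,
                         probes = c("apcD2", "apcD3", "apcD5")) {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (!all(probes %in% catalog$symbol)) {
    stop_domain("probe gene(s) missing from catalog: ",
                paste(setdiff(probes, catalog$symbol), collapse = ", "))
  }
  if (is.vector(presence)) {
    presence <- matrix(presence, nrow = 1,
                       dimnames = list("dataset", names(presence)))
  }
  ids <- catalog$gene_id[catalog$symbol %in% probes]
  got <- intersect(ids, colnames(presence))
  if (!length(got)) {
    return(setNames(rep(FALSE, nrow(presence)), rownames(presence)))
  }
  setNames(rowSums(presence[, got, drop = FALSE]) > 0, rownames(presence))
}

#' Community composition and Shannon diversity from ATPase gene hits
#'
#' Relative abundances of the species contributing reads to the (near
#' universal) F-type ATPase genes, and the Shannon index (natural log,
#' via `vegan::diversity`).
#'
#' @param counts Named non-negative counts per species; at least one must be
#'   positive.
#' @return A list with `abundance` (named, sums to 1) and `shannon`.
#' @examples
#' community_profile(c(a = 5, b = 5, c = 5, d = 5))$shannon  # log(4)
#' @export
community_profile <- function(counts) {
  if (!is.numeric(counts) || !length(counts) || any(!is.finite(counts)) ||
      any(counts < 0)) {
    stop_domain("counts must be finite and non-negative")
  }
  if (sum(counts) == 0) stop_domain("all counts are zero")
  p <- counts / sum(counts)
  list(abundance = p,
       shannon = as.numeric(vegan::diversity(counts, index = "shannon")))
}

#' Run the completeness pipeline over several datasets
#'
#' Parses (or accepts) per-dataset alignment tables, builds coverage tables,
#' calls gene presence at the breadth threshold, and assembles the
#' completeness matrix with vent types and the FaRLiP check.
#'
#' @param hits Named list: per dataset, either a parsed hit data frame or a
#'   path to an `outfmt 6` file.
#' @param catalog A [gene_catalog()].
#' @param meta Data frame with columns `dataset` and `vent_type`.
#' @param library_sizes Named numeric vector of per-dataset library sizes.
#' @param threshold Breadth-of-coverage presence threshold (default 0.8).
#' @return List with `coverage` (per-dataset tables), `presence` (logical
#'   matrix), `completeness` ([apparatus_completeness()] matrix) and
#'   `farlip` (logical vector).
#' @export
score_datasets <- function(hits, catalog, meta, library_sizes,
                           threshold = 0.8) {
  stopifnot(inherits(catalog, "gene_catalog"),
            all(c("dataset", "vent_type") %in% names(meta)))
  ds <- names(hits)
  if (is.null(ds)) stop_domain("hits must be a named list of datasets")
  if (!all(ds %in% meta$dataset)) {
    stop_domain("metadata missing for dataset(s): ",
                paste(setdiff(ds, meta$dataset), collapse = ", "))
  }
  if (!all(ds %in% names(library_sizes))) {
    stop_domain("library size missing for dataset(s): ",
                paste(setdiff(ds, names(library_sizes)), collapse = ", "))
  }
  cov <- lapply(ds, function(d) {
    h <- hits[[d]]
    if (is.character(h)) h <- parse_hits(h)
    coverage_table(h, catalog, library_sizes[[d]])
  })
  names(cov) <- ds
  pres <- do.call(rbind, lapply(cov, gene_presence, threshold = threshold))
  rownames(pres) <- ds
  vt <- meta$vent_type[match(ds, meta$dataset)]
  comp <- apparatus_completeness(pres, catalog, vent_type = vt)
  list(coverage = cov, presence = pres, completeness = comp,
       farlip = farlip_check(pres, catalog))
}

#' Export / import a completeness matrix
#'
#' Writes a heatmap-ready TSV (rows grouped by vent type, cells formatted to
#' 3 decimals) and, alongside it, a lossless JSON file (`<path>.json`) with
#' full-precision values.  [read_completeness_json()] restores the matrix
#' exactly.
#'
#' @param m A `completeness_matrix` from [apparatus_completeness()].
#' @param path Output TSV path.
#' @param json Whether to also write `<path>.json` (default TRUE).
#' @return `path`, invisibly.
#' @export
export_matrix <- function(m, path, json = TRUE) {
  stopifnot(inherits(m, "completeness_matrix"))
  vt <- attr(m, "vent_type")
  ord <- if (is.null(vt)) seq_len(nrow(m)) else order(vt, rownames(m))
  df <- data.frame(dataset = as.character(rownames(m))[ord],
                   vent_type = if (is.null(vt)) {
                     rep(NA_character_, length(ord))
                   } else vt[ord],
                   stringsAsFactors = FALSE)
  body <- m[ord, , drop = FALSE]
  for (j in colnames(m)) df[[j]] <- sprintf("%.3f", body[, j])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (json) {
    rec <- list(datasets = rownames(m), categories = colnames(m),
                vent_type = if (is.null(vt)) NULL else unname(vt[rownames(m)]),
                values = unclass(m)[, , drop = FALSE])
    attr(rec$values, "vent_type") <- NULL
    jsonlite::write_json(rec, paste0(path, ".json"), digits = NA,
                         auto_unbox = TRUE, matrix = "rowmajor")
  }
  invisible(path)
}

#' @rdname export_matrix
#' @param json_path Path to a JSON file written by [export_matrix()].
#' @export
read_completeness_json <- function(json_path) {
  rec <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  m <- matrix(as.numeric(rec$values), nrow = length(rec$datasets),
              byrow = FALSE, dimnames = list(rec$datasets, rec$categories))
  if (is.matrix(rec$values)) m <- rec$values
  dimnames(m) <- list(rec$datasets, rec$categories)
  if (!is.null(rec$vent_type)) {
    attr(m, "vent_type") <- setNames(rec$vent_type, rec$datasets)
  }
  class(m) <- c("completeness_matrix", class(m))
  m
}
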