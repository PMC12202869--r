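test_that("outfmt-6 parsing handles well-formed, minus-frame and empty files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_outfmt6(list(
    c("r1", "K0001", 97.0, 50, 1, 0, 1, 150, 1, 50, 1e-20, 95.2),
    c("r2", "K0001", 92.5, 50, 3, 0, 1, 150, 60, 11, 1e-18, 88.0),
    c("r3", "K0002", 99.0, 50, 0, 0, 1, 150, 101, 150, 1e-25, 120.0)
  ), path)
  hits <- parse_hits(path)
  expect_equal(nrow(hits), 3L)
  # minus-frame row normalized so sstart <= send
  expect_equal(hits$sstart[2], 11)
  expect_equal(hits$send[2], 60)
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_equal(nrow(parse_hits(empty)), 0L)
})

test_that("malformed alignment rows are rejected with their line numbers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("r1", "K0001", 97, 50, 1, 0, 1, 150, 1, 50, 1e-20, 95),
                     collapse = "\t"),
               "r2\tK0001\t97"), path)
  expect_error(parse_hits(path), "line.*2")
})

test_that("best hits keep maximal-bitscore records and flag ties as shared", {
  hits <- data.frame(
    qseqid = c("r1", "r1", "r2", "r2", "r3"),
    sseqid = c("K0001", "K0002", "K0001", "K0002", "K0003"),
    pident = 95, length = 50, mismatch = 0, gapopen = 0,
    qstart = 1, qend = 150, sstart = 1, send = 50, evalue = 1e-20,
    bitscore = c(50, 80, 80, 80, 60), stringsAsFactors = FALSE)
  best <- best_hits(hits)
  expect_equal(nrow(best), 4L)
  expect_equal(best$sseqid[best$qseqid == "r1"], "K0002")
  expect_equal(sort(best$shared_n[best$qseqid == "r2"]), c(2L, 2L))
  expect_equal(nrow(best_hits(hits[0, ])), 0L)
  agg <- aggregate_read_hits(best)
  expect_equal(agg$read_hits[agg$gene_id == "K0001"], 0.5)
  expect_equal(agg$read_hits[agg$gene_id == "K0002"], 1.5)
  expect_equal(sum(agg$read_hits), 3)  # 3 mapped reads conserved
})

test_that("fractional 1/k splitting conserves mapped-read totals on random tables", {
  set.seed(99)
  for (rep in 1:10) {
    n_reads <- sample(5:40, 1)
    rows <- do.call(rbind, lapply(seq_len(n_reads), function(r) {
      k <- sample(1:3, 1)
      genes <- sample(paste0("K", 1:6), k)
      top <- runif(1, 50, 100)
      # the tied best score is shared by k genes; add some lower decoys
      decoy <- sample(paste0("K", 1:6), sample(0:2, 1))
      data.frame(qseqid = paste0("r", r),
                 sseqid = c(genes, decoy),
                 pident = 90, length = 50, mismatch = 0, gapopen = 0,
                 qstart = 1, qend = 150, sstart = 1, send = 50,
                 evalue = 1e-10,
                 bitscore = c(rep(top, k), runif(length(decoy), 1, top - 1)),
                 stringsAsFactors = FALSE)
    }))
    agg <- aggregate_read_hits(best_hits(rows))
    expect_equal(sum(agg$read_hits), n_reads, tolerance = 1e-12)
  }
})

test_that("covered fraction equals interval union over gene length", {
  expect_equal(covered_fraction(c(1, 41), c(50, 100), 100), 1)
  expect_equal(covered_fraction(1, 40, 100), 0.4)
  expect_equal(covered_fraction(numeric(0), numeric(0), 100), 0)
  expect_error(covered_fraction(10, 5, 100), "sstart <= send")
  expect_error(covered_fraction(90, 120, 100), "outside")
})

test_that("covered fraction matches a brute-force positional oracle", {
  set.seed(7)
  for (rep in 1:25) {
    len <- sample(50:1000, 1)
    n <- sample(1:12, 1)
    st <- sample(seq_len(len), n, replace = TRUE)
    en <- pmin(st + sample(10:80, n, replace = TRUE), len)
    expect_equal(covered_fraction(st, en, len),
                 oracle_covered_fraction(st, en, len), tolerance = 1e-12)
  }
})

test_that("presence threshold is >= 0.8 with the boundary counted present", {
  cov <- data.frame(gene_id = c("a", "b", "c"),
                    read_hits = 1, normalized_hits = 1,
                    covered_fraction = c(0.85, 0.79, 0.80))
  expect_equal(unname(gene_presence(cov)), c(TRUE, FALSE, TRUE))
  expect_error(gene_presence(cov, threshold = 0), "\\(0, 1\\]")
})

test_that("apparatus completeness is the per-category fraction of present genes", {
  catalog <- toy_catalog()
  genes <- catalog$gene_id
  pres <- matrix(FALSE, 2, length(genes),
                 dimnames = list(c("d1", "d2"), genes))
  pres["d1", ] <- TRUE
  m <- apparatus_completeness(pres, catalog)
  expect_true(all(m["d1", ] == 1))
  expect_true(all(m["d2", ] == 0))
  expect_error(apparatus_completeness(pres, catalog, categories = "Cytb6f"),
               "absent from catalog")
  # monotone: turning on one more gene never lowers a cell
  pres2 <- pres
  pres2["d2", "K0001"] <- TRUE
  m2 <- apparatus_completeness(pres2, catalog)
  expect_true(all(m2 >= m))
  expect_equal(m2["d2", "PSI"], 1)
})

test_that("FaRLiP check fires on any probe gene and errors without probes", {
  catalog <- toy_catalog()
  pres <- setNames(rep(FALSE, nrow(catalog)), catalog$gene_id)
  expect_false(unname(farlip_check(pres, catalog)))
  pres["FRL0001"] <- TRUE  # apcD2
  expect_true(unname(farlip_check(pres, catalog)))
  no_probe <- gene_catalog(data.frame(gene_id = "K1", symbol = "psaA",
                                      category = "PSI", length = 100))
  expect_error(farlip_check(pres, no_probe), "missing from catalog")
})

test_that("community profile normalizes abundances and computes Shannon H", {
  one <- community_profile(c(cyano = 10))
  expect_equal(one$shannon, 0)
  four <- community_profile(c(a = 5, b = 5, c = 5, d = 5))
  expect_equal(four$shannon, log(4), tolerance = 1e-12)
  set.seed(3)
  counts <- setNames(runif(7, 0.1, 50), paste0("sp", 1:7))
  prof <- community_profile(counts)
  expect_equal(sum(prof$abundance), 1, tolerance = 1e-12)
  # independent check of the index definition
  p <- counts / sum(counts)
  expect_equal(prof$shannon, -sum(p * log(p)), tolerance = 1e-12)
  expect_error(community_profile(c(a = 0, b = 0)), "zero")
})

test_that("coverage table covers every catalog gene and normalizes per million reads", {
  catalog <- toy_catalog()
  hits <- data.frame(
    qseqid = c("r1", "r2", "r3"), sseqid = c("K0001", "K0001", "K0002"),
    pident = 95, length = 50, mismatch = 0, gapopen = 0,
    qstart = 1, qend = 150,
    sstart = c(1, 51, 1), send = c(50, 100, 50), evalue = 1e-20,
    bitscore = c(90, 85, 70), stringsAsFactors = FALSE)
  cov <- coverage_table(hits, catalog, library_size = 2e6)
  expect_setequal(cov$gene_id, catalog$gene_id)
  expect_equal(cov$read_hits[cov$gene_id == "K0001"], 2)
  expect_equal(cov$normalized_hits[cov$gene_id == "K0001"], 1)
  expect_equal(cov$covered_fraction[cov$gene_id == "K0001"], 1)
  expect_equal(cov$covered_fraction[cov$gene_id == "K0002"], 0.25)
  expect_equal(cov$covered_fraction[cov$gene_id == "K0003"], 0)
})

test_that("completeness matrix export writes 3-decimal TSV and lossless JSON", {
  catalog <- read_gene_catalog()
  sim <- gen_hit_table(catalog = catalog, n_per_type = 1, seed = 5)
  sc <- score_datasets(sim$hits, catalog, sim$meta, sim$library_sizes)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_matrix(sc$completeness, path)
  back <- read_completeness_json(paste0(path, ".json"))
  expect_equal(unclass(back)[, ], unclass(sc$completeness)[, ],
               tolerance = 1e-15)
  expect_equal(attr(back, "vent_type"), attr(sc$completeness, "vent_type"))
  tsv <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(nrow(tsv), nrow(sc$completeness))
  expect_true(all(abs(tsv$PSI - unclass(sc$completeness)[tsv$dataset, "PSI"])
                  <= 5e-4))
  # rows grouped by vent type
  expect_false(is.unsorted(tsv$vent_type))
})

test_that("an empty completeness matrix exports as a header-only file", {
  catalog <- toy_catalog()
  pres <- matrix(logical(0), 0, nrow(catalog),
                 dimnames = list(NULL, catalog$gene_id))
  m <- apparatus_completeness(pres, catalog)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_matrix(m, path, json = FALSE)
  expect_length(readLines(path), 1L)
})
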