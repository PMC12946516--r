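# File formats and coordinate conventions.

test_that("GFF3 genes round-trip through write/read with 0-based half-open coordinates", {
  genes <- make_genes(c("g1", "g2"), c("1M", "1U"),
                      start = c(100L, 500L), end = c(200L, 900L),
                      strand = c("+", "-"), cds_start = c(120L, 850L))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(genes, path)
  # GFF3 on disk is 1-based closed: the + gene spanning [100, 200) is 101..200
  lines <- grep("\tgene\t", readLines(path), value = TRUE)
  f <- strsplit(lines[1], "\t")[[1]]
  expect_equal(as.integer(f[4:5]), c(101L, 200L))
  back <- read_gff3(path)
  expect_equal(back[order(back$gene_id), names(genes)],
               genes, ignore_attr = TRUE)
})

test_that("coding start is strand-aware: rightmost CDS base for minus-strand genes", {
  # minus-strand gene with CDS at 1-based 101..200 -> cds_start is 0-based 199
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1U\tsrc\tgene\t51\t260\t.\t-\t.\tID=g1",
    "1U\tsrc\tmRNA\t51\t260\t.\t-\t.\tID=g1.m1;Parent=g1",
    "1U\tsrc\tCDS\t101\t200\t.\t-\t0\tParent=g1.m1"), path)
  g <- read_gff3(path)
  expect_equal(g$start, 50L)
  expect_equal(g$end, 260L)
  expect_equal(g$cds_start, 199L)
  # the same file read with gene-anchored coding starts uses the gene edge
  expect_equal(read_gff3(path, cds_start_from = "gene")$cds_start, 259L)
})

test_that("GFF3 reader flags empty, malformed and duplicated input", {
  empty <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_warning(g <- read_gff3(empty), "empty")
  expect_equal(nrow(g), 0)

  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "1M\tsrc\tgene\t1\t100"), bad)
  expect_error(read_gff3(bad), "line 2")

  dup <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1M\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
               "1M\tsrc\tgene\t201\t300\t.\t+\t.\tID=g1"), dup)
  expect_error(read_gff3(dup), "duplicate")
})

test_that("hits tables round-trip and reject wrong layouts", {
  hits <- make_hit(c("gM1", "gM2"), c("gU1", "gU2"),
                   e_value = c(1e-50, 2.5e-21),
                   pct_identity = c(98.5, 91.2), subject_length = c(1005, 998))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_table(hits, path)
  back <- read_hits_table(path)
  expect_equal(back$pct_identity, hits$pct_identity)
  expect_equal(back$e_value, hits$e_value, tolerance = 1e-12)
  expect_equal(back$subject_length, hits$subject_length)

  short <- withr::local_tempfile(fileext = ".tsv")
  write.table(hits[, 1:12], short, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(read_hits_table(short), "14")

  commented <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# a header line", readLines(path)), commented)
  expect_equal(nrow(read_hits_table(commented)), 2)
})

test_that("bedGraph tracks round-trip and overlapping intervals are rejected", {
  track <- make_track(c("1M", "1M", "2U"), c(0L, 100L, 50L),
                      c(100L, 250L, 90L), c(2, 3.141593, 0.5))
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(track, path)
  back <- read_bedgraph(path)
  expect_equal(back$start, c(0L, 100L, 50L))
  expect_equal(back$score, track$score, tolerance = 1e-6)

  ov <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("1M\t0\t100\t2.0", "1M\t99\t150\t1.0"), ov)
  expect_error(read_bedgraph(ov), "step function")
})

test_that("TPM matrices round-trip and missing values are rejected by default", {
  tpm <- matrix(round(runif(21, 0, 50), 4), 3, 7,
                dimnames = list(c("g1", "g2", "g3"), paste0("t", 1:7)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tpm_matrix(tpm, path)
  back <- read_tpm_matrix(path)
  expect_equal(back, tpm, tolerance = 1e-6)
  expect_equal(ncol(back), 7)

  lines <- readLines(path)
  lines[2] <- sub("\t[0-9.]+$", "\tNA", lines[2])
  na_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, na_path)
  expect_error(read_tpm_matrix(na_path), "missing")
  expect_silent(m <- read_tpm_matrix(na_path, allow_missing = TRUE))
  expect_equal(sum(is.na(m)), 1)
})

test_that("subgenome is derived from the chromosome-name suffix with override", {
  expect_equal(subgenome_from_chrom(c("1M", "7U", "chr3M", "chrX")),
               c("M", "U", "M", NA))
  expect_equal(subgenome_from_chrom("scaf1", override = c(scaf1 = "U")), "U")
})
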