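test_that("SOFT sample tables read in file order with missing-value handling", {
  p <- write_soft_fixture(c("g1\t1.5", "g2\t-0.2", "g3\t0.0"))
  tab <- read_soft_sample(p)
  expect_equal(tab$id, c("g1", "g2", "g3"))
  expect_equal(tab$value, c(1.5, -0.2, 0.0))
  expect_equal(attr(tab, "sample_id"), "s1")
  expect_equal(read_log(tab)$rows_read, 3L)

  p2 <- write_soft_fixture(c("g1\t1.5", "g2\tnull", "g3\t0.25"))
  tab2 <- read_soft_sample(p2)
  expect_equal(tab2$value, c(1.5, NA, 0.25))

  p3 <- write_soft_fixture(c("g1\t1.5", "g2\twhoops"))
  expect_warning(tab3 <- read_soft_sample(p3), "unparsable")
  expect_equal(tab3$value, c(1.5, NA))
})

test_that("SOFT reader rejects malformed tables and dedups probes first-wins", {
  no_sentinel <- withr::local_tempfile(fileext = ".soft")
  readr::write_lines(c("ID_REF\tVALUE", "g1\t1.0"), no_sentinel)
  expect_error(read_soft_sample(no_sentinel), "sentinel")

  bad_header <- withr::local_tempfile(fileext = ".soft")
  readr::write_lines(c("!sample_table_begin", "PROBE\tSIGNAL", "g1\t1.0",
                       "!sample_table_end"), bad_header)
  expect_error(read_soft_sample(bad_header), "PROBE")

  dup <- write_soft_fixture(c("g1\t1.0", "g1\t2.0", "g2\t3.0"))
  expect_warning(tab <- read_soft_sample(dup), "duplicate")
  expect_equal(tab$value[tab$id == "g1"], 1.0)
  log <- read_log(tab)
  expect_equal(log$rows_read + log$rows_skipped + log$rows_errored, 3L)
})

test_that("aligned spans follow the reference-consuming CIGAR operations", {
  p <- write_sam_fixture(c(
    sam_record("r1", 100L, "50M"),
    sam_record("r2", 10L, "10M5N10M"),
    sam_record("r3", 500L, "5S20M3I10D2M4S"),
    sam_record("r4", 999L, "50M", flag = 4L)
  ))
  aln <- read_sam(p)
  expect_equal(aln$qname, c("r1", "r2", "r3"))  # unmapped r4 never emitted
  expect_equal(aln$start, c(100L, 10L, 500L))
  expect_equal(aln$end, c(149L, 34L, 500L + 20L + 10L + 2L - 1L))
  log <- read_log(aln)
  expect_equal(log$rows_read, 3L)
  expect_equal(log$rows_skipped, 1L)
})

test_that("CIGAR span law matches a per-base walk on random CIGARs", {
  withr::with_seed(7, {
    for (i in 1:200) {
      cg <- random_cigar()
      expect_equal(cigar_reference_span(cg), walk_cigar_span(cg), label = cg)
    }
  })
})

test_that("SAM reader rejects short and non-numeric records with line numbers", {
  short <- withr::local_tempfile(fileext = ".sam")
  readr::write_lines(c("@HD\tVN:1.6", "r1\t0\tchr1\t100"), short)
  expect_error(read_sam(short), "line 2")

  badpos <- write_sam_fixture("r1\t0\tchr1\tabc\t60\t50M\t*\t0\t0\t*\t*")
  expect_error(read_sam(badpos), "POS")
})

test_that("GFF reader filters by feature type and extracts gene ids by key priority", {
  p <- withr::local_tempfile(fileext = ".gff")
  readr::write_lines(c(
    "##gff-version 3",
    "chr1\t.\tgene\t50\t200\t.\t+\t.\tID=g1;Name=foo",
    "chr1\t.\tCDS\t60\t190\t.\t+\t0\tID=c1",
    "chr1\t.\tgene\t300\t400\t.\t-\t.\tlocus_tag \"g2\"",
    "chr1\t.\tgene\t500\t600\t.\t+\t.\tgene_id=g3"
  ), p)
  feats <- read_gff_genes(p)
  expect_equal(feats$gene_id, c("g1", "g2", "g3"))
  expect_equal(feats$start[1], 50L)
  expect_equal(feats$end[1], 200L)
  expect_equal(feats$strand, c("+", "-", "+"))

  inv <- withr::local_tempfile(fileext = ".gff")
  readr::write_lines("chr1\t.\tgene\t300\t250\t.\t+\t.\tID=g1", inv)
  expect_error(read_gff_genes(inv), "start > end")

  noid <- withr::local_tempfile(fileext = ".gff")
  readr::write_lines(c("chr1\t.\tgene\t1\t10\t.\t+\t.\tNote=x",
                       "chr1\t.\tgene\t20\t30\t.\t+\t.\tID=g9"), noid)
  expect_warning(kept <- read_gff_genes(noid), "skipped")
  expect_equal(kept$gene_id, "g9")
})

test_that("matrix write/read round-trips ids and values exactly, including NA", {
  m <- delimited_matrix(
    tibble::tibble(gene_id = c("g1", "g2"),
                   c1 = c(1.5, NA), c2 = c(-0.25, 3), c3 = c(0, 1e-7)))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, p)
  lines <- readr::read_lines(p)
  expect_length(lines, 3L)  # header + 2 data rows
  expect_length(strsplit(lines[2], "\t")[[1]], 4L)
  expect_match(lines[3], "NA")

  back <- read_matrix(p)
  expect_equal(matrix_content(back), matrix_content(m))

  withr::with_seed(11, {
    for (i in 1:20) {
      rm <- random_matrix(sample(1:30, 1), sample(1:6, 1))
      write_matrix(rm, p)
      expect_equal(matrix_content(read_matrix(p)), matrix_content(rm))
    }
  })
})

test_that("ragged matrix rows are rejected with the row number", {
  p <- withr::local_tempfile(fileext = ".tsv")
  readr::write_lines(c("gene_id\tc1\tc2", "g1\t1\t2", "g2\t3"), p)
  expect_error(read_matrix(p), "line 3")
})

test_that("KEGG color lists render one id-color pair per line in order", {
  p <- withr::local_tempfile(fileext = ".txt")
  entries <- tibble::tibble(gene_id = c("PVX_000100", "PVX_000200", "PVX_09"),
                            color = c("red", "yellow", "green"))
  write_kegg_colors(entries, p)
  expect_equal(readr::read_lines(p),
               c("PVX_000100 red", "PVX_000200 yellow", "PVX_09 green"))

  write_kegg_colors(entries[0, ], p)
  expect_equal(readr::read_lines(p), character(0))

  expect_error(
    write_kegg_colors(tibble::tibble(gene_id = "x", color = "blue"), p),
    "blue")
})

test_that("platform mappings collapse 2-column files and keep 3-column splits", {
  p <- withr::local_tempfile(fileext = ".tsv")
  readr::write_lines(c("probe7\tPVX_000100", "probe8\tPVX_000200"), p)
  m <- read_platform_mapping(p)
  expect_equal(m$official_id, m$kegg_id)
  expect_equal(c2_map_to_kegg("probe7", m), "PVX_000100")

  p3 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_lines("probe1\tgeneX\tkegg:123", p3)
  m3 <- read_platform_mapping(p3)
  expect_equal(m3$official_id, "geneX")
  expect_equal(m3$kegg_id, "kegg:123")

  dup <- withr::local_tempfile(fileext = ".tsv")
  readr::write_lines(c("probe1\tA", "probe1\tB"), dup)
  expect_warning(md <- read_platform_mapping(dup), "conflicting")
  expect_equal(md$kegg_id, "A")

  empty <- withr::local_tempfile(fileext = ".tsv")
  readr::write_lines("# nothing", empty)
  expect_error(read_platform_mapping(empty), "empty")
})

test_that("SOFT-wrapped platform tables are accepted", {
  p <- withr::local_tempfile(fileext = ".soft")
  readr::write_lines(c("^PLATFORM = GPL1", "!platform_table_begin",
                       "ID\tORF", "probe7\tPVX_000100",
                       "!platform_table_end"), p)
  m <- read_platform_mapping(p)
  expect_equal(m$experiment_id, "probe7")
  expect_equal(m$kegg_id, "PVX_000100")
})

test_that("HTself tables parse with p-value range enforcement", {
  p <- withr::local_tempfile(fileext = ".tsv")
  readr::write_lines(c("gene\thtself\tp", "g1\t0.9\t0.01", "g2\t0.3\t0.7"), p)
  ht <- read_htself(p)
  expect_equal(ht$gene_id, c("g1", "g2"))
  expect_equal(ht$htself_value, c(0.9, 0.3))
  expect_equal(ht$p_value, c(0.01, 0.7))

  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_lines("g1\t0.9\t1.5", bad)
  expect_error(read_htself(bad), "\\[0, 1\\]")
})

test_that("gene lists round-trip one id per line", {
  p <- withr::local_tempfile(fileext = ".txt")
  write_gene_list(c("g2", "g1", "g3"), p)
  expect_equal(read_gene_list(p), c("g2", "g1", "g3"))
})

test_that("shortest decimal rendering is bit-faithful", {
  withr::with_seed(3, {
    x <- c(0, 1, -1, 0.1, 1/3, pi, 1e-300, -2.5e17,
           stats::rnorm(200) * 10^sample(-10:10, 200, replace = TRUE))
    expect_identical(as.numeric(format_shortest(x)), x)
    expect_identical(format_shortest(NA_real_), "NA")
  })
})
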