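feats3 <- tibble::tibble(
  seqid = "chr1", ftype = "gene",
  start = c(50L, 210L, 500L), end = c(200L, 400L, 600L),
  strand = c("+", "-", "+"), gene_id = c("g1", "g2", "g3"))

aln_at <- function(start, end, rname = "chr1", strand = "+") {
  tibble::tibble(qname = "r", flag = 0L, rname = rname, pos = start,
                 cigar = paste0(end - start + 1L, "M"), strand = strand,
                 start = start, end = end)
}

test_that("reads are assigned by overlap with largest-overlap tie-breaks", {
  expect_equal(assign_read_to_gene(aln_at(100, 149), feats3), "g1")
  expect_true(is.na(assign_read_to_gene(aln_at(420, 470), feats3)))
  # read [190,239]: 11 bases in g1, 30 in g2 -> g2
  expect_equal(assign_read_to_gene(aln_at(190, 239), feats3), "g2")
  # exact tie: lexicographically smallest gene wins
  tie_feats <- tibble::tibble(
    seqid = "chr1", ftype = "gene", start = c(100L, 160L),
    end = c(150L, 210L), strand = "+", gene_id = c("gB", "gA"))
  expect_equal(assign_read_to_gene(aln_at(141, 169), tie_feats), "gA")
  # other chromosome: no assignment
  expect_true(is.na(assign_read_to_gene(aln_at(100, 149, rname = "chr2"),
                                        feats3)))
})

test_that("stranded mode only accepts same-strand genes", {
  expect_equal(assign_read_to_gene(aln_at(250, 300, strand = "-"), feats3,
                                   stranded = TRUE), "g2")
  expect_true(is.na(assign_read_to_gene(aln_at(250, 300, strand = "+"),
                                        feats3, stranded = TRUE)))
  # unstranded gene accepts both
  dot <- feats3
  dot$strand <- "."
  expect_equal(assign_read_to_gene(aln_at(250, 300, strand = "+"), dot,
                                   stranded = TRUE), "g2")
})

test_that("indexed assignment agrees with the brute-force scan on random instances", {
  withr::with_seed(101, {
    for (trial in 1:100) {
      n_genes <- sample(1:20, 1)
      n_reads <- sample(1:200, 1)
      # overlapping genes and duplicated coordinates on purpose, to force ties
      g_start <- sample(1:2000, n_genes, replace = TRUE)
      g_len <- sample(c(30, 50, 50, 100), n_genes, replace = TRUE)
      feats <- tibble::tibble(
        seqid = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
        ftype = "gene", start = g_start, end = g_start + g_len - 1L,
        strand = sample(c("+", "-", "."), n_genes, replace = TRUE),
        gene_id = sprintf("g%02d", sample(n_genes)))
      r_start <- sample(1:2100, n_reads, replace = TRUE)
      r_len <- sample(c(25, 36, 50), n_reads, replace = TRUE)
      aln <- tibble::tibble(
        qname = sprintf("r%03d", seq_len(n_reads)), flag = 0L,
        rname = sample(c("chr1", "chr2"), n_reads, replace = TRUE),
        pos = r_start, cigar = paste0(r_len, "M"),
        strand = sample(c("+", "-"), n_reads, replace = TRUE),
        start = r_start, end = r_start + r_len - 1L)
      stranded <- trial %% 2L == 0L
      expect_identical(assign_read_to_gene(aln, feats, stranded = stranded),
                       brute_force_assign(aln, feats, stranded = stranded))
    }
  })
})

test_that("annotation keeps assignable reads in order and counts removals", {
  sam <- write_sam_fixture(c(
    sam_record("r1", 100L, "36M"),    # g1
    sam_record("r2", 250L, "36M"),    # g2
    sam_record("r3", 1000L, "36M"),   # intergenic -> removed
    sam_record("r4", 60L, "36M"),     # g1
    sam_record("r5", 999L, "36M", flag = 4L)  # unmapped: not even read
  ))
  set <- c3_1_annotate(sam, feats3, "c1")
  expect_s3_class(set, "gexpo_annotated_reads")
  expect_equal(set$gene_hits, c("g1", "g2", "g1"))
  expect_equal(set$removed, 1L)
  expect_equal(set$n_mapped, 4L)
  expect_equal(length(set$gene_hits) + set$removed, set$n_mapped)

  empty <- write_sam_fixture(character(0))
  eset <- c3_1_annotate(empty, feats3, "c2")
  expect_equal(length(eset$gene_hits), 0L)
  expect_equal(eset$removed, 0L)
})

test_that("totals count annotated reads (or distinct genes on request)", {
  s1 <- structure(list(condition_id = "c1",
                       gene_hits = c("g1", "g1", "g2"),
                       removed = 0L, n_mapped = 3L),
                  class = "gexpo_annotated_reads")
  s2 <- structure(list(condition_id = "c2", gene_hits = "g2",
                       removed = 1L, n_mapped = 2L),
                  class = "gexpo_annotated_reads")
  totals <- c3_2_total(list(s1, s2))
  expect_equal(totals$total, c(3L, 1L))
  expect_equal(c3_2_total(list(s1, s2), total = "distinct-genes")$total,
               c(2L, 1L))
  expect_error(c3_2_total(list(s1, s1)), "duplicate condition")
  expect_equal(nrow(c3_2_total(list())), 0L)

  counts <- c3_3_count(list(s1, s2))
  expect_equal(counts$gene_id, c("g1", "g2"))
  expect_equal(counts$c1, c(2L, 1L))
  expect_equal(counts$c2, c(0L, 1L))
  # conservation: totals equal column sums
  expect_equal(unname(colSums(as.matrix(counts[-1]))),
               as.numeric(totals$total))
})

test_that("C3 recovers planted counts exactly and conserves reads", {
  planted <- tibble::tibble(gene_id = c("gA", "gB", "gC"),
                            c1 = c(5, 0, 2), c2 = c(1, 3, 0))
  bundle <- gen_rnaseq_fixture(planted, intergenic_reads = 2L, seed = 17)
  feats <- read_gff_genes(bundle$files[["gff"]])
  sets <- lapply(c("c1", "c2"), function(cond) {
    aln <- read_sam(bundle$files[[paste0("sam_", cond)]])
    set <- c3_1_annotate(aln, feats, cond)
    expect_equal(length(set$gene_hits) + set$removed, nrow(aln))
    expect_equal(set$removed, 2L)
    set
  })
  counts <- c3_3_count(sets)
  truth <- bundle$truth$counts
  expect_equal(matrix_content(counts)$ids, matrix_content(truth)$ids)
  expect_equal(matrix_content(counts)$cells, matrix_content(truth)$cells)
  totals <- c3_2_total(sets)
  expect_equal(totals$total, bundle$truth$totals$total)
})

test_that("normalization divides by library size and columns sum to one", {
  counts <- delimited_matrix(tibble::tibble(
    gene_id = c("g1", "g2"), c1 = c(5, 5), c2 = c(1, 3)))
  totals <- tibble::tibble(condition_id = c("c1", "c2"), total = c(10L, 4L))
  rel <- c4_normalize(counts, totals)
  expect_equal(rel$c1, c(0.5, 0.5))
  expect_equal(rel$c2, c(0.25, 0.75))
  expect_equal(concept_tag(rel), "relative_cdna_reads_counting_based_value")

  # zero counts stay zero
  z <- c4_normalize(delimited_matrix(tibble::tibble(gene_id = "g", c1 = 0)),
                    tibble::tibble(condition_id = "c1", total = 7L))
  expect_equal(z$c1, 0)

  expect_error(
    c4_normalize(counts, tibble::tibble(condition_id = "c1", total = 10L)),
    "c2")
  expect_error(
    c4_normalize(counts, tibble::tibble(condition_id = c("c1", "c2"),
                                        total = c(10L, 0L))),
    "c2")
})

test_that("column sums hit 1 within 1e-12 when totals are column sums", {
  withr::with_seed(51, {
    for (trial in 1:10) {
      n <- sample(3:30, 1)
      k <- sample(2:4, 1)
      cells <- matrix(stats::rpois(n * k, 5), nrow = n)
      cells[1, ] <- cells[1, ] + 1L  # no all-zero column
      m <- tibble::tibble(gene_id = sprintf("g%02d", 1:n))
      for (j in 1:k) m[[paste0("c", j)]] <- cells[, j]
      totals <- tibble::tibble(condition_id = paste0("c", 1:k),
                               total = as.integer(colSums(cells)))
      rel <- c4_normalize(delimited_matrix(m), totals)
      expect_true(all(abs(colSums(as.matrix(rel[-1])) - 1) < 1e-12))
    }
  })
})

test_that("the composite C3 writes the same bytes as manually chained children", {
  planted <- tibble::tibble(gene_id = c("gA", "gB"), c1 = c(3, 1), c2 = c(2, 2))
  bundle <- gen_rnaseq_fixture(planted, seed = 23)
  sams <- stats::setNames(bundle$files[c("sam_c1", "sam_c2")], c("c1", "c2"))

  dir_composite <- withr::local_tempdir()
  res <- run_c3(sams, bundle$files[["gff"]], out_dir = dir_composite)

  # manual chaining: run each child connector by hand, passing files along
  dir_manual <- withr::local_tempdir()
  r1 <- run_connector(connector_c3_1(config = list(out_dir = dir_manual)),
                      inputs = list(sam_files = sams,
                                    gff_file = bundle$files[["gff"]]))
  r2 <- run_connector(connector_c3_2(config = list(out_dir = dir_manual)),
                      inputs = list(annotated_files = r1$outputs$annotated_files))
  r3 <- run_connector(connector_c3_3(config = list(out_dir = dir_manual)),
                      inputs = list(annotated_files = r1$outputs$annotated_files))

  for (f in c("annotated_c1.txt", "annotated_c2.txt", "totals.tsv",
              "counts.tsv")) {
    expect_identical(readr::read_file(file.path(dir_composite, f)),
                     readr::read_file(file.path(dir_manual, f)),
                     label = f)
  }

  # C4 over the composite's outputs
  rel_path <- withr::local_tempfile(fileext = ".tsv")
  r4 <- run_connector(connector_c4(config = list(out = rel_path)),
                      inputs = list(counts_file = res$outputs$counts_file,
                                    totals_file = res$outputs$totals_file))
  rel <- read_matrix(rel_path)
  expect_true(all(abs(colSums(as.matrix(rel[-1])) - 1) < 1e-12))
})
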