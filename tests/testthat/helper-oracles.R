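# Independent oracles and small fixture builders used across the suite.

# Brute-force read-to-gene assignment: all-pairs overlap scan with the
# largest-overlap / lexicographic tie-break, written without any interval
# index so it can cross-check the indexed implementation.
brute_force_assign <- function(alignments, features, stranded = FALSE) {
  vapply(seq_len(nrow(alignments)), function(i) {
    best_gene <- NA_character_
    best_ov <- 0L
    for (j in seq_len(nrow(features))) {
      if (features$seqid[j] != alignments$rname[i]) next
      if (stranded && features$strand[j] != "." &&
          features$strand[j] != alignments$strand[i]) next
      ov <- min(alignments$end[i], features$end[j]) -
        max(alignments$start[i], features$start[j]) + 1L
      if (ov < 1L) next
      if (ov > best_ov ||
          (ov == best_ov && !is.na(best_gene) &&
           features$gene_id[j] < best_gene)) {
        best_ov <- ov
        best_gene <- features$gene_id[j]
      }
    }
    best_gene
  }, character(1L))
}

# Per-base walk over a CIGAR: advance a reference cursor one base at a time
# for reference-consuming operations, never using arithmetic shortcuts.
walk_cigar_span <- function(cigar) {
  ops <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")[[1L]]
  consumed <- 0L
  for (k in seq_len(nrow(ops))) {
    n <- as.integer(ops[k, 2L])
    if (ops[k, 3L] %in% c("M", "D", "N", "=", "X")) {
      for (b in seq_len(n)) consumed <- consumed + 1L
    }
  }
  consumed
}

random_cigar <- function() {
  n_ops <- sample(1:5, 1L)
  ops <- sample(c("M", "I", "D", "N", "S", "=", "X"), n_ops, replace = TRUE)
  # soft clips are only legal at the ends; keep M somewhere for realism
  ops[sample(n_ops, 1L)] <- "M"
  inner <- ops[ops != "S"]
  body <- paste0(sample(1:50, length(inner), replace = TRUE), inner,
                 collapse = "")
  lead <- if (stats::runif(1) < 0.3) paste0(sample(1:10, 1L), "S") else ""
  tail <- if (stats::runif(1) < 0.3) paste0(sample(1:10, 1L), "S") else ""
  paste0(lead, body, tail)
}

write_soft_fixture <- function(rows, path = tempfile(fileext = ".soft"),
                               sample_id = "s1") {
  readr::write_lines(c(
    paste0("^SAMPLE = ", sample_id),
    "!sample_table_begin",
    "ID_REF\tVALUE",
    rows,
    "!sample_table_end"
  ), path)
  path
}

write_sam_fixture <- function(records, path = tempfile(fileext = ".sam")) {
  readr::write_lines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:100000", records),
                     path)
  path
}

sam_record <- function(qname, pos, cigar, flag = 0L, rname = "chr1") {
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
          qname, flag, rname, pos, cigar)
}

# id/value content of a matrix, attributes stripped, for exact comparisons
matrix_content <- function(m) {
  list(ids = m$gene_id, cols = names(m)[-1L],
       cells = unname(as.matrix(tibble::as_tibble(m)[-1L])))
}

random_matrix <- function(n_genes, n_conds, na_fraction = 0.15) {
  vals <- matrix(stats::rnorm(n_genes * n_conds) * 10^sample(-3:3, 1L),
                 nrow = n_genes)
  vals[stats::runif(length(vals)) < na_fraction] <- NA_real_
  out <- tibble::tibble(gene_id = sprintf("g%03d", seq_len(n_genes)))
  for (j in seq_len(n_conds)) out[[paste0("c", j)]] <- vals[, j]
  delimited_matrix(out, "ratio_intensity_based_value")
}

# deterministic categorized-samples bundle built in memory
toy_categorized <- function(sizes, n_genes = 6L, seed = 42L) {
  withr::with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(n_genes))
    cats <- purrr::imap(sizes, function(n, cat) {
      tabs <- lapply(seq_len(n), function(i) {
        tibble::tibble(id = genes,
                       value = stats::rlnorm(n_genes, meanlog = 6))
      })
      names(tabs) <- sprintf("%s_%d", cat, seq_len(n))
      tabs
    })
    categorized_samples(cats)
  })
}
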