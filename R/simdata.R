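# Deterministic fixture generators emulating the three integration
# scenarios' input shapes: per-condition two-color SOFT ratio files, SAM
# alignments over a small prokaryote-like genome with GFF genes, one-color
# intensity samples in biological categories, an HTself result table and a
# platform mapping. Each bundle carries the planted ground truth so every
# connector can be checked against known answers without downloads.
# All files are written in exactly the dialects the package readers parse.

with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

new_fixture_bundle <- function(files, truth, seed) {
  structure(list(files = files, truth = truth, seed = seed),
            class = "gexpo_fixture_bundle")
}

#' @export
print.gexpo_fixture_bundle <- function(x, ...) {
  cat("<gexpo_fixture_bundle> seed=", x$seed, ", ", length(x$files),
      " file(s)\n", sep = "")
  for (nm in names(x$files)) cat("  ", nm, ": ", x$files[[nm]], "\n", sep = "")
  invisible(x)
}

gene_names <- function(n) sprintf("g%03d", seq_len(n))

write_soft_file <- function(path, sample_id, ids, values) {
  readr::write_lines(c(
    paste0("^SAMPLE = ", sample_id),
    paste0("!Sample_title = synthetic sample ", sample_id),
    "!sample_table_begin",
    "ID_REF\tVALUE",
    sprintf("%s\t%s", ids, format_shortest(values)),
    "!sample_table_end"
  ), path)
}

#' Generate per-condition two-color SOFT sample files
#'
#' Values are zero-centred log2 ratios drawn from a normal distribution; a
#' fraction of (gene, condition) cells is omitted from the files to
#' exercise missing-value merging. Regeneration with the same seed is
#' byte-identical.
#'
#' @param n_genes,n_conditions Positive counts.
#' @param seed Integer seed for the generator stream.
#' @param out_dir Output directory (created if needed).
#' @param omit_fraction Fraction of cells omitted per condition (default
#'   0.1; each file always keeps at least one row).
#' @param sd Standard deviation of the log2 ratios (default 1).
#' @return A `gexpo_fixture_bundle`: `files` (one SOFT path per condition,
#'   named by condition id), `truth` (long tibble of every planted value,
#'   `NA` where omitted, plus `sd`), `seed`.
#' @export
gen_two_color_soft <- function(n_genes, n_conditions, seed = 1L,
                               out_dir = tempfile("twocolor_"),
                               omit_fraction = 0.1, sd = 1) {
  if (n_genes < 1L || n_conditions < 1L) {
    stop("n_genes and n_conditions must be at least 1", call. = FALSE)
  }
  if (omit_fraction < 0 || omit_fraction >= 1) {
    stop("omit_fraction must be in [0, 1)", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genes <- gene_names(n_genes)
  conds <- sprintf("cond%d", seq_len(n_conditions))
  with_local_seed(seed, {
    truth <- list()
    files <- character(0)
    for (cond in conds) {
      values <- stats::rnorm(n_genes, mean = 0, sd = sd)
      n_omit <- min(floor(omit_fraction * n_genes), n_genes - 1L)
      omit <- if (n_omit > 0L) sample.int(n_genes, n_omit) else integer(0)
      keep <- setdiff(seq_len(n_genes), omit)
      path <- file.path(out_dir, paste0(cond, ".soft"))
      write_soft_file(path, cond, genes[keep], values[keep])
      files[cond] <- path
      values[omit] <- NA_real_
      truth[[cond]] <- tibble::tibble(gene_id = genes, condition = cond,
                                      value = values)
    }
    new_fixture_bundle(files,
                       truth = list(values = dplyr::bind_rows(truth), sd = sd),
                       seed = seed)
  })
}

#' Generate a SAM + GFF RNA-Seq fixture with planted counts
#'
#' Lays out `nrow(counts)` non-overlapping genes on one reference sequence
#' (`gene_length` bases each, separated by `spacing`-base intergenic gaps,
#' with a leading gap) and writes one SAM file per count column containing
#' exactly `counts[g, c]` reads placed uniformly and wholly inside gene `g`,
#' plus `intergenic_reads` reads placed wholly between genes (these are the
#' reads the annotation step must remove).
#'
#' @param counts Planted gene-by-condition count table: a `gexpo_matrix`, or
#'   any data frame whose first column is the gene id, with non-negative
#'   integer cells.
#' @param gene_length,spacing,read_length Geometry in bases; both
#'   `gene_length` and `spacing` must be at least `read_length` so every
#'   read fits wholly inside its target region.
#' @param intergenic_reads Unassignable reads per condition.
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return A `gexpo_fixture_bundle`: `files` (`gff` plus one SAM per
#'   condition named `sam_<condition>`), `truth` (`counts` matrix sorted by
#'   gene, `totals`, `removed` per condition, gene coordinates), `seed`.
#' @export
gen_rnaseq_fixture <- function(counts, gene_length = 100L, spacing = 50L,
                               intergenic_reads = 2L, read_length = 36L,
                               seed = 1L, out_dir = tempfile("rnaseq_")) {
  counts <- tibble::as_tibble(counts)
  names(counts)[1L] <- "gene_id"
  cells <- as.matrix(counts[-1L])
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop("planted counts must be non-negative integers", call. = FALSE)
  }
  if (gene_length < read_length || spacing < read_length) {
    stop("infeasible geometry: gene_length and spacing must each be >= ",
         "read_length", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_genes <- nrow(counts)
  conds <- names(counts)[-1L]
  # gene i occupies [spacing*i + gene_length*(i-1) + 1, same + gene_length - 1]
  starts <- spacing * seq_len(n_genes) +
    gene_length * (seq_len(n_genes) - 1L) + 1L
  ends <- starts + gene_length - 1L
  genome_len <- ends[n_genes] + spacing
  gaps <- tibble::tibble(start = c(1L, ends + 1L),
                         end = c(starts - 1L, genome_len))

  gff_path <- file.path(out_dir, "genes.gff")
  readr::write_lines(c(
    "##gff-version 3",
    sprintf("chr1\tsimdata\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            starts, ends, rep_len(c("+", "-"), n_genes), counts$gene_id)
  ), gff_path)

  with_local_seed(seed, {
    files <- c(gff = gff_path)
    for (cond in conds) {
      recs <- character(0)
      read_no <- 0L
      emit <- function(pos) {
        read_no <<- read_no + 1L
        sprintf("r%04d\t0\tchr1\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                read_no, pos, read_length,
                strrep("A", read_length))
      }
      for (g in seq_len(n_genes)) {
        k <- cells[g, cond]
        if (k > 0L) {
          pos <- starts[g] +
            sample.int(gene_length - read_length + 1L, k, replace = TRUE) - 1L
          recs <- c(recs, vapply(pos, emit, ""))
        }
      }
      if (intergenic_reads > 0L) {
        gap_i <- sample.int(nrow(gaps), intergenic_reads, replace = TRUE)
        pos <- gaps$start[gap_i] +
          vapply(gap_i, function(i) {
            sample.int(gaps$end[i] - gaps$start[i] - read_length + 2L, 1L)
          }, integer(1L)) - 1L
        recs <- c(recs, vapply(pos, emit, ""))
      }
      sam_path <- file.path(out_dir, paste0(cond, ".sam"))
      readr::write_lines(c(
        "@HD\tVN:1.6\tSO:unsorted",
        sprintf("@SQ\tSN:chr1\tLN:%d", genome_len),
        recs
      ), sam_path)
      files[paste0("sam_", cond)] <- sam_path
    }
    truth_counts <- dplyr::arrange(counts, .data$gene_id)
    new_fixture_bundle(
      files,
      truth = list(
        counts = delimited_matrix(
          truth_counts, "absolute_cdna_reads_counting_based_value"),
        totals = tibble::tibble(condition_id = conds,
                                total = as.integer(colSums(cells))),
        removed = stats::setNames(rep(as.integer(intergenic_reads),
                                      length(conds)), conds),
        genes = tibble::tibble(gene_id = counts$gene_id, start = starts,
                               end = ends)
      ),
      seed = seed)
  })
}

#' Generate categorized one-color SOFT intensity files
#'
#' Positive absolute intensities are drawn log-normally per sample around a
#' shared per-gene baseline, emulating one-color arrays of the same tissue
#' measured in separate hybridizations.
#'
#' @param n_genes Number of genes.
#' @param category_sizes Named integer vector: samples per biological
#'   category (e.g. `c(normal = 2, tumor = 3)`).
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param meanlog,sdlog Log-scale location of the per-gene baselines and
#'   per-sample spread around them.
#' @return A `gexpo_fixture_bundle`: `files` (`<category>_<i>.soft` per
#'   sample, named by sample id), `truth` (long intensity tibble,
#'   `files_by_category` ready for [read_categorized_samples()]), `seed`.
#' @export
gen_one_color_fixture <- function(n_genes, category_sizes, seed = 1L,
                                  out_dir = tempfile("onecolor_"),
                                  meanlog = 7, sdlog = 0.4) {
  if (n_genes < 1L || length(category_sizes) < 1L ||
      any(category_sizes < 1L) || is.null(names(category_sizes))) {
    stop("need n_genes >= 1 and a named vector of category sizes >= 1",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genes <- gene_names(n_genes)
  with_local_seed(seed, {
    baseline <- stats::rlnorm(n_genes, meanlog = meanlog, sdlog = sdlog)
    files <- character(0)
    by_cat <- list()
    truth <- list()
    for (cat in names(category_sizes)) {
      for (i in seq_len(category_sizes[[cat]])) {
        sample_id <- sprintf("%s_%d", cat, i)
        values <- baseline * stats::rlnorm(n_genes, meanlog = 0,
                                           sdlog = sdlog / 2)
        path <- file.path(out_dir, paste0(sample_id, ".soft"))
        write_soft_file(path, sample_id, genes, values)
        files[sample_id] <- path
        by_cat[[cat]] <- c(by_cat[[cat]],
                           stats::setNames(path, sample_id))
        truth[[sample_id]] <- tibble::tibble(
          gene_id = genes, category = cat, sample_id = sample_id,
          intensity = values)
      }
    }
    new_fixture_bundle(
      files,
      truth = list(intensities = dplyr::bind_rows(truth),
                   files_by_category = by_cat),
      seed = seed)
  })
}

#' Generate an HTself result table with a planted significant set
#'
#' Planted genes receive an HTself statistic above and a p-value below the
#' generator's thresholds; every other gene fails at least one criterion,
#' so the significance filter must recover exactly the planted set.
#'
#' @param n_genes Number of genes.
#' @param planted_significant Character subset of the generated gene names
#'   (`g001`, `g002`, ...).
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param stat_threshold,p_threshold The generator's thresholds, recorded in
#'   the truth (defaults 0.8 and 0.05).
#' @return A `gexpo_fixture_bundle`: `files` (`htself`), `truth`
#'   (`significant`, `stat_threshold`, `p_threshold`, full table), `seed`.
#' @export
gen_htself_fixture <- function(n_genes, planted_significant, seed = 1L,
                               out_dir = tempfile("htself_"),
                               stat_threshold = 0.8, p_threshold = 0.05) {
  genes <- gene_names(n_genes)
  if (!all(planted_significant %in% genes)) {
    stop("planted_significant must be a subset of the generated genes ",
         "(g001..g", sprintf("%03d", n_genes), ")", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_local_seed(seed, {
    planted <- genes %in% planted_significant
    ht <- numeric(n_genes)
    p <- numeric(n_genes)
    ht[planted] <- stats::runif(sum(planted), stat_threshold + 0.01,
                                stat_threshold + 0.2)
    p[planted] <- stats::runif(sum(planted), 0, p_threshold * 0.8)
    # non-planted genes fail the statistic, the p-value, or both
    mode <- sample.int(3L, sum(!planted), replace = TRUE)
    fail_stat <- mode != 2L
    fail_p <- mode != 1L
    ht[!planted] <- ifelse(
      fail_stat,
      stats::runif(sum(!planted), 0, stat_threshold - 0.01),
      stats::runif(sum(!planted), stat_threshold + 0.01, stat_threshold + 0.2))
    p[!planted] <- ifelse(
      fail_p,
      stats::runif(sum(!planted), min(p_threshold * 2, 1), 1),
      stats::runif(sum(!planted), 0, p_threshold * 0.8))
    path <- file.path(out_dir, "htself.tsv")
    readr::write_lines(c(
      "gene_id\thtself\tp_value",
      sprintf("%s\t%s\t%s", genes, format_shortest(ht), format_shortest(p))
    ), path)
    new_fixture_bundle(
      c(htself = path),
      truth = list(significant = genes[planted],
                   stat_threshold = stat_threshold,
                   p_threshold = p_threshold,
                   table = tibble::tibble(gene_id = genes, htself_value = ht,
                                          p_value = p)),
      seed = seed)
  })
}

#' Generate a platform gene-identifier mapping file
#'
#' A two-column mapping (experiment-specific id to KEGG id, the KEGG id
#' doubling as the official gene identifier) covering a stated fraction of
#' the genes; the rest are absent from the file, emulating platforms where
#' not every probe has a pathway-database entry.
#'
#' @param gene_ids Character vector of experiment-specific gene ids.
#' @param mappable_fraction Fraction of ids present in the mapping
#'   (default 0.8).
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return A `gexpo_fixture_bundle`: `files` (`mapping`), `truth` (`mapped`
#'   tibble of the covered ids and their KEGG ids), `seed`.
#' @export
gen_platform_mapping_fixture <- function(gene_ids, mappable_fraction = 0.8,
                                         seed = 1L,
                                         out_dir = tempfile("mapping_")) {
  if (mappable_fraction < 0 || mappable_fraction > 1) {
    stop("mappable_fraction must be in [0, 1]", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_local_seed(seed, {
    n <- length(gene_ids)
    n_mapped <- round(mappable_fraction * n)
    mapped_idx <- sort(sample.int(n, n_mapped))
    kegg <- sprintf("PVX_%06d", 100L * seq_len(n_mapped))
    path <- file.path(out_dir, "mapping.tsv")
    readr::write_lines(
      sprintf("%s\t%s", gene_ids[mapped_idx], kegg),
      path)
    new_fixture_bundle(
      c(mapping = path),
      truth = list(mapped = tibble::tibble(experiment_id = gene_ids[mapped_idx],
                                           kegg_id = kegg)),
      seed = seed)
  })
}
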