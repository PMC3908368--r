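# Scenario 2 connectors. Composite C3 turns per-condition SAM alignments
# plus a GFF gene annotation into a gene-by-condition count matrix in three
# steps (C3.1 annotate reads to genes, C3.2 per-condition totals, C3.3
# counts); C4 divides counts by library size to give relative values.

#' Assign mapped reads to overlapping genes
#'
#' A read is assigned to the gene whose interval overlaps the read's aligned
#' span on the same reference sequence by at least one base. Among several
#' overlapping genes the one with the largest overlap length wins; an exact
#' tie goes to the lexicographically smallest `gene_id`. Reads overlapping
#' no gene get `NA`. Strand is ignored unless `stranded = TRUE`, in which
#' case a gene on `+`/`-` only accepts reads on the same strand (gene strand
#' `.` accepts both).
#'
#' Overlap search is interval-index based (IRanges), per reference sequence.
#'
#' @param alignments Tibble of mapped alignments (needs `rname`, `start`,
#'   `end`, and `strand` when `stranded`), e.g. from [read_sam()].
#' @param features Tibble of gene features (needs `seqid`, `start`, `end`,
#'   `gene_id`, and `strand` when `stranded`), e.g. from [read_gff_genes()].
#' @param stranded Require matching strand (default `FALSE`).
#' @return Character vector, one gene id (or `NA`) per alignment row, in
#'   input order.
#' @export
assign_read_to_gene <- function(alignments, features, stranded = FALSE) {
  out <- rep(NA_character_, nrow(alignments))
  if (nrow(alignments) == 0L || nrow(features) == 0L) return(out)
  for (chr in unique(alignments$rname)) {
    q_idx <- which(alignments$rname == chr)
    s_idx <- which(features$seqid == chr)
    if (length(s_idx) == 0L) next
    query <- IRanges::IRanges(start = alignments$start[q_idx],
                              end = alignments$end[q_idx])
    subject <- IRanges::IRanges(start = features$start[s_idx],
                                end = features$end[s_idx])
    hits <- IRanges::findOverlaps(query, subject, minoverlap = 1L)
    if (length(hits) == 0L) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (stranded) {
      fs <- features$strand[s_idx][sh]
      ok <- fs == "." | fs == alignments$strand[q_idx][qh]
      qh <- qh[ok]
      sh <- sh[ok]
    }
    if (length(qh) == 0L) next
    ov <- pmin(alignments$end[q_idx][qh], features$end[s_idx][sh]) -
      pmax(alignments$start[q_idx][qh], features$start[s_idx][sh]) + 1L
    cand <- tibble::tibble(read = qh, gene = features$gene_id[s_idx][sh],
                           overlap = ov)
    best <- cand |>
      dplyr::arrange(.data$read, dplyr::desc(.data$overlap), .data$gene) |>
      dplyr::distinct(.data$read, .keep_all = TRUE)
    out[q_idx[best$read]] <- best$gene
  }
  out
}

#' C3.1: annotate reads of one condition with gene identifiers
#'
#' Replaces each assignable mapped read with its associated gene identifier,
#' in read order; reads with no overlapping gene are removed and counted.
#'
#' @param sam Path to a SAM file, or an alignment tibble from [read_sam()].
#' @param features Gene features from [read_gff_genes()].
#' @param condition_id Condition identifier for this alignment file.
#' @param stranded Passed to [assign_read_to_gene()].
#' @return An object of class `gexpo_annotated_reads`: list with
#'   `condition_id`, `gene_hits` (character, one per retained read),
#'   `removed` and `n_mapped` counts (`length(gene_hits) + removed ==
#'   n_mapped`).
#' @export
c3_1_annotate <- function(sam, features, condition_id, stranded = FALSE) {
  aln <- if (is.character(sam)) read_sam(sam) else sam
  gene <- assign_read_to_gene(aln, features, stranded = stranded)
  structure(list(condition_id = condition_id,
                 gene_hits = gene[!is.na(gene)],
                 removed = sum(is.na(gene)),
                 n_mapped = nrow(aln)),
            class = "gexpo_annotated_reads")
}

#' @export
print.gexpo_annotated_reads <- function(x, ...) {
  cat("<gexpo_annotated_reads> ", x$condition_id, ": ",
      length(x$gene_hits), " annotated, ", x$removed, " removed of ",
      x$n_mapped, " mapped reads\n", sep = "")
  invisible(x)
}

check_condition_ids <- function(sets) {
  ids <- vapply(sets, `[[`, "", "condition_id")
  if (anyDuplicated(ids)) {
    stop("duplicate condition id: '", ids[duplicated(ids)][1L], "'",
         call. = FALSE)
  }
  ids
}

#' C3.2: per-condition totals of annotated reads
#'
#' The library size used for normalization: by default the number of
#' annotated reads per condition. The alternative literal reading -- the
#' number of distinct annotated genes -- is available via
#' `total = "distinct-genes"` but does not reflect library size.
#'
#' @param sets List of `gexpo_annotated_reads` (unique condition ids).
#' @param total `"reads"` (default) or `"distinct-genes"`.
#' @return A tibble with columns `condition_id`, `total`.
#' @export
c3_2_total <- function(sets, total = c("reads", "distinct-genes")) {
  total <- match.arg(total)
  ids <- check_condition_ids(sets)
  tibble::tibble(
    condition_id = ids,
    total = vapply(sets, function(s) {
      if (total == "reads") length(s$gene_hits)
      else length(unique(s$gene_hits))
    }, integer(1L))
  )
}

#' Write / read per-condition totals
#'
#' Tab-delimited, one column per experimental condition, a single data row
#' of totals.
#'
#' @param totals Tibble from [c3_2_total()].
#' @param path File path.
#' @return `write_totals()` returns `path` invisibly; `read_totals()` the
#'   totals tibble.
#' @export
write_totals <- function(totals, path) {
  readr::write_lines(
    c(paste(totals$condition_id, collapse = "\t"),
      paste(totals$total, collapse = "\t")),
    path)
  invisible(path)
}

#' @rdname write_totals
#' @export
read_totals <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("totals file needs header and one data row",
                               call. = FALSE)
  tibble::tibble(
    condition_id = stringr::str_split_1(lines[1L], "\t"),
    total = as.integer(stringr::str_split_1(lines[2L], "\t"))
  )
}

#' C3.3: gene-by-condition read counts
#'
#' Rows are the union of genes hit in any condition, sorted
#' lexicographically; each cell counts how often the gene appears among the
#' condition's annotated reads (0 when absent).
#'
#' @param sets List of `gexpo_annotated_reads` (unique condition ids).
#' @return A `gexpo_matrix` tagged `absolute_cdna_reads_counting_based_value`.
#' @export
c3_3_count <- function(sets) {
  ids <- check_condition_ids(sets)
  genes <- sort(unique(unlist(lapply(sets, `[[`, "gene_hits"))))
  out <- tibble::tibble(gene_id = genes)
  for (i in seq_along(sets)) {
    tab <- table(sets[[i]]$gene_hits)
    cnt <- as.integer(tab[genes])
    out[[ids[i]]] <- ifelse(is.na(cnt), 0L, cnt)
  }
  delimited_matrix(out,
                   concept_tag = "absolute_cdna_reads_counting_based_value")
}

#' C4: library-size normalization of a count matrix
#'
#' Divides each count by its condition's total of annotated reads, yielding
#' relative cDNA reads counting-based values; when the totals are the column
#' sums, every output column sums to 1.
#'
#' @param counts Count matrix from [c3_3_count()] (or [read_matrix()]).
#' @param totals Totals tibble from [c3_2_total()] (or [read_totals()]);
#'   must cover every count column with a positive total.
#' @return A `gexpo_matrix` tagged `relative_cdna_reads_counting_based_value`.
#' @export
c4_normalize <- function(counts, totals) {
  conds <- names(counts)[-1L]
  missing_t <- setdiff(conds, totals$condition_id)
  if (length(missing_t) > 0L) {
    stop("no total for condition(s): ", paste(missing_t, collapse = ", "),
         call. = FALSE)
  }
  t_of <- stats::setNames(totals$total, totals$condition_id)
  zero <- conds[t_of[conds] <= 0]
  if (length(zero) > 0L) {
    stop("zero library-size total for condition(s): ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  out <- counts
  for (cond in conds) out[[cond]] <- counts[[cond]] / t_of[[cond]]
  delimited_matrix(out,
                   concept_tag = "relative_cdna_reads_counting_based_value")
}

#' Connector specifications for scenario 2
#'
#' The three C3 children wire together as a composite: `connector_c3_1()`
#' consumes `sam_files` (named character vector, names are condition ids)
#' and `gff_file`, producing `annotated_files` (one gene id per line per
#' condition); `connector_c3_2()` and `connector_c3_3()` consume
#' `annotated_files` and produce `totals_file` and `counts_file`.
#' `connector_c4()` consumes `counts_file` and `totals_file` and produces
#' `relative_file`. [c3_plan()] returns the children in execution order;
#' [run_c3()] validates the wiring and runs them serially.
#'
#' @param policy An [access_policy()].
#' @param config Default configuration list (`out_dir` for C3 children;
#'   `out`, `total`, `stranded` where relevant).
#' @return A [connector_spec()] (or a list of them for [c3_plan()]).
#' @export
connector_c3_1 <- function(policy = access_policy("manual"), config = list()) {
  connector_spec(
    id = "C3.1",
    consumes = c("sam_files", "gff_file"),
    produces = "annotated_files",
    equivalence_table = load_equivalence_table("C3.1"),
    policy = policy,
    config = utils::modifyList(list(out_dir = NULL, stranded = FALSE), config),
    blocks = list(
      data_input_processing = function(ctx) {
        ctx$raw <- list(
          alignments = purrr::map(ctx$inputs$sam_files, read_sam),
          features = read_gff_genes(ctx$inputs$gff_file)
        )
        ctx$tally$records_in <-
          sum(vapply(ctx$raw$alignments, nrow, integer(1L)))
        ctx
      },
      lifting = function(ctx) {
        sets <- purrr::imap(ctx$raw$alignments, function(aln, cond) {
          c3_1_annotate(aln, ctx$raw$features, cond,
                        stranded = ctx$config$stranded)
        })
        ctx$canonical <- list(
          annotated = tag_concept(sets, "gene"),
          conditions = tag_concept(names(sets), "experimental_condition")
        )
        ctx
      },
      lowering = function(ctx) {
        ctx$lowered <- ctx$canonical$annotated
        removed <- sum(vapply(ctx$lowered, `[[`, integer(1L), "removed"))
        if (removed > 0L) tally_drop(ctx, "no_gene_overlap", removed)
        ctx$tally$records_out <- sum(vapply(ctx$lowered, function(s) {
          length(s$gene_hits)
        }, integer(1L)))
        ctx
      },
      data_output_processing = function(ctx) {
        dir <- ctx$config$out_dir %||% tempfile("c3_")
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        paths <- vapply(ctx$lowered, function(s) {
          p <- file.path(dir, paste0("annotated_", s$condition_id, ".txt"))
          write_gene_list(s$gene_hits, p)
          p
        }, "")
        names(paths) <- vapply(ctx$lowered, `[[`, "", "condition_id")
        ctx$outputs$annotated_files <- paths
        ctx
      }
    ))
}

read_annotated_sets <- function(paths) {
  purrr::imap(as.list(paths), function(p, cond) {
    hits <- read_gene_list(p)
    structure(list(condition_id = cond, gene_hits = hits,
                   removed = NA_integer_, n_mapped = NA_integer_),
              class = "gexpo_annotated_reads")
  })
}

#' @rdname connector_c3_1
#' @export
connector_c3_2 <- function(policy = access_policy("manual"), config = list()) {
  connector_spec(
    id = "C3.2",
    consumes = "annotated_files",
    produces = "totals_file",
    equivalence_table = load_equivalence_table("C3.2"),
    policy = policy,
    config = utils::modifyList(list(out_dir = NULL, total = "reads"), config),
    blocks = list(
      data_input_processing = function(ctx) {
        ctx$raw <- read_annotated_sets(ctx$inputs$annotated_files)
        ctx$tally$records_in <- sum(vapply(ctx$raw, function(s) {
          length(s$gene_hits)
        }, integer(1L)))
        ctx
      },
      lifting = function(ctx) {
        ctx$canonical <- list(
          totals = tag_concept(
            c3_2_total(ctx$raw, total = ctx$config$total),
            "absolute_cdna_reads_counting_based_value")
        )
        ctx
      },
      lowering = function(ctx) {
        ctx$lowered <- ctx$canonical$totals
        ctx$tally$records_out <- nrow(ctx$lowered)
        ctx
      },
      data_output_processing = function(ctx) {
        dir <- ctx$config$out_dir %||% tempfile("c3_")
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        out <- file.path(dir, "totals.tsv")
        write_totals(ctx$lowered, out)
        ctx$outputs$totals_file <- out
        ctx
      }
    ))
}

#' @rdname connector_c3_1
#' @export
connector_c3_3 <- function(policy = access_policy("manual"), config = list()) {
  connector_spec(
    id = "C3.3",
    consumes = "annotated_files",
    produces = "counts_file",
    equivalence_table = load_equivalence_table("C3.3"),
    policy = policy,
    config = utils::modifyList(list(out_dir = NULL), config),
    blocks = list(
      data_input_processing = function(ctx) {
        ctx$raw <- read_annotated_sets(ctx$inputs$annotated_files)
        ctx$tally$records_in <- sum(vapply(ctx$raw, function(s) {
          length(s$gene_hits)
        }, integer(1L)))
        ctx
      },
      lifting = function(ctx) {
        ctx$canonical <- list(
          counts = tag_concept(c3_3_count(ctx$raw),
                               "absolute_cdna_reads_counting_based_value")
        )
        ctx
      },
      lowering = function(ctx) {
        ctx$lowered <- ctx$canonical$counts
        ctx$tally$records_out <- nrow(ctx$lowered)
        ctx
      },
      data_output_processing = function(ctx) {
        dir <- ctx$config$out_dir %||% tempfile("c3_")
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        out <- file.path(dir, "counts.tsv")
        write_matrix(ctx$lowered, out)
        ctx$outputs$counts_file <- out
        ctx
      }
    ))
}

#' @rdname connector_c3_1
#' @export
connector_c4 <- function(policy = access_policy("manual"), config = list()) {
  connector_spec(
    id = "C4",
    consumes = c("counts_file", "totals_file"),
    produces = "relative_file",
    equivalence_table = load_equivalence_table("C4"),
    policy = policy,
    config = utils::modifyList(list(out = NULL), config),
    blocks = list(
      data_input_processing = function(ctx) {
        ctx$raw <- list(
          counts = read_matrix(ctx$inputs$counts_file,
                               "absolute_cdna_reads_counting_based_value"),
          totals = read_totals(ctx$inputs$totals_file)
        )
        ctx$tally$records_in <- nrow(ctx$raw$counts)
        ctx
      },
      lifting = function(ctx) {
        ctx$canonical <- list(
          counts = tag_concept(ctx$raw$counts,
                               "absolute_cdna_reads_counting_based_value"),
          totals = tag_concept(ctx$raw$totals,
                               "absolute_cdna_reads_counting_based_value")
        )
        ctx
      },
      lowering = function(ctx) {
        ctx$lowered <- c4_normalize(ctx$canonical$counts,
                                    ctx$canonical$totals)
        ctx$tally$records_out <- nrow(ctx$lowered)
        ctx
      },
      data_output_processing = function(ctx) {
        out <- ctx$config$out %||% tempfile("relative_", fileext = ".tsv")
        write_matrix(ctx$lowered, out)
        ctx$outputs$relative_file <- out
        ctx
      }
    ))
}

#' @rdname connector_c3_1
#' @param ... Passed to the child constructors (e.g. `config`).
#' @export
c3_plan <- function(...) {
  list(connector_c3_1(...), connector_c3_2(...), connector_c3_3(...))
}

#' Run the composite connector C3
#'
#' Runs C3.1, then C3.2, then C3.3 over per-condition SAM files and a GFF
#' gene annotation, writing `annotated_<condition>.txt`, `totals.tsv` and
#' `counts.tsv` under `out_dir`.
#'
#' @param sam_files Named character vector of SAM paths (names = condition
#'   ids).
#' @param gff_file GFF file path.
#' @param out_dir Output directory.
#' @param ... Extra configuration for the children (`total`, `stranded`).
#' @return As [run_composite()].
#' @export
run_c3 <- function(sam_files, gff_file, out_dir = tempfile("c3_"), ...) {
  run_composite("C3", c3_plan(config = list(out_dir = out_dir, ...)),
                inputs = list(sam_files = sam_files, gff_file = gff_file))
}
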