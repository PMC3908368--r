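# Scenario 1 connectors. C1 merges per-condition two-color log-ratio sample
# files into one multi-column dataset so normalization can run over all
# conditions at once; C2 turns a differential-expression matrix into a KEGG
# Mapper Search&Color gene list via platform ID mapping and a symmetric
# regulation threshold.

#' Merge per-condition two-color sample tables into one ratio matrix
#'
#' Rows are the union of gene ids across the input tables, ordered by first
#' appearance (or their intersection with `genes = "intersection"`); one
#' column per experimental condition; a gene absent from a table yields a
#' missing cell. Present cells preserve the source values bit-exactly.
#'
#' @param tables List of sample tables (tibbles with columns `id`, `value`,
#'   as returned by [read_soft_sample()]).
#' @param condition_ids Unique condition identifiers, one per table.
#' @param genes Gene universe policy: `"union"` (default, missing cells
#'   padded with `NA`) or `"intersection"`.
#' @return A `gexpo_matrix` tagged `ratio_intensity_based_value`.
#' @export
#' @examples
#' t1 <- tibble::tibble(id = c("g1", "g2"), value = c(1.5, -0.2))
#' t2 <- tibble::tibble(id = "g1", value = 0.4)
#' c1_merge(list(t1, t2), c("c1", "c2"))
c1_merge <- function(tables, condition_ids, genes = c("union", "intersection")) {
  genes <- match.arg(genes)
  if (length(tables) == 0L) {
    stop("at least one sample table is required", call. = FALSE)
  }
  if (length(tables) != length(condition_ids)) {
    stop("got ", length(tables), " tables but ", length(condition_ids),
         " condition ids", call. = FALSE)
  }
  if (anyDuplicated(condition_ids)) {
    stop("duplicate condition id: '",
         condition_ids[duplicated(condition_ids)][1L], "'", call. = FALSE)
  }
  long <- purrr::map2(tables, condition_ids, function(tab, cond) {
    tibble::tibble(gene_id = tab$id, condition = cond, value = tab$value)
  }) |>
    dplyr::bind_rows()
  gene_order <- unique(long$gene_id)  # first-appearance order across tables
  wide <- tidyr::pivot_wider(long, id_cols = "gene_id",
                             names_from = "condition",
                             values_from = "value")
  wide <- wide[match(gene_order, wide$gene_id),
               c("gene_id", condition_ids)]
  if (genes == "intersection") {
    wide <- wide[stats::complete.cases(wide), ]
  }
  delimited_matrix(wide, concept_tag = "ratio_intensity_based_value")
}

#' Classify log2 ratios into regulation classes
#'
#' A gene is upregulated when its log2 ratio is at least `+t`, downregulated
#' when at most `-t`, undefined otherwise (closed boundaries, symmetric
#' threshold).
#'
#' @param log2_ratio Numeric vector of finite log2 expression ratios.
#' @param threshold Positive threshold `t` in absolute log2-ratio units.
#' @return Character vector over `upregulated`/`downregulated`/`undefined`.
#' @export
#' @examples
#' c2_classify(c(2, -2, 0.5, 1), threshold = 1)
c2_classify <- function(log2_ratio, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0) {
    stop("threshold must be a single positive finite number", call. = FALSE)
  }
  if (any(!is.finite(log2_ratio))) {
    stop("log2 ratios must be finite (missing values are excluded upstream)",
         call. = FALSE)
  }
  dplyr::case_when(
    log2_ratio >= threshold ~ "upregulated",
    log2_ratio <= -threshold ~ "downregulated",
    .default = "undefined"
  )
}

#' Map experiment-specific gene ids to KEGG identifiers
#'
#' Resolves experiment-specific identifiers through the platform mapping
#' (experiment to official to KEGG, collapsed to one step for two-column
#' mappings where the KEGG identifier corresponds directly to the official
#' gene identifier). Identifiers absent from the mapping yield `NA` --
#' absence is a value, not an error.
#'
#' @param gene_id Character vector of experiment-specific identifiers.
#' @param mapping A platform mapping from [read_platform_mapping()].
#' @return Character vector of KEGG identifiers, `NA` where unmapped.
#' @export
c2_map_to_kegg <- function(gene_id, mapping) {
  if (nrow(mapping) == 0L) stop("empty platform mapping", call. = FALSE)
  mapping$kegg_id[match(gene_id, mapping$experiment_id)]
}

#' Run connector C2: differential-expression matrix to KEGG color list
#'
#' For each gene with a non-missing value in the chosen condition column and
#' a successful KEGG mapping, emits one color entry: upregulated maps to
#' red, downregulated to green, undefined to yellow. Entries appear in
#' matrix row order; genes dropped for missing values or unmapped ids are
#' tallied per reason in the run report.
#'
#' @param matrix A gene-by-condition matrix (e.g. from [read_matrix()]).
#' @param condition_id Column to classify on; must name a matrix column.
#' @param threshold Positive regulation threshold (absolute log2 ratio).
#' @param mapping Platform mapping from [read_platform_mapping()].
#' @param scale `"log2"` (default) classifies values as-is; `"linear"`
#'   classifies on `log2(value)`.
#' @return A list with `entries` (tibble `gene_id`, `color`) and `report`
#'   (`gexpo_run_report`).
#' @export
c2_run <- function(matrix, condition_id, threshold, mapping,
                   scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!condition_id %in% names(matrix)[-1L]) {
    stop("condition '", condition_id, "' not found; available conditions: ",
         paste(names(matrix)[-1L], collapse = ", "), call. = FALSE)
  }
  tally <- new_tally()
  tally$records_in <- nrow(matrix)
  value <- matrix[[condition_id]]
  if (scale == "linear") value <- ifelse(value > 0, log2(value), NA_real_)
  keep <- !is.na(value)
  if (any(!keep)) tally$dropped["missing_value"] <- sum(!keep)
  kegg <- c2_map_to_kegg(matrix$gene_id[keep], mapping)
  mapped <- !is.na(kegg)
  if (any(!mapped)) tally$dropped["no_kegg_id"] <- sum(!mapped)
  class_of <- c2_classify(value[keep][mapped], threshold)
  entries <- tibble::tibble(
    gene_id = kegg[mapped],
    color = c(upregulated = "red", downregulated = "green",
              undefined = "yellow")[class_of]
  )
  entries$color <- unname(entries$color)
  tally$records_out <- nrow(entries)
  list(entries = entries,
       report = new_run_report("C2", tally, block_order()))
}

#' Connector specifications for scenario 1
#'
#' `connector_c1()` consumes the role `soft_files` (named character vector
#' of per-condition SOFT paths; names are the condition ids) and produces
#' `merged_matrix`. `connector_c2()` consumes `matrix_file` and
#' `mapping_file` and produces `color_list`. Configuration (with defaults
#' overridable per run): `out` / output paths; for C2 `condition_id`,
#' `threshold`, `scale`; for C1 `genes`.
#'
#' @param policy An [access_policy()].
#' @param config Default configuration list.
#' @return A [connector_spec()].
#' @export
connector_c1 <- function(policy = access_policy("manual"), config = list()) {
  connector_spec(
    id = "C1",
    consumes = "soft_files",
    produces = "merged_matrix",
    equivalence_table = load_equivalence_table("C1"),
    policy = policy,
    config = utils::modifyList(list(out = NULL, genes = "union"), config),
    blocks = list(
      data_input_processing = function(ctx) {
        paths <- ctx$inputs$soft_files
        ctx$raw <- purrr::map(paths, read_soft_sample)
        ctx$tally$records_in <- sum(vapply(ctx$raw, nrow, integer(1L)))
        ctx
      },
      lifting = function(ctx) {
        conds <- names(ctx$inputs$soft_files) %||%
          vapply(ctx$raw, attr, "", "sample_id")
        ctx$canonical <- list(
          genes = tag_concept(unique(unlist(lapply(ctx$raw, `[[`, "id"))),
                              "gene"),
          conditions = tag_concept(conds, "experimental_condition"),
          ratios = tag_concept(ctx$raw, "ratio_intensity_based_value")
        )
        ctx
      },
      lowering = function(ctx) {
        ctx$lowered <- c1_merge(ctx$canonical$ratios,
                                ctx$canonical$conditions,
                                genes = ctx$config$genes)
        m <- ctx$lowered
        ctx$tally$records_out <- sum(!is.na(as.matrix(m[-1L])))
        ctx
      },
      data_output_processing = function(ctx) {
        out <- ctx$config$out %||% tempfile("merged_", fileext = ".tsv")
        write_matrix(ctx$lowered, out)
        ctx$outputs$merged_matrix <- out
        ctx
      }
    ))
}

#' @rdname connector_c1
#' @export
connector_c2 <- function(policy = access_policy("manual"), config = list()) {
  connector_spec(
    id = "C2",
    consumes = c("matrix_file", "mapping_file"),
    produces = "color_list",
    equivalence_table = load_equivalence_table("C2"),
    policy = policy,
    config = utils::modifyList(
      list(out = NULL, condition_id = NULL, threshold = 1, scale = "log2"),
      config),
    blocks = list(
      data_input_processing = function(ctx) {
        ctx$raw <- list(matrix = read_matrix(ctx$inputs$matrix_file,
                                             "ratio_intensity_based_value"),
                        mapping = read_platform_mapping(ctx$inputs$mapping_file))
        ctx$tally$records_in <- nrow(ctx$raw$matrix)
        ctx
      },
      lifting = function(ctx) {
        ctx$canonical <- list(
          ratios = tag_concept(ctx$raw$matrix, "ratio_intensity_based_value"),
          genes = tag_concept(ctx$raw$mapping, "gene")
        )
        ctx
      },
      lowering = function(ctx) {
        cond <- ctx$config$condition_id %||%
          names(ctx$canonical$ratios)[2L]
        res <- c2_run(ctx$canonical$ratios, cond, ctx$config$threshold,
                      ctx$canonical$genes, scale = ctx$config$scale)
        ctx$lowered <- res$entries
        ctx$tally$records_out <- nrow(res$entries)
        for (r in names(res$report$records_dropped)) {
          tally_drop(ctx, r, res$report$records_dropped[[r]])
        }
        ctx
      },
      data_output_processing = function(ctx) {
        out <- ctx$config$out %||% tempfile("colors_", fileext = ".txt")
        write_kegg_colors(ctx$lowered, out)
        ctx$outputs$color_list <- out
        ctx
      }
    ))
}
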