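# Scenario 3 connectors. Composite C5 builds virtual two-color data from
# one-color absolute intensities: C5.1 emits within-category self-self
# log-ratio columns (used to calibrate the HTself statistic), C5.2 emits
# cross-category comparison columns. C6 filters the HTself result table
# into the gene list handed to functional analysis.

#' Bundle one-color samples into biological categories
#'
#' @param categories Named list: category id to a named list of sample
#'   tables (tibbles with `id`, `value`, e.g. from [read_soft_sample()]);
#'   element names are the sample ids.
#' @return A tibble of class `gexpo_categorized_samples` with columns
#'   `category`, `sample_id`, `data` (list of tibbles); sample ids are
#'   unique across all categories.
#' @export
categorized_samples <- function(categories) {
  if (length(categories) == 0L || is.null(names(categories))) {
    stop("at least one named category is required", call. = FALSE)
  }
  if (any(vapply(categories, length, integer(1L)) == 0L)) {
    stop("category '",
         names(categories)[vapply(categories, length, integer(1L)) == 0L][1L],
         "' has no samples", call. = FALSE)
  }
  out <- purrr::imap(categories, function(tables, cat) {
    ids <- names(tables) %||%
      vapply(tables, function(t) attr(t, "sample_id") %||% NA_character_, "")
    if (anyNA(ids) || any(!nzchar(ids))) {
      stop("every sample in category '", cat, "' needs a sample id",
           call. = FALSE)
    }
    tibble::tibble(category = cat, sample_id = ids,
                   data = unname(tables))
  }) |>
    dplyr::bind_rows()
  if (anyDuplicated(out$sample_id)) {
    stop("duplicate sample id across categories: '",
         out$sample_id[duplicated(out$sample_id)][1L], "'", call. = FALSE)
  }
  structure(out, class = c("gexpo_categorized_samples",
                           class(tibble::tibble())))
}

#' Read categorized one-color samples from SOFT files
#'
#' @param files_by_category Named list: category id to a character vector of
#'   SOFT paths (element names, when present, become sample ids; otherwise
#'   each file's own sample id is used).
#' @return A [categorized_samples()] bundle.
#' @export
read_categorized_samples <- function(files_by_category) {
  categorized_samples(purrr::map(files_by_category, function(paths) {
    tables <- purrr::map(paths, read_soft_sample)
    names(tables) <- names(paths) %||%
      vapply(tables, attr, "", "sample_id")
    tables
  }))
}

#' C5.1 pair plan: all within-category sample pairs
#'
#' For each category with ordered samples `s1..sn`, emits the unordered
#' pairs `(si, sj)` with `i < j` (no self-pairs, no dye-swap duplicates),
#' `choose(n, 2)` pairs per category, labelled `<category>:<si>/<sj>`.
#'
#' @param samples A [categorized_samples()] bundle.
#' @return A pair-plan tibble with columns `numerator`, `denominator`,
#'   `label`.
#' @export
enumerate_self_self_pairs <- function(samples) {
  plans <- lapply(unique(samples$category), function(cat) {
    ids <- samples$sample_id[samples$category == cat]
    if (length(ids) < 2L) return(NULL)
    idx <- utils::combn(length(ids), 2L)
    tibble::tibble(
      numerator = ids[idx[1L, ]],
      denominator = ids[idx[2L, ]],
      label = sprintf("%s:%s/%s", cat, ids[idx[1L, ]], ids[idx[2L, ]])
    )
  })
  dplyr::bind_rows(c(list(tibble::tibble(numerator = character(0),
                                         denominator = character(0),
                                         label = character(0))), plans))
}

#' C5.2 pair plan: all cross-category sample pairs
#'
#' Emits every `(a_i, b_j)` with the numerator from `cat_a` (outer loop over
#' `cat_a` samples, inner over `cat_b`, both in input order): `n_a * n_b`
#' pairs labelled `<a_i>/<b_j>`.
#'
#' @param samples A [categorized_samples()] bundle.
#' @param cat_a,cat_b Distinct category ids; `cat_a` supplies numerators.
#' @return A pair-plan tibble with columns `numerator`, `denominator`,
#'   `label`.
#' @export
enumerate_cross_pairs <- function(samples, cat_a, cat_b) {
  cats <- unique(samples$category)
  for (cat in c(cat_a, cat_b)) {
    if (!cat %in% cats) {
      stop("unknown category '", cat, "'; available: ",
           paste(cats, collapse = ", "), call. = FALSE)
    }
  }
  if (identical(cat_a, cat_b)) {
    stop("cross-category pairs need two distinct categories", call. = FALSE)
  }
  a <- samples$sample_id[samples$category == cat_a]
  b <- samples$sample_id[samples$category == cat_b]
  grid <- expand.grid(denominator = b, numerator = a,
                      stringsAsFactors = FALSE)[, c("numerator", "denominator")]
  tibble::tibble(
    numerator = grid$numerator,
    denominator = grid$denominator,
    label = sprintf("%s/%s", grid$numerator, grid$denominator)
  )
}

#' Compute virtual two-color ratio columns from a pair plan
#'
#' Rows are the union of gene ids across all samples (first-appearance
#' order); the cell for gene `g` and pair `(num, den)` is
#' `log2(I_num(g) / I_den(g))` (or the raw quotient with
#' `scale = "linear"`). A missing or non-positive intensity on either side
#' yields a missing cell; the count of such masked cells is available as
#' `attr(, "n_masked")`.
#'
#' @param samples A [categorized_samples()] bundle.
#' @param plan Pair plan from [enumerate_self_self_pairs()] or
#'   [enumerate_cross_pairs()].
#' @param scale `"log2"` (default) or `"linear"`.
#' @return A `gexpo_matrix` tagged `ratio_intensity_based_value`, one column
#'   per plan pair in plan order.
#' @export
compute_ratio_columns <- function(samples, plan, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  unknown <- setdiff(unique(c(plan$numerator, plan$denominator)),
                     samples$sample_id)
  if (length(unknown) > 0L) {
    stop("pair plan references unknown sample id '", unknown[1L], "'",
         call. = FALSE)
  }
  genes <- unique(unlist(lapply(samples$data, `[[`, "id")))
  value_of <- function(sample_id) {
    tab <- samples$data[[match(sample_id, samples$sample_id)]]
    tab$value[match(genes, tab$id)]
  }
  out <- tibble::tibble(gene_id = genes)
  n_masked <- 0L
  for (i in seq_len(nrow(plan))) {
    num <- value_of(plan$numerator[i])
    den <- value_of(plan$denominator[i])
    ok <- !is.na(num) & !is.na(den) & num > 0 & den > 0
    n_masked <- n_masked + sum(!ok)
    q <- ifelse(ok, num / den, NA_real_)
    out[[plan$label[i]]] <- if (scale == "log2") log2(q) else q
  }
  m <- delimited_matrix(out, concept_tag = "ratio_intensity_based_value")
  attr(m, "n_masked") <- n_masked
  m
}

#' Run the composite connector C5
#'
#' Runs C5.1 (within-category self-self ratios over every category) then
#' C5.2 (cross-category ratios with `cat_a` as numerator), producing one
#' virtual two-color matrix each; with `out_dir` set they are written to
#' `selfself.tsv` and `cross.tsv`.
#'
#' @param samples A [categorized_samples()] bundle.
#' @param cat_a,cat_b Distinct category ids for the cross comparison.
#' @param out_dir Optional output directory.
#' @param scale Passed to [compute_ratio_columns()].
#' @return A list with `self_self` and `cross` (`gexpo_matrix`), `files`
#'   (paths, when written) and `report` (composite `gexpo_run_report` with
#'   per-child sections).
#' @export
c5_run <- function(samples, cat_a, cat_b, out_dir = NULL,
                   scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  plan_self <- enumerate_self_self_pairs(samples)
  plan_cross <- enumerate_cross_pairs(samples, cat_a, cat_b)

  child <- function(id, plan) {
    tally <- new_tally()
    tally$records_in <- nrow(samples)
    m <- compute_ratio_columns(samples, plan, scale = scale)
    tally$records_out <- max(ncol(m) - 1L, 0L)
    if (attr(m, "n_masked") > 0L) {
      tally$dropped["nonpositive_or_missing_intensity"] <-
        attr(m, "n_masked")
    }
    list(matrix = m, report = new_run_report(id, tally, block_order()))
  }
  r1 <- child("C5.1", plan_self)
  r2 <- child("C5.2", plan_cross)

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(selfself = file.path(out_dir, "selfself.tsv"),
               cross = file.path(out_dir, "cross.tsv"))
    write_matrix(r1$matrix, files[["selfself"]])
    write_matrix(r2$matrix, files[["cross"]])
  }
  list(self_self = r1$matrix, cross = r2$matrix, files = files,
       report = new_run_report("C5", new_tally(), character(0),
                               children = list(r1$report, r2$report)))
}

#' Connector specifications for scenario 3
#'
#' `connector_c5_1()` consumes `category_files` (named list: category to
#' SOFT paths) and produces `selfself_file`; `connector_c5_2()` additionally
#' uses config `cat_a`/`cat_b` and produces `cross_file`; [c5_plan()]
#' returns both in order. `connector_c6()` consumes `htself_file` and
#' produces `gene_list` (config `stat_threshold`, `p_threshold`, `strict`).
#'
#' @param policy An [access_policy()].
#' @param config Default configuration list.
#' @return A [connector_spec()] (a list of them for [c5_plan()]).
#' @export
connector_c5_1 <- function(policy = access_policy("manual"), config = list()) {
  connector_spec(
    id = "C5.1",
    consumes = "category_files",
    produces = "selfself_file",
    equivalence_table = load_equivalence_table("C5.1"),
    policy = policy,
    config = utils::modifyList(list(out_dir = NULL, scale = "log2"), config),
    blocks = list(
      data_input_processing = function(ctx) {
        ctx$raw <- read_categorized_samples(ctx$inputs$category_files)
        ctx$tally$records_in <- nrow(ctx$raw)
        ctx
      },
      lifting = function(ctx) {
        ctx$canonical <- list(
          intensities = tag_concept(ctx$raw, "absolute_intensity_based_value")
        )
        ctx
      },
      lowering = function(ctx) {
        s <- ctx$canonical$intensities
        ctx$lowered <- compute_ratio_columns(
          s, enumerate_self_self_pairs(s), scale = ctx$config$scale)
        ctx$tally$records_out <- ncol(ctx$lowered) - 1L
        ctx
      },
      data_output_processing = function(ctx) {
        dir <- ctx$config$out_dir %||% tempfile("c5_")
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        out <- file.path(dir, "selfself.tsv")
        write_matrix(ctx$lowered, out)
        ctx$outputs$selfself_file <- out
        ctx
      }
    ))
}

#' @rdname connector_c5_1
#' @export
connector_c5_2 <- function(policy = access_policy("manual"), config = list()) {
  connector_spec(
    id = "C5.2",
    consumes = "category_files",
    produces = "cross_file",
    equivalence_table = load_equivalence_table("C5.2"),
    policy = policy,
    config = utils::modifyList(
      list(out_dir = NULL, scale = "log2", cat_a = NULL, cat_b = NULL),
      config),
    blocks = list(
      data_input_processing = function(ctx) {
        ctx$raw <- read_categorized_samples(ctx$inputs$category_files)
        ctx$tally$records_in <- nrow(ctx$raw)
        ctx
      },
      lifting = function(ctx) {
        ctx$canonical <- list(
          intensities = tag_concept(ctx$raw, "absolute_intensity_based_value")
        )
        ctx
      },
      lowering = function(ctx) {
        s <- ctx$canonical$intensities
        cats <- unique(s$category)
        cat_a <- ctx$config$cat_a %||% cats[1L]
        cat_b <- ctx$config$cat_b %||% cats[2L]
        ctx$lowered <- compute_ratio_columns(
          s, enumerate_cross_pairs(s, cat_a, cat_b),
          scale = ctx$config$scale)
        ctx$tally$records_out <- ncol(ctx$lowered) - 1L
        ctx
      },
      data_output_processing = function(ctx) {
        dir <- ctx$config$out_dir %||% tempfile("c5_")
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        out <- file.path(dir, "cross.tsv")
        write_matrix(ctx$lowered, out)
        ctx$outputs$cross_file <- out
        ctx
      }
    ))
}

#' @rdname connector_c5_1
#' @param ... Passed to the child constructors (e.g. `config`).
#' @export
c5_plan <- function(...) {
  list(connector_c5_1(...), connector_c5_2(...))
}

#' C6: filter HTself results into a gene list
#'
#' Keeps gene `g` iff its HTself statistic is at least `stat_threshold` and
#' its p-value at most `p_threshold` (strict inequalities with
#' `strict = TRUE`); input order is preserved.
#'
#' @param rows HTself result tibble from [read_htself()] (columns `gene_id`,
#'   `htself_value`, `p_value`).
#' @param stat_threshold Minimum HTself statistic.
#' @param p_threshold Maximum p-value, in `[0, 1]`.
#' @param strict Use strict inequalities (default `FALSE`).
#' @return Character vector of kept gene ids.
#' @export
c6_filter <- function(rows, stat_threshold, p_threshold, strict = FALSE) {
  stopifnot(is.finite(stat_threshold), is.finite(p_threshold),
            p_threshold >= 0, p_threshold <= 1)
  keep <- if (strict) {
    rows$htself_value > stat_threshold & rows$p_value < p_threshold
  } else {
    rows$htself_value >= stat_threshold & rows$p_value <= p_threshold
  }
  rows$gene_id[keep]
}

#' @rdname connector_c5_1
#' @export
connector_c6 <- function(policy = access_policy("manual"), config = list()) {
  connector_spec(
    id = "C6",
    consumes = "htself_file",
    produces = "gene_list",
    equivalence_table = load_equivalence_table("C6"),
    policy = policy,
    config = utils::modifyList(
      list(out = NULL, stat_threshold = 0.8, p_threshold = 0.05,
           strict = FALSE),
      config),
    blocks = list(
      data_input_processing = function(ctx) {
        ctx$raw <- read_htself(ctx$inputs$htself_file)
        ctx$tally$records_in <- nrow(ctx$raw)
        ctx
      },
      lifting = function(ctx) {
        ctx$canonical <- list(results = tag_concept(ctx$raw, "gene"))
        ctx
      },
      lowering = function(ctx) {
        ctx$lowered <- c6_filter(ctx$canonical$results,
                                 ctx$config$stat_threshold,
                                 ctx$config$p_threshold,
                                 strict = ctx$config$strict)
        ctx$tally$records_out <- length(ctx$lowered)
        dropped <- ctx$tally$records_in - length(ctx$lowered)
        if (dropped > 0L) tally_drop(ctx, "failed_thresholds", dropped)
        ctx
      },
      data_output_processing = function(ctx) {
        out <- ctx$config$out %||% tempfile("genes_", fileext = ".txt")
        write_gene_list(ctx$lowered, out)
        ctx$outputs$gene_list <- out
        ctx
      }
    ))
}
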