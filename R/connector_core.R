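# Connector engine: concept equivalence tables validated against the
# reference ontology, access policies, the four serial functional blocks
# (data input processing -> lifting -> lowering -> data output processing),
# run reports, and composite-connector orchestration.

block_order <- function() {
  c("data_input_processing", "lifting", "lowering", "data_output_processing")
}

.gexpo_cache <- new.env(parent = emptyenv())

bundled_ontology <- function() {
  if (is.null(.gexpo_cache$ontology)) {
    .gexpo_cache$ontology <- load_reference_ontology()
  }
  .gexpo_cache$ontology
}

split_concepts <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else stringr::str_trim(stringr::str_split_1(s, ","))
  })
}

#' List the bundled connectors
#'
#' @return Character vector of connector ids with a bundled equivalence
#'   table (`C1`--`C6`; `C3` and `C5` are composites whose tables carry one
#'   section per simple child connector).
#' @export
list_connectors <- function() {
  sort(sub("\\.tsv$", "",
           basename(list.files(dirname(gexpo_resource(file.path("equivalence", "C1.tsv"))),
                               pattern = "\\.tsv$"))))
}

#' Load a connector's concept equivalence table
#'
#' An equivalence table links the concepts of a connector's consumed data
#' items, the matching reference-ontology concept, and the concepts of its
#' produced data items, annotated with a transformation rule where the
#' mapping is not direct. Rows flagged `unused` record consumed items that
#' do not contribute to any output (the first partial-mapping case), for
#' which no reference concept is required.
#'
#' @param connector_id A connector id from [list_connectors()]; a simple
#'   child id such as `"C3.2"` selects that child's rows of the composite's
#'   table.
#' @param path Optional path to an equivalence-table TSV overriding the
#'   bundled one.
#' @return A tibble of class `gexpo_equivalence_table` with columns
#'   `connector`, `consumed` (list), `reference`, `produced` (list),
#'   `rule_id`, `unused`.
#' @export
load_equivalence_table <- function(connector_id, path = NULL) {
  file_id <- sub("\\..*$", "", connector_id)
  path <- path %||% gexpo_resource(file.path("equivalence",
                                             paste0(file_id, ".tsv")))
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  needed <- c("connector", "consumed", "reference", "produced", "rule_id",
              "unused")
  if (!all(needed %in% names(raw))) {
    stop("equivalence table '", basename(path), "' lacks column(s): ",
         paste(setdiff(needed, names(raw)), collapse = ", "), call. = FALSE)
  }
  tab <- tibble::tibble(
    connector = raw$connector,
    consumed = split_concepts(raw$consumed),
    reference = ifelse(is.na(raw$reference) | !nzchar(raw$reference),
                       NA_character_, raw$reference),
    produced = split_concepts(raw$produced),
    rule_id = ifelse(is.na(raw$rule_id) | !nzchar(raw$rule_id),
                     NA_character_, raw$rule_id),
    unused = toupper(raw$unused) %in% c("TRUE", "T", "1")
  )
  if (grepl("\\.", connector_id)) {
    tab <- tab[tab$connector == connector_id, ]
    if (nrow(tab) == 0L) {
      stop("no equivalence rows for connector '", connector_id, "'",
           call. = FALSE)
    }
  }
  structure(tab, connector_id = connector_id,
            class = c("gexpo_equivalence_table", class(tibble::tibble())))
}

#' Validate an equivalence table against the reference ontology
#'
#' Checks, per simple connector: every present reference concept resolves in
#' the graph; every non-unused row lacking a reference concept carries a
#' transformation rule (the second and third partial-mapping cases); unused
#' rows produce nothing and carry no rule; and no consumed or produced
#' concept appears in more than one row. Violations are returned as data,
#' never raised.
#'
#' @param table A `gexpo_equivalence_table`.
#' @param graph A `gexpo_ontology` (defaults to the bundled one).
#' @return A tibble of violations (`connector`, `row`, `problem`); zero rows
#'   means the table supports semantic integration.
#' @export
validate_equivalence_table <- function(table, graph = bundled_ontology()) {
  v <- list()
  note <- function(connector, row, problem) {
    v[[length(v) + 1L]] <<- tibble::tibble(connector = connector,
                                           row = row, problem = problem)
  }
  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    if (!is.na(r$reference) && !r$reference %in% graph$concepts$id) {
      note(r$connector, i, paste0("reference concept '", r$reference,
                                  "' does not resolve in the ontology"))
    }
    if (r$unused) {
      if (length(r$produced[[1L]]) > 0L || !is.na(r$rule_id)) {
        note(r$connector, i,
             "unused row must produce nothing and carry no rule")
      }
    } else if (is.na(r$reference) && is.na(r$rule_id)) {
      note(r$connector, i, paste0(
        "row without a reference concept requires a transformation rule ",
        "(partial-mapping cases 2-3)"))
    }
  }
  for (conn in unique(table$connector)) {
    sub <- table[table$connector == conn, ]
    for (fld in c("consumed", "produced")) {
      all_ids <- unlist(sub[[fld]])
      dup <- unique(all_ids[duplicated(all_ids)])
      for (d in dup) {
        note(conn, NA_integer_, paste0(fld, " concept '", d,
                                       "' appears in more than one row"))
      }
    }
  }
  if (length(v) == 0L) {
    tibble::tibble(connector = character(0), row = integer(0),
                   problem = character(0))
  } else {
    dplyr::bind_rows(v)
  }
}

#' Define a connector access policy
#'
#' Describes how the integration target (downstream tool or data source) is
#' reached: `manual` leaves the written outputs for the user to hand over;
#' `automatic` fires `post_output_hook` once data output processing has
#' completed. A hook failure after successful output is reported as a
#' warning and outputs are retained.
#'
#' @param transfer_mode `"manual"` or `"automatic"`.
#' @param location Path or URL descriptor of the target (informational).
#' @param post_output_hook A function of one argument (the named output
#'   list); required when `transfer_mode = "automatic"`.
#' @return An object of class `gexpo_access_policy`.
#' @export
access_policy <- function(transfer_mode = c("manual", "automatic"),
                          location = NULL, post_output_hook = NULL) {
  transfer_mode <- match.arg(transfer_mode)
  if (transfer_mode == "automatic" && !is.function(post_output_hook)) {
    stop("automatic transfer mode requires a post_output_hook function",
         call. = FALSE)
  }
  structure(list(transfer_mode = transfer_mode, location = location,
                 post_output_hook = post_output_hook),
            class = "gexpo_access_policy")
}

#' Reference hooks for automatic transfer of control
#'
#' `hook_noop()` does nothing (useful to exercise automatic mode);
#' `hook_shell(command)` runs a shell command with the output paths appended,
#' for tools reachable from the command line.
#'
#' @param command Shell command prefix.
#' @return A hook function of one argument (named list of outputs).
#' @export
hook_noop <- function() function(outputs) invisible(NULL)

#' @rdname hook_noop
#' @export
hook_shell <- function(command) {
  force(command)
  function(outputs) {
    paths <- unlist(Filter(is.character, outputs))
    status <- system(paste(c(command, shQuote(paths)), collapse = " "))
    if (!identical(status, 0L)) {
      stop("post-output shell hook exited with status ", status,
           call. = FALSE)
    }
    invisible(NULL)
  }
}

#' Construct a connector specification
#'
#' A connector is four functional blocks executed strictly in order: data
#' input processing (concrete inputs to raw in-memory form), lifting (raw
#' form to semantically tagged canonical instances), lowering (canonical
#' instances to output-ready form) and data output processing (write the
#' concrete outputs, then optionally hand control to the target tool). Each
#' block is a function receiving and returning the run context; blocks
#' populate `ctx$raw`, `ctx$canonical`, `ctx$lowered` and `ctx$outputs`
#' respectively, and may add to the drop tallies via [tally_drop()].
#'
#' @param id Connector id token.
#' @param consumes,produces Role names of the inputs consumed and outputs
#'   produced, used for composite wiring validation.
#' @param blocks Named list with exactly the four block functions, in order
#'   `data_input_processing`, `lifting`, `lowering`, `data_output_processing`.
#' @param equivalence_table The connector's `gexpo_equivalence_table`.
#' @param policy A [access_policy()] (default manual transfer).
#' @param config Default configuration list, overridable at run time.
#' @return An object of class `gexpo_connector`.
#' @export
connector_spec <- function(id, consumes, produces, blocks,
                           equivalence_table = NULL,
                           policy = access_policy("manual"),
                           config = list()) {
  if (!identical(names(blocks), block_order())) {
    stop("blocks must be exactly ", paste(block_order(), collapse = ", "),
         " in that order", call. = FALSE)
  }
  if (!all(vapply(blocks, is.function, logical(1L)))) {
    stop("every block must be a function", call. = FALSE)
  }
  stopifnot(inherits(policy, "gexpo_access_policy"))
  structure(list(id = id, consumes = consumes, produces = produces,
                 blocks = blocks, equivalence_table = equivalence_table,
                 access_policy = policy, config = config),
            class = "gexpo_connector")
}

#' @export
print.gexpo_connector <- function(x, ...) {
  cat("<gexpo_connector> ", x$id, "\n  consumes: ",
      paste(x$consumes, collapse = ", "), "\n  produces: ",
      paste(x$produces, collapse = ", "), "\n  transfer: ",
      x$access_policy$transfer_mode, "\n", sep = "")
  invisible(x)
}

#' Tag data with a reference-ontology concept
#'
#' Canonical instances exchanged between the lifting and lowering blocks are
#' ordinary tibbles/vectors carrying the reference concept that gives them
#' meaning.
#'
#' @param x Data to tag.
#' @param concept A concept id resolving in the bundled ontology.
#' @return `x` with a `concept_tag` attribute.
#' @export
tag_concept <- function(x, concept) {
  assert_concept(bundled_ontology(), concept)
  attr(x, "concept_tag") <- concept
  x
}

new_tally <- function() {
  env <- new.env(parent = emptyenv())
  env$records_in <- 0L
  env$records_out <- 0L
  env$dropped <- integer(0)
  env$warnings <- character(0)
  env
}

#' Record dropped records in the current run's tally
#'
#' @param ctx The run context handed to a block.
#' @param reason Token naming why the records were dropped.
#' @param n How many records.
#' @return `ctx`, invisibly.
#' @export
tally_drop <- function(ctx, reason, n = 1L) {
  prev <- ctx$tally$dropped[reason]
  ctx$tally$dropped[reason] <- (if (is.na(prev)) 0L else prev) + as.integer(n)
  invisible(ctx)
}

new_run_report <- function(connector_id, tally, trace, children = list()) {
  structure(list(
    connector_id = connector_id,
    records_in = tally$records_in,
    records_out = tally$records_out,
    records_dropped = tally$dropped,
    warnings = tally$warnings,
    trace = trace,
    children = children
  ), class = "gexpo_run_report")
}

#' @export
print.gexpo_run_report <- function(x, ...) {
  cat("<gexpo_run_report> ", x$connector_id, ": in=", x$records_in,
      " out=", x$records_out, " dropped=", sum(x$records_dropped), "\n",
      sep = "")
  for (r in names(x$records_dropped)) {
    cat("  dropped[", r, "] = ", x$records_dropped[[r]], "\n", sep = "")
  }
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  for (ch in x$children) {
    cat("  child ", ch$connector_id, ": in=", ch$records_in, " out=",
        ch$records_out, " dropped=", sum(ch$records_dropped), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a run report into per-tally rows
#'
#' @method tidy gexpo_run_report
#'
#' @param x A `gexpo_run_report`.
#' @param ... Unused.
#' @return A tibble with one row per metric (`connector`, `metric`, `value`),
#'   including child connectors' metrics for composite runs.
#' @export
tidy.gexpo_run_report <- function(x, ...) {
  own <- tibble::tibble(
    connector = x$connector_id,
    metric = c("records_in", "records_out",
               if (length(x$records_dropped) > 0L)
                 paste0("dropped_", names(x$records_dropped))),
    value = as.numeric(c(x$records_in, x$records_out, x$records_dropped))
  )
  dplyr::bind_rows(c(list(own), lapply(x$children, tidy)))
}

#' One-row summary of a run report
#'
#' @param x A `gexpo_run_report`.
#' @param ... Unused.
#' @return A one-row tibble: records in/out, total dropped, warning count,
#'   child count.
#' @export
#' @method glance gexpo_run_report
glance.gexpo_run_report <- function(x, ...) {
  tibble::tibble(
    connector = x$connector_id,
    records_in = x$records_in,
    records_out = x$records_out,
    records_dropped = sum(x$records_dropped),
    n_warnings = length(x$warnings),
    n_children = length(x$children)
  )
}

#' Write a run report as a machine-readable summary file
#'
#' @param report A `gexpo_run_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  t <- tidy(report)
  readr::write_lines(
    c("connector\tmetric\tvalue",
      sprintf("%s\t%s\t%s", t$connector, t$metric, format_shortest(t$value))),
    path)
  invisible(path)
}

assert_canonical <- function(canonical, id) {
  if (!is.list(canonical) || length(canonical) == 0L) {
    stop("lifting block of '", id, "' yielded no canonical instances",
         call. = FALSE)
  }
  for (nm in names(canonical)) {
    tag <- attr(canonical[[nm]], "concept_tag")
    if (is.null(tag)) {
      stop("lifting block of '", id, "' yielded untagged instance '", nm,
           "': canonical instances must carry a concept tag", call. = FALSE)
    }
    assert_concept(bundled_ontology(), tag)
  }
  invisible(canonical)
}

#' Execute a connector
#'
#' Runs the four functional blocks strictly in their fixed order. After the
#' lifting block, the canonical instances are checked to be semantically
#' tagged with resolvable concepts; the raw representation is withdrawn
#' before lowering so the lowering block consumes canonical instances only.
#' When the access policy requests automatic transfer, the post-output hook
#' fires only after data output processing has completed; a hook failure is
#' downgraded to a warning and the outputs are retained.
#'
#' @param spec A [connector_spec()].
#' @param inputs Named list of input values/paths covering `spec$consumes`.
#' @param config Configuration overrides merged over `spec$config`.
#' @return A list with `outputs` (named list) and `report`
#'   (`gexpo_run_report` whose `trace` lists the four blocks in execution
#'   order).
#' @export
run_connector <- function(spec, inputs = list(), config = list()) {
  stopifnot(inherits(spec, "gexpo_connector"))
  missing_in <- setdiff(spec$consumes, names(inputs))
  if (length(missing_in) > 0L) {
    stop("connector '", spec$id, "' is missing input(s): ",
         paste(missing_in, collapse = ", "), call. = FALSE)
  }
  ctx <- list(inputs = inputs,
              config = utils::modifyList(spec$config, config),
              raw = NULL, canonical = NULL, lowered = NULL,
              outputs = list(), tally = new_tally())
  trace <- character(0)
  for (block in block_order()) {
    trace <- c(trace, block)
    ctx <- tryCatch(
      spec$blocks[[block]](ctx),
      error = function(e) {
        stop("connector '", spec$id, "' failed in block '", block, "': ",
             conditionMessage(e), call. = FALSE)
      })
    if (block == "lifting") {
      assert_canonical(ctx$canonical, spec$id)
      ctx$raw <- NULL  # lowering consumes canonical instances only
    }
  }
  if (spec$access_policy$transfer_mode == "automatic") {
    tally <- ctx$tally  # environment: mutated in place by the handler
    tryCatch(
      spec$access_policy$post_output_hook(ctx$outputs),
      error = function(e) {
        tally$warnings <- c(
          tally$warnings,
          paste0("post-output hook failed after successful output: ",
                 conditionMessage(e)))
        warning("connector '", spec$id, "': post-output hook failed, ",
                "outputs retained: ", conditionMessage(e), call. = FALSE)
      })
  }
  missing_out <- setdiff(spec$produces, names(ctx$outputs))
  if (length(missing_out) > 0L) {
    stop("connector '", spec$id, "' did not produce declared output(s): ",
         paste(missing_out, collapse = ", "), call. = FALSE)
  }
  list(outputs = ctx$outputs,
       report = new_run_report(spec$id, ctx$tally, trace))
}

#' Validate a composite connector plan's wiring
#'
#' Every child's consumed role must be either an external input or an output
#' produced by an earlier child in the plan.
#'
#' @param plan Ordered list of [connector_spec()]s.
#' @param input_roles Character vector of externally supplied role names.
#' @return `TRUE` invisibly; a dangling role raises an error before any
#'   execution.
#' @export
validate_plan <- function(plan, input_roles = character(0)) {
  pool <- input_roles
  for (spec in plan) {
    dangling <- setdiff(spec$consumes, pool)
    if (length(dangling) > 0L) {
      stop("composite plan is mis-wired: connector '", spec$id,
           "' consumes '", dangling[1L],
           "' which no earlier connector produces and no external input ",
           "supplies", call. = FALSE)
    }
    pool <- union(pool, spec$produces)
  }
  invisible(TRUE)
}

#' Execute a composite connector
#'
#' Validates the wiring, then runs the child connectors serially in plan
#' order, handing each child's outputs to later children. The combined
#' report keeps one section per child (granularities such as reads versus
#' genes are never summed across children).
#'
#' @param id Composite connector id (e.g. `"C3"`).
#' @param plan Ordered list of child [connector_spec()]s.
#' @param inputs Named list of external inputs.
#' @param config Configuration overrides passed to every child.
#' @return A list with `outputs` (external inputs excluded) and a composite
#'   `gexpo_run_report` with per-child sections.
#' @export
run_composite <- function(id, plan, inputs = list(), config = list()) {
  validate_plan(plan, names(inputs))
  pool <- inputs
  children <- list()
  outputs <- list()
  for (spec in plan) {
    res <- run_connector(spec, pool[spec$consumes], config)
    children[[length(children) + 1L]] <- res$report
    pool[names(res$outputs)] <- res$outputs
    outputs[names(res$outputs)] <- res$outputs
  }
  tally <- new_tally()
  list(outputs = outputs,
       report = new_run_report(id, tally, trace = character(0),
                               children = children))
}
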