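onto <- load_reference_ontology()

make_table <- function(rows) {
  structure(dplyr::bind_rows(rows),
            class = c("gexpo_equivalence_table", class(tibble::tibble())))
}

eq_row <- function(connector = "CX", consumed = list(character(0)),
                   reference = NA_character_, produced = list(character(0)),
                   rule_id = NA_character_, unused = FALSE) {
  tibble::tibble(connector = connector, consumed = consumed,
                 reference = reference, produced = produced,
                 rule_id = rule_id, unused = unused)
}

test_that("equivalence validation accepts direct mappings and flags defects", {
  good <- make_table(list(
    eq_row(consumed = list("gene_id"), reference = "gene",
           produced = list("official_symbol"))))
  expect_equal(nrow(validate_equivalence_table(good, onto)), 0L)

  bad_ref <- make_table(list(
    eq_row(consumed = list("x"), reference = "nonexistent_concept")))
  v <- validate_equivalence_table(bad_ref, onto)
  expect_equal(nrow(v), 1L)
  expect_match(v$problem, "nonexistent_concept")

  no_rule <- make_table(list(
    eq_row(consumed = list("x"), produced = list("y"))))
  v2 <- validate_equivalence_table(no_rule, onto)
  expect_match(v2$problem, "partial-mapping cases 2-3")

  dup <- make_table(list(
    eq_row(consumed = list("x"), reference = "gene"),
    eq_row(consumed = list("x"), reference = "gene")))
  v3 <- validate_equivalence_table(dup, onto)
  expect_match(v3$problem, "more than one row")

  bad_unused <- make_table(list(
    eq_row(consumed = list("x"), produced = list("y"), unused = TRUE)))
  v4 <- validate_equivalence_table(bad_unused, onto)
  expect_match(v4$problem, "unused")
})

test_that("all bundled connector tables validate with zero violations", {
  expect_setequal(list_connectors(), c("C1", "C2", "C3", "C4", "C5", "C6"))
  for (id in list_connectors()) {
    v <- validate_equivalence_table(load_equivalence_table(id), onto)
    expect_equal(nrow(v), 0L, label = id)
  }
})

test_that("access policies require a hook only for automatic transfer", {
  expect_s3_class(access_policy("manual"), "gexpo_access_policy")
  expect_error(access_policy("automatic"), "hook")
  expect_s3_class(access_policy("automatic", post_output_hook = hook_noop()),
                  "gexpo_access_policy")
})

# a minimal pass-through connector used to probe the engine
toy_connector <- function(id = "TOY", policy = access_policy("manual"),
                          lowering = NULL) {
  connector_spec(
    id = id, consumes = "numbers", produces = "result",
    policy = policy,
    blocks = list(
      data_input_processing = function(ctx) {
        ctx$raw <- ctx$inputs$numbers
        ctx$tally$records_in <- length(ctx$raw)
        ctx
      },
      lifting = function(ctx) {
        ctx$canonical <- list(
          values = tag_concept(ctx$raw, "gene_expression_value"))
        ctx
      },
      lowering = lowering %||% function(ctx) {
        ctx$lowered <- as.vector(ctx$canonical$values * 2)
        ctx$tally$records_out <- length(ctx$lowered)
        ctx
      },
      data_output_processing = function(ctx) {
        ctx$outputs$result <- ctx$lowered
        ctx
      }
    ))
}

test_that("the four blocks run serially, once each, in the fixed order", {
  res <- run_connector(toy_connector(), inputs = list(numbers = 1:3))
  expect_equal(res$report$trace,
               c("data_input_processing", "lifting", "lowering",
                 "data_output_processing"))
  expect_equal(res$outputs$result, c(2, 4, 6))
  expect_equal(res$report$records_in, 3L)
})

test_that("a failing block aborts the run with the block named", {
  boom <- toy_connector(lowering = function(ctx) stop("bad math"))
  expect_error(run_connector(boom, inputs = list(numbers = 1:3)),
               "failed in block 'lowering'.*bad math")
})

test_that("lifting must yield concept-tagged canonical instances", {
  untagged <- connector_spec(
    id = "U", consumes = "numbers", produces = "result",
    blocks = list(
      data_input_processing = function(ctx) { ctx$raw <- 1; ctx },
      lifting = function(ctx) { ctx$canonical <- list(values = 1); ctx },
      lowering = function(ctx) ctx,
      data_output_processing = function(ctx) ctx
    ))
  expect_error(run_connector(untagged, inputs = list(numbers = 1)),
               "untagged")
})

test_that("automatic transfer with a no-op hook leaves outputs identical", {
  manual <- run_connector(toy_connector(), inputs = list(numbers = 1:5))
  auto <- run_connector(
    toy_connector(policy = access_policy("automatic",
                                         post_output_hook = hook_noop())),
    inputs = list(numbers = 1:5))
  expect_identical(auto$outputs, manual$outputs)
})

test_that("a hook failure after output is a warning and outputs survive", {
  failing <- toy_connector(
    policy = access_policy("automatic",
                           post_output_hook = function(outputs) {
                             stop("target tool unreachable")
                           }))
  expect_warning(res <- run_connector(failing, inputs = list(numbers = 1:2)),
                 "outputs retained")
  expect_equal(res$outputs$result, c(2, 4))
  expect_match(res$report$warnings, "hook failed")
})

test_that("missing declared inputs are rejected up front", {
  expect_error(run_connector(toy_connector(), inputs = list()),
               "missing input")
})

test_that("composite wiring is validated before any child executes", {
  ran <- FALSE
  tracked <- connector_spec(
    id = "T", consumes = "a", produces = "b",
    blocks = list(
      data_input_processing = function(ctx) { ran <<- TRUE; ctx },
      lifting = function(ctx) {
        ctx$canonical <- list(x = tag_concept(1, "gene")); ctx
      },
      lowering = function(ctx) ctx,
      data_output_processing = function(ctx) { ctx$outputs$b <- 1; ctx }
    ))
  needs_b <- connector_spec(
    id = "N", consumes = "missing_role", produces = "c",
    blocks = tracked$blocks)
  expect_error(
    run_composite("X", list(needs_b, tracked), inputs = list(a = 1)),
    "mis-wired")
  expect_false(ran)
})

test_that("C3 children out of order are rejected as dangling wiring", {
  plan_bad <- list(connector_c3_3(), connector_c3_1())
  expect_error(validate_plan(plan_bad, c("sam_files", "gff_file")),
               "annotated_files")
  expect_silent(validate_plan(c3_plan(), c("sam_files", "gff_file")))
  expect_silent(validate_plan(c5_plan(), "category_files"))
})

test_that("composite reports keep one section per child", {
  bundle <- gen_rnaseq_fixture(
    tibble::tibble(gene_id = c("gA", "gB"), c1 = c(2, 1), c2 = c(0, 3)),
    seed = 5)
  sams <- stats::setNames(bundle$files[c("sam_c1", "sam_c2")], c("c1", "c2"))
  res <- run_c3(sams, bundle$files[["gff"]])
  expect_equal(vapply(res$report$children, `[[`, "", "connector_id"),
               c("C3.1", "C3.2", "C3.3"))
  t <- tidy(res$report)
  expect_true(all(c("C3.1", "C3.2", "C3.3") %in% t$connector))
  g <- glance(res$report)
  expect_equal(g$n_children, 3L)
})

test_that("run reports can be written as machine-readable summaries", {
  res <- run_connector(toy_connector(), inputs = list(numbers = 1:3))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_run_report(res$report, p)
  lines <- readr::read_lines(p)
  expect_equal(lines[1], "connector\tmetric\tvalue")
  expect_true(any(grepl("records_in\t3", lines)))
})
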