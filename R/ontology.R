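# Reference gene-expression ontology: a small typed concept graph bundled as
# plain-text edge and concept lists, queried for subsumption and relations.

#' Closed vocabulary of ontology relations
#'
#' The relation types the concept graph may use. `is_a` carries the
#' subsumption hierarchy; `part_of`/`has_part` are mereological;
#' `preceded_by` orders (sub)processes and is treated as non-transitive;
#' `produced_by`, `affected_by` and `quantifies` relate processes, entities,
#' conditions and quantities; `has_participant` and `derives_from` complete
#' the process/entity vocabulary.
#'
#' @return Character vector of admissible relation tokens.
#' @export
#' @examples
#' relation_vocabulary()
relation_vocabulary <- function() {
  c("is_a", "part_of", "has_part", "preceded_by", "produced_by",
    "has_participant", "affected_by", "quantifies", "derives_from")
}

#' Normalize a concept label into a concept id
#'
#' Concept ids are lowercase tokens with every run of spaces or hyphens
#' replaced by a single underscore, so `"RNA-Seq experimental process"`
#' becomes `"rna_seq_experimental_process"`.
#'
#' @param label Character vector of human-readable concept labels.
#' @return Character vector of normalized ids.
#' @export
normalize_concept_id <- function(label) {
  stringr::str_replace_all(stringr::str_to_lower(label), "[\\s-]+", "_")
}

gexpo_resource <- function(file) {
  path <- system.file("extdata", file, package = "gexpoconnect")
  if (!nzchar(path)) {
    # during development the package may not be installed yet
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) {
    stop("bundled resource not found: ", file, call. = FALSE)
  }
  path
}

read_edge_lines <- function(path) {
  lines <- readr::read_lines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  fields <- stringr::str_split(lines[keep], "\t")
  bad <- which(lengths(fields) != 3L)
  if (length(bad) > 0L) {
    stop("corrupted ontology resource '", basename(path), "' at line ",
         keep[bad[1L]], ": expected 3 tab-separated fields, got ",
         length(fields[[bad[1L]]]), call. = FALSE)
  }
  tibble::tibble(
    subject  = vapply(fields, `[[`, "", 1L),
    relation = vapply(fields, `[[`, "", 2L),
    object   = vapply(fields, `[[`, "", 3L)
  )
}

#' Load the bundled reference gene-expression ontology
#'
#' Reads the packaged concept registry and typed edge list into an in-memory
#' graph used for semantic tagging of connector data and for validating
#' concept equivalence tables. The graph covers the gene-expression process,
#' the measurement processes (one-/two-color microarray, RNA-Seq) and the
#' expression-value hierarchy (absolute/ratio intensity-based values,
#' absolute/relative cDNA reads counting-based values).
#'
#' Validation at load time enforces: unique concept ids that are the
#' normalization of their labels, relations drawn from
#' [relation_vocabulary()], edge endpoints that resolve to known concepts, an
#' acyclic `is_a` sub-graph, and reachability of every concept from the root
#' concept `thing` along reversed `is_a` edges.
#'
#' @param edges_path,concepts_path Optional paths overriding the bundled
#'   resources (same plain-text formats).
#' @return An object of class `gexpo_ontology`: a list with tibbles
#'   `concepts` (`id`, `label`, `source`) and `edges`
#'   (`subject`, `relation`, `object`).
#' @export
#' @examples
#' onto <- load_reference_ontology()
#' is_subconcept(onto, "ratio_intensity_based_value", "gene_expression_value")
load_reference_ontology <- function(edges_path = NULL, concepts_path = NULL) {
  concepts_path <- concepts_path %||% gexpo_resource("gexpo_concepts.tsv")
  edges_path <- edges_path %||% gexpo_resource("gexpo_edges.tsv")

  craw <- read_edge_lines(concepts_path)  # same 3-column shape: id, label, source
  concepts <- tibble::tibble(id = craw$subject, label = craw$relation,
                             source = craw$object)
  if (anyDuplicated(concepts$id)) {
    stop("corrupted ontology resource: duplicate concept id '",
         concepts$id[duplicated(concepts$id)][1L], "'", call. = FALSE)
  }
  bad_src <- setdiff(unique(concepts$source),
                     c("introduced", "gene_ontology", "sequence_ontology"))
  if (length(bad_src) > 0L) {
    stop("corrupted ontology resource: unknown concept source '", bad_src[1L],
         "'", call. = FALSE)
  }
  mismatch <- concepts$id != normalize_concept_id(concepts$label)
  if (any(mismatch)) {
    stop("concept id '", concepts$id[mismatch][1L],
         "' is not the normalization of its label", call. = FALSE)
  }

  edges <- read_edge_lines(edges_path)
  bad_rel <- setdiff(unique(edges$relation), relation_vocabulary())
  if (length(bad_rel) > 0L) {
    stop("corrupted ontology resource: unknown relation '", bad_rel[1L], "'",
         call. = FALSE)
  }
  unknown <- setdiff(unique(c(edges$subject, edges$object)), concepts$id)
  if (length(unknown) > 0L) {
    stop("ontology edge references unknown concept '", unknown[1L], "'",
         call. = FALSE)
  }

  graph <- structure(list(concepts = concepts, edges = edges),
                     class = "gexpo_ontology")

  cyc <- find_isa_cycle(graph)
  if (!is.null(cyc)) {
    stop("is_a hierarchy contains a cycle: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  }
  unreachable <- setdiff(concepts$id, concepts_under(graph, "thing"))
  if (length(unreachable) > 0L) {
    stop("concept(s) not reachable from root 'thing' via is_a: ",
         paste(unreachable, collapse = ", "), call. = FALSE)
  }
  graph
}

#' @export
print.gexpo_ontology <- function(x, ...) {
  cat("<gexpo_ontology> ", nrow(x$concepts), " concepts, ",
      nrow(x$edges), " edges\n", sep = "")
  tab <- table(x$edges$relation)
  cat("  relations: ",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

assert_concept <- function(graph, id, arg = "concept") {
  ok <- id %in% graph$concepts$id
  if (!all(ok)) {
    stop("unknown ", arg, " id: '", id[!ok][1L], "'", call. = FALSE)
  }
  invisible(id)
}

isa_parents <- function(graph, id) {
  e <- graph$edges
  e$object[e$relation == "is_a" & e$subject == id]
}

# depth-first walk of is_a edges; returns the first cycle found or NULL
find_isa_cycle <- function(graph) {
  isa <- graph$edges[graph$edges$relation == "is_a", ]
  state <- new.env(parent = emptyenv())
  visit <- function(node, path) {
    if (node %in% path) {
      return(c(path[seq(match(node, path), length(path))], node))
    }
    if (isTRUE(state[[node]])) return(NULL)
    for (p in isa$object[isa$subject == node]) {
      cyc <- visit(p, c(path, node))
      if (!is.null(cyc)) return(cyc)
    }
    state[[node]] <- TRUE
    NULL
  }
  for (n in unique(isa$subject)) {
    cyc <- visit(n, character(0))
    if (!is.null(cyc)) return(cyc)
  }
  NULL
}

# all concepts at or below `id` in the is_a hierarchy (id included)
concepts_under <- function(graph, id) {
  isa <- graph$edges[graph$edges$relation == "is_a", ]
  seen <- character(0)
  frontier <- id
  while (length(frontier) > 0L) {
    seen <- union(seen, frontier)
    frontier <- setdiff(isa$subject[isa$object %in% frontier], seen)
  }
  seen
}

#' Test subsumption between two concepts
#'
#' `TRUE` iff `a` equals `b` or `a` reaches `b` through one or more `is_a`
#' edges (reflexive-transitive subsumption).
#'
#' @param graph A `gexpo_ontology` from [load_reference_ontology()].
#' @param a,b Concept ids.
#' @return Logical scalar.
#' @export
#' @examples
#' onto <- load_reference_ontology()
#' is_subconcept(onto, "mrna", "mature_transcript")
is_subconcept <- function(graph, a, b) {
  stopifnot(inherits(graph, "gexpo_ontology"))
  assert_concept(graph, a)
  assert_concept(graph, b)
  if (a == b) return(TRUE)
  frontier <- a
  seen <- character(0)
  while (length(frontier) > 0L) {
    seen <- union(seen, frontier)
    parents <- unique(unlist(lapply(frontier, isa_parents, graph = graph)))
    if (b %in% parents) return(TRUE)
    frontier <- setdiff(parents, seen)
  }
  FALSE
}

#' Test whether a typed relation holds between two concepts
#'
#' Checks for a declared edge `(a, relation, b)`. When `inherit = TRUE` and no
#' exact edge exists, the edge may instead be declared between any
#' sub-concepts of `a` and `b` along `is_a` (declared-edge inheritance); the
#' exact edge always takes precedence.
#'
#' @inheritParams is_subconcept
#' @param relation A token from [relation_vocabulary()].
#' @param inherit Permit matching declared edges of sub-concepts when the
#'   exact edge is absent (default `FALSE`).
#' @return Logical scalar.
#' @export
#' @examples
#' onto <- load_reference_ontology()
#' relation_holds(onto, "transcription", "part_of", "gene_expression")
relation_holds <- function(graph, a, relation, b, inherit = FALSE) {
  stopifnot(inherits(graph, "gexpo_ontology"))
  assert_concept(graph, a)
  assert_concept(graph, b)
  if (!relation %in% relation_vocabulary()) {
    stop("unknown relation token: '", relation, "' (see relation_vocabulary())",
         call. = FALSE)
  }
  e <- graph$edges[graph$edges$relation == relation, ]
  if (any(e$subject == a & e$object == b)) return(TRUE)
  if (!inherit) return(FALSE)
  any(e$subject %in% concepts_under(graph, a) &
        e$object %in% concepts_under(graph, b))
}

#' Export the ontology edge list
#'
#' Writes the graph's edges in the same plain-text format the loader reads:
#' one `subject<TAB>relation<TAB>object` line per edge, UTF-8, Unix newlines.
#'
#' @inheritParams is_subconcept
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ontology_edges <- function(graph, path) {
  stopifnot(inherits(graph, "gexpo_ontology"))
  readr::write_lines(
    sprintf("%s\t%s\t%s", graph$edges$subject, graph$edges$relation,
            graph$edges$object),
    path)
  invisible(path)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of an ontology graph
#'
#' @param x A `gexpo_ontology`.
#' @param ... Unused.
#' @return A one-row tibble with concept and edge counts.
#' @export
#' @method glance gexpo_ontology
glance.gexpo_ontology <- function(x, ...) {
  tibble::tibble(
    n_concepts = nrow(x$concepts),
    n_edges = nrow(x$edges),
    n_is_a = sum(x$edges$relation == "is_a"),
    n_relation_types = length(unique(x$edges$relation))
  )
}

#' Edges of an ontology graph as a tibble
#'
#' @param x A `gexpo_ontology`.
#' @param ... Unused.
#' @return Tibble with columns `subject`, `relation`, `object`.
#' @export
#' @method tidy gexpo_ontology
tidy.gexpo_ontology <- function(x, ...) {
  x$edges
}

`%||%` <- function(a, b) if (is.null(a)) b else a
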