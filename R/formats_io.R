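# Readers and writers for the concrete syntaxes the connectors touch:
# GEO-SOFT sample tables, a minimal mapped-read SAM subset, GFF gene
# features, tab-delimited matrices, platform ID mappings, HTself result
# tables, KEGG color lists and plain gene lists. All text IO is UTF-8;
# Unix or Windows line endings are accepted on read, Unix emitted on write.

read_text_lines <- function(path) {
  sub("\r$", "", readr::read_lines(path))
}

verbose_log <- function(...) {
  if (isTRUE(getOption("gexpoconnect.verbose", FALSE))) message(...)
}

# every reader attaches a tally satisfying read + skipped + errored = data lines
set_read_log <- function(x, read, skipped = 0L, errored = 0L) {
  attr(x, "read_log") <- tibble::tibble(
    rows_read = as.integer(read), rows_skipped = as.integer(skipped),
    rows_errored = as.integer(errored))
  verbose_log("read ", read, " rows (skipped ", skipped,
              ", errored ", errored, ")")
  x
}

#' Read-log of the last read
#'
#' Readers attach a one-row tally (`rows_read`, `rows_skipped`,
#' `rows_errored`) whose sum equals the physical data lines consumed.
#'
#' @param x An object returned by one of the package readers.
#' @return A one-row tibble, or `NULL` when `x` carries no log.
#' @export
read_log <- function(x) attr(x, "read_log")

#' Read a GEO-SOFT sample table
#'
#' Parses the sample-table block delimited by `!sample_table_begin` /
#' `!sample_table_end` sentinel lines (case-insensitive). All `!`, `^` and
#' `#` metadata lines outside the block are ignored; only the ID and VALUE
#' columns inside it are consumed, extra columns are ignored. Unparsable
#' value cells become missing with a warning; duplicate probe ids keep the
#' first occurrence with a warning.
#'
#' @param path Path to a SOFT-formatted text file.
#' @param sample_id Optional sample identifier; defaults to the file's
#'   `^SAMPLE = ...` line when present, else the file name sans extension.
#' @return A tibble with columns `id` (character) and `value` (double), rows
#'   in file order, with attributes `sample_id` and a [read_log()].
#' @export
read_soft_sample <- function(path, sample_id = NULL) {
  lines <- read_text_lines(path)
  begin <- grep("^!sample_table_begin\\s*$", lines, ignore.case = TRUE)
  end <- grep("^!sample_table_end\\s*$", lines, ignore.case = TRUE)
  if (length(begin) == 0L || length(end) == 0L || end[1L] <= begin[1L] + 1L) {
    stop("no sample table found in '", basename(path),
         "': expected !sample_table_begin/!sample_table_end sentinels",
         call. = FALSE)
  }
  if (is.null(sample_id)) {
    caret <- grep("^\\^SAMPLE\\s*=", lines, ignore.case = TRUE, value = TRUE)
    sample_id <- if (length(caret) > 0L) {
      stringr::str_trim(sub("^\\^SAMPLE\\s*=", "", caret[1L], ignore.case = TRUE))
    } else {
      sub("\\.[^.]*$", "", basename(path))
    }
  }
  block <- lines[(begin[1L] + 1L):(end[1L] - 1L)]
  header <- stringr::str_split_1(block[1L], "\t")
  id_col <- which(toupper(header) %in% c("ID_REF", "ID"))[1L]
  value_col <- which(toupper(header) == "VALUE")[1L]
  if (is.na(id_col) || is.na(value_col)) {
    stop("sample table header lacks ID/VALUE columns; found: ",
         paste(header, collapse = ", "), call. = FALSE)
  }
  data_lines <- block[-1L][nzchar(stringr::str_trim(block[-1L]))]
  if (length(data_lines) == 0L) {
    stop("sample table in '", basename(path), "' has no data rows",
         call. = FALSE)
  }
  fields <- stringr::str_split(data_lines, "\t")
  ids <- vapply(fields, function(f) if (length(f) >= id_col) f[[id_col]] else NA_character_, "")
  raw <- vapply(fields, function(f) if (length(f) >= value_col) f[[value_col]] else NA_character_, "")
  values <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & raw != "" & !toupper(raw) %in% c("NA", "NULL") &
                 is.na(values))
  if (length(bad) > 0L) {
    warning("unparsable VALUE cell(s) set to missing in '", basename(path),
            "': ", paste(utils::head(raw[bad], 3L), collapse = ", "),
            call. = FALSE)
  }
  out <- tibble::tibble(id = ids, value = values)
  dup <- duplicated(out$id)
  if (any(dup)) {
    warning("duplicate probe id(s) in '", basename(path),
            "', first occurrence kept: ",
            paste(unique(out$id[dup]), collapse = ", "), call. = FALSE)
    out <- out[!dup, ]
  }
  attr(out, "sample_id") <- sample_id
  set_read_log(out, read = nrow(out), skipped = sum(dup))
}

#' Reference span of a CIGAR string
#'
#' Number of reference bases consumed by a CIGAR: the sum of the lengths of
#' `M`, `D`, `N`, `=` and `X` operations. Insertions (`I`), soft/hard clips
#' (`S`, `H`) and padding (`P`) consume no reference.
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of reference-consumed lengths.
#' @export
#' @examples
#' cigar_reference_span("10M5N10M")  # 25
cigar_reference_span <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- stringr::str_match_all(cg, "(\\d+)([MIDNSHP=X])")[[1L]]
    if (nrow(ops) == 0L ||
        nchar(paste0(ops[, 1L], collapse = "")) != nchar(cg)) {
      stop("malformed CIGAR string: '", cg, "'", call. = FALSE)
    }
    consumes <- ops[, 3L] %in% c("M", "D", "N", "=", "X")
    sum(as.integer(ops[consumes, 2L]))
  }, integer(1L), USE.NAMES = FALSE)
}

#' Read mapped alignments from a SAM file
#'
#' Minimal SAM subset reader: `@`-prefixed header lines are skipped, records
#' with flag bit `0x4` (unmapped) are never emitted, and the aligned span is
#' derived from `pos` and the CIGAR as
#' `end = pos - 1 + cigar_reference_span(cigar)`. Only the six mandatory
#' leading columns are interpreted.
#'
#' @param path Path to a SAM text file.
#' @return A tibble with columns `qname`, `flag`, `rname`, `pos`, `cigar`,
#'   `strand` (`-` when flag bit `0x10` is set), `start`, `end`, one row per
#'   mapped alignment in file order, with a [read_log()].
#' @export
read_sam <- function(path) {
  lines <- read_text_lines(path)
  body_idx <- which(!startsWith(lines, "@") & nzchar(lines))
  fields <- stringr::str_split(lines[body_idx], "\t")
  short <- which(lengths(fields) < 6L)
  if (length(short) > 0L) {
    stop("SAM line ", body_idx[short[1L]], " has fewer than 6 mandatory ",
         "columns", call. = FALSE)
  }
  col <- function(i) vapply(fields, `[[`, "", i)
  flag <- suppressWarnings(as.integer(col(2L)))
  pos <- suppressWarnings(as.integer(col(4L)))
  if (anyNA(flag)) {
    stop("SAM line ", body_idx[which(is.na(flag))[1L]],
         ": non-numeric FLAG field", call. = FALSE)
  }
  if (anyNA(pos)) {
    stop("SAM line ", body_idx[which(is.na(pos))[1L]],
         ": non-numeric POS field", call. = FALSE)
  }
  mapped <- bitwAnd(flag, 4L) == 0L
  out <- tibble::tibble(
    qname = col(1L)[mapped],
    flag = flag[mapped],
    rname = col(3L)[mapped],
    pos = pos[mapped],
    cigar = col(6L)[mapped]
  )
  if (any(out$pos < 1L)) {
    stop("SAM record with POS < 1: '", out$qname[out$pos < 1L][1L], "'",
         call. = FALSE)
  }
  out$strand <- ifelse(bitwAnd(out$flag, 16L) > 0L, "-", "+")
  out$start <- out$pos
  out$end <- out$pos - 1L + cigar_reference_span(out$cigar)
  set_read_log(out, read = nrow(out), skipped = sum(!mapped))
}

extract_gff_attribute <- function(attrs, keys = c("ID", "locus_tag", "gene_id")) {
  out <- rep(NA_character_, length(attrs))
  for (key in keys) {
    # GFF3 `key=value` and GFF2 `key "value"` attribute styles
    pat <- paste0("(?:^|;)\\s*", key, "(?:=|\\s+)\"?([^;\"]+)\"?")
    hit <- stringr::str_match(attrs, pat)[, 2L]
    out[is.na(out)] <- stringr::str_trim(hit[is.na(out)])
  }
  out
}

#' Read gene features from a GFF file
#'
#' Keeps only features whose type is in `feature_types`; the gene identifier
#' is taken from the first present of the attribute keys `ID`, `locus_tag`,
#' `gene_id` (GFF2 and GFF3 attribute styles both accepted). Kept features
#' with no identifying attribute are skipped with a warning.
#'
#' @param path Path to a GFF text file.
#' @param feature_types Non-empty character vector of feature types to keep
#'   (default `"gene"`).
#' @return A tibble with columns `seqid`, `ftype`, `start`, `end`, `strand`,
#'   `gene_id`, with a [read_log()].
#' @export
read_gff_genes <- function(path, feature_types = "gene") {
  if (length(feature_types) == 0L) {
    stop("feature_types must be non-empty", call. = FALSE)
  }
  lines <- read_text_lines(path)
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  fields <- stringr::str_split(lines[body_idx], "\t")
  short <- which(lengths(fields) < 9L)
  if (length(short) > 0L) {
    stop("GFF line ", body_idx[short[1L]], " has fewer than 9 columns",
         call. = FALSE)
  }
  col <- function(i) vapply(fields, `[[`, "", i)
  ftype <- col(3L)
  keep <- ftype %in% feature_types
  start <- suppressWarnings(as.integer(col(4L)[keep]))
  end <- suppressWarnings(as.integer(col(5L)[keep]))
  if (anyNA(start) || anyNA(end)) {
    stop("GFF feature with non-numeric coordinates at line ",
         body_idx[keep][which(is.na(start) | is.na(end))[1L]], call. = FALSE)
  }
  inverted <- start > end
  if (any(inverted)) {
    stop("GFF feature with start > end at line ",
         body_idx[keep][which(inverted)[1L]], call. = FALSE)
  }
  gene_id <- extract_gff_attribute(col(9L)[keep])
  no_id <- is.na(gene_id) | gene_id == ""
  if (any(no_id)) {
    warning(sum(no_id), " GFF feature(s) skipped: no ID/locus_tag/gene_id ",
            "attribute", call. = FALSE)
  }
  out <- tibble::tibble(
    seqid = col(1L)[keep][!no_id],
    ftype = ftype[keep][!no_id],
    start = start[!no_id],
    end = end[!no_id],
    strand = col(7L)[keep][!no_id],
    gene_id = gene_id[!no_id]
  )
  set_read_log(out, read = nrow(out),
               skipped = sum(!keep) + sum(no_id))
}

#' Shortest round-trippable decimal rendering
#'
#' Renders doubles with the fewest significant digits that still parse back
#' to the identical double, so written matrices round-trip bit-faithfully.
#' `NA` renders as the token `NA`.
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @export
format_shortest <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "g", width = 1L)
      if (as.numeric(s) == v) return(s)
    }
    formatC(v, digits = 17L, format = "g", width = 1L)
  }, "", USE.NAMES = FALSE)
}

#' Construct a semantically tagged gene-by-condition matrix
#'
#' The package's tabular exchange container: a tibble whose first column
#' (`gene_id`) holds unique row identifiers, every other column one
#' experimental condition, carrying a reference-ontology concept id that says
#' what the cells mean (e.g. `ratio_intensity_based_value`).
#'
#' @param x A data frame whose first column is the row identifier.
#' @param concept_tag Reference-ontology concept id describing the cells.
#' @return A tibble of class `gexpo_matrix` with a `concept_tag` attribute.
#' @export
delimited_matrix <- function(x, concept_tag = NA_character_) {
  x <- tibble::as_tibble(x)
  if (ncol(x) < 1L) stop("matrix needs at least a row-id column", call. = FALSE)
  names(x)[1L] <- "gene_id"
  if (anyDuplicated(x$gene_id)) {
    stop("duplicate row id: '", x$gene_id[duplicated(x$gene_id)][1L], "'",
         call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    stop("duplicate column id: '", names(x)[duplicated(names(x))][1L], "'",
         call. = FALSE)
  }
  structure(x, concept_tag = concept_tag,
            class = c("gexpo_matrix", class(tibble::tibble())))
}

#' Concept tag of a tagged object
#'
#' @param x A tagged object (e.g. a `gexpo_matrix`).
#' @return The concept id, or `NA` when untagged.
#' @export
concept_tag <- function(x) attr(x, "concept_tag") %||% NA_character_

#' Write / read a tab-delimited matrix
#'
#' One header row of condition ids over a `gene_id` column, one data row per
#' gene, missing cells written as `NA`, finite values in the shortest
#' round-trippable decimal form so `read_matrix(write_matrix(m))` reproduces
#' ids and values exactly.
#'
#' @param m A [delimited_matrix()] (any data frame with the same shape works).
#' @param path Output (input) file path.
#' @param concept_tag Concept id to attach to the matrix read back.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()` a
#'   `gexpo_matrix`.
#' @export
write_matrix <- function(m, path) {
  header <- paste(names(m), collapse = "\t")
  cells <- vapply(seq_len(nrow(m)), function(i) {
    vals <- vapply(seq_along(m)[-1L], function(j) {
      v <- m[[j]][i]
      if (is.numeric(v)) format_shortest(v) else as.character(v)
    }, "")
    paste(c(m$gene_id[i], vals), collapse = "\t")
  }, "")
  readr::write_lines(c(header, cells), path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, concept_tag = NA_character_) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty matrix file", call. = FALSE)
  fields <- stringr::str_split(lines, "\t")
  width <- length(fields[[1L]])
  ragged <- which(lengths(fields) != width)
  if (length(ragged) > 0L) {
    stop("ragged matrix row at line ", ragged[1L], ": expected ", width,
         " fields, got ", length(fields[[ragged[1L]]]), call. = FALSE)
  }
  header <- fields[[1L]]
  body <- fields[-1L]
  out <- tibble::tibble(gene_id = vapply(body, `[[`, "", 1L))
  for (j in seq_len(width - 1L)) {
    raw <- vapply(body, `[[`, "", j + 1L)
    out[[header[j + 1L]]] <- suppressWarnings(
      ifelse(toupper(raw) == "NA", NA_real_, as.numeric(raw)))
  }
  set_read_log(delimited_matrix(out, concept_tag), read = nrow(out))
}

#' Write a KEGG Mapper Search&Color gene list
#'
#' One `gene_id<SPACE>color` line per entry, in input order; colors must be
#' drawn from the closed set red/green/yellow encoding up-, down- and
#' undefined regulation.
#'
#' @param entries Data frame with columns `gene_id` and `color`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kegg_colors <- function(entries, path) {
  bad <- setdiff(unique(entries$color), c("red", "green", "yellow"))
  if (length(bad) > 0L) {
    stop("invalid KEGG color '", bad[1L],
         "': must be one of red, green, yellow", call. = FALSE)
  }
  readr::write_lines(
    if (nrow(entries) == 0L) character(0)
    else sprintf("%s %s", entries$gene_id, entries$color),
    path)
  invisible(path)
}

#' Read a platform gene-identifier mapping
#'
#' Accepts either a plain TSV or a SOFT-wrapped platform table (rows between
#' `!platform_table_begin`/`!platform_table_end`, first row a header). Two
#' columns mean the KEGG identifier corresponds directly to the official gene
#' identifier; three columns give experiment-specific, official and KEGG
#' identifiers. Duplicate experiment-specific ids keep the first occurrence;
#' a conflicting duplicate additionally warns.
#'
#' @param path Path to the mapping file.
#' @return A tibble with columns `experiment_id`, `official_id`, `kegg_id`
#'   (`NA` when a gene has no KEGG identifier), with a [read_log()].
#' @export
read_platform_mapping <- function(path) {
  lines <- read_text_lines(path)
  begin <- grep("^!platform_table_begin\\s*$", lines, ignore.case = TRUE)
  end <- grep("^!platform_table_end\\s*$", lines, ignore.case = TRUE)
  if (length(begin) > 0L && length(end) > 0L && end[1L] > begin[1L] + 1L) {
    lines <- lines[(begin[1L] + 2L):(end[1L] - 1L)]  # +2 skips the header row
  } else {
    lines <- lines[!grepl("^\\s*(#|!|\\^|$)", lines)]
  }
  if (length(lines) == 0L) stop("empty platform mapping", call. = FALSE)
  fields <- stringr::str_split(lines, "\t")
  n <- lengths(fields)
  if (any(n < 2L)) {
    stop("platform mapping row ", which(n < 2L)[1L],
         " has fewer than 2 columns", call. = FALSE)
  }
  blank_to_na <- function(x) ifelse(nzchar(stringr::str_trim(x)), x, NA_character_)
  experiment <- vapply(fields, `[[`, "", 1L)
  second <- blank_to_na(vapply(fields, `[[`, "", 2L))
  third <- blank_to_na(vapply(fields, function(f) {
    if (length(f) >= 3L) f[[3L]] else NA_character_
  }, ""))
  out <- tibble::tibble(
    experiment_id = experiment,
    official_id = ifelse(is.na(third), second, second),
    kegg_id = ifelse(is.na(third), second, third)
  )
  dup <- duplicated(out$experiment_id)
  if (any(dup)) {
    conflicting <- vapply(unique(out$experiment_id[dup]), function(id) {
      rows <- out[out$experiment_id == id, ]
      nrow(dplyr::distinct(rows)) > 1L
    }, logical(1L))
    if (any(conflicting)) {
      warning("duplicate experiment id(s) with conflicting targets, first ",
              "occurrence kept: ",
              paste(names(conflicting)[conflicting], collapse = ", "),
              call. = FALSE)
    }
    out <- out[!dup, ]
  }
  if (nrow(out) == 0L) stop("empty platform mapping", call. = FALSE)
  set_read_log(out, read = nrow(out), skipped = sum(dup))
}

#' Read an HTself result table
#'
#' A tab-delimited table of one row per gene with the HTself statistic and
#' its associated p-value; an optional header row is detected and skipped.
#'
#' @param path Path to the result file.
#' @return A tibble with columns `gene_id`, `htself_value`, `p_value`, with
#'   a [read_log()].
#' @export
read_htself <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("empty HTself table", call. = FALSE)
  fields <- stringr::str_split(lines, "\t")
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop("HTself row ", short[1L], " has fewer than 3 columns", call. = FALSE)
  }
  header <- is.na(suppressWarnings(as.numeric(fields[[1L]][[2L]])))
  if (header) fields <- fields[-1L]
  out <- tibble::tibble(
    gene_id = vapply(fields, `[[`, "", 1L),
    htself_value = as.numeric(vapply(fields, `[[`, "", 2L)),
    p_value = as.numeric(vapply(fields, `[[`, "", 3L))
  )
  if (anyNA(out$htself_value) || anyNA(out$p_value)) {
    stop("non-numeric HTself/p-value cell", call. = FALSE)
  }
  if (any(out$p_value < 0 | out$p_value > 1)) {
    stop("p-value outside [0, 1] for gene '",
         out$gene_id[out$p_value < 0 | out$p_value > 1][1L], "'",
         call. = FALSE)
  }
  set_read_log(out, read = nrow(out), skipped = as.integer(header))
}

#' Write / read a plain gene list
#'
#' One gene identifier per line, order preserved.
#'
#' @param genes Character vector of gene identifiers.
#' @param path File path.
#' @return `write_gene_list()` returns `path` invisibly; `read_gene_list()`
#'   a character vector.
#' @export
write_gene_list <- function(genes, path) {
  readr::write_lines(as.character(genes), path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  lines <- read_text_lines(path)
  lines[nzchar(lines)]
}
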