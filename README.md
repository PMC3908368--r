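# gexpoconnect

Semantic software connectors for moving bulk gene-expression data between
analysis tools.

## The problem

Gene-expression studies chain together tools that were never designed to
talk to each other: GEO supplies two-color microarray samples as SOFT
files, aligners emit SAM, genome annotations come as GFF, a normalization
environment wants one multi-column table, a pathway painter wants a gene
list with colors, and a statistics package for two-color arrays cannot read
one-color data at all. Gluing these together is usually done with throwaway
scripts whose semantics live in nobody's head but the author's.

`gexpoconnect` makes that glue explicit and checkable. It bundles:

* **A reference gene-expression ontology** — a small typed concept graph
  covering the expression process (transcription → RNA processing →
  translation → protein maturation), the measurement processes (one-/two-
  color microarray, RNA-Seq) and the expression-value hierarchy
  (*absolute/ratio intensity-based value*, *absolute/relative cDNA reads
  counting-based value*), queryable for subsumption (`is_subconcept()`) and
  typed relations (`relation_holds()`).
* **A connector engine** — every connector runs four functional blocks
  strictly in order: *data input processing* → *lifting* (concrete syntax to
  concept-tagged canonical instances) → *lowering* (canonical instances to
  output form) → *data output processing*. Each connector ships a declarative
  **equivalence table** linking consumed-data concepts, reference-ontology
  concepts and produced-data concepts; `validate_equivalence_table()`
  machine-checks these against the ontology, including the three
  partial-mapping cases (unused inputs, many-to-one rules, derived outputs).
* **Six concrete connectors**:
  | id | transformation |
  |----|----------------|
  | C1 | per-condition two-color SOFT files → one multi-column log-ratio matrix |
  | C2 | differential-expression matrix → KEGG Mapper color list (red/green/yellow = up/down/undefined at threshold *t*: value ≥ *t*, ≤ −*t*, otherwise) |
  | C3 | composite C3.1→C3.2→C3.3: SAM reads annotated to GFF genes (largest-overlap, lexicographic ties), per-condition library sizes, gene × condition counts |
  | C4 | counts ÷ library size → relative values (columns sum to 1) |
  | C5 | composite C5.1→C5.2: one-color intensities → virtual two-color log2 ratios (within-category self-self pairs, then cross-category pairs) |
  | C6 | HTself statistic/p-value table → filtered gene list (statistic ≥ and p ≤ thresholds) |
* **Deterministic synthetic-data generators** (`gen_*`) that emit each input
  shape with planted ground truth, so every transformation is testable
  offline and byte-reproducibly.

All user-facing functions take data frames and return tibbles; fitted-run
summaries come via `tidy()`/`glance()`, and `autoplot()` draws matrices and
run reports.

## Worked example: scenario 1 (two-color microarray → KEGG colors)

```r
library(gexpoconnect)

# three steps: generate per-condition SOFT files, merge them (C1),
# classify and color one condition (C2)
b <- gen_two_color_soft(6, 2, seed = 42, omit_fraction = 0.2)
m <- c1_merge(lapply(b$files, read_soft_sample), names(b$files))
m
#> # A tibble: 6 × 3
#>   gene_id  cond1   cond2
#> 1 g001     1.37  -0.0947
#> 2 g002    -0.565  2.02
#> 3 g003     0.363 -0.0627
#> 4 g005     0.404 NA
#> 5 g006    -0.106 -1.39
#> 6 g004    NA      1.30
```

The merged matrix has one column per input file; genes missing from a file
are NA-padded (union policy) and present values are carried bit-exactly.
`g005` was omitted from the `cond2` file by the generator, so its cell is
missing.

```r
mp <- gen_platform_mapping_fixture(m$gene_id, 0.8, seed = 42)
mapping <- read_platform_mapping(mp$files[["mapping"]])
res <- c2_run(m, "cond1", threshold = 1.0, mapping)
res$entries
#> # A tibble: 4 × 2
#>   gene_id    color
#> 1 PVX_000100 red
#> 2 PVX_000200 yellow
#> 3 PVX_000300 yellow
#> 4 PVX_000400 yellow
glance(res$report)
#>   connector records_in records_out records_dropped n_warnings n_children
#> 1 C2                 6           4               2          0          0
```

Only `g001` has |log2 ratio| ≥ 1.0 in `cond1` (1.37 → red = upregulated);
mapped genes inside the threshold band are yellow (undefined). Of 6 genes,
2 were dropped with tallied reasons: one missing value in `cond1`, one probe
without a KEGG identifier — so 4 = 6 − 2 entries are emitted, ready for the
KEGG Mapper Search&Color Pathway form.

A command-line wrapper with the same capabilities ships in
`inst/scripts/gexpo-connect.R` (`list`, `validate`, `run C1..C6`,
`simdata`).

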