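---
title: "Ontology-grounded connectors for gene-expression data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-grounded connectors for gene-expression data: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gexpoconnect)
```

## The integration model

`gexpoconnect` treats every data handoff between two gene-expression tools
as a *connector*: a unit that consumes files in one concrete syntax and
produces files in another, with its semantics made explicit rather than
implicit. Three ideas carry the design:

1. **A reference ontology as the shared vocabulary.** The bundled concept
   graph names the things connectors move around — genes, experimental
   conditions, and the expression-value hierarchy in which *ratio
   intensity-based value* (two-color arrays) and *absolute intensity-based
   value* (one-color arrays) specialize *fluorescence intensity-based
   value*, while *absolute* and *relative cDNA reads counting-based value*
   specialize the RNA-Seq counting branch. Subsumption queries
   (`is_subconcept()`) and typed relation queries (`relation_holds()`)
   back the validation machinery.

2. **Equivalence tables as machine-checked design artifacts.** Each
   connector declares, in a shipped TSV, how its consumed-data concepts and
   produced-data concepts line up with reference concepts, and which
   transformation rule bridges them when the mapping is not one-to-one.
   Three partial-mapping situations are modelled: an input consumed but
   unused (no reference concept required), several inputs combining into
   one output, and an output derived from inputs — the latter two require a
   named rule. `validate_equivalence_table()` turns these conventions into
   checks that run at test time, so the documentation of what a connector
   *means* cannot silently rot.

3. **Four serial functional blocks.** Execution is always *data input
   processing* → *lifting* → *lowering* → *data output processing*. The
   engine enforces the order, verifies after lifting that every canonical
   instance carries a concept tag resolving in the ontology, and withdraws
   the raw representation before lowering so the lowering block can only
   consume canonical instances. Composite connectors (C3 = C3.1→C3.2→C3.3,
   C5 = C5.1→C5.2) are ordered plans of simple connectors whose wiring is
   validated before anything runs; their combined run report keeps one
   section per child, because children count different record kinds (reads
   versus genes) that must not be summed.

Access to the downstream tool is part of the connector contract: `manual`
transfer leaves written files for the user; `automatic` transfer fires a
post-output hook — but only after data output processing has completed, and
a hook failure is downgraded to a warning with outputs retained, since the
data products are already valid at that point. The package ships a no-op
hook and a shell-command hook; hooks are an interface, so site-specific
transports (e.g. a TCP bridge into a running R session) can be plugged in
without touching connector internals.

## The ontology registry

Concept ids are normalized labels (lowercase, spaces/hyphens →
underscores), which makes equivalence tables stable under label editing.
The relation vocabulary is closed: `is_a`, `part_of`/`has_part`,
`preceded_by`, `produced_by`, `has_participant`, `affected_by`,
`quantifies`, `derives_from`. Loading validates acyclicity of `is_a` and
reachability of every concept from the root `thing`; concepts with no
declared parent are attached to the root explicitly in the edge list.

Two deliberate choices:

* **`preceded_by` is non-transitive.** It records the declared ordering of
  adjacent subprocess pairs only; deriving longer chains is left to the
  caller. Nothing in the connectors needs transitive precedence, and
  declaring it would assert more than the source material states.
* **The alternative between read alignment and de-novo assembly** upstream
  of RNA-Seq profiling is encoded as two ordinary `preceded_by` edges plus
  a comment in the edge list, since the edge format has no notation for an
  exclusive choice. Consumers that care must treat those two edges as
  alternatives.

`relation_holds()` checks declared edges exactly by default; an optional
`inherit` flag lets an edge declared on sub-concepts satisfy a query on
their ancestors, which is useful for questions like "is a fluorescence
value produced by some microarray process?" without polluting the graph
with derived edges.

## The six connectors and their numerical conventions

**C1 (merge two-color samples).** The merged matrix takes the *union* of
gene ids across files (first-appearance order) with `NA` fill; an
`intersection` policy is available. Union is the default because dropping
genes before normalization loses data irrecoverably, whereas downstream
tools handle `NA`. Values are carried bit-exactly; duplicate probe ids
within one file keep the first occurrence with a warning (determinism over
guesswork).

**C2 (threshold classification and KEGG coloring).** Classification
operates on log2 ratios with a symmetric threshold *t* > 0 and *closed*
boundaries: up iff value ≥ *t*, down iff value ≤ −*t*, undefined otherwise.
Closed boundaries make the degenerate limit well-behaved and are pinned by
tests that enumerate both conventions. Two-color SOFT VALUE columns are
conventionally log ratios, so `log2` is the default scale; a `linear` mode
classifies on `log2(value)` for inputs stored as raw quotients. Colors
follow the KEGG Mapper Search&Color scheme: red/green/yellow for
up/down/undefined. Genes with missing values or no KEGG mapping are never
errors: they are dropped with per-reason tallies in the run report, and the
emitted set always partitions into exactly one color per gene.

**C3 (reads → counts).** A read is assigned to a gene when their intervals
overlap by at least one base on the same reference sequence; among several
candidates the largest overlap wins, and an exact tie goes to the
lexicographically smallest gene id. The rule is deliberately simple enough
to be oracle-checkable: the test suite replays randomized instances
(≤ 200 reads × ≤ 20 genes, 100 trials) against a brute-force all-pairs
scan, ties included. Strand is ignored by default (`stranded = TRUE`
available) since early single-end protocols are strand-ambiguous;
multi-mapped records each count independently; each read contributes to at
most one gene. Aligned spans come from POS plus the reference-consuming
CIGAR operations (M, D, N, =, X) — insertions and clips consume nothing —
and unmapped records (flag bit 0x4) are filtered at the reader.

The per-condition total (C3.2) is the number of **annotated reads**, i.e.
the library size that normalization needs. The literal alternative — the
number of *distinct* annotated genes — would not correct for sequencing
depth; because the wording is genuinely ambiguous, both are implemented
(`total = "reads"` default, `"distinct-genes"` on request) rather than
choosing silently. Count rows (C3.3) are sorted lexicographically so output
files are diff-stable.

**C4 (library-size normalization).** Each count is divided by its
condition's total; when totals are the column sums every output column sums
to 1, asserted in tests to 1e-12 (double-precision accumulation over
desk-scale columns stays well inside this). Zero totals are rejected by
name rather than producing NaN columns.

**C5 (virtual two-color construction).** "All pairwise comparisons" within
a category is read as unordered pairs excluding self-pairs: a self-self
ratio of a sample against itself is identically zero and a reversed
duplicate adds only a sign flip, so `choose(n, 2)` columns per category.
Cross-category pairs are ordered — numerator category named first — giving
`n_a × n_b` columns; only one orientation is emitted, surfaced as a CLI
choice, since the reverse orientation is the negation of the same
information. Ratios are `log2(I_num / I_den)` because the downstream
differential-expression statistic operates on log ratios (a `linear` scale
flag emits raw quotients). Missing or non-positive intensities — common in
background-subtracted one-color data — yield a missing cell with a tallied
count, never an error.

**C6 (significance filter).** Keeps genes with statistic ≥ and p-value ≤
their thresholds, preserving input order. Boundaries are non-strict by
default ("at least as extreme as the cutoff passes"), with a strict mode;
the monotonicity property (tightening either threshold never adds a gene)
is test-pinned.

## What the synthetic data emulates — and what it does not

The generators produce files in exactly the dialects the package readers
parse, because the parsers are part of the tested surface; they are
seed-deterministic to the byte, so fixtures regenerate identically anywhere.

* `gen_two_color_soft()`: zero-centred Gaussian log2 ratios (sd 1 by
  default, the conventional scale of normalized two-color data), with a
  configurable fraction of cells omitted per condition to exercise `NA`
  merging.
* `gen_rnaseq_fixture()`: a single-chromosome, prokaryote-like layout of
  non-overlapping 100-base genes separated by 50-base gaps, 36-base reads
  placed uniformly and wholly inside their planted gene, plus wholly
  intergenic reads that the annotation step must remove. Geometry is
  validated (genes and gaps must fit a read) so planted counts are exactly
  recoverable.
* `gen_one_color_fixture()`: log-normal positive intensities around shared
  per-gene baselines (meanlog 7, sdlog 0.4 — intensities in the thousands,
  as scanners report), in named biological categories.
* `gen_htself_fixture()`: planted significant genes pass both thresholds
  with margin; every other gene fails at least one, so exact set recovery
  is the correct answer, not a lucky one.

Deliberately absent: sequencing errors and quality strings, dye bias,
spatial artifacts, overlapping gene models, paired-end structure, and any
real normalization noise. Passing tests therefore demonstrate that the
*transformations* are correct and conserving — not that the statistical
pipeline downstream would behave well on real data. The generators' default
scales are tiny (≤ 50 genes, ≤ 5 conditions, ≤ 500 reads) to keep the full
suite fast; the acceptance checks run 20-seed sweeps for conservation and
recovery and 100 randomized trials for the overlap oracle at those scales.

## Degenerate inputs and failure behavior

Readers report a conservation log (rows read + skipped + errored = physical
data lines) on every read. Malformed structure — missing SOFT sentinels,
short SAM records, inverted GFF intervals, ragged matrix rows — fails fast
with the offending line named. Content-level oddities — unparsable value
cells, probes without mapping entries, features without identifying
attributes — degrade to missing values or skips with warnings and tallies,
because desk-scale curation data is full of them and a connector that dies
on the first oddity never finishes. Matrix numerics are written in the
shortest decimal form that round-trips to the identical double, so
write→read is bit-faithful without bloating files.

## Known limitations

* The ontology is a compact transcription sufficient for the bundled
  connectors, not a complete OWL artifact: no description-logic reasoning,
  no GO/SO accession cross-references, and the serial-analysis (SAGE)
  branch is out of scope.
* Composite execution is strictly serial by design; children that could run
  concurrently (C3.2/C3.3) do not.
* Bidirectional integrations are not built in; they compose from two
  unidirectional runs.
* The statistical steps the connectors feed — normalization,
  differential-expression testing, clustering, pathway analysis — are the
  wrapped tools' job and are intentionally not reimplemented here.
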