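---
title: "Annotating genomic regions: overlap taxonomy, neighbors and anchored distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating genomic regions: overlap taxonomy, neighbors and anchored distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granno)
```

## The problem

Nearly every genomic experiment — ChIP-seq peak calling, DNase-seq, RRBS
methylation profiling, small-RNA quantification, variant calling, in-silico
motif screens — ends with a set of genomic intervals that must be related to
known features: transcripts, promoters, CpG islands, or any user-supplied
track. `granno` answers the two questions asked first in such analyses:

* **Overlap**: which annotations share at least one position with each
  query region?
* **Neighborhood**: when nothing overlaps on a given side, which annotation
  is nearest — and, for stranded features, how far away is a chosen anchor
  such as the transcription start site (TSS)?

## Coordinate model

Internally every region is a 0-based, half-open interval `[start, end)` on a
case-insensitively matched chromosome label — the native BED convention, which
makes results directly comparable with standard interval toolkits. Query input
may instead use the 1-based inclusive *position coordinates* familiar from
genome browsers (`chr1:7577506-7577606`); the parser is deliberately tolerant
(case-insensitive chromosome, optional thousands separators, colon/minus or
whitespace field separators, so regions can be pasted straight from a
spreadsheet), and `normalize_region()` shifts the printed start down by one to
reach the internal convention.

A region with `start == end` is a **zero-length element**: an insertion point
rather than a stretch of sequence. Two display subtleties follow from
supporting them:

* A zero-length element renders in positions form on its raw half-open bounds
  (`chr1:5-5`); shifting it would produce an end before the start.
* This makes the positions display of a *single 1-bp base* (`chrN:p-p` in
  1-based terms) indistinguishable from a zero-length point. The package
  resolves the collision in favor of zero-length elements: `p-p` in positions
  input is read as an insertion point and passes through normalization
  unchanged. A single base can always be expressed unambiguously in BED form
  (`chrN <TAB> p-1 <TAB> p`). The synthetic-region generator's default length
  floor is 2 bp for the same reason, so that formatting and re-parsing any
  generated set is the identity.

## The 16 overlap configurations

Any two positions are related in exactly one of three ways — smaller, equal,
larger. Comparing the query's start and end with the annotation's start and
end gives four such relations, and the realizable combinations define the
complete taxonomy of overlap configurations. Under the package's overlap
convention —

* proper intervals overlap iff their half-open intersection is non-empty
  (abutting intervals do **not** overlap),
* a zero-length element at `p` overlaps a proper `[s, e)` iff `s <= p <= e`
  (boundary contact counts),
* two zero-length elements overlap iff they coincide

— exhaustive enumeration of all start/end placements on a small grid yields
exactly **16** distinct classes, stable for every grid with at least 5
positions:

```{r}
tab <- overlap_classes()
tab[, c("class_id", "pattern", "q_is_point", "a_is_point", "label")]
```

The canonical numbering is the package's own: classes 1–9 are the
proper-proper configurations (the interval-algebra relations that share at
least one position under the half-open convention: overlaps, finished-by,
contains, starts, equals, started-by, during, finishes, overlapped-by),
10–12 involve a zero-length query, 13–15 a zero-length annotation, and 16 is
two coincident points; within each group patterns are ordered
lexicographically with less < equal < greater. This convention is the unique
natural one reproducing the 16-class total; choosing boundary-*exclusive*
point containment, for instance, would lose the boundary classes, while
letting abutting intervals overlap would add meets/met-by classes and
overshoot the total. Each class carries an ASCII sketch:

```{r}
cat(tab$diagram[tab$label == "contains"], "\n")
cat(tab$diagram[tab$q_is_point & grepl("start", tab$label)], "\n")
```

`enumerate_overlap_classes()` re-derives the table by brute force at run time
and is the package's own correctness check on the classifier.

## Neighbor definition

A **neighbor** is the closest annotation that does *not* overlap the query —
closest in the sense that no other annotation lies between it and the query,
not in physical distance to an arbitrary part of the annotation. Concretely:

* the **left** neighbor maximizes the annotation end subject to
  `end <= query start` (ties: maximal start, then smallest name;
  among fully identical duplicates, the earliest input record);
* the **right** neighbor minimizes the annotation start subject to
  `start >= query end` (ties: minimal end, then name).

The max-end/min-start formulation is the only one under which the distance
conventions — left distance = query start − annotation end, right distance =
annotation start − query end — are always non-negative. Two consequences of
the overlap convention propagate here deliberately: an *abutting proper*
annotation is a neighbor at distance 0, while a *zero-length* annotation
sitting exactly on a query boundary overlaps the query and is therefore never
its neighbor. One neighbor is reported per side; ties are broken
deterministically as above rather than reported as sets.

## The sweep engine

`build_index()` partitions an annotation source by chromosome and sorts each
partition by `(start, end, name)`. Overlap queries then process the queries
of each chromosome in ascending start order while a memoized cursor advances
monotonically past the front of the annotation list. The cursor's safety
condition matters with long annotations: it may pass an annotation only when
that annotation's end precedes the current query's start — and therefore every
future query's start — so a long feature spanning many queries is never
skipped. Candidates between the cursor and the start-order break
(`annotation start <= query end`) are scanned and filtered through the exact
overlap predicate, which preserves strict equivalence with the all-pairs
brute-force evaluation while visiting each annotation a bounded number of
times. Neighbor queries use the same sorted partition plus a per-chromosome
end-sorted view, located by binary search per query; only boundary cases
(candidates that turn out to overlap, which can only happen at coordinate
equality with zero-length elements involved) trigger a short linear fix-up.

Query order is restored on output, so duplicated query lines — e.g.
alternative transcripts with identical coordinates — annotate independently
and keep the output table row-compatible with the input.

## Anchored distances

Distance annotation (the third use case) requires stranded annotations
because the biologically interesting anchors are strand-dependent: the 5'
end of a feature is its start on the plus strand and its end on the minus
strand, and vice versa for the 3' end. Available anchors are `five_prime`,
`three_prime`, `start`, `end`, `center` on the annotation and `start`,
`end`, `center` on the query. Numerical choices, fixed so results are
bit-reproducible:

* anchors use the half-open bounds directly (no last-base adjustment);
* `center` is the floor of the mean of the bounds and is strand-independent;
* the reported distance is **signed**: annotation anchor minus query anchor
  on the reference strand, positive when the annotation anchor lies at the
  larger coordinate. A signed distance preserves orientation information
  that common TSS-distance analyses rely on; callers wanting magnitudes can
  take the absolute value.
* distances are reported to **both** the left and the right neighbor, so no
  information is discarded; downstream filtering can keep the nearer one.

## Promoters

`make_promoters()` builds promoter windows as the region from 1 kb upstream
to 1 kb downstream of the TSS (start on `+`, end on `-`), clamped at
coordinate 0, inheriting the transcript name. The half-width is a parameter
(bases, default 1000). Chromosome-end clamping is not applied because
chromosome lengths are not an input of the package.

## Synthetic fixtures and what the tests show

`generate_regions()` draws uniform starts on a configurable number of
chromosomes, uniform lengths (default 2–1000 bp, in the range of typical
peaks and exons), and an exact fraction of zero-length elements (default 5%,
emulating insertion-point records in variation data); fixtures are
deterministic under a seed, and generation leaves the caller's RNG state
untouched. The brute-force oracles `oracle_overlaps()`/`oracle_neighbors()`
re-state the overlap predicate and the neighbor rule independently of the
engine code, so a predicate bug cannot validate itself; every engine result
in the test suite is compared against them exactly, on fixture sets spanning
10 to 100,000 queries against 1 or 10 annotation sources (annotation-set
sizes 10–500 per source at the largest sweeps, chosen so the quadratic
all-pairs oracle itself remains fast), with duplicated, nested, abutting and
zero-length regions forced into every set.

What passing these tests does *not* show about real data: fixtures have
uniform coverage and no chromosome-length bounds checking, no aliasing
between `"1"` and `"chr1"` (the package deliberately treats them as distinct
labels, as no aliasing rule is universally safe), and no malformed-file
stress beyond the error cases tested. Wall-clock comparisons with other
toolkits are hardware-dependent and are not asserted; the suite only checks
that engine time grows subquadratically across a 10³–10⁵ query sweep against
10⁵ annotations.

## Output contract

The output is a tab-delimited table, one row per query in input order
(duplicates preserved), with the 1-based display form of the region, an
optional UCSC browser hyperlink (`db=<assembly>&position=<region>`), and one
column (or neighbor column group) per annotation source. Multiple hits in a
cell are joined with the literal separator `"//"`; annotation names
containing `"//"` are rejected at ingest so cells re-parse unambiguously. A
header line is written by default and can be suppressed for piping. The
interactive result-filtering of a GUI is deliberately out of scope: the
table is designed to be filtered with standard tools (`grep`, spreadsheet
filters, `awk -F'\t'`).

## Known limitations

* No liftover, no validation against chromosome lengths, no GFF/GTF/VCF
  ingestion — inputs are BED-like delimited text and position strings.
* One neighbor per side; k-nearest queries are not provided.
* The positions display cannot express a 1-bp region distinctly from an
  insertion point (see above); BED form is exact for both.
* Registry files map `(release, genome, annotation)` to local files; no
  download machinery is included.
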