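# granno — overlap and neighbor annotation of genomic regions

`granno` annotates sets of genomic query regions — ChIP-seq peaks, DNase
hypersensitive sites, methylation windows, variant positions, motif matches —
with **overlapping** and **neighboring** features from one or more annotation
sources, and computes strand-aware **anchored distances** (e.g. to the nearest
transcription start site). It is a library plus a thin command-line tool,
aimed at the tabular-annotation step that sits between peak calling and
biological interpretation.

## The model

All intervals are 0-based half-open `[start, end)` (BED native); `start == end`
denotes a zero-length element (an insertion point). Comparing the query's
start/end with an annotation's start/end under the three-way position relation
(<, =, >) yields a complete taxonomy of **16** overlap configurations —
9 between proper intervals, 3 with a zero-length query, 3 with a zero-length
annotation, 1 with two coincident points — under the convention:

* proper intervals overlap iff `q.start < a.end && a.start < q.end`
  (abutting intervals do not overlap);
* a zero-length element at `p` overlaps `[s, e)` iff `s <= p <= e`;
* two zero-length elements overlap iff they coincide.

A **neighbor** is the closest non-overlapping annotation on one side:
left = max end with `end <= q.start`, right = min start with
`start >= q.end`, with distances `q.start - a.end` and `a.start - q.end`.
Anchored distances are signed (annotation anchor − query anchor on the
reference strand) with anchors `5'`, `3'`, `start`, `end`, `center`; the 5'
end is the start on `+` and the end on `-`.

Annotation sources are indexed per chromosome, sorted by `(start, end, name)`,
and queried with a start-sorted sweep and memoized cursors; results are
provably identical to all-pairs brute force (the test suite checks exactly
that, against independent oracles).

## Worked example

Queries (`queries.txt`, position coordinates; thousands separators and case
are tolerated, and duplicated lines annotate independently):

```
chr17:7,577,506-7,577,606
chr17:7590000-7590200
```

Annotations (`genes.bed`, standard BED):

```
chr17	7571719	7590868	TP53	0	-
chr17	7589388	7606820	WRAP53	0	+
chr17	7610000	7615000	EFNB3	0	+
```

```sh
exec/annotate-regions custom --queries queries.txt --files genes.bed \
    --genome hg19 --neighbors --out overlaps.tsv
```

`overlaps.tsv` (link column abbreviated):

```
region                 link   genes.bed     genes.bed.left  genes.bed.left_dist  genes.bed.right  genes.bed.right_dist
chr17:7577506-7577606  ...    TP53                                               WRAP53           11782
chr17:7590000-7590200  ...    TP53//WRAP53                                       EFNB3            19800
```

Row 1 overlaps only `TP53`; its left side has no non-overlapping gene, and the
nearest non-overlapping gene to the right is `WRAP53`, 11,782 bases from the
query end to the gene start. Row 2 falls in the TP53/WRAP53 overlap zone, so
both names appear joined by `//`.

Distance to the nearest TSS (stranded 5-column annotations, 5' anchor vs
query start):

```sh
exec/annotate-regions distance --queries q2.txt --file tss.txt \
    --annotation-anchor five_prime --query-anchor start --out dist.tsv
```

```
region                 tss.txt.left  tss.txt.left_distance  tss.txt.right  tss.txt.right_distance
chr17:7591000-7591500  TP53          -131                   EFNB3          19001
```

`TP53` is on the minus strand, so its 5' end is its *end* coordinate
(7,590,868); the signed distance −131 means that TSS lies 131 bases upstream
(smaller coordinate) of the query start. The same operations are available as
R functions (`read_queries()`, `build_index()`, `find_overlaps()`,
`find_neighbors()`, `distance_annotate()`, `make_promoters()`,
`overlap_classes()`, ...); see the vignette in `vignettes/` for the full
account of the conventions and design choices.

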