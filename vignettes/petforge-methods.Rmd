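---
title: "petforge: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{petforge: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the statistical models, the tunable parameters with their defaults and
why, what the synthetic-data generator does and does not emulate, and the
design choices made where the design was genuinely open.  It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The mate-pair model

A DNA-PET library sequences short terminal tags of size-selected genomic
fragments.  Writing `mu` and `sigma` for the insert-length mean and sd,
a correctly mapped pair on an error-free assembly shows (i) both tags on
one reference, (ii) mate-pair orientation (both tags on the same strand,
the fragment's 5' tag upstream on `+`, downstream on `-`), and (iii) a
genome span — 5'-most tag start to 3'-most tag end — inside the
library's concordant range.  `classify_pairs()` applies exactly these
three conditions; everything else is discordant, split into same- and
different-reference classes.  The three classes partition the input by
construction, which the tests re-check.

Span ranges are library properties.  The two profiles used throughout
the tests (9.6 kb library: 5,997–11,961 bp; 17.5 kb library:
9,318–22,026 bp) reproduce the concordance windows of a real large-insert
experiment of this design; users supply their own via
`library_profile()`.

Tag "position" for all span arithmetic is the 5'-most mapped base on the
reference strand.  Duplicate pairs (identical coordinates on both tags)
are collapsed before every statistic, so counts refer to independent,
non-redundant PETs.

## 2. Gap length re-estimation

Draft assemblies carry N-runs whose annotated length is often a
placeholder (a fixed 50 bp is typical).  A cPET whose fragment spans
exactly one gap measures it: if the gap's true length exceeds its
annotated length, the observed scaffold-coordinate span shrinks by the
difference, so

    estimate = annotated_len + (mu_measured - observed_span).

Each spanning PET contributes one estimate; the per-gap mean and median
are reported, with `min_support = 5` PETs required.  Negative estimates
are reported as-is and flagged (the minimal region is genuinely shorter
than annotated — structural polymorphism between the sequenced
individuals and the reference), never clamped: clamping would destroy
the evidence.

Two numerical points matter in practice:

* **The expected-span reference is re-measured, not nominal.**
  `estimate_insert_size()` takes the 5%-trimmed mean of cPET spans, and
  the pipeline restricts it to cPETs spanning *no* gap
  (`gap_free_cpets()`): spans across mis-annotated gaps carry the gap
  error and would bias `mu_measured`, hence every estimate.  The trimmed
  sd is corrected for truncation (division by ~0.79 at 5% trim under
  normality) so it estimates the full insert sd.
* **Bimodality is tested with known variance.**  Each per-PET estimate
  carries exactly the insert-length noise `sigma`, which is measured
  library-wide with thousands of pairs.  The 1- vs 2-component Gaussian
  mixture EM therefore fixes the component sd at the measured `sigma`
  and estimates only means and weights.  With the typical 10–30
  supporting PETs per gap, a free-variance mixture is unusable: BIC
  under free variances needs a likelihood gain on the scale of `sigma`,
  while the real question — are there two allele-length means? — lives
  on the standard-error scale `sigma/sqrt(n)`.  A gap is reported
  bimodal when the 2-component fit wins by BIC, the means differ by
  more than twice the component sd, and the minor weight is at least
  0.15.  EM initializes by splitting the sorted sample at its widest
  spacing, which is exact for separated modes and isolates tail points
  (then rejected by the weight rule) on unimodal data.  On simulated
  worlds this rule detects planted biallelic gaps (allele separation
  2.5 kb, ~18 supporting PETs) in >95% of cases with a false-bimodal
  rate of a few percent; the acceptance suite recomputes both numbers.

## 3. Breakpoints

A mis-assembly leaves a signature no single statistic fakes: the
per-base *fragment* coverage of concordant PETs (tag1 start to tag2 end)
drops to exactly zero, because no correctly sized fragment can bridge
the junction.  `detect_breakpoints()` reports maximal zero-coverage
intervals, excluding a terminal margin of one `span_max` at each
scaffold end where zero coverage is geometric, not diagnostic.  Each
breakpoint is annotated with any overlapping assembly gap and the counts
of discordant cross-reference tags within `span_max` on each side — the
flanking dPET clusters that typically point to the scaffolds the two
sides really belong to.  Every reported interval is re-checkable by
brute force (the tests do), since the claim is literal zero coverage.

## 4. The scaffold graph and chaining

Before graph building, scaffolds are split (i) at N-runs of at least
10 kb that no cPET fragment spans — such gaps can swallow whole smaller
scaffolds, and splitting lets re-scaffolding re-fill them; smaller gaps
are left alone because fragments shorter than the insert size
over-fragment the graph — and (ii) at breakpoints (midpoint split, no
sequence removed).  Windows with more than 500 tags per kb are masked as
repeat-dense and whole PETs touching them are excluded: a repeat tag's
placement, and therefore the edge it supports, is arbitrary.

Deduplicated pairs whose tags map to two different fragments become edge
evidence.  Mate-pair geometry dictates which fragment end each tag
attaches to (a 5' tag on `+` points past the fragment tail, etc.), and
both tags must lie within `span_max` of their attachment end.  Edges are
per-library, weighted by supporting PET count; weights of 3 or less are
discarded as background.  The estimated link length is the mean of
`mu - dist_a - dist_b`, clamped to >= 1 only in AGP output.

Chaining maximizes, per connected component, the conflict-aware score:
traversed weight minus the weight of non-traversed edges incident to an
occupied fragment end (each physical scaffold end joins at most one
neighbour, so such edges are irreconcilable with the chosen path).
Components of at most 12 edges — the overwhelming majority in sparse
scaffold graphs, where bubbles are common but forks rare — are solved
exactly by enumeration over valid (end-disjoint, acyclic) edge subsets;
larger components use greedy descending-weight construction with
add/remove local moves.  The exact/greedy split is this package's
design: the score definition forces non-local trade-offs (dropping two
profitable edges can beat any single swap), so pure local search
demonstrably misses optima even on 6-node instances, while exhaustive
search on small components is cheap and deterministic.  The heuristic
can never exceed the exhaustive optimum (it returns a valid edge set
scored identically), and the tests assert both that bound and >= 95%
optimality on random small graphs.

Weight-1 provenance edges record pre-split order and are traversed only
when no dPET edge claims either end: they encode prior belief, not
evidence.  Ties between equal-weight candidates break by smaller
absolute link length, then lexicographic fragment id — determinism over
elegance.

## 5. RNA-PET annotation

The 3' signature (`AACTGCTG`) is searched in both 36 bp reads with an
ungapped local alignment over every 8 bp window; with indels disallowed
this reduces to minimum Hamming distance, and the acceptance criterion
is distance <= 2.  An 8 bp probe cannot tolerate more: at three
mismatches the match is indistinguishable from background, which is
exactly why HH "noise" pairs in real libraries resist rescue by
parameter relaxation.  Pairs with the signature on exactly one read (HT)
carry usable orientation; the signature read is the 3' tag and the
transcript strand is the mapped strand of the 5' tag.

Clustering is a single greedy pass per (reference, strand) over pairs
sorted by 5' position: a PET joins the open cluster when its 5' tag
overlaps the cluster's 5' window extended by `slack`.  Canonical sorting
makes the result order-invariant.  Two parameter sets run: stringent
(slack 0) and relaxed (slack 1,000 bp).  The promotion step chooses, per
transcription unit, the longer relaxed model *unless* it bridges two or
more stringent clusters across an internal window of >= 1,000 bp with
RNA-Seq density below 5 reads/kb — the over-clustering test.  The slack
values are package defaults (no published values exist to follow); the
promotion design intentionally makes the final models insensitive to the
relaxed value, because any spurious merge it introduces is undone
wherever transcription evidence has a hole.  The coverage-gulf reading
of "over-clustering" is an interpretation and is flagged as such.

Filters are applied literally and re-checkably: cluster span >= 2,000 bp
(the low-PET-count noise mode of real cluster-span distributions sits
below ~2 kb) and RNA-Seq support >= 5 reads/kb over the span.  Both
thresholds are configurable; whether the span filter should apply only
to low-count strata is ambiguous in the source material, so the default
filters everything below 2 kb and the alternative is a parameter.

Overlapping same-strand clusters coalesce transitively into gene models
(connected components of the interval-overlap graph); TSS/TTS sets are
deduplicated within a 10 bp `merge_radius`, consistent with the near-bp
boundary resolution full-length ditags provide.  Annotation comparison
matches genes by reciprocal best overlap and flags extensions by ratio
(> 1.3) or absolute growth (> 5 kb) — the absolute rule exists because a
100 kb gene extended by 6 kb is biologically meaningful at ratio 1.06.
Cross-scaffold HT pairs become split-gene records, and co-occurrence of
the two scaffolds in one chain cross-validates the DNA-PET and RNA-PET
sides independently.

SOLiD-style boundary-only mode (no 5'/3' distinction) is represented by
classifying and clustering without orientation; it is off by default and
not wired into the pipeline.

## 6. Metagene profiles

Gene bodies are rescaled to 100 bins by the index map
`bin = floor(k * B / G)`, which partitions bases exactly and therefore
conserves binned mass to machine precision — the conservation assertion
in the tests is 1e-9.  Flanks of 10 kb are binned at fixed 100 bp.
Profiles are strand-flipped and averaged with equal gene weight; whether
real analyses weight by expression is an open choice, so equal weight is
the default and coverage weighting a documented alternative
(`tss_peak_offset()` is unweighted by construction).  The TSS peak
offset is the argmax of the strand-aware average in a ±200 bp window;
ties resolve toward zero, flat signal returns NA.

## 7. What the generator emulates — and what it does not

`simulate_genome()` states the world the tests live in: chromosomes cut
into scaffolds separated by 0.5–8 kb unsequenced links; internal gaps at
~1/20 kb whose true lengths are log-normal with median 500 bp (the
typical real size of placeholder gaps) while half are annotated at a
fixed 50 bp; optional second alleles (+2.5 kb, fraction 0.5) for
bimodality tests; optional chimeric mis-joins for breakpoint tests;
random scaffold orientation.  `simulate_dnapet()` draws fragments on
true coordinates (Gaussian insert: sd 500 bp for the 10 kb library,
1,000 bp for the 17 kb one — consistent with concordant ranges spanning
roughly ±3 sd), projects tags through the fragment map (tags landing in
unsequenced regions are dropped as unmappable) and can inject a
chimera-rate fraction of random artefactual pairs, emulating the ~8–10%
discordant background of real libraries.  An optional shared log-normal
per-20 kb coverage landscape (off by default) emulates
mappability/GC-style bias; it is what makes two independent libraries'
coverage tracks correlate, as they do in real data.

Deliberately not emulated: platform-specific error models and quality
scores, PCR duplicates (deduplication is tested with explicit
duplicates instead), repeat-induced mismapping (repeat tests plant tag
pileups directly), exon/intron structure (out of scope for boundary
data), and expression-level heterogeneity beyond on/off.  A green test
therefore establishes algorithmic correctness under the stated
statistical model, not robustness to every artefact of a real sequencing
run.

## 8. Known limitations

* The chain-score heuristic for components above the exact-solve limit
  is greedy with local moves; adversarial dense components can be
  suboptimal (never above the optimum, and bounded below it in tests
  only for small instances).
* Gap estimation uses only single-gap-spanning pairs; nested or closely
  spaced gaps (< insert apart) lose support, and gaps near `span_max`
  leak spanning pairs into the discordant class, biasing support
  downward (not the estimate itself).
* Insert-sd measurement inherits contamination from undetected
  polymorphic spans; the sd is then conservative (slightly large),
  which lowers bimodality sensitivity rather than specificity.
* `detect_split_genes()` groups cross-scaffold pairs by 5' proximity
  only; it does not attempt isoform resolution.
* The CLI is a thin dispatcher over the exported functions with a JSON
  config; it is not a workflow manager.
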