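---
title: "Habitat preference scoring: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat preference scoring: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habscore)
```

## The model

Habitat-based community analysis starts from a reference collection of 16S
rRNA gene sequences in which every sequence carries exactly one
environmental-category label (soil, marine, human_gut, hydrothermal_vent,
...) recording the kind of metagenome sample it was mined from, together
with the id of the research project that produced it. A query sequence is
assigned habitat information by similarity search: among its significant
hits, let $n_c$ be the number of hit references labeled with category $c$.
The habitat preference score of the query is the composition

$$ s_c = \frac{n_c}{\sum_{c'} n_{c'}}, $$

a non-negative vector over categories summing to one. Because reference
collections deliberately retain (nearly) identical sequences from different
environments, one query is genuinely mapped one-to-many; the compositional
presentation is the point, not a nuisance. A query with no significant hit
is *unmapped* and reported as such rather than being given a score.

For a community profile (a feature-by-sample count table of exact sequence
variants with one representative sequence per feature), each feature is
scored once and a sample's score is the read-abundance-weighted mean of its
mapped features' score vectors, renormalized over the mapped features:

$$ S_c^{(j)} = \frac{\sum_{f \in M_j} w_{fj}\, s_c^{(f)}}
                    {\sum_{f \in M_j} w_{fj}}, \qquad
   w_{fj} = \text{reads of } f \text{ in } j, $$

where $M_j$ is the set of mapped features present in sample $j$. Unmapped
features are excluded and reported separately through a coverage pair: the
fraction of present features that mapped and the fraction of reads
belonging to mapped features. Excluding (rather than spreading) unmapped
features and renormalizing keeps scores comparable across samples of
different coverage; the coverage columns keep the exclusion honest. An
unweighted mean (`weight_by_abundance = FALSE`) is available for
presence/absence designs.

Two aggregation choices deserve emphasis because they are genuinely open:

* **Per-sequence counting.** Each hit reference contributes one count to
  its category, regardless of which project it came from. Weighting hits
  per project instead would be defensible, but per-sequence counting is the
  natural reading of a score defined as hit composition, and project-size
  imbalance is already addressed upstream by per-project capping.
* **Category-size normalization** (`normalize_by_category_size = TRUE`)
  divides $n_c$ by the category's database size before renormalizing.
  Soil alone is a quarter of the bundled reference release, so raw hit
  compositions tilt toward large categories. The flag is off by default
  because the score is conventionally presented as a plain hit
  composition; turn it on when comparing categories of very different
  sizes on equal footing.

## Reference databases and per-project capping

References live in a tibble (`sequence_id`, `sequence`, `category`,
`project_id`); category and project sizes are always recounted from the
rows. Public projects differ in size by orders of magnitude, so
`cap_per_project()` retains at most `cap` sequences (default 100) per
(category, project) pair, by uniform sampling without replacement under a
caller-supplied seed. The published category sizes bundled as
`prokatlas_category_counts()` are consistent with a 100-per-project rule
(e.g. wetland: 11,900 sequences from 119 projects; phyllosphere: 12,100
from 121), which is why 100 is the default; the cap is a parameter, not a
constant. Capping is deterministic for a fixed seed and idempotent.

`category_summary()` reports per-category fractions and cumulative
coverage of the $k$ largest categories. On the bundled table the four
largest categories (soil, marine, freshwater, rhizosphere) cover 55.3% of
the 361,474 sequences and the top 26 cover just over 90% — the two
arithmetic facts the test suite pins exactly.

## Similarity search

`search_queries()` shortlists candidate references through an exact-match
k-mer index (default $k = 12$; windows containing N are skipped) and
requires `min_seed_count = 2` distinct shared k-mers before aligning — the
classic two-hit seeding compromise. A genuine hit at the default
thresholds (150 aligned bases at 97% identity) shares dozens of 12-mers
with its reference, so two-hit seeding prunes only chance matches; set
`min_seed_count = 1` for maximal seeding sensitivity.

Each candidate is then aligned with an affine-gap Smith-Waterman over the
full dynamic-programming matrix (Rcpp). We deliberately do not restrict
the extension to a band around the seed diagonal: at the sequence lengths
this package targets (up to a few kilobases) the full matrix costs
milliseconds, and it guarantees the optimal local alignment — a guarantee
the test suite exercises by comparing against an independent exhaustive
implementation. Scoring defaults are +1 match, −2 mismatch, and
`gap_open + L × gap_extend` = −5 − 2L for a gap of length L. N never
counts as a match (it scores as a mismatch against everything, including
N); degenerate IUPAC codes other than N are rejected at load. Percent
identity is `100 × matches / aligned_length` with gaps counted in the
alignment length, the BLAST tabular convention.

Per (query, reference) pair only the best-scoring alignment is kept —
ties broken toward the plus strand, then smaller query start, then
lexicographic reference id — so one reference can never contribute twice
to a score. Both strands are searched by default; minus-strand hits keep
ascending query coordinates plus a strand flag, and are exported with
descending subject coordinates in the 12-column tabular format. Users who
prefer an external search tool (e.g. BLAST) can bypass the internal
aligner entirely via `import_tabular_hits()`, which applies the same
length/identity filters plus an optional E-value cutoff; the internal
aligner computes no E-values, and "significant hit" in this package always
means passing the length and identity thresholds.

The default 150-base minimum span reflects the shortest alignment we
consider reliable for habitat assignment of 16S fragments; 200 and 250 are
natural stricter settings and the monotonicity property (raising either
threshold never adds hits) is tested.

## Downstream statistics

`group_score_test()` sums a category group's scores per sample and
compares labeled in-group samples against everything else with a
Mann-Whitney U test; `gradient_correlation()` relates grouped scores to a
numeric covariate by Spearman correlation. Both wrap the corresponding
base-R machinery: `wilcox.test` with an exact p-value when the smaller
group has at most 8 observations and no ties (normal approximation with
tie correction otherwise — the switch is exposed), and
`cor.test(method = "spearman", exact = FALSE)`, whose p-value is the
t approximation on $r\sqrt{(n-2)/(1-r^2)}$. Tests are two-sided
throughout; with many groups, Benjamini-Hochberg adjustment is available
(`group_score_tests(adjust = TRUE)`) but off by default since single-group
analyses need none.

## The co-occurrence network

`composition_matrix()` tabulates how many of each category's references
map to each representative entry; a representative mapping can be supplied
externally (TSV `reference_id`/`representative_id`, e.g. from a full
taxonomy-database mapping) or computed at desk scale by
`cluster_representatives()`, a greedy centroid clusterer: in input order a
sequence joins the first centroid it aligns to at ≥97% identity over the
minimum span, else founds a new centroid. Greedy input-order clustering is
deterministic and cheap; it is order-dependent like every greedy
clusterer, which is acceptable because the network only needs a stable
partition into near-identical groups.

`build_network()` connects two categories when the Bray-Curtis
dissimilarity of their composition rows (via `vegan::vegdist`) is
*strictly* below the threshold, default 0.9. Node centrality is
**pair-counting betweenness**: for node $v$, the number of connected
unordered pairs $\{s,t\}$, both distinct from $v$, with at least one
shortest path through $v$. This counts each pair at most once — unlike
standard Freeman betweenness, which splits credit across all shortest
paths of a pair — and matches the "number of node pairs whose shortest
paths contain the node" reading of centrality over an unweighted,
thresholded graph. The standard fractional variant is available with
`betweenness = "fractional"` (via igraph) when comparability with other
tools matters. Shortest paths are unweighted: edges either exist or do
not; dissimilarity magnitudes below the threshold affect display only.

## The synthetic-data generator

Every claim the package makes is testable offline because the generator
produces reference databases, query sets, and community studies with known
ground truth:

* **Ancestors** are i.i.d. uniform nucleotide strings, by default 1500
  bases (full-length 16S). Each category's pool holds
  `pool_size_per_category` ancestors (default 50); a symmetric `overlap`
  matrix shares ancestors between category pairs with the given
  probability (identity matrix — disjoint pools — by default).
* **References** are one mutated copy per pool member (default 1%
  per-base substitutions; substitutions only, so identities are exactly
  interpretable — an indel mode exists for gap-handling tests), assigned
  round-robin to 5 projects per category.
* **Communities** allocate features to categories by largest remainder on
  the mixture, then draw multinomial reads with each category's features
  sharing its proportion equally, so the expected read composition equals
  the requested mixture exactly and recovery error reflects the pipeline,
  not allocation noise. Gradient studies interpolate the mixture linearly
  across samples over a shared feature panel and record the interpolation
  coordinate as the `gradient` covariate.

All randomness flows through explicit integer seeds; identical
configurations produce byte-identical FASTA/TSV output.

What the generator does **not** emulate: 16S secondary structure and
conserved/variable-region architecture, GC and codon biases, chimeras,
sequencing-error profiles, copy-number variation, and compositional
correlations between taxa. Passing recovery tests therefore demonstrate
that the search-score-aggregate pipeline is correct and well calibrated
under controlled similarity structure; they do not certify accuracy on
real communities, where reference coverage and category imbalance
dominate.

## Problem sizes and numerical choices

The bundled test and acceptance runs use 3-category databases with 50
references per category at 1500 bases, communities of 30 features and
10,000 reads, and 10-sample gradients, each repeated over 10 seeds —
small enough to run anywhere, large enough that mixture recovery error
(mean absolute error ≤ 0.05) and gradient correlations (ρ ≥ 0.9) are
meaningful. Compositions are checked to sum to one within 1e-9; Bray-Curtis
uses exact arithmetic on counts; alignment scores are integers, so oracle
comparisons are exact. Ties in the aligner are resolved deterministically
(first-best cell in row-major order; substitution preferred over gaps;
opening preferred over extending) so results are reproducible to the byte.

## Known limitations

* Habitat labels inherit the annotation vocabulary of public metagenome
  archives; labels of different granularity (e.g. `seawater` vs `marine`)
  coexist and are best analyzed through user-defined groups
  (`merge_categories()`).
* The internal aligner is exact but not E-value-calibrated; for very large
  reference collections an external search plus `import_tabular_hits()`
  will be faster.
* Greedy clustering depends on input order and is a stand-in for mapping
  references onto a curated representative set.
* Per-query scores can be wrong for individual organisms that are rare in
  their recorded source environment; community-level aggregates are the
  intended unit of interpretation.
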