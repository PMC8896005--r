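---
title: "Transcription-factor motifs in transposable elements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcription-factor motifs in transposable elements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TEmotifs)
```

# The question

Transposable elements (TEs) carry sequence that can be read by the host's
transcription factors (TFs). When a TE copy lands upstream of a gene, any
TF-binding motif inside it becomes a candidate regulatory element. TEmotifs
implements a genome-wide accounting of this process for compact genomes in
the *Caenorhabditis* mould: where TF motifs occur, how strongly individual
TE types are enriched for them, whether the TE-provided motifs sit in open
chromatin and under cognate TF binding, and whether orthologous genes in a
second species carry motif-bearing TEs in their promoters more often than
chance allows.

All stages run on real annotation files (FASTA, BED-style TE tables,
GFF-lite gene models, summit BEDs, two-column ortholog maps) or on the
package's seeded synthetic genomes with planted ground truth.

# Motif model and exact match p-values

A motif is a position weight matrix (PWM): independent per-position base
probabilities $p_{ib}$ over $\{A,C,G,T\}$, width $w$. The null model is a
zero-order Markov background with frequencies $f_b$ estimated from the
scanned genome, pooled over both strands (so $f_A = f_T$, $f_C = f_G$)
with add-one smoothing. Scoring uses log2-odds with a pseudocount $c$
(default 0.1) distributed proportionally to the background:

$$ S(i,b) = \log_2 \frac{(p_{ib} + c\,f_b)/(1+c)}{f_b}. $$

The match p-value of a window is the probability that a random
background-generated word scores at least as high. It is computed exactly
on a discretized copy of the score matrix: per-position scores are shifted
to zero and rounded to integer bins (1000 bins across the matrix's total
score range by default), and the distribution of the total integer score
is built by dynamic programming -- a convolution of the four-point
per-position distributions. For widths up to 8 the tail table is checked
against exhaustive enumeration of all $4^w$ words in the test suite. A
word's discretized total can drift from its real score by at most $w/2$
bins; scanning therefore thresholds on the integer score whose tail first
drops to the requested p-value, which makes "p at or below threshold" an
exact statement about the discretized model.

Degenerate inputs are handled explicitly: zero-probability entries (only
possible with pseudocount 0) are floored just below the finite score
range, so impossible words can never outrank possible ones while tail
p-values at attainable cutoffs remain exact.

The scanner slides over every position of every chromosome on both
strands (the reverse strand scores the reverse-complemented window,
implemented as a reversed-complemented matrix on the forward sequence).
Windows containing ambiguous bases are skipped entirely -- the simplest
defensible choice; scoring them against a background fallback would
silently mix models. When both strands pass at the same start, only the
better-scoring strand is kept, with ties resolved to `+` for determinism.
The default threshold is p <= 1e-4. No q-value filtering is applied on
top of the raw threshold.

# Interval conventions

External files follow BED semantics (0-based half-open); in memory every
positional object is a `GRanges` (1-based closed), with readers and
writers converting at the boundary. Merging unions overlapping *and*
book-ended intervals, the common default of interval-merge tools.

"A motif resides within a TE" means strict subset containment of the hit
interval in a single TE record, strand ignored; a hit overlapping a TE
boundary does not count. Containment is tested against the un-merged TE
track so the covering record's type and family labels stay unambiguous.
When overlapping TE records both contain a hit -- annotation tracks do
contain such records, and the convention is genuinely open -- the longest
covering record wins, with ties broken by lexicographically smallest type
name, and the hit is flagged `te_ambiguous` so downstream users can audit
the choice.

Promoters are the `upstreamBp` (default 2500 bp) window upstream of a
gene or operon start, strand-aware and clipped at chromosome ends rather
than dropped. Two variants exist because the analyses need both: the
*exclusive* variant subtracts coding exons, UTRs and introns of any gene
and substitutes a single operon promoter for operon member genes (used by
the genome partition); the *inclusive* variant keeps every gene's raw
window, overlapping features included (used by gene-counting analyses,
which count genes, not bases). Feature classes in the partition may
overlap each other; only "distal intergenic" is defined residually as the
space outside every other class.

# Enrichment statistic and filter cascade

For motif $m$ and TE type $t$: $n$ is the motif's genome-wide instance
count (after best-strand collapsing), $k$ the number of instances fully
inside type-$t$ records, $B_t$ the merged bp of the type and $G$ the
genome size. The fold enrichment is

$$ \mathrm{fold} = \frac{k/n}{B_t/G}, $$

and significance is the one-sided binomial tail
$P(X \ge k \mid n, p_0 = B_t/G)$ -- each instance treated as an
independent Bernoulli trial with success probability equal to the type's
genome share. Overlap-induced dependence between instances is ignored, as
is conventional for this statistic. The selection cascade keeps records
with $B_t$ strictly greater than 20 kb, fold strictly greater than 20 and
p strictly below 1e-12; all three thresholds are configurable.

The per-motif summary `motifPercentInTe()` is plain count arithmetic:
100 times the sum of in-type counts over chosen types divided by $n$.
Gene-level reporting counts a gene once per motif when at least one
TE-contained hit lies fully within its inclusive promoter window; a hit
inside two genes' overlapping windows counts both genes.

# Chromatin association

Peak summits (ATAC or TF ChIP) are extended 50 bp each side into 101-bp
regions, clipped at chromosome ends, and merged across all available
developmental stages before any fraction is computed. "Within open
chromatin" means full containment of the motif interval in a merged
summit region, deliberately consistent with the TE-containment rule; the
looser any-overlap reading would make the accessible and TE conditions
asymmetric.

Accessible fractions gate motifs on strictly more than 3000 accessible
instances and strictly more than 10% of them TE-contained; bound
fractions pair each motif with its cognate TF's ChIP regions and gate on
strictly more than 500 bound regions and 5% TE-derived. A bound region
with several cognate hits counts once and is TE-derived if any contained
hit is TE-contained; an instance-level mode is exposed because the
region/instance unit is a genuinely open reading. All motifs are returned
with their gate flags so census statements ("every TE-residing motif type
is accessible at least once") remain checkable from the output.

The accessibility association is a two-sided Fisher's exact test on a
2x2 table built over one TF's bound regions: rows = contains a
TE-provided cognate motif (yes/no), columns = overlaps a merged
accessible region (yes/no). The construction is recorded in the output
header because other 2x2 framings are defensible. Degenerate margins
return p = 1 with a flag rather than an error.

# Cross-species ortholog sharing

Both genomes are scanned with the same PWMs against their own
backgrounds. For each motif, the species-specific gene sets with
promoter TE-provided motifs are intersected with a strict one-to-one
ortholog map of $N$ pairs: $K$ and $n$ are the per-species member counts
inside the map, $k$ the pairs present on both sides, and significance is
the upper-tail hypergeometric $P(X \ge k \mid N, K, n)$, starred at
0.05 / 0.01 / 1e-5. The population is all mapped orthologs, not all
genes -- that is what "expected by chance among orthologs" means -- and
not only orthologs that happen to carry promoter TEs; restricting the
population is available to the caller by pre-filtering the map.

Shared pairs are classified by TE-family similarity after normalizing
annotation-specific family spellings through an editable table
(`familyNormalizationTable()`); unknown labels fall back to raw string
equality with a warning. A shared pair is "similar" if any normalized
family on its A side equals any on its B side. `boundShared()` counts
shared pairs whose A-side promoter hit sits inside a cognate bound
region.

# The synthetic-data generator

`generateBundle()` emits every input the pipeline consumes, plus
ground-truth tables, from one integer seed. Named substreams (motifs,
genome, TEs, genes, planting, summits, orthologs, per species) keep the
draws independent, so editing one plan section does not perturb the
others; identical seeds give byte-identical files.

What it emulates: a two-chromosome 750 kb genome at worm-like base
composition (64% AT); a TE library of named types in families and repeat
classes at about 9% genome coverage, two types covering more than 20 kb
so the coverage gate has both passing and failing material; ten
width-10 motifs; three motifs planted at a controlled in-TE excess; one
motif reserved for the cross-species plan; genes with UTRs, split coding
exons, introns and operons; multi-stage ATAC and per-TF ChIP summits
covering planted sites at configured rates plus noise; and a second,
smaller species sharing one-to-one orthologs whose promoters carry
similar- or different-family TEs by plan.

Three quantitative choices deserve explanation:

* **Scale.** At p <= 1e-4 the expected chance-hit load is about
  $10^{-4} \cdot 2L$ windows per motif whatever the motif's information
  content. A type covering the gate-minimum 20 kb in a small genome has a
  large genome share, and fold enrichment can never exceed $G/B_t$; the
  750 kb default is the smallest scale at which a >20-fold, >20 kb type
  coexists comfortably with the chance-hit load while the full pipeline
  stays fast (single-digit seconds to generate, low tens of seconds to
  analyse).
* **Planted fold.** The plan's target fold is the *expected realized*
  fold of the pipeline estimate, not the raw planted ratio: the planting
  solver accounts for chance hits, for secondary hits from windows
  partially overlapping a planted word, and for cross-motif contamination
  (another motif's planted words passing this motif's threshold), all
  computed exactly under the discretized score model. Motifs are drawn to
  be mutually dissimilar (low self- and cross-overlap hit rates), as a
  curated motif collection's entries are distinguishable. The default
  enriched target is 22-fold: the selection gate is strictly
  greater-than-20, and a target sitting on the gate would fail it half
  the time through chance-hit noise alone; published selected motifs
  likewise exceed the gate, often by large factors.
* **Null bundles.** With planting disabled, motifs are placed uniformly
  irrespective of TEs. Position-only null bundles (no sequence written)
  also allow planted sites to overlap, because the non-overlap constraint
  exists only to stop words overwriting each other; enforcing it would
  under-disperse per-type counts and make the binomial calibration look
  artificially conservative.

What the generator does **not** emulate: decayed TE copies, indels and
nested insertions; non-uniform chromosomal TE distribution; motif
correlations within TE consensus sequences; read-level noise (no FASTQ);
realistic inter-gene distance distributions. Passing closed-loop tests
therefore demonstrates that the statistics and bookkeeping are correct
under the stated model, not that the biological conclusions transfer to
any particular real genome.

# Numerical choices and degenerate inputs

* Discretization: 1000 bins across the total score range; error bound
  documented above; tests compare the DP to enumeration on the same
  discretized scores to 1e-12.
* Binomial, hypergeometric and Fisher tests are delegated to R's exact
  implementations (`pbinom`, `phyper`, `fisher.test`) and each is
  cross-checked in the suite against independent combinatorial summation
  oracles to 1e-10 for population sizes up to 30-40. Exact discrete
  tests are conservative: their attained level sits below the nominal
  alpha, which is visible in null calibrations as rejection rates
  slightly under 5%.
* Ties: max-strand keeps `+`; covering-TE ties keep the longest record,
  then lexicographic type; top-contributor ties are lexicographic.
* Degenerate inputs: zero-length feature classes are flagged, not
  divided by; motifs with zero genomic instances are omitted from
  enrichment with a notice; all-`N` sequence is rejected; summits off
  their chromosome are rejected with a notice; degenerate Fisher margins
  return p = 1 flagged; an infeasible synthetic plan fails before any
  file is written.
* The report tables round percentages and folds for display but keep
  p-values at full precision.

# Reproducibility and problem sizes

Every stochastic quantity flows from one integer seed through named
substreams; the pipeline itself is deterministic, and a rerun on the same
inputs is byte-identical (the manifest records inputs, thresholds,
package version and seed). The test suite and the acceptance script use
toy problem sizes chosen so the whole suite runs in minutes on one CPU:
750 kb two-species bundles for end-to-end runs, 20 replicates for fold
recovery, 2000 pair-tests for binomial calibration, 2000 draws for
hypergeometric calibration, and per-base bitmap oracles on instances up
to 100 kb.

# Known limitations

* The binomial null ignores dependence between overlapping instances of
  the same motif, as the statistic conventionally does.
* The hit-to-TE attribution for motifs spanning two abutting TE records
  is a convention (longest cover, then name); such hits are flagged but
  alternative attributions would change per-type counts marginally.
* First- and higher-order Markov backgrounds, gapped motifs and q-value
  control are out of scope.
* Cross-species conclusions depend on the supplied one-to-one ortholog
  map; the package neither infers orthology nor distinguishes conserved
  insertions from independent ones.
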