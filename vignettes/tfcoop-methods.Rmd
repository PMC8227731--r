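---
title: "Inferring cooperative TF pairs from promoter binding-site co-occurrence"
author: "tfcoop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cooperative TF pairs from promoter binding-site co-occurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfcoop)
```

## The problem

Transcription factors (TFs) rarely act alone: many regulatory decisions are
made by pairs of factors whose binding sites co-occur at short, constrained
spacings in the same promoter. Given (i) a library of position weight
matrices (PWMs), (ii) a set of promoter sequences (conventionally the
−500/+100 bp window around each transcription start site), and (iii) one or
two gene lists of interest, `tfcoop` predicts binding sites, counts
distance-constrained co-occurrences of heterotypic site pairs, scores each
TF pair by background-corrected pointwise mutual information (PMI), and
reports the pairs whose z-score reaches 3 as a phenotype cooperation
network. Two phenotype networks can then be compared for common edges,
phenotype-specific edges, and partner-switching TFs.

## The model, step by step

### Promoter windows and redundancy filters

Promoters are strand-aware windows of `upstream = 500` and
`downstream = 100` bp around the TSS, measured along the transcribed strand
(minus-strand windows are reverse-complemented so position 0 is always the
most upstream base; the genomic interval is `[tss − downstream + 1,
tss + upstream + 1)` in 0-based half-open coordinates — the standard
promoter convention, fixed here because several are defensible). Promoters
that share even one base with another promoter are removed — by default the
whole overlapping cluster is dropped, since co-occurrence counts over
stacked promoters would double-count the same sites; `keep-first` is
available for users who prefer one representative. Exact duplicate
sequences (typically gene duplications or duplicated TSS annotations) are
also removed; similarity-based deduplication below exact identity would
need an arbitrary threshold and is deliberately out of scope.

### MATCH-style site prediction

Each PWM is regularized with a pseudocount of $10^{-3}$ per count cell
(guaranteeing strictly positive frequencies) and characterized by its
per-position information content in natural-log units,

$$I(i) = \sum_{b \in \{A,C,G,T\}} f(i,b)\,\ln\!\big(4 f(i,b)\big),$$

which is 0 at a uniform position and $\ln 4$ at a degenerate one. A window
$w$ is scored by the information-weighted, min–max-normalized similarity

$$\mathrm{score}(w) = \frac{\mathrm{Current} - \mathrm{Min}}
  {\mathrm{Max} - \mathrm{Min}}, \qquad
  \mathrm{Current} = \sum_i I(i)\, f(i, w_i),$$

with Max/Min the per-position maxima/minima. The *core* score is the same
quantity restricted to the 5 consecutive positions with the largest summed
information (leftmost window on ties, for determinism). A site is emitted
where both scores reach their cutoffs; both strands are scanned and
minus-strand hits are reported in forward coordinates. `N` bases contribute
the position minimum, so an `N` can lower a score but never create a site.

The default cutoffs (0.75 core, 0.80 matrix) are conventional conservative
values; the upstream literature used per-matrix profiles that are not
printed anywhere reproducible, so results on real data are cutoff-sensitive
and the profile is exposed (globally and per matrix). Overlapping hits of
the same matrix are all kept: the co-occurrence statistic operates on the
complete site list, and no masking rule is part of the method.

Sites are pooled per *TF name*, obtained from matrix accessions by
stripping the site-type prefix and quality/version suffix
(`V$GATA4_Q3 → GATA4`). This is the pairing unit: cooperation is reported
between factors, not between individual matrices. The rule is a convention
of this package — motif libraries do not agree on how matrices map to the
factor families shown in published cooperation networks.

### Distance-constrained co-occurrence and PMI

Within each promoter, every unordered pair of sites with *different* TF
names is a candidate; the pair qualifies when the edge-to-edge gap
$\max(\mathrm{starts}) - \min(\mathrm{ends})$ lies in $[d_\min, d_\max]$
(defaults 5 and 20 bp, inclusive). The edge-to-edge definition makes the
minimum distance exclude overlapping and adjacent sites, which is the
stated motivation for a minimum distance in the first place;
center-to-center is available as an option. Homotypic pairs are excluded by
default (`homotypic = TRUE` restores them).

Summing over the whole promoter set, with $f_{ab}$ the number of
qualifying site pairs for TFs $a,b$, $F_{\text{pairs}} = \sum f_{ab}$,
$f_a$ each TF's total site count and $F_{\text{sites}} = \sum_a f_a$:

$$\mathrm{PMI}(a;b) = \log_2 \frac{f_{ab}/F_{\text{pairs}}}
  {(f_a/F_{\text{sites}})(f_b/F_{\text{sites}})}.$$

Pairs never observed under the distance constraint are excluded rather
than scored at $-\infty$. The normalization (pair frequency over total
pair count, marginals over total site count, log base 2) follows the
text-mining-style convention of PMI-based co-occurrence analysis; the log
base is configurable.

### Background correction and significance

Promoter composition alone (GC content, CpG islands, dinucleotide skew)
produces co-occurrences with no regulatory meaning. The background level
of each pair is estimated by shuffling every promoter with an
Eulerian-path shuffle that preserves its dinucleotide counts exactly
(mononucleotide shuffling is available), rescanning, and re-scoring;
$\mathrm{AVG(PMI)}$ is the arithmetic mean over `n_shuffles = 10`
replicates, with replicates where the pair is absent contributing 0, and
pairs absent from every replicate getting AVG = 0 (no background
cooperation, so the correction leaves their PMI unchanged). The corrected
score is

$$\mathrm{PMI}_{cor}(a;b) = \mathrm{PMI}(a;b) - (1+\alpha)\,
  \mathrm{AVG(PMI}(a;b)),$$

with the recommended $\alpha = 0.2$ ($\alpha \in [-1,+1]$; $-1$ switches
the correction off). Corrected scores are z-transformed over the
population of scored pairs (population standard deviation, since the
transform is over the complete population, not a sample) and a pair is
significant at $z \ge 3$, inclusive. No further multiple-testing layer is
added: the $z \ge 3$ rule *is* the method's significance criterion.

A structural consequence worth knowing: the z-score of $n$ values is
bounded by $\sqrt{n-1}$, so $z \ge 3$ is unattainable when fewer than ~10
pairs are scored. Small motif libraries or very small gene lists cannot
produce significant pairs regardless of signal strength; study designs
need enough TFs for a null population.

### Networks

Significant pairs form an undirected network per phenotype with z as the
edge weight. Hubs are the top-`k` (default 3) nodes by degree, ties broken
by summed |z| of incident edges and then by name — a total order.
Comparing two networks partitions each edge set into common and
phenotype-specific edges; *partner-switching* TFs are nodes present in
both networks with no common incident edge — factors that cooperate in
both phenotypes but with different partners in each. Networks export to
GraphML (for Cytoscape-style rendering; no plotting is done here) and to
TSV edge lists that round-trip z bit-exactly.

## The synthetic benchmark

`generate_corpus()` builds corpora with known ground truth: background
sequence from a mononucleotide (or first-order Markov dinucleotide)
model, one or more *planted pairs* — a site sampled from each of two PWMs
(sampled from the frequency model, not the consensus, so matrix scores
vary realistically around the cutoff), separated by a gap drawn uniformly
from a configured range, placed at a uniform feasible offset in a
`penetrance` fraction of promoters — plus *decoy* PWMs placed
independently (Poisson counts), which form a true null for specificity.
Placements never overwrite one another (rejection sampling with a retry
cap); generation is byte-deterministic in (spec, seed).

The default geometry — 200 promoters of 600 bp — mirrors the −500/+100
window and a study-scale gene-list size; the decoy rate of 0.5 sites per
promoter reflects the site density of a conservatively cutoff scan. The
shipped benchmarks (also recomputed by `scripts/acceptance.R`) plant one
pair at penetrance 0.4 against 8 decoy TFs with 10 shuffle replicates:
across 20 seeded corpora the planted pair reaches $z \ge 3$ at rank 1 in
every run, and at penetrance 0 about 1% of null pairs reach $z \ge 3$
(the threshold is conservative under the null).

What the generator does *not* emulate: nucleosome occupancy, conservation,
chromatin context, clustered TSS structure, motif families with shared
cores, and promoter GC heterogeneity at the scale of real genomes. Passing
benchmarks therefore demonstrate the statistic behaves as designed — they
do not certify performance on real promoters, which hinges on motif
quality and cutoff profiles.

### PMI's low-frequency bias

One property of the pinned normalization deserves emphasis. If a pair's
TFs occur *only* where they are planted, marginals scale with penetrance
$q$ and $\mathrm{PMI} \approx \mathrm{const} - \log_2 q$: a *rarer* pair
scores *higher*. Signal strength is monotone in penetrance only when the
TFs' marginal site counts are dominated by pair-independent occurrences —
the realistic condition, since real TFs bind throughout the genome. The
penetrance-monotonicity test constructs exactly that condition (pair TFs
also placed as abundant independent decoys). Users comparing z-scores
across pairs should keep this bias in mind when marginals differ wildly.

## Numerical and design choices

- **Coordinates** are 0-based half-open everywhere (BED-compatible;
  touching windows do not overlap).
- **Pseudocount** $10^{-3}$ per count cell, applied once at construction.
- **Degenerate scores**: an all-uniform matrix has Max = Min and scores 0
  everywhere (never a site).
- **Tie-breaks**: leftmost core window; site tables sorted by (start,
  end, tf_name, strand); pair tables by descending z then pair name —
  every output order is deterministic.
- **Seeding**: every stochastic stage (corpus generation, each shuffle
  replicate, each sequence within a replicate) draws from a stream
  derived from the master seed and a stage label, so adding replicates
  never perturbs earlier draws, the two arms of a study draw independent
  backgrounds, and a full `run_study()` is byte-identical under one seed.
  Library calls restore the caller's RNG state.
- **Problem sizes** in the shipped tests and acceptance script (200 × 600
  bp corpora, 10–20 seeds, 10 shuffles) were chosen as the smallest
  geometry at which the z ≥ 3 machinery is exercised meaningfully.

## Limitations

- Published cooperation networks built on curated vertebrate motif
  libraries are not reproducible here: the TRANSFAC non-redundant
  vertebrate library is proprietary, and the per-matrix MATCH cutoff
  profiles used with it are not public. This package therefore validates
  the statistic on synthetic ground truth rather than re-deriving any
  published network.
- Pair scoring is corpus-level: no per-promoter cooperation calls, no
  modeling of the gap distribution beyond the hard window.
- TF-name pooling is purely lexical; paralogous matrices with different
  names are not merged, and family collapsing (e.g. reporting "IRF" for
  all IRF-family matrices) follows the accession text only.
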