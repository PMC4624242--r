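---
title: "Methods: variant scoring, orthology and MLST phylogeny in strainprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant scoring, orthology and MLST phylogeny in strainprofiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainprofiler)
```

# Scope and model overview

`strainprofiler` implements the comparative-genomics computation used to
profile panels of closely related haploid bacterial strains — typified by
soybean-fermenting *Bacillus subtilis* isolates — from three angles:

1. **Variant-impact profiling.** Haploid variant calls against a shared
   reference are filtered on depth and quality, classified at four impact
   levels, compressed into a per-gene *genetic variant score*, and the
   resulting strains × genes matrix is explored with unscaled PCA and
   complete-linkage clustering.
2. **Orthology.** Gene sets of two strains are related by reciprocal best
   hits (RBH) under dual criteria: more than 80% identity in both
   directions and more than 80% of each gene's own length aligned.
3. **MLST phylogeny.** Allelic profiles over seven housekeeping loci
   (*glpF*, *ilvD*, *pta*, *purH*, *pycA*, *rpoD*, *tpiA*), Kimura
   2-parameter (K2P) distances on the concatenated fragments,
   neighbor-joining (NJ) tree construction, and bootstrap supports.

A synthetic-data module generates every input with planted ground truth, so
each stage is testable end to end without sequencing data.

# Variant filtering and impact classification

Filtering retains records with `DP >= 10`, `QUAL >= 100` and `QD >= 5`
simultaneously — the logical complement of the GATK-style exclusion
expressions `"DP < 10 || QUAL < 100.0"` and `"QD < 5.0"`. Because the
exclusions are strict, records sitting exactly on a threshold are kept.
Records lacking any of the three fields fail the filter (with a warning):
a record whose quality is unknown should not survive a quality filter.

Classification follows SnpEff-style semantics in a deliberately compact
rule set:

| situation | consequence | impact |
|---|---|---|
| CDS indel, in-CDS length change not divisible by 3 | frameshift | high |
| CDS SNP creating a stop before the terminal codon | stop_gained | high |
| SNP in the initiator ATG | start_lost | high |
| CDS in-frame indel | inframe_indel | moderate |
| CDS SNP changing the amino acid | missense | moderate |
| CDS SNP preserving the amino acid | synonymous | low |
| outside every gene model | intergenic | modifier |

Conventions worth stating explicitly:

* A variant is assigned by the containment of its **leftmost reference
  base** (0-based half-open gene intervals); a deletion anchored in a CDS
  but running past its end is a frameshift when the in-CDS deleted length
  is not a multiple of 3. Full transcript-model annotation is out of scope.
* Minus-strand genes are classified on the reverse complement of the CDS.
* Multi-allelic VCF records are split into bi-allelic records first.
* The stop codon is treated as an ordinary residue symbol in the
  amino-acid comparison, so a SNP turning the terminal stop into a sense
  codon is reported as `missense`/moderate (a stop-to-stop change is
  synonymous). This keeps the consequence vocabulary closed; variants of
  this kind are never planted by the generator.
* `gene_id` is `NA` exactly for modifier variants; upstream/downstream
  modifier subtypes are collapsed into one `intergenic` label because the
  score formula ignores modifiers entirely.

# The genetic variant score

For strain $X$ and gene $i$, with $N_{\mathrm{high}}$, $N_{\mathrm{mod}}$,
$N_{\mathrm{low}}$ the counts of high/moderate/low-impact variants in that
gene,

$$\mathrm{gene}_i(X) = \log\!\big(C_{\mathrm{high}}(X)\,N_{\mathrm{high}_i}(X)
 + C_{\mathrm{mod}}(X)\,N_{\mathrm{mod}_i}(X)
 + C_{\mathrm{low}}(X)\,N_{\mathrm{low}_i}(X) + 1\big)$$

with per-strain constants

$$C_{\mathrm{low}} = 1,\qquad C_{\mathrm{mod}} = \mathrm{MAX}_{\mathrm{low}}/2,
\qquad C_{\mathrm{high}} = (C_{\mathrm{mod}} + \mathrm{MAX}_{\mathrm{mod}})/2,$$

where $\mathrm{MAX}_{\mathrm{low}}$ and $\mathrm{MAX}_{\mathrm{mod}}$ are
the maximum per-gene low and moderate counts **within that strain**. The
`+ 1` pins zero-variant genes to score exactly 0, and the log compresses
heavy-tailed per-gene counts.

Design decisions:

* **Log base.** The natural logarithm is used. The base only rescales all
  scores by a common constant, which changes neither PCA directions nor
  any clustering topology, so any fixed base is equivalent; `ln` is the
  documented choice.
* **Degenerate constants.** The formulas are applied literally: a strain
  with no low-impact variants gets $C_{\mathrm{mod}} = 0$, silencing its
  moderate counts. The constants are meant to be positive weights, so
  `strain_constants()` warns whenever a zero weight would discard nonzero
  counts, but it does not invent a floor the formulas do not define.
* **Gene universe.** By default the matrix columns are the sorted union of
  genes carrying at least one scored variant in at least one strain;
  `genes =` forces a fixed universe (e.g. all reference genes). Either way
  every strain shares one column order and absent genes score 0.

# PCA and clustering of score vectors

`strain_pca()` mean-centers columns (exposed as `center`, default `TRUE`)
but **never scales columns to unit variance**: variant scores are already
on a comparable scale, and variance-scaling would re-weight exactly the
high-variance genes the analysis is looking for. Centering itself is the
standard default of PCA implementations and affects component directions,
not the interpretation of variance ratios; `center = FALSE` is available.

Numerical conventions: components are retained while their eigenvalue
exceeds $10^{-12}$ of the total variance (a rank guard, not a model
choice); explained-variance ratios are normalized over retained
components; each component's sign is fixed by making its
largest-magnitude loading positive, so results are reproducible across
platforms. A matrix with zero total variance yields a degenerate result
with zero components rather than an error.

`cluster_strains()` is Euclidean distance + furthest-neighbor (complete)
linkage via `stats::hclust`; merge heights are then the maximum pairwise
distance between merged clusters and are guaranteed non-decreasing. Ties
between equal-height merges follow `hclust`'s deterministic order —
documented because tie topology can differ between implementations; on
continuous score data exact ties have probability zero.

# Reciprocal best hits

The RBH decision logic is the package's own; the pairwise similarity
search behind it is pluggable:

* the built-in route is Smith–Waterman local alignment
  (`Biostrings::pairwiseAlignment`) with simple match/mismatch scoring and
  affine gaps, reporting identity as matches over alignment columns
  (gap columns count in the denominator);
* alternatively, precomputed directional hit tables in the tabular
  "outfmt 6" dialect (`qseqid sseqid pident length qlen slen bitscore`)
  can be supplied, so an external search tool can stand in at scale.

A pair $(i, j)$ is orthologous iff $i$'s top hit is $j$, $j$'s top hit is
$i$, both directional identities strictly exceed the threshold ("more
than 80%" is implemented as $>$, not $\ge$), and the alignment covers
strictly more than 80% of **each gene's own length**. Whether the
coverage criterion binds one or both genes is genuinely ambiguous in the
method's usual statement; both-genes is the default and
`coverage_mode = "query"` gives the one-sided variant. Top-hit ties are
broken by score, then identity, then lexicographic subject id.

# MLST, K2P and neighbor joining

Allele ids are assigned per locus in order of first appearance across
strains (1, 2, ...), and sequence types likewise over whole allele
vectors. These are internal labels, not database-issued allele numbers.
Locus fragments must arrive pre-aligned (equal length per locus); the
package deliberately performs no multiple alignment and rejects ragged
input with a message saying so.

The K2P distance from transition proportion $P$ and transversion
proportion $Q$ over comparable sites is

$$d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q).$$

Columns with a non-ACGT character in either sequence are excluded
pairwise (a documented convention; gap handling is not standardized).
When $1 - 2P - Q \le 0$ or $1 - 2Q \le 0$ the distance is undefined and
the package raises a saturation error instead of returning an infinite or
imaginary value.

`nj_tree()` is the Saitou–Nei algorithm with the standard Q-criterion and
two-point branch-length formulas. Ties in the criterion are broken by the
lowest active-index pair; negative estimated branch lengths are clamped
to 0 with the deficit moved to the sister edge (a common convention —
additive inputs never trigger it, and NJ's defining exactness on additive
matrices is preserved and tested). With three taxa the unique star
solution is used directly.

`bootstrap_support()` resamples columns of the **concatenated** alignment
(matching the single concatenated sequence the analysis studies, not
per-locus resampling), rebuilds K2P + NJ per replicate, and scores each
internal edge of the full-alignment tree by the percentage of replicate
trees containing the same bipartition. Replicates whose resampled
distances saturate are skipped and counted; supports are percentages of
successful replicates. Internally the alignment is compressed to site
patterns, so 1500 replicates — the conventional MLST choice and the
package default — cost seconds at MLST scale.

# The synthetic-data generator

The generator defines the study conditions under which the package's
guarantees are demonstrated:

* **Reference genome** — single replicon, non-overlapping forward-strand
  genes (the classifier itself supports both strands), CDS lengths
  uniform over 300–600 bp in steps of 3, intergenic spacers 50–150 bp,
  GC 0.45: typical orders of magnitude for dense bacterial gene layouts
  at miniature scale. Every gene starts ATG, ends in a stop, and has no
  internal in-frame stop.
* **Variants** — requested per-class counts are planted exactly, each
  unambiguous for its class under the classifier's rules: high = 1-bp CDS
  deletion or mid-CDS stop-gain SNP; moderate = missense SNP or 3-bp
  in-frame deletion; low = synonymous third-position SNP; modifier =
  intergenic SNP. Positions (including indel anchor bases) are unique per
  strain. Quality fields default above the filter thresholds so filtering
  and classification can be tested independently. The default pipeline
  draws per-strain counts of 1–5 high, 3–10 moderate, 5–15 low and 2–8
  modifier variants: enough signal for distinct strain profiles without
  crowding the miniature genome. Real per-gene variant-count
  distributions are not modeled; the generator aims at test coverage,
  not at mimicking any particular population.
* **Orthologs** — set B carries copies of the reference genes with
  exactly `round((1 - identity) * length)` random point substitutions
  (so realized identity is within a rounding error of the target, well
  inside ±2%), and a `drop_fraction` of genes (default 20%) receive no
  counterpart, mirroring gene-content differences between strains.
* **MLST loci** — seven 450-bp loci evolved site-independently along a
  known tree under the K2P model with `kappa = 4` (a typical bacterial
  transition bias), root sequence uniform random, rates normalized so
  branch lengths are expected substitutions per site. A designated strain
  group can sit on a zero-length subtree, planting a shared allelic
  profile and sequence type — the structure observed in real
  soybean-fermenting isolate panels, where a five-strain cluster shares
  one sequence type.

What passing tests on these inputs do **not** show: robustness to
misaligned or partial locus fragments, recombination within loci,
indel-containing orthologs, overlapping genes, or annotation of real
transcript models — all explicitly outside the generator's world and the
package's claims.

# Reproducibility and problem sizes

Every stochastic function takes an explicit integer seed and is
byte-deterministic given it; the pipeline derives per-stage seeds from one
master seed by fixed offsets, so a single integer reproduces an entire
run. The default study sizes — 8 strains, 60 genes, ~200 variants,
7 × 450 bp loci, 1500 bootstrap replicates, 20-replicate topology-recovery
experiments — were chosen once as the smallest panel on which every
stage's behavior (group structure, ortholog recovery, shared sequence
types, tree recovery) is clearly expressed.

# Known limitations

* The classifier handles one variant at a time against the reference;
  compound effects of nearby variants (e.g. two frameshifts restoring
  frame) are not modeled.
* Variants in overlapping genes are assigned to the first containing
  gene; the generator never creates overlapping genes.
* The built-in aligner is meant for test-scale gene sets; genome-scale
  searches should come in through hit tables.
* NJ and bootstrap conventions (tie-breaking, gap handling, clamping) are
  documented choices, not claimed to be bit-identical to any particular
  phylogenetics GUI's output.
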