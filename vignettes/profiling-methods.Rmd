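---
title: "Reference-mapped species-level profiling of 16S V1-V2 amplicons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-mapped species-level profiling of 16S V1-V2 amplicons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliprof)
```

# The analysis in one paragraph

`ampliprof` profiles gut microbial communities from 16S rRNA V1-V2 amplicon
reads and compares a case group against controls at the species level.
Instead of clustering error-prone reads directly into OTUs, reads are first
mapped to a curated full-length 16S reference database; the references that
attract reads are then clustered into species-level units ("rclusts"), and
only the minority of reads with no acceptable reference hit are clustered
de novo ("unmap_OTUs").  This reference-first design keeps sequencing
errors from inflating the species count, while the de-novo arm still
captures taxa missing from the database.  Downstream, the package computes
alpha diversity (observed OTUs, Chao1, Shannon), phylogeny-aware beta
diversity (UniFrac, PCoA, ANOSIM), per-species differential abundance
(Welch's *t*, Benjamini-Hochberg), a longitudinal consistency check of the
significant species, and a bootstrapped neighbor-joining phylogeny of the
shifted species.

# Pipeline stages and their parameters

## Reference database construction

Raw full-length 16S records pass three sequential removal rules: length
< 1,400 bp, then >= 4 ambiguous (non-ACGT) bases, then a eukaryote flag.
Applying the rules in this order makes the three removal counts disjoint,
so they add up with the retained count to the input size.  Eukaryote
detection is an input flag, not a classifier: curated collections annotate
it, and the synthetic generator plants it.

Retained records are dereplicated by greedy centroid clustering at 99.8%
identity: records are processed in descending length (ties broken by id)
and each joins the first centroid it matches at or above the threshold,
else founds a new centroid.  This mirrors the common centroid-search
convention and is fully deterministic.

## Identity, the alignment kernel, and two identity flavours

Every identity in the package comes from one semi-global (overlap)
alignment kernel: free end gaps on both sequences, match +1, mismatch -2,
affine gaps costing 5 + 2 per base, IUPAC ambiguity codes matching
whenever their base sets intersect.  Two summary statistics are derived
from the optimal path:

* **span identity** - matches / alignment columns within the aligned span.
  This is the BLAST-like quantity used for read mapping, where a separate
  coverage threshold (aligned read fraction >= 90%) guards against short
  spurious spans.
* **clustering identity** - matches / (alignment columns + unaligned query
  bases).  Overlap alignments of unrelated sequences degenerate into short
  perfect-looking spans; penalising the unaligned query remainder makes
  the quantity safe as a single-number criterion, and it equals span
  identity whenever the query aligns end to end.  All clustering
  (dereplication, rclust, de-novo OTUs, per-sample OTUs) and the
  taxonomy/phylogeny similarity matrices use this flavour.

Candidate pruning uses shared 8-mers.  A pair at identity *t* can lose at
most *k* distinct k-mers per edit, giving a conservative lower bound on
shared 8-mers; candidates below 0.75 x that bound are skipped without
aligning.  Alignments run in a band around the best shared-k-mer diagonal
(half-width 16 for read mapping, 24 for read-vs-read, 64 for full-length
references).  Both heuristics are exactness-checked in the test suite
against unbanded, unpruned alignment of every pair on small instances, and
against an independent implementation (Biostrings) of the same scoring.

## Read preparation

Reads are kept when their mean Phred quality is strictly above 25, the
forward primer (27Fmod, `agrgtttgatymtggctcag`) matches the 5' end within
2 IUPAC-aware mismatches, and trimming leaves a non-empty insert; the
reverse primer (338R) is trimmed when present but not required, since
454-style reads may end before it.  Each sample is then subsampled without
replacement to exactly 3,000 reads.  The package trims before subsampling
so that every prepared sample holds exactly 3,000 reads — the fixed-depth
contract that makes observed-OTU counts comparable across samples; a
sample that cannot reach the depth is a hard error, not a warning.

Per-sample randomness derives from one master seed by hashing the sample
id, so any single sample can be regenerated in isolation and the whole
study is byte-reproducible.

## Profiling

Mapping accepts the best hit at >= 96% span identity and >= 90% coverage;
ties break by identity, then coverage, then lexicographic reference id.
References receiving at least one read are clustered at 97% (full length)
into rclusts, and each read contributes its count to the rclust containing
its best-hit reference — reads are mapped once, never re-mapped to cluster
representatives.  Unmapped reads from the cross-sectional samples are
clustered de novo at 96%; longitudinal samples are quantified against the
units the cross-sectional study defined (their mapped reads inherit rclust
membership through their best-hit reference, their unmapped reads are
matched to the existing de-novo OTU representatives at the same
thresholds).  Longitudinal unmapped reads matching no existing OTU are
dropped: the validation asks how the *defined* species behave over time.

Clusters are retained when their mean relative abundance reaches 0.1% in
at least one group, with the group mean computed as the unweighted mean of
count/3,000 across the group's samples — the natural estimator under fixed
depth.

## Taxonomy

A cluster representative's best hit against the lineage-labelled reference
set names it at the level its clustering identity supports: species at
>= 96% (the mapping threshold, i.e. the pipeline's operative species-level
split), genus at [94%, 96%), phylum at [70%, 94%), otherwise unassigned.
Names always come from the best hit's lineage.  Hits within 0.3 percentage
points of the best are reported as a secondary hit rather than silently
dropped, since V1-V2 cannot separate some species pairs.  Aggregation to
genus or phylum sums counts within labels and pools shallower assignments
into "unclassified", conserving column totals.

## Alpha diversity

Observed OTUs come from greedy 96% clustering of each sample's 3,000
reads; Chao1 uses the bias-corrected form S~obs~ + F1(F1-1)/(2(F2+1)),
which stays defined without doubletons; Shannon entropy is reported in
nats (-sum p ln p, with 0 ln 0 := 0).  Base-e is a deliberate choice — it
is the default of the field's standard R tooling, against which the
implementation is cross-checked in the tests.

## Beta diversity

UniFrac runs over a midpoint-rooted NJ tree built from the retained
clusters' V1-V2 representative sequences: the representatives are
center-star aligned and p-distances taken on the aligned columns with
pairwise deletion, with no substitution-model correction.  (Raw pairwise
kernel identities are also available as a distance source, but for pairs
below ~67% identity the overlap optimum goes score-negative and collapses
to a degenerate short span, so the alignment-based distance is the
default.)  Unweighted UniFrac is the
branch length unique to either sample over the branch length of their
union; weighted UniFrac is sum l~b~ |A~b~ - B~b~| over branches, by
default normalized by its pairwise maximum sum (p~A~ + p~B~) x depth so it
stays in [0, 1].  PCoA is classical scaling; negative eigenvalues are
dropped from the explained-variance denominator and reported in the
output.  ANOSIM uses the rank-based R statistic with label permutations,
p = (1 + #{R\* >= R}) / (1 + n~perm~), defaulting to 10,000 permutations;
an exact mode enumerates all two-group assignments for small designs.
Within/between-group distance summaries are tested by label permutation of
the pair-set means rather than a *t*-test, because pairs sharing a sample
are not independent.

## Differential abundance and longitudinal validation

Welch's *t*-test runs per retained cluster on relative abundances
(equivalent to counts under fixed depth), two-sided, with
Benjamini-Hochberg q-values reported alongside.  The headline significance
flag uses the raw p < 0.05; q is always present in the output so either
criterion can be applied.  Fold changes are log10(case mean / control
mean) with the **not-detected rule**: a group mean of exactly zero is
replaced by one read (1/3,000) before the ratio, keeping fold changes
finite while honestly bounding how much a zero can claim.

Longitudinal validation recomputes, for each significant cluster and each
timepoint, log10(case mean / control mean at that timepoint), where the
timepoint mean averages subjects (a subject's replicate samples are
averaged first; a subject missing a timepoint is omitted from that
timepoint).  Sign consistency is the fraction of timepoints whose
fold-change sign matches the cross-sectional one; a persistent effect
scores 1.

## Phylogeny of the shifted species

Pairwise V1-V2 similarity, NJ (negative branch lengths clamped to zero
with the clamped total recorded), midpoint rooting for display, and
bootstrap support from 1,000 column resamples.  The multiple alignment
behind the bootstrap is a center-star alignment around the longest
sequence, with the pairwise step a standard global alignment (end gaps
charged) under the package's scoring: global rather than overlap, because
free end gaps let alignments of deeply diverged pairs collapse to a
degenerate span.  For the equal-length, indel-free amplicon sets this
package profiles the construction is exact, and it is deterministic — a
full progressive aligner would add machinery without changing these
inputs.  Bootstrap distances use pairwise deletion (columns
with a gap in either sequence of a pair are skipped), and taxa are sorted
internally so supports do not depend on input leaf order (NJ breaks ties
positionally).

# The synthetic study

The generator is first-class, tested code: it is the only way to exercise
the full pipeline end to end without large external downloads, and every
acceptance-level claim about the pipeline is a claim about its output.

**Backbone.** Species are leaves of a random birth-death tree.  Each
full-length gene is assembled from a conserved head, a concrete
27F-compatible primer site, a fast-evolving 310 bp V1-V2 core, the 338R
site, and a slowly evolving 1,120 bp tail (~1.5 kb total).  Rates are set
so cores diverge ~10-30% between species and full-length identities sit in
a realistic 88-96% band; a minimum terminal branch keeps every species
pair below ~93.5% core identity, so species remain separable at the
96%/97% thresholds.  Species closer than that are pruned — real 16S
databases contain such pairs, and the pipeline would (correctly) merge
them; the generator excludes this regime so that "one planted species, one
recovered cluster" is a meaningful test.

**Reference collection.** Database species get 1-3 near-identical copies
(<= 2 substitutions, always >= 99.8% identity) plus planted defect records
in the three removal categories, constructed disjointly.  A
metadata-only generator (`simulate_ref_metadata()`) produces record tables
with lengths, ambiguity counts and flags but no sequence strings for
database-scale accounting checks of the filter, where materialising
hundreds of thousands of 1.5 kb strings would add nothing.

**Design.** Defaults are the study conditions the pipeline targets: 20
case and 40 control cross-sectional samples; 18 longitudinal control
subjects at 9 timepoints; raw per-sample yields drawn from negative
binomials with mean +/- sd of 7,080 +/- 825 (case) and 7,590 +/- 616
(control); profiling depth 3,000; per-base substitution error rate 0.5%;
Phred qualities with per-read mean ~N(32, 4) and per-base scatter sd 3,
so roughly 4% of reads fail the Q > 25 filter.  The community holds 134
species, 10 of them absent from the 150-species reference database
("novel", the source of de-novo OTUs).

**Planted effects.** Twenty-one species-level effects — 2 enrichments and
19 depletions with |log10 FC| from 0.23 to 1.77, six of them on novel
species — are applied to the case composition before sampling; the planted
species keep exactly baseline x 10^FC and the remaining species are
renormalized proportionally (compositional closure).  Hosts are placed at
moderate baselines (0.4-3%) so that depleted species stay above the 0.1%
filter through their control-group mean.  Note a consequence of closure:
renormalization gives every non-planted species a small genuine shift
(~+0.03 log10 here), so "null" species in a closed community are not
exactly null — the FDR-control simulations therefore use independent
per-cluster abundances instead.

**Variability.** Per-sample compositions are Dirichlet draws around the
group mean with concentration 150 (coefficient of variation ~0.8 for a 1%
species), chosen once from a power analysis: with n = 20 vs 40 it puts
effects of |log10 FC| >= 0.4 at high power while leaving the weakest
planted effect (0.23) genuinely marginal — a realistic, not rigged,
recovery problem.  Longitudinal subjects draw a subject baseline at the
same concentration, then per-timepoint compositions around it at
concentration 500 (within-subject stability exceeding between-subject
variability, as repeated-sampling studies observe).

**What the generator does not emulate**: 454 homopolymer indels (errors
are substitutions only), chimeras, primer-site polymorphism beyond IUPAC
degeneracy, contaminants, and real-world reference taxonomy errors.
Passing tests therefore demonstrate the pipeline's logic and statistics,
not robustness to every artefact of real amplicon data; the alignment
kernel handles indels, but the end-to-end claims are substitution-regime
claims.

# Numerical choices and degenerate inputs

* Ties everywhere resolve deterministically (longest first, then
  lexicographic id; best hit by identity, coverage, id).
* A zero-variance Welch comparison with equal means returns t = 0, p = 1,
  flagged `degenerate`; with unequal means it returns p = 0.
* An all-zero distance matrix ordinates to a flagged degenerate PCoA with
  explained variance 0 rather than NaN.
* `observed_otus()` refuses depths other than the rarefaction depth.
* Chao1's bias-corrected form handles F2 = 0; Shannon errors on all-zero
  input.
* Mean quality is the arithmetic mean of integer Phred scores, not the
  error-probability mean.

# Problem sizes in the tests

The test suite runs the full study design once (60 cross-sectional plus
162 longitudinal samples at depth 3,000, about 666,000 profiled reads) for
the parameter-recovery check, and exercises everything else on reduced
instances: oracle equivalence on 500 reads x 12 references and on
engineered 20-60-sequence clustering problems, UniFrac against a
branch-enumeration oracle on 10-leaf trees, exact ANOSIM on 6 samples, and
statistical calibration on 200 simulated count tables.  These sizes were
chosen so each claim is checked where its failure modes live: heuristics
against exhaustive search where exhaustive search is exact, statistics at
the design's n where calibration matters.

# Known limitations

* The greedy centroid order (length, then id) is a convention; other
  orders give slightly different partitions near thresholds, which is
  inherent to greedy clustering.
* Banded alignment assumes near-diagonal optima; heavily indel-ed inputs
  would need larger bands (every band is a user-visible parameter).
* Welch's *t* on proportions is mildly anti-conservative at the rare end
  (measured type-I ~0.056 at nominal 0.05 under the study design); BH
  q-values are reported alongside raw p for stricter control.
* Compositional closure couples all species; the package deliberately
  reports standard relative-abundance statistics rather than
  log-ratio-transformed ones, matching the analysis tradition it
  implements.
* Taxonomy is best-hit, not probabilistic: a cluster equidistant from two
  genera is named by the marginally better hit, with the runner-up only
  surfaced via the secondary-hit field.
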