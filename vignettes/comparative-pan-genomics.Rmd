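---
title: "Comparative pan-genomics of two bacterial strain groups: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative pan-genomics of two bacterial strain groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

`salipan` compares two groups of bacterial strains — the motivating case is
*Lactobacillus salivarius* isolated from the swine intestine before (SBP)
and after (SAP) the legal ban of antibiotic growth promoters — through
their pan-genome. The questions it answers are the standard comparative
ones: which orthologous gene families are core, accessory, or exclusive to
a group or a strain; whether the groups differ in genome-level features
(size, CDS count, GC%); whether resistance or cell-surface gene panels
are distributed differently; which functional categories are enriched in
one group; whether presence/absence and housekeeping-gene phylogenies
separate the groups; and how qPCR measurements convert into absolute
genome copies for competition and biofilm assays.

## The pipeline model, stage by stage

### Pseudogene filtering

A CDS is treated as a pseudogene and removed before clustering iff any
codon before its final codon is TAA, TAG or TGA read in frame 0 (a
sequence whose length is not a multiple of 3 cannot be framed and is
removed as well, with its own reason code). This is deliberately a purely
syntactic rule: annotation-based pseudogene calls are out of scope.

### Ortholog clustering

All remaining CDSs of all strains are pooled. Two CDSs are linked when
their global pairwise nucleotide identity is at least the threshold
(default 0.85), and ortholog clusters are the *connected components* of
that graph — single linkage, so members are chained through intermediates
and need not all be mutually similar. Identity is defined as matching
columns divided by **all** aligned columns of the optimal global
alignment, counting gap columns as aligned and non-matching; the
denominator convention matters at the threshold and is stated here
because tools differ. The scoring scheme is match +1, mismatch −1, and an
affine gap of length L costs 2 + L; N never matches anything.

Aligning every pair is quadratic, so two screens run first: a provable
length bound (identity can never exceed `min(m,n)/max(m,n)`, since
matches are at most `min` and columns at least `max`) and a shared-10-mer
count (pairs sharing fewer than 20 ten-mers are skipped). The k-mer
screen is calibrated for i.i.d. substitution processes: at the 85%
boundary a true pair of ≥600 bp genes still shares on the order of a
hundred 10-mers, while unrelated pairs share about one, so the miss
probability is negligible — but a pathological periodic substitution
pattern could evade it. For that reason `prefilter = FALSE` provides the
exact brute-force route, and the test suite asserts that both routes give
identical partitions on pools of up to 200 CDSs. Pairs already connected
through earlier links are never aligned; this provably cannot change the
connected components. Paralogs are allowed: several CDSs of one strain
may join one cluster and are counted in the copy-number matrix.

### Consensus sequences

Each cluster gets a majority-vote consensus: members of equal length are
stacked directly, otherwise members are star-aligned to the longest
member (insertions relative to the reference dropped, deletions padded).
Per column the plurality base wins, ties break by the fixed order
A < C < G < T, and columns where gaps hold a strict majority are dropped.
This replaces assembly-based consensus building; for the tight clusters
the identity threshold produces, the majority vote and an assembler agree.

### Pan-genome matrices and summary

`copy_number[i,j]` counts strain *i*'s CDSs in ortholog *j*; presence is
its indicator. Core orthologs are present in all strains, strain-specific
in exactly one, group-exclusive in at least one member of one group and
none of the other; the sharing histogram counts orthologs by the number
of carrying strains. Note that "group-exclusive" includes that group's
strain-specific genes, matching the usual reading of group-specific
ortholog counts.

### Fragment ANI

Average nucleotide identity follows the BLAST-style fragment recipe: the
query genome is cut into consecutive 1,020-bp fragments, each is locally
aligned against the subject, and fragments whose best hit covers ≥70% of
the fragment at ≥30% identity contribute their identity to the mean. Both
filter parameters and the fragment size are the conventional ANIb values
and are fixed for reproducibility (they are exposed as arguments).

### Reference-panel screening

Ortholog consensi are screened against labelled gene panels (antibiotic
resistance categories such as lincosamide/tetracycline, EPS synthesis,
extracellular-protein families). Each (consensus, panel gene) pair is
aligned **locally** — reference genes may be fragments of longer CDSs, so
local alignment mirrors BLAST semantics — and both the identity and the
E-value come from that single alignment. A pair is accepted iff identity
≥ 0.90 **and** E ≤ the operational zero. The E-value uses the
Karlin–Altschul form `E = K·m·n·exp(−λS)` with the standard ungapped
nucleotide constants λ = 1.33, K = 0.621. A printed "E-value = 0" in
BLAST output is a display artifact; a literal floating-point zero from a
re-implemented formula would be representation-dependent, so the
operational threshold is 1e-180, recorded in the configuration and
logged. Rows are reported down to identity 0.5 so near-misses stay
auditable.

One consequence of the *joint* rule deserves emphasis: at these constants
an alignment needs roughly 450 matched-dominated columns for E ≤ 1e-180,
so genes much shorter than ~450 bp can never satisfy the rule even at
100% identity. The synthetic generator therefore defaults to gene lengths
of 600–1200 bp — also the realistic scale, as the typical bacterial CDS
is about 900 bp.

Protein-family labels (choline-binding, LPXTG, lipoprotein anchor, LysM,
peptidoglycan-binding, WXL) ride along as panel metadata; HMM domain
scanning is explicitly out of scope and replaced by the labelled panel.

### Group statistics

Genome features are summarised per group as mean and sample SD (n−1) and
compared by a two-sided *Welch* unequal-variance t-test. Welch rather
than pooled variance is a deliberate choice: on the 21-isolate feature
table shipped with the package, only the Welch test reproduces the
published CDS-count p-value (0.0009); the pooled test gives 0.014. The
pooled variant stays available behind `pooled = TRUE`. Conventions:
both samples constant and equal gives t = 0, p = 1; both constant and
different gives p = 0; fewer than two values per group is an error, not
a silent NA.

Subsystem enrichment builds, per functional category, the 2×2 table of
(genes in category, all other categorised genes) × (group 1, group 2),
counts summed over the strains of each group, and applies the exact
two-sided Fisher test (minimum-likelihood two-sided definition — the sum
of all hypergeometric probabilities not exceeding the observed table's —
which is what `fisher.test` implements; alternatives such as doubling the
one-sided p differ and are not used). The reported odds ratio is the
sample cross-product ratio ad/bc. No multiple-testing correction is
applied by default, matching the raw P < 0.05 screening convention;
Benjamini–Hochberg is available via `adjust = "BH"`.

### Phylogenetics

*Presence trees.* Strains are clustered on the Euclidean distance between
binary presence rows (presence, not copy number — where the two differ
because of paralogs, presence is used) with average linkage by default.
Support comes from an ordinary bootstrap: ortholog columns are resampled
with replacement, the dendrogram recomputed, and each original node's
leaf set counted across replicates. These are plain bootstrap
proportions (BP); the multiscale AU bootstrap is out of scope, so
supports are conservative.

*Sequence trees.* Distances are Tamura–Nei (TN93) with base frequencies
estimated per pair and pairwise deletion of gap/N sites. The published
workflow's "Maximum Composite Likelihood" shares substitution parameters
across pairs; the per-pair TN93 closed form is used here instead and the
difference is documented — on desk-scale data the topologies, which are
the claims of interest (group separation), are insensitive to it, and in
the equal-frequency limit TN93 reduces to the Jukes–Cantor form
−(3/4)·ln(1 − 4p/3), which the tests verify. Saturated pairs (a
non-positive logarithm argument) are flagged and set to a configurable
ceiling (default 3 substitutions/site) rather than dropped silently.

Trees are built by a canonical Saitou–Nei neighbor-joining
implementation: Q-criterion agglomeration, taxa sorted by label first so
the result is order-invariant and Q-ties resolve deterministically,
negative branch lengths clamped to zero with the length moved to the
sister edge (their sum is preserved). On additive matrices NJ provably
recovers the generating tree, and the tests assert exact topology and
branch-length recovery on random additive trees, cross-checked against
an independent implementation.

Bootstrap consensus trees resample alignment columns, build one NJ tree
per replicate, and return the strict-majority (>50%) consensus with
per-split support percentages. An all-identical alignment carries no
signal and returns a star tree flagged `undefined_support`. MLST
concatenation uses the seven housekeeping loci pstB, rpsB, pheS, ftsQ,
nrdB, rpoA, parB in that fixed order.

### Quantification

DNA mass converts to genome copies as
`copies = mass · N_A / (genome_size_bp · m_bp)` with m_bp = 655
g·mol⁻¹·bp⁻¹ — the unique conventional base-pair molar mass (among
650/655/660) that reproduces 4.16×10² copies per pg at the 2.21 Mbp mean
genome size of the 21 isolates; both constants are configurable. The
standard curve is an OLS fit of Cq on log₁₀(copies), reporting slope,
intercept, r², and amplification efficiency 10^(−1/slope) − 1 (1.00 for
perfect doubling chemistry, slope −log₂10 ≈ −3.32). Unknowns invert the
curve; Cq values outside the fitted standard range are flagged as
extrapolated, never silently trusted. Crystal-violet absorbance converts
to dye mass through an OLS standard; readings below the blank clamp to 0
with a flag. Competition fold change is value(48 h)/value(24 h) per
strain, strains missing a time point or with zero baseline are excluded
with a warning, and the group test runs on *log* fold changes because
counts act multiplicatively (the original analysis does not state its
test scale; the log scale is this package's choice).

## The synthetic-data generator

Every downstream stage is testable without external downloads because
the generator plants a known truth:

- a pan-gene pool of core, accessory (per-strain carriage probability
  0.5 by default — the real sharing structure of the motivating isolates
  is unknown, so it is a parameter, not an assertion), group-specific and
  strain-specific orthologs;
- CDS-like ancestral genes (ATG, sense codons, terminal TAA) of 600–1200
  bp; per-strain copies mutated by i.i.d. per-site substitution, uniform
  over the three alternatives, with **no indels by default** so identity
  stays analytically predictable;
- substitutions that would create an in-frame premature stop are
  reverted to the ancestral codon. This models purifying selection
  against nonsense mutations and, just as importantly, keeps the truth
  table exact: a CDS carries a premature stop iff its pseudogene flag is
  set, so the filter can be checked for *exact* agreement;
- pseudogenes planted by rewriting one internal codon (within the first
  80% of the gene, never the first or last codon) to TAA;
- reference panels derived from ancestral ortholog sequences with an
  *exact* count `round((1−identity)·L)` of substitutions at distinct
  sites, so the realised identity equals the request — at the 0.90
  acceptance boundary a Bernoulli mutation process would randomly land on
  either side of the rule and no exact truth comparison would be
  possible;
- MLST loci with fixed group-diagnostic substitutions plus per-strain
  noise; and measurement tables with Gaussian (dye mass) or log-normal
  (cell count) replicate noise around group means.

One master seed drives everything; per-stage child seeds are derived by
fixed offsets so stages are individually reproducible.

What the generator does **not** emulate: indel variation within
orthologs (available as an option but off by default), horizontal
transfer, assembly artifacts, contig structure, strand orientation,
GC-content gradients, and realistic codon usage. Passing tests therefore
demonstrate that the pipeline's logic is correct under its stated model,
not that the thresholds are optimal for any particular real data set.

## Numerical choices and degenerate inputs

- Identity threshold 0.85, panel threshold 0.90, α = 0.05, 1000
  bootstrap replicates, 2.21 Mbp and 655 g/mol/bp are the pipeline's
  defaults and all configurable in one `pipeline_config()` object that
  is echoed into every output directory.
- Within-ortholog divergence defaults to 0.02 in the generator; truth
  clusters are recoverable whenever divergence < (1 − threshold)/2,
  which the spec-level invariant tests check by brute force.
- Deterministic tie-breaks everywhere: consensus ties by base order,
  cluster ordering by size then lexicographically smallest member,
  NJ Q-ties by sorted taxon order — runs are diffable.
- Degenerate inputs fail loudly and early: empty FASTA, duplicate ids,
  non-ACGTN characters, single-group statistics, one-replicate group
  tests, unfitted quantification models, zero competition baselines.
- Validation designs in the test suite use 6 + 15 strains (the group
  sizes of the motivating study) over pools of ~100–120 orthologs and
  600–1200 bp genes, qPCR standards as triplicate ten-fold dilutions
  spanning 4.16×10²–4.16×10⁷ copies, and 500-seed simulation sweeps —
  sizes at which every documented recovery property holds exactly or at
  its stated rate.

## Known limitations

- Single-linkage chaining can, in principle, merge gene families through
  intermediate sequences; at 85% nucleotide identity this matches the
  original workflow's behaviour but is not a phylogenetic orthology
  inference (no synteny, no tree reconciliation).
- The k-mer prefilter is calibrated for i.i.d. substitution processes;
  use `prefilter = FALSE` for adversarial inputs.
- TN93 is a per-pair approximation to shared-parameter composite
  likelihood distances; branch lengths should not be over-interpreted.
- Bootstrap proportions on presence/absence dendrograms are ordinary BP,
  not AU values, and are known to be conservative.
- The Karlin–Altschul constants are the ungapped nucleotide values; the
  alignments scored are gapped, so E-values are approximate and serve as
  the operational threshold they implement, not as literature-grade
  significance estimates.
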