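---
title: "Methods: gene-family characterization with genefam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family characterization with genefam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genefam)
library(dplyr)
```

`genefam` implements the analysis stages of a genome-wide gene-family
survey — the kind routinely run on plant transcription-factor families such
as the grapevine basic helix-loop-helix (bHLH) family: codon-usage bias,
duplicate/triplicate detection, Ka/Ks selection analysis, intron-phase
structure analysis, promoter cis-element scanning, replicate-aware
differential expression, and a bootstrapped neighbor-joining phylogeny.
Every stage consumes and returns plain tabular objects (tibbles), so whole
pipelines compose with the pipe. A synthetic-data module generates every
input type with known ground truth; the test suite leans on those
round-trips wherever the real inputs (a full genome, microarray series)
are out of reach.

## Codon-usage bias

For a gene's 61 sense-codon counts the package computes GC, GC3s, RSCU,
Wright's effective number of codons (ENC), and the reference-dependent
indices CAI, FOP and CBI.

**GC3s** is the G+C fraction at third positions of *synonymously
degenerate* codons: Met (ATG), Trp (TGG) and stops contribute no
synonymous choice and are excluded. Genes with no eligible codon report
`NA` rather than a fabricated 0.

**RSCU** of codon $j$ in a family of size $k$ is $k x_j / \sum x$; codons
of families never observed are undefined (`NA`), which keeps downstream
averages honest.

**ENC (observed)** follows Wright's estimator
$\mathrm{ENC} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$,
with family homozygosity $F = (n\sum \hat p^2 - 1)/(n-1)$. Numerical
choices: families with $n < 2$, or with $\hat F = 0$ (which would
contribute an infinite term), are dropped from their degeneracy-class
mean; a wholly missing class is imputed from the mean of its nearest
available neighbour classes, Wright's own recommendation. The result is
clamped to $[20, 61]$ — 20 means one codon per amino acid, 61 random
usage — and genes under 30 codons are flagged low-confidence.

**ENC (expected)** uses the corrected Wright null curve
$\mathrm{ENC}_{exp}(s) = 2 + s + 29/(s^2 + (1-s)^2)$, where $s$ is GC3s.
(A commonly reprinted form collapses the denominator to a constant and
cannot produce the curve; the corrected form gives 60.5 at $s = 0.5$ and
tends to 32 as $s \to 1$.) Note the curve is only near-symmetric: the
linear term gives $\mathrm{ENC}_{exp}(s) - \mathrm{ENC}_{exp}(1-s) =
2s - 1$ exactly, and the maximum sits just above $s = 0.5$.

**CAI / FOP / CBI** all require a reference set, and CodonW-style defaults
are organism-specific, so there is deliberately *no silent default*:
`reference_weights()` must be built explicitly, normally from a
user-designated highly expressed gene set, with +0.5 pseudocounts so
unobserved codons keep positive weight. Optimal codons are the
argmax-RSCU codon per family; ties break lexicographically and are
reported. CAI is the geometric mean weight over the gene's codons
(Met/Trp/stops excluded); FOP is the optimal fraction over degenerate
amino acids; CBI rescales FOP against its uniform-usage expectation,
so 0 means random usage and negative values mean avoidance.

`correlate_features()` reports Pearson correlations (Spearman optional) of
GC/GC3s/gene length/mean exon length against FOP/CBI/CAI with two-sided
p-values flagged at $p < 0.01$; family-survey tables usually print these
at one decimal, so a rounded column is included.

## Duplicates and triplicates

All $\binom{n}{2}$ protein pairs are aligned globally (Needleman–Wunsch via
`Biostrings::pairwiseAlignment`, BLOSUM62, gap open 10, extend 0.5 — the
classic needle defaults). Two inclusive stringency standards classify
pairs: low = identity ≥ 30% covering ≥ 70%, high = identity ≥ 50% covering
≥ 90%.

Two readings of these thresholds were genuinely open:

* *Coverage denominator.* "Covering X% of the protein length" does not say
  which protein; the package uses the longer one (the conservative
  reading) and counts the residues of that protein lying inside the
  non-terminal-gap span of the alignment, so coverage is always in
  $[0, 1]$.
* *Identity denominator.* With needle-style gap penalties, gap-excluded
  (BLAST-style) identity of *unrelated* 200-aa proteins averages about
  0.26 and can cross 0.30, because cheap gap extension aligns only the
  residues that happen to match; a 30%-identity screen under that
  convention misclassifies random pairs as paralogs. The default is
  therefore needle-style identity over all alignment columns (~0.16 for
  random pairs), with the gap-excluded variant available via
  `identity_denominator = "gap_excluded"`.

Triplicate groups are the 3-cliques of the duplicate-pair graph (larger
cliques are reported as all their 3-subsets, with a notice). Mechanism
classification is intentionally modest: *tandem* requires the same
chromosome, ≤ 200 kb apart and at most 5 intervening family genes;
*segmental/large-scale* requires user-supplied collinear-block evidence —
genome-wide synteny detection is out of scope; anything else is
*unclassified*.

## Ka/Ks and selection regime

`backtranslate_alignment()` threads each CDS through its gapped protein
row (gaps become whole-codon `---` triplets; any CDS/protein mismatch is
an error naming the first offending codon). `nei_gojobori()` then applies
classic NG86 counting:

* fractional synonymous/nonsynonymous *sites* per codon, averaged over the
  two sequences. Mutations that would create a stop codon are counted as
  nonsynonymous so that sites partition exactly as $S + N = 3 \times$
  codons;
* *differences* averaged with equal weight over the minimal mutational
  pathways of each multi-hit codon, excluding pathways that pass through a
  stop codon (all pathways are used if every one is blocked);
* Jukes–Cantor correction $d = -\tfrac34\ln(1 - \tfrac{4p}{3})$, with
  saturation ($p \ge 3/4$) reported as an undefined distance;
* $\omega = K_a/K_s$ only when $K_s > 0$; gap and stop columns are dropped
  before counting.

The regime split is strict by default ($\omega < 1$ purifying, $> 1$
positive), with an optional neutral band. NG86 is a transparent counting
estimator, not a maximum-likelihood codon model; published $\omega$ values
computed with other estimators will differ in the third decimal, which is
why exact reproduction of published per-pair values is not attempted —
their *classification* (all published triplicate-pair values < 1, hence
purifying) is reproduced instead.

## Gene structure

`parse_gene_models()` reads GFF3 (via `rtracklayer`), keeps the longest
CDS per gene (families are reported one structure per gene), orders CDS
exons in transcript order (descending genomic coordinates on the minus
strand) and validates: overlapping CDS exons are an error; a CDS length
not divisible by 3 flags the model and excludes it from phase analysis.
All coordinates are GFF3 1-based inclusive throughout.

Intron phase $i$ = (cumulative CDS length of exons $1..i$) mod 3. An
internal exon is *symmetric* when its two flanking introns share a phase.
Terminal exons have one flank and are excluded from the symmetric/
asymmetric tally by default; `count_terminal = TRUE` classifies them
against a virtual phase-0 boundary, since published symmetric-exon counts
do not always state which convention was used. Phases are defined on CDS
only; UTR structure is ignored.

## Promoter scanning

Promoters default to 2000 nt upstream of the translation start — the
conventional choice for plant promoter scans when the original tool's
setting is unrecorded — extracted strand-aware (minus-strand promoters are
reverse-complemented so position 1 is most distal) and clipped with a flag
at contig edges.

Scanning is IUPAC consensus matching (PlantCARE-style presence/absence,
not PWM scoring). Semantics: degenerate letters in the *consensus* match
their sets; an `N` in the *sequence* never matches; overlapping hits are
all reported; for a palindromic consensus (e.g. the G-box CACGTG) forward
and reverse hits coincide, so only the + strand record is kept. The
bundled motif table (G-box CACGTG, E-box CANNTG, ABRE ACGTG, MBS CAACTG,
MRE AACCTAA, HSE AAAAAATTTC, LTR CCGAAA, CRT/DRE RCCGAC, P-box CCTTTTG,
TATC-box TATCCCA) is representative data, not code — PlantCARE's exact
strings vary across releases, and the table is meant to be edited.
`summarize_elements()` reduces hits to per-gene booleans and "any-of"
group fractions (e.g. the share of flavonoid-pathway promoters carrying a
G-box or E-box).

## Differential expression

Intensities are RMA-normalized microarray values, already positive and on
a linear scale. High expression is a strict cut: log2 value > 14.

Per gene, with control and treatment replicates paired by index:

* means over replicates; fold change = ratio of raw means (this is what
  published fold columns reproduce exactly — not log-scale or
  per-replicate ratios);
* one-tailed paired t-test on the raw intensities (treatment > control,
  df = n − 1). Zero-variance differences make $t$ undefined; p is then
  reported as 0 or 1 by the sign of the mean difference, with a flag;
* induction = fold ≥ 1.5 (inclusive) with the treatment mean above the
  control mean; the p-value is reported but not filtered on, matching the
  fold-change-based convention of microarray family surveys (published
  induced rows carry p-values up to 0.23).

Table output rounds half-up to 2 decimals; full precision is retained
internally. The bundled GSE31594 cold-stress replicate table ships with
its published means/folds/p-values; four of its 25 rows print fold values
that disagree with the ratio of their own printed means (they equal the
third-replicate ratio instead) and are flagged as internally inconsistent
rather than silently matched.

A caveat the calibration tests surface: under multiplicative log-normal
noise the raw-intensity paired t-test is mildly conservative (its null
rejection rate at nominal 5% sits near 3–4% for three replicates), because
the paired differences are right-skewed. This is a property of the
published procedure being reproduced, not of the implementation; the
calibration is therefore estimated from 4 × 1000 null simulations.

## Phylogeny

Protein distances are p-distances with pairwise gap deletion (the common
default for distance trees on protein alignments); a Poisson correction is
available by flag. The neighbor-joining implementation is the standard
Saitou–Nei algorithm with the Studier–Keppler $Q$ criterion; ties in $Q$
break at the lowest (row, column) pair so results are reproducible;
negative branch lengths are clamped to zero with the clamped total
recorded. The multiple alignment itself is consumed, not computed —
re-implementing MSA would dwarf the package, and family surveys treat it
as an external preprocess.

Bootstrap support resamples alignment columns with replacement, rebuilds
the tree per replicate, and scores each original internal edge by the
percentage of replicates containing the same bipartition (bipartitions are
canonicalized by the side not containing the alphabetically first taxon).
Clade calling at a support threshold (default 70) takes, for each passing
bipartition, the minority side as the candidate clade (both sides for an
even split), keeps maximal candidates under inclusion, and reports
everything outside a called clade as an orphan — the "k clades plus
orphans" reporting pattern. Note that with the minority-side convention a
taxon attached at the exact centre of a balanced tree may belong to no
minority side; such taxa are reported as orphans even under universal
support, which matches how such genes are described in family surveys.

## Synthetic data: what it emulates, and what it does not

The generator produces every input with known truth, all randomness
flowing from one locally seeded RNG per call (identical seed + arguments
give byte-identical output, and the caller's RNG state is untouched):

* **CDS** start with ATG, contain no internal stop, and hit a target GC3s
  through a single logistic weight on third-position G/C within each
  synonymous family, calibrated by solving for the expected GC3s under
  uniform amino-acid usage. Targets of exactly 0 or 1 restrict the choice
  set outright.
* **Divergence** (`diverge_cds`) plants synonymous/nonsynonymous change
  counts derived by inverting the Jukes–Cantor correction on the NG86
  site counts of the input, accepting random point mutations (one per
  position, never creating a stop) until the quotas fill. This puts the
  planted $\omega$ on the same counting scale the selection module
  estimates, which is the point: parameter recovery is a round-trip test,
  not a codon-model simulation.
* **Gene models** insert introns (canonical GT..AG ends) at random cut
  points consistent with requested phases, on either strand.
* **Promoters** overwrite a GC-controlled background with concrete
  realizations of planted consensi; overlapping plants are an error.
* **Expression** draws a per-gene base intensity uniformly from
  `base_range` (default 50–500, the mid-range of RMA-normalized
  intensities in the bundled table), then generates control replicate
  $i$ and, from it, treatment replicate $i$ times the planted fold —
  the paired structure the paired t-test assumes. Noise is mean-1
  multiplicative log-normal with coefficient of variation `noise_cv`
  (default 0.2, comparable to the replicate scatter in the bundled
  table); `noise_cv = 0` puts a planted 1.5 fold exactly on the inclusive
  induction threshold.

What passing the round-trips does *not* show: real CDS have
amino-acid composition and codon autocorrelation the uniform sampler
lacks; real paralogs diverge with transition/transversion and rate
heterogeneity NG86-scale planting ignores; microarray intensities have
probe effects and intensity-dependent variance the log-normal model
flattens; real promoters are not i.i.d. background. The round-trips
validate the *computations*, not the biology.

## Problem sizes

The shipped tests and acceptance script use sizes chosen to exercise every
code path at desk scale: 100–200-codon gene sets of ~100 genes for codon
statistics, 150–520-codon pairs for Ka/Ks recovery, families of ~10
proteins for duplicate detection, 5–8-taxon trees for exact NJ round-trips
(with 50–100 bootstrap replicates where support values are needed), and
4 × 1000 null genes for the DE calibration.
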