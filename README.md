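# genefam

Genome-wide characterization of plant gene families, built around the
grapevine basic helix-loop-helix (bHLH) transcription-factor family.
Surveys of this kind answer a fixed set of questions about a family of
~100 genes: how biased is their codon usage and why; which members arose
by duplication or whole-genome triplication and under what selective
pressure; how are their exon/intron structures organized; which
cis-regulatory elements sit in their promoters; which members respond to
stress in expression data; and how do they group phylogenetically.
`genefam` implements each of those stages as composable, tested R
functions operating on tibbles.

What the package computes:

* **Codon usage** — per-gene GC, GC3s, RSCU, Wright's effective number of
  codons (ENC, clamped to [20, 61]) with the expected curve
  `ENC_exp(s) = 2 + s + 29/(s² + (1−s)²)`, and the reference-set indices
  CAI, FOP, CBI; feature–index correlation tables; ENC-plot tables and a
  ggplot (`plot_enc()`).
* **Homology** — all-vs-all Needleman–Wunsch protein alignments (BLOSUM62,
  gap 10/0.5), duplicate pairs under inclusive low (≥30% identity, ≥70%
  coverage) and high (≥50%, ≥90%) stringency standards, triplicate groups
  as 3-cliques, and tandem vs segmental mechanism calls.
* **Selection** — codon-aware back-translation of protein alignments and
  Nei–Gojobori (1986) Ka/Ks with Jukes–Cantor correction; regime
  classification (ω < 1 purifying).
* **Gene structure** — GFF3 parsing, intron phases
  (cumulative CDS length mod 3), symmetric/asymmetric exon classes,
  family summaries, intron-less gene lists.
* **Promoters** — strand-aware promoter extraction (default 2000 nt
  upstream of ATG) and IUPAC consensus scanning for G-box/E-box, ABRE,
  MBS, HSE, LTR, CRT/DRE and relatives; presence matrices and group
  fractions.
* **Expression** — log2 high-expression calls (> 14), paired fold-change
  differential expression with a one-tailed paired t-test on
  RMA-normalized intensities, inclusive 1.5-fold induction calls, and
  union counts across timepoints. The published GSE31594 cold-stress
  replicate table for the grape bHLH family is bundled
  (`grape_cold_bhlh()`), as are the published triplicate-pair ω values
  (`grape_triplicate_omega()`).
* **Phylogeny** — p-distances with pairwise gap deletion, Saitou–Nei
  neighbor joining with documented tie-breaking, bootstrap bipartition
  support, and clade/orphan calls at a support threshold.
* **Synthetic data** — seeded generators for CDS with controllable GC3s,
  diverged paralogs with a target ω and Ks, gene models with planted
  intron phases, promoters with planted motifs, and paired-replicate
  expression matrices with planted folds; every analysis stage is tested
  as a round-trip against this ground truth.

## Worked example

Differential expression on the bundled cold-stress replicates, then codon
statistics on a synthetic family:

```r
library(genefam)
library(dplyr)

t3 <- grape_cold_bhlh()
de_8h <- t3 |>
  filter(timepoint == "8h") |>
  differential_expression(c("ck1", "ck2", "ck3"), c("cold1", "cold2", "cold3")) |>
  format_de_table()
de_8h
#> # A tibble: 13 × 7
#>   gene_id   mean_control mean_treatment  fold p_value flat_variance induced
#>   <chr>            <dbl>          <dbl> <dbl>   <dbl> <lgl>         <lgl>
#> 1 VvbHLH021         3.05          165.  54.2     0    FALSE         TRUE
#> 2 VvbHLH083        41.4            64.1  1.55    0.18 FALSE         TRUE
#> 3 VvbHLH046        36.3            68    1.87    0.02 FALSE         TRUE
#> 4 VvbHLH090       269.            414.   1.54    0.06 FALSE         TRUE
#> # …
```

Thirteen genes pass the inclusive 1.5-fold rule at 8 h; pooling the three
timepoints gives the family's cold-induced census:

```r
per_tp <- lapply(split(t3, t3$timepoint), function(tp)
  select_induced(differential_expression(tp, paste0("ck", 1:3), paste0("cold", 1:3))))
length(union_induced(per_tp))
#> [1] 17
```

Codon-usage statistics and the ENC plot for a synthetic family (a real
analysis would read a CDS FASTA with `Biostrings::readDNAStringSet()` and
supply a reference set of highly expressed genes):

```r
cds <- generate_cds(60, c(120, 250), gc3_target = 0.45, seed = 42)
ref <- reference_weights(cds)      # explicit reference, no silent default
stats <- codon_usage_stats(cds, ref)
enc_plot_table(stats)
#> # A tibble: 60 × 5
#>   gene_id  gc3s enc_obs enc_exp residual
#>   <chr>   <dbl>   <dbl>   <dbl>    <dbl>
#> 1 gene060 0.367    61      56.5     4.46
#> 2 gene033 0.381    61      57.2     3.75
#> 3 gene001 0.385    51.0    57.5    -6.43
#> # …
plot_enc(stats)                    # points vs Wright's expected curve
```

Genes on the curve use codons as expected from their base composition
alone; genes far below it carry bias beyond composition. `residual` is
`enc_obs − ENC_exp(gc3s)`.

## Notes and limitations

* Ka/Ks is the transparent NG86 counting estimator, not a
  maximum-likelihood codon model; ω values from other estimators differ
  slightly, so published per-pair values are classified, not reproduced
  digit-for-digit.
* CAI/FOP/CBI depend entirely on the chosen reference set; the package
  refuses to guess one.
* The bundled motif table is representative, editable data; it is not a
  copy of any PlantCARE release.
* Mechanism calls beyond tandem require user-supplied collinearity
  evidence; synteny detection is out of scope, as are MSA construction,
  RMA normalization and de-novo motif discovery.

See the methods vignette (`vignettes/genefam-methods.Rmd`) for the models,
conventions and design decisions in full.
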