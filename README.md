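# dgescreen

Replicate-calibrated Digital Gene Expression (DGE) screening across
perturbations.

## What this solves

Tag-count transcriptomics compares conditions by counting reads mapped
to a reference transcriptome. Deciding which genes respond to a
perturbation — and which apparent responses are sampling noise,
injection damage, or contamination — requires a calibrated per-gene
statistic and a set of cross-condition filters. This package implements
that workflow for screens in which one perturbation (e.g. a morpholino
knockdown of a signaling ligand) is compared against an un-manipulated
control alongside several related perturbations, as used to dissect
Wnt/β-catenin versus planar-cell-polarity signaling in cnidarian
embryos. It is aimed at analysts reproducing or stress-testing this
class of screen without access to raw reads: a negative-binomial
simulator with planted ground truth makes every stage testable.

## The statistic

For a gene with counts $C_1, C_2$ in two libraries (totals $n_1, n_2$),
on the MA plane

$$M = \log_2(C_1+pc) - \log_2(C_2+pc),\qquad
A = \tfrac12(\log_2(C_1+pc)+\log_2(C_2+pc)),$$

the random-sampling null partitions $K = C_1+C_2$ binomially with
$p_0 = n_1/(n_1+n_2)$, giving

$$z = \frac{M - \log_2\frac{p_0}{1-p_0}}
           {\sqrt{1/\big((\ln 2)^2 K p_0 (1-p_0)\big)}} .$$

When technical replicates exist, the theoretical spread is replaced by
the empirical spread of $M$ between replicates, estimated in sliding
windows along $A$ (the MATR calibration). Downstream, genes are tiered
at $|z| \ge 3.3$ and $|z| \ge 5$, flagged as injection artifacts
(elevated in all knockdowns) or contaminants (depleted in the primary
and opposite-phenotype knockdowns), and the remaining strict responders
are split into four DGE classes by their joint primary/secondary
knockdown response. The package also ships the downstream concordance
tools (class × expression-pattern tallies, exact 2×2 Fisher test with an
enumeration oracle, ΔΔCt fold changes) and a six-frame best-ORF
predictor for assembled transcripts.

## Worked example

Simulate the default five-condition experiment (20,000 genes, mean
depth 100, planted response classes, artifacts and contaminants), run
the screen, and evaluate recovery:

```r
library(dgescreen)
res <- run_pipeline(sim_config(seed = 7), verbose = FALSE)
res$recovery$class_recovery
#> [1] 0.94875
res$recovery$stats
#>         label     n precision recall
#> 1      class1   200  0.900000  0.945
#> 2      class2   200  0.994152  0.850
#> 3      class3   200  1.000000  1.000
#> 4      class4   200  1.000000  1.000
#> 5    artifact    50  1.000000  1.000
#> 6 contaminant    50  1.000000  0.800
#> 7        null 19100  0.998484  1.000
```

About 95% of planted class-1..4 genes receive their true class; the
depleted classes (1 and 2) and the contaminants lose some recall in the
low-abundance tail, where a 16-fold depletion cannot clear the strict
$|z| \ge 5$ threshold (see the methods vignette). The concordance stage
on the shipped annotated-transcript table:

```r
cpt <- class_pattern_table(load_table1_fixture())
cpt$counts
#>      pattern
#> class  O IE  A  D D_A
#>     1 11  2  0  0   0
#>     2  1 11  0  0   0
#>     3  0  0  9  0   1
#>     4  0  0  1  7   3
```

i.e. 11/13 class-1 transcripts are oral-type, 11/12 class-2 transcripts
ingressing/endodermal, 9/10 class-3 transcripts aboral, and class 4
holds 7 delayed plus 3 mixed delayed/aboral of 11 — the class
assignment from paired knockdown z-scores predicts where and when a
transcript is expressed.

The numbered scripts under `analysis/` run the same stages as a
narrative workflow (simulate → calibrate → screen → concordance → ORF
prediction), writing their tables under `results/`.

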