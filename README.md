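# sicompat

Dissecting multi-locus gametophytic self-incompatibility (SI) from diallel
cross-pollination data.

Outbreeding grasses such as perennial ryegrass prevent self-fertilisation
through two unlinked, polyallelic loci, *S* and *Z*, acting
complementarily: a pollen grain is rejected only when its haploid allele at
**every** SI locus is present in the stigma's diploid genotype. Between two
fully heterozygous plants the expected compatible fraction is therefore one
of 0, 1/2, 3/4 or 1, and the relation is directional. In a population with
unrestricted allelic diversity the raw diallel of ordinal pollination
scores (0–10, with missing cells) is too complex to read against the model
directly. `sicompat` is for geneticists and breeders who want to distil
such a diallel into mappable phenotypes and locate the controlling loci:

1. **SI50** — for a group of crosses, the quantile at which half the
   compatibility reactions are half-compatible: the inflection *D* of the
   four-parameter logistic
   *Y* = *A* + (*B* − *A*) / (1 + e^((*D* − *x*)/*C*))
   fitted by Levenberg–Marquardt least squares to the quantile curve of
   the scores (sorted scores at *x*ᵢ = *i*/(*n*+1), every score + 1, and
   100 artificial anchor points per side — score 0 at *x* = −100…−1,
   score 10 at *x* = 101…200 — pinning the asymptotes). Fit quality is
   reported as *R*² = 1 − Σ*r*²/Σ(*x* − *x̄*)² over the real points only.
2. **Compatibility Components (CCs)** — principal components (unscaled
   SVD) of the genotype-by-genotype Euclidean pollination-distance
   structure, computed pairwise-complete under missingness, matched across
   replicate years by absolute correlation (component order can switch
   between years), and Ward-clustered.
3. **GWAS** — per matched CC, ordinary-least-squares single-marker
   association of component scores on SNP dosage with population-structure
   covariates, after excluding markers with minor allele frequency < 0.05,
   against the Bonferroni threshold −log₁₀(α/*m*).

A forward simulator of the whole study design — half-sib families fathered
by a polycross pollen cloud under pollen-side SI selection, founder
haplotypes mosaicked from ancestral chromosomes so markers near the SI loci
are in linkage disequilibrium with them, Haldane recombination, ordinal
scoring noise, year effects and missing cells — provides ground truth for
power and recovery studies.

## Worked example

Simulate the default study (52 genotypes in 4 half-sib families, two
replicate diallels, ~2,000 mapped SNPs on 7 linkage groups, S at LG 1 /
20 cM and Z at LG 2 / 54 cM) and run the full analysis:

```r
library(sicompat)
run <- run_si_pipeline(list(seed = 42))
run
#> <si_run>
#>  - simulated 52 genotypes, 2002 markers, 2 replicate diallel(s)
#>  - replicate 1: 19 reciprocal-difference flags (|diff| > 3)
#>  - replicate 2: 15 reciprocal-difference flags (|diff| > 3)
#>  - between-replicate correlation R = 0.88 over 2299 shared cells
#>  - SI50 fits: 32 groups, 0 skipped
#>  - matched components: CC1=PC1/PC1 (r=0.98), CC2=PC2/PC2 (r=0.68), CC3=PC3/PC3 (r=0.63), CC4=PC4/PC4 (r=0.84)
#>  - MAF filter: 1944 of 2002 markers retained (threshold 0.05)
#>  - significant marker associations: 39
#>  - localization: rep1 S: top marker 10.5 cM away (miss); rep1 Z: top marker 2.5 cM away (hit); rep2 S: top marker 1.4 cM away (hit); rep2 Z: top marker 0.9 cM away (hit)
```

The replicate correlation (R = 0.88) says the two simulated "years" agree
well cell-by-cell; the 19 and 15 reciprocal flags are pairs whose two cross
directions differ by more than three rubric points. Component variance
shares behave like real diallel data (first four components ≈ 63% of
variation here):

```r
glance(run$components[[1]])
#> # A tibble: 52 × 3
#>   component variance_fraction cumulative_variance
#> 1 PC1                  0.284                0.284
#> 2 PC2                  0.152                0.436
#> 3 PC3                  0.116                0.552
#> 4 PC4                  0.0770               0.629
```

An SI50 fit for the within-family crosses of family 1 — a low index, i.e.
sibs are largely inter-compatible in this realization, with the asymptotes
pinned at the augmented scores 1 and 11:

```r
fit_si50(subset_scores(run$diallels[[1]], "HSF-1", "HSF-1"))
#> <si50_fit> SI50 = 0.070 (A = 1.00, B = 11.04, C = 0.150), R2 = 0.971
```

And the truth-based localization summary: per SI locus, the matched CC
whose scores its allele composition explains best, and how far that CC's
top association marker lands from the true position:

```r
run$localization[, c("replicate", "locus", "component", "top_marker",
                     "top_log10p", "distance_cM", "hit")]
#> # A tibble: 4 × 7
#>   replicate locus component top_marker top_log10p distance_cM hit
#> 1 rep1      S     CC2       M1_0031          5.06      10.5   FALSE
#> 2 rep1      Z     CC1       M2_0180          9.83       2.53  TRUE
#> 3 rep2      S     CC3       M1_0060          8.21       1.37  TRUE
#> 4 rep2      Z     CC4       M2_0175          8.73       0.947 TRUE
```

Both loci are pinned to within ~1–2.5 cM where the attributed component is
locus-specific; the rep1 S row shows the method's known attribution limit —
a component correlated with both loci peaked 10.5 cM out.

Each result type has `tidy()`/`glance()` methods and an `autoplot()`
(diallel heat map, quantile curve with fitted logistic, CC scatter,
Manhattan plot). `run_si_pipeline()` also accepts `mode = "files"` with
paths to diallel/metadata/genotype tables in the package's plain TSV
formats, and an `output_dir` to write every intermediate table with a
seed-stamped header.

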