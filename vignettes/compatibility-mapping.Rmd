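---
title: "Mapping multi-locus gametophytic self-incompatibility from diallel pollination data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping multi-locus gametophytic self-incompatibility from diallel pollination data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sicompat)
```

## The problem

Outbreeding grasses such as perennial ryegrass carry a two-locus gametophytic
self-incompatibility (SI) system: two unlinked, highly polyallelic loci,
conventionally called *S* and *Z*, act complementarily. A pollen grain is
rejected on a stigma only when its haploid allele at **every** SI locus is
also present in the stigma's diploid genotype. Because each diploid pollen
parent produces up to four S/Z gametic combinations, a cross between two
fully heterozygous plants can only be 0, 1/2, 3/4 or fully compatible, and
the relation is directional: the expected compatible fraction of pollen from
A on stigmas of B need not equal the reverse cross.

In a population where neither allelic nor non-allelic diversity is
artificially restricted, the raw diallel of pairwise pollination scores is
far too complex to interpret against the genetic model directly. `sicompat`
implements a three-stage distillation:

1. **SI50** — a population-level index summarising a set of ordinal
   compatibility scores as the quantile at which half the reactions are
   half-compatible, estimated from a four-parameter logistic fit to the
   quantile curve;
2. **Compatibility Components (CCs)** — principal components of the
   genotype-by-genotype pollination-distance structure, matched across
   replicate years so that reproducible latent factors keep a stable label;
3. **Association mapping** — a single-marker genome-wide scan of each CC
   against SNP dosages, with minor-allele-frequency filtering, population
   structure covariates and a Bonferroni significance threshold.

A forward simulator of the whole study design provides the test surface:
ground-truth SI genotypes, linked markers and noisy replicate diallels with
the statistical structure the analysis assumes.

## Diallel data and quality control

A diallel matrix holds ordinal scores 0--10 (0 fully incompatible, 4
half-compatible, 7 three-quarters compatible, 10 fully compatible), rows =
pollen recipient (female), columns = pollen donor (male), diagonal = selfs,
with missing cells first-class (a mask, never a sentinel score). The reader
rejects non-integers rather than rounding: the scale is an ordinal rubric.

Two QC views mirror how replicated diallels are assessed in practice:

- `reciprocal_flags()` lists unordered pairs whose two cross directions
  differ by **more than three** rubric points (strictly; a difference of
  exactly 3 is not flagged). Under a purely gametophytic model reciprocal
  scores should agree up to scoring error, so these flags mark candidate
  non-model behaviour.
- `replicate_correlation()` reports Pearson's R over cells scored in both
  replicates (the conventional meaning of an unqualified "R"; Spearman is
  available as an option), for all shared cells or restricted to one family
  or one genotype's crosses as female or male parent.

## The SI50 index

Ordinal compatibility scores from a group of crosses are rarely normal;
their empirical quantile curve, however, traces a sigmoid. `fit_si50()`
models it with the four-parameter logistic

$$Y = A + \frac{B - A}{1 + e^{(D - x)/C}},$$

where $x$ is the quantile coordinate, $A$ and $B$ the lower and upper
asymptotes, $C$ a scale and $D$ the inflection — the SI50 index. The series
construction is deliberate:

- observed scores are sorted and placed at $x_i = i/(n+1)$, keeping all real
  points strictly inside $(0, 1)$;
- every score is incremented by one (a zero response is degenerate under
  the logistic);
- the asymptotes are anchored by 100 artificial points on each side:
  augmented score 1 at $x = -100\ldots-1$ and augmented score 11 at
  $x = 101\ldots200$. The anchors dominate the asymptote estimates (fitted
  $A \approx 1$, $B \approx 11$), so $D$ is identified by the real points
  alone and is interpretable on $[0, 1]$.

The reported goodness of fit is computed over the real points only as
$R^2 = 1 - \sum r^2 / \sum (x - \bar x)^2$ with $x$ the observed scores.
The denominator uses score deviations rather than a residual-free total sum
of squares, so the quantity can be negative for a fit worse than the group
mean; it is implemented in exactly this printed form for comparability.
Similarly, $D$ itself is not constrained to $[0, 1]$: a group of almost
uniformly compatible crosses can fit an inflection slightly below 0.

Numerical choices: Levenberg--Marquardt least squares
(`minpack.lm::nls.lm`), at most 200 iterations, relative tolerance `1e-8`,
unweighted by default (weights are exposed but none are defined by the
method); starting values are self-derived ($A_0 = \min y$, $B_0 = \max y$,
$D_0$ = the $x$ of the median real score, $C_0$ = a quarter of the real
$x$-range). The curve is evaluated through `plogis`, which stays finite at
the far-out anchor coordinates where a naive `exp` overflows once $C$
becomes small on step-like score sets. Degenerate groups (all scores
identical) are refused, and `group_si50()` skips any family pair below a
configurable floor of 10 observed scores, recording the reason.

```{r}
scores <- c(0, 0, 1, 2, 4, 5, 7, 8, 9, 10, 10, 10, 10, 10)
fit <- fit_si50(scores)
glance(fit)
```

## Compatibility Components

Each genotype's pollination behaviour is summarised by a profile
concatenating its matrix row (all scores as female) and column (all scores
as male), so both roles — and reciprocal asymmetry — inform similarity;
row-only and column-only profiles are available as options. Pairwise
similarity is the Euclidean distance computed over jointly scored
coordinates and rescaled by $p/m$ (profile length over shared coordinates,
the pairwise-complete convention); with no missing data this is exactly the
textbook distance. A pair sharing no coordinate is a hard error, not a
guess.

The distance matrix itself is the feature set: each genotype's feature
vector is its row, columns are centred (not variance-scaled) and decomposed
by SVD. Centring is the standard unscaled PCA; the uncentred variant is
retained as a sensitivity option because the first uncentred component is
dominated by the mean distance. Variance fractions come from the squared
singular values.

Principal components are reproducible across replicate years, but their
*order* need not be: two components explaining similar variance shares can
swap rank. `match_components()` therefore pairs the leading components of
two replicates by greedy assignment on descending absolute Pearson
correlation, flips signs so matched correlations are positive, and
relabels the pairs CC1..CCn in replicate-1 variance order. Greedy rather
than optimal assignment is deliberate: with four components the two rarely
differ and the greedy trace mirrors how the pairing is reasoned about.
Ward clustering (`hclust`, `ward.D2` — the Ward criterion proper on
Euclidean input) of the first four component scores, cut at four groups,
gives the compatibility clusters.

## Association scans

Markers with minor allele frequency below 0.05 (strictly), computed from
non-missing dosages as $\min(\bar p, 1 - \bar p)$ with $\bar p$ = mean
dosage / 2, are excluded and reported with a reason. Population structure
is summarised by the top principal components of the mean-imputed,
centred dosage matrix; the default is 2 axes, kept deliberately small
because a single closed population with four half-sib families has little
deep structure, and family structure itself carries SI signal that heavier
correction would absorb.

The per-marker model is ordinary least squares of the CC score on additive
dosage plus intercept and structure covariates; the p-value is the
two-sided t-test on the dosage coefficient. Missing dosages are mean-imputed
marker-wise by default (keeping n constant; implemented as an exact
Frisch--Waugh partial regression, vectorised across markers), with a
per-marker complete-case alternative. Markers collinear with the covariates
are skipped with a reason; numerically perfect fits are reported at a
documented cap of $-\log_{10} p = 15$. Significance uses the Bonferroni
threshold $-\log_{10}(\alpha/m)$ with $m$ the number of markers actually
tested — the threshold is always computed from $\alpha$ and $m$, never
hard-coded. `manhattan_table()` and `autoplot()` order markers by linkage
group and map position, unmapped markers trailing.

## The simulator

`simulate_population()` emulates the study design at desk scale:

| parameter | default | meaning |
|---|---|---|
| `n_families`, `family_sizes` | 4; 11, 12, 14, 15 | half-sib families with a common mother, 52 genotypes |
| `n_founders` | 20 | founder pool; mothers are 4 of them, the pollen cloud is every founder but the mother |
| `loci` | S: LG 1, 20 cM; Z: LG 2, 54 cM; 8 alleles each | complementary SI loci (any number supported) |
| `n_lg`, `lg_length_cM`, `markers_per_lg` | 7; 90 cM; 286 | ~2,000 evenly spaced biallelic SNPs |
| `n_ancestral` | max allele series (8) | ancestral chromosomes per LG founders are mosaicked from |
| `mosaic_generations` | 12 | expected historical meioses separating founders from the ancestral chromosomes |
| `score_noise_sd` | 0.75 | Gaussian scoring error on the 0--10 latent scale before rounding |
| `replicate_noise_sd` | 0.5 | extra per-cell year effect |
| `missing_rate` | 0.08 | unscored cells |
| `self_fertility_leak` | 0.02 | per-gamete probability an incompatible gamete fertilises anyway |

Two design points matter for what the simulator can and cannot show:

- **Ancestral mosaics create the linkage disequilibrium.** Each SI allele
  rides one ancestral chromosome at its map position, and founder
  haplotypes are mosaics of those chromosomes (block length set by
  `mosaic_generations`, matching a population ~12 generations from a
  narrow base). Without this the SI alleles would sit on random marker
  backgrounds and no marker could tag them. Meiosis uses a Poisson
  crossover process under Haldane's map function, no interference, one
  process per linkage group; SI alleles are co-inherited with the
  surrounding haplotype.
- **Pollen-side selection only.** Gametophytic SI screens pollen, not
  eggs: a pollen gamete is redrawn (father and all) until one is accepted,
  an incompatible gamete passing only with the leak probability. A gamete
  is rejected only when matched at *every* SI locus, so an accepted gamete
  is mismatched somewhere — no offspring can be homozygous at all SI loci
  jointly and strict selfing is impossible at zero leak. Homozygosity at a
  *single* locus, however, can and does arise from three-quarter-compatible
  matings; that is a property of the complementary model, not a simulator
  artefact.

Latent diallel scores are 10 x the expected compatible fraction; observed
scores add replicate and scoring noise, are rounded to the rubric and
clipped, and cells go missing independently. The simulator is simpler than
reality in ways that bound what passing tests show: one polycross
generation instead of a deep selected pedigree, a uniform marker grid, no
genotyping error, Gaussian-plus-rounding scoring noise rather than
rater-specific ordinal error, and missingness completely at random rather
than flowering-time structured.

## The orchestrated pipeline

`run_si_pipeline()` executes the whole analysis under one seed — simulate
(or ingest) two replicate diallels and genotypes, QC, grouped SI50 fits,
CC derivation and matching, clustering, MAF filter, structure covariates,
one scan per matched CC per replicate — and, in simulation mode, a
truth-based localization summary: for each simulated SI locus, the matched
CC whose scores are best explained (regression $R^2$) by the locus's true
allele dosages is identified, and the map distance between that CC's top
scan marker and the true locus position is reported. Outputs are plain TSV
with a commented header carrying the package version, seed and a config
hash; a fixed seed reproduces every file byte-for-byte.

```{r, eval = FALSE}
run <- run_si_pipeline(list(seed = 1))
run$localization
```

Typical desk-scale problem sizes (the defaults above) run the full
pipeline in about a second; the package's own acceptance studies use 20
replicate runs, which keeps parameter-recovery and localization summaries
inside a coffee break on one core.

## Known limitations

- The SI50 quantile positions $i/(n+1)$ and the treatment of the anchor
  blocks as literal coordinates on the same axis are documented
  conventions; other quantile grids shift $D$ slightly.
- CC derivation treats the Euclidean distance matrix itself as the PCA
  input (not a double-centred Gram matrix as in classical MDS); the two
  give similar but not identical components.
- The association model is plain OLS: no kinship mixed model, no
  haplotype or multi-marker tests. With strong family structure and few
  genotypes, a CC can be genuinely correlated with *both* SI loci, in
  which case its peak marker localises only the stronger one — the
  distillation's known attribution limit, visible in simulation runs
  where one locus's best CC peaks at the other locus.
- SI50 values are comparable within a study design but are not calibrated
  probabilities; a negative fitted SI50 simply means "more compatible than
  any observed quantile".
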