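---
title: "Pedigree-based QTL and SNP haplotype analysis for fruit-crop breeding germplasm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based QTL and SNP haplotype analysis for fruit-crop breeding germplasm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cherryhap)
library(dplyr)
```

## The problem

Breeding programs for clonally propagated fruit crops such as sweet cherry
(*Prunus avium* L.) accumulate large, multi-parental seedling populations
connected by a known pedigree. Two fruit-quality traits dominate selection
decisions in many programs: rain-induced fruit cracking, scored as the
percentage of a fixed sample of fruit (typically 50) that crack after a
standardized water soak, and flesh firmness, measured in g/mm by
compression. Both are heritable, polygenic and measured in only a couple
of seasons per seedling, so the analysis has to (i) condense noisy yearly
records into a single genetic estimate per seedling, (ii) locate and size
QTLs against a background of family structure, (iii) translate QTLs into
*SNP haplotypes* that breeders can select on, and (iv) track those
haplotypes through the pedigree to the ancestors that introduced them.

`cherryhap` implements that pipeline end to end, together with a
gene-dropping simulator that generates germplasm of exactly this shape
with known ground truth, so that every stage can be validated by
parameter-recovery rather than by anecdote.

## Multi-year BLUPs

Yearly records are combined with the mixed model

$$y_{iy} = \mu + \beta_y + u_i + e_{iy},\qquad
u_i \sim N(0, \sigma_u^2),\; e_{iy} \sim N(0, \sigma_e^2),$$

fitted by REML (`lme4`), with year a fixed factor and individual a random
intercept. The per-seedling estimate reported is the predicted random
effect $\hat u_i$ — the *deviation from the model intercept* — which keeps
the trait units (% incidence, g/mm) and shrinks noisy individuals toward
zero. For a balanced two-year design the predictor has the closed form
$\hat u_i = \frac{2\sigma_u^2}{2\sigma_u^2 + \sigma_e^2}(\bar y_i - \bar
y)$, which the test suite uses as an independent oracle; shrinkage
($|\hat u_i| \le |\bar y_i - \bar y|$) is asserted as a property. Data are
analysed untransformed. Subpopulation or planting-year covariates are
deliberately not included: the model is the minimal one consistent with
"deviation from the intercept" reporting, and anything else can be added
by the user upstream.

Subpopulation comparisons use Welch's *t* test for firmness (effectively
normal) and the Wilcoxon rank-sum test for cracking (bounded,
non-normal); the choice is a convention, overridable per call.

## The genome scan

`blink_scan()` follows the iterative two-model fixed-effects scheme of
BLINK-style association testing:

1. every SNP is tested in a linear model with the current cofactor SNPs as
   covariates (missing dosages mean-imputed per SNP);
2. Bonferroni-significant SNPs, in ascending p order, are greedily
   admitted as cofactors when they lower the BIC of the joint model *and*
   have $|r| \le 0.7$ (Pearson, on dosages) with every already-admitted
   cofactor;
3. the two steps alternate until the cofactor set is unchanged or
   `max_iter` (default 10) is reached. Reported p-values come from the
   final testing pass, each cofactor tested with itself removed from the
   covariates.

The ordering of the greedy pass, the stopping rule, and the BIC variant
(the generic $n\log(\mathrm{RSS}/n) + k\log n$) are our own
codification — published descriptions of the algorithm leave them open —
chosen to make the scan deterministic. With no admitted cofactors the scan
reduces exactly to single-SNP regression, an oracle equality the tests
assert. Per-SNP variance explained is the adjusted $r^2$ of the simple
regression, $1 - (1 - r^2)(n-1)/(n-2)$, clipped at zero. SNPs are
pre-filtered at minor allele frequency strictly above 0.01. No principal
components are used by default (the germplasm this emulates showed ~18%
of variance on the first two PCs); `covariates` accepts any fixed columns
when structure correction is wanted, and `pca_structure()` provides the
diagnostic.

Genomic heritability (`estimate_h2_additive()`) builds a VanRaden-type
relationship matrix from centred dosages, normalized to unit mean
diagonal, and maximizes the one-component REML likelihood on the GRM
eigenbasis; $h^2 = \sigma_a^2/(\sigma_a^2+\sigma_e^2)$. The spectral REML
is written in the package because no installed dependency fits a dense-GRM
variance component directly; Haseman–Elston regression is the documented
fallback if the optimizer fails.

## QTL summary arithmetic

Bayesian pedigree-based analysis (PBA) engines report, per trait, the QTL
additive variance `vQTL11`, the residual `vERR11`, the per-QTL
probability-weighted variance `wAVt1` and the phenotypic variance
$\sigma_p^2$. The package consumes such components (it does not
re-implement the MCMC engine) and applies the standard arithmetic:
$h^2 = \mathrm{vQTL11}/(\mathrm{vQTL11}+\mathrm{vERR11})$, QTL PVE
$= \mathrm{wAVt1}/\sigma_p^2$, with two-run estimates averaged ratio-wise.
Bayes factors classify evidence as none (< 2), positive [2, 5), strong
[5, 10) and decisive (≥ 10). `total_pve()` sums per-QTL PVE within a trait
and method, and `additive_fraction()` expresses that total as an integer
percentage of $h^2$.

`consolidate_stability()` merges detections across datasets (years and the
multi-year BLUP) and methods into named QTLs. Two interval detections
merge when they overlap; a GWAS peak SNP merges into an interval when it
lies inside it or within 2 cM of an endpoint — strict containment fails
on real published pairings by about 1 cM, and 2 cM is the smallest round
slack that reproduces them all without creating spurious merges (the
nearest non-merged SNP sits ~21 cM away); two GWAS detections merge only
when they report the identical peak SNP. Names follow `q<Trait>-LG<x>.<k>`
with QTLs ordered by position. The `m` suffix marks multi-year support,
judged on *distinct evidence*: detections repeating the identical interval
or identical peak SNP collapse to one piece of evidence, and `m` requires
at least two pieces from at least two datasets. A QTL is *stable* when
detected in every PBA dataset available for the trait and in at least two
GWAS datasets. These rules are the package's own codification; they
reproduce, as a fixture-based test shows, all 18 published QTL names and
exactly the four published stable QTLs of the germplasm the package
emulates.

## Haplotype analysis

At each stable QTL a *primary SNP* (PS) is designated: Bonferroni
significant, housed in a haploblock whose boundary lies within 10 cM of
the PBA peak, and of maximal adjusted-$r^2$ PVE among qualifiers (ties go
to the smaller genetic position — an arbitrary but deterministic choice).
Haploblocks — runs of adjacent SNPs without known historic
recombination — are treated as multi-SNP alleles written as strings over
{A, B}.

The haplotype catalog of a block consists of the distinct parental
strings, labelled H1…Hk by descending frequency (ties lexicographic; the
ordering is our choice, as label order carries no meaning). A seedling
string matching a catalog entry takes its label; a recombinant string
takes the label of the transmitting parent's haplotype sharing its PS
allele; a missing PS allele, or two parental haplotypes sharing the PS
allele while differing elsewhere, leaves the strand unassigned. Where
phase is uncertain, `parent_guided_phasing()` enumerates the at most four
parental gamete pairs consistent with the observed dosages and accepts
only a unique solution; zero consistent pairs flag a Mendelian
inconsistency.

Only haplotypes represented at least five times among the seedlings enter
comparisons. The effect of a haplotype is the mean trait value of its
carriers minus the mean over all phenotyped seedlings — positive means
carriers sit above the population average. (The mean is taken over
phenotyped seedlings only; including unphenotyped ones is impossible
without imputation.) Pairwise contrasts use Tukey's HSD (firmness) or
pairwise Wilcoxon tests with Bonferroni correction over all unordered
pairs (cracking) at a family-wise error rate of 0.05, and the resulting
significance digraph is turned into relational classes: both-directions →
moderate; only-higher (only-lower) with the maximal number of contrasts
among such haplotypes → high (low), the rest moderate; no contrast →
none. The rule is deterministic given the digraph and is verified in the
tests against an independently coded oracle on *all* 729 digraphs over
four labels.

## Haplotype tracking

`assign_origin()` compares a seedling strand with each parental strand:
`identical` (exact), `imputed` (unique completion of at most `max_impute`
missing alleles, default 2 — "easily imputed" is not quantified in
practice, so the bound is configurable), `recombinant` (PS-allele match
without string match) or `unassignable`. `trace_to_terminal()` repeats
this up the pedigree, following carriers until unknown parents, missing
data, or a recombinant/unassignable outcome, never visiting an individual
twice; when both parents carry the haplotype (inbreeding loops are common
in breeding germplasm), both branches are traced and all terminal
ancestors reported rather than one being chosen arbitrarily.

## The simulator, and what passing its tests does not show

`sim_germplasm()` generates: a pedigree of unnamed ancestors, 22
important breeding parents and 259 seedlings in two subpopulations (A,
n = 119; B, n = 140; one self-cross included); 1,617 biallelic SNPs evenly
spaced on 8 linkage groups (~587 cM); founder gametes drawn i.i.d. at
configurable B-allele frequency (0.5 by default); gene dropping under the
Haldane no-interference model (crossovers Poisson on the cM scale, so the
recombinant fraction at distance $d$ is $(1-e^{-2d/100})/2$, a closed form
the tests check by Monte Carlo); and two years of phenotypes. Firmness is
intercept (309 g/mm) + year + subpopulation (A −28, B +21 g/mm,
mirroring the ~49 g/mm program-vs-reference gap of the emulated study) +
planted QTL effects + a polygenic value (SD 44 g/mm) + residual (SD 40
g/mm), with subpopulation A measured in 2012 + 2020 and B in 2019 + 2020.
Cracking is a logit-scale liability (year shifts −0.12 and +0.45 give
~47% and ~61% incidence; polygenic SD 0.9; tree-by-year SD 0.7) pushed
through a Binomial(50) fruit sample, giving bounded, non-normal values on
a 2% grid. These variance choices put the between-year correlations near
0.6, the range reported for both traits in the emulated germplasm; where
the study gives no value (founder allele frequencies, founder LD — none by
default — crossover interference, liability SDs) the defaults are one-time
choices of plausible magnitudes, stated here and not tuned further.

Planted QTLs are haplotype-level additive effects keyed by the B allele of
a focal SNP inside a haploblock (defaults: cracking +0.45 and −0.40 logit
units on LG 1 and LG 5; firmness +30 and +18 g/mm on LG 1 and LG 3). The
generator records complete ground truth — founder strand ids per SNP,
every transmission's breakpoints, true genetic values — which the tests
use as oracles.

The simulator does **not** emulate: genotyping error and array curation,
founder linkage disequilibrium (optional block correlation is out of
scope), dominance and epistasis, genotype-by-environment weather effects,
or selective sampling of seedlings. Tests passing on this synthetic
germplasm therefore demonstrate the *statistical machinery* — calibration,
power, recovery of planted truth — not that real cherry data meet the
model's assumptions.

## Numerical and design notes

- p-values are floored at the smallest positive double; PVE and $h^2$ are
  clipped to [0, 1].
- Constant dosages yield PVE 0 with a warning; zero-variance phenotypes
  yield zero BLUP deviations with a warning; two identical constant
  groups compare with p = 1 by convention.
- Effect sign: "carrier mean minus population mean", so a desirable
  low-cracking haplotype has a negative effect — this matches how such
  effects are reported in practice even where prose descriptions invert
  the subtraction.
- Unknown ancestors are `NA` parent fields; explicit placeholder
  individuals are supported as ordinary nodes, and tracing terminates at
  either.
- Problem sizes in the test suite are the package's own choices: the
  scan's family-wise error is checked on 500 null replicates (1,000 SNPs,
  n = 300), power on 200 replicates of a 15%-PVE QTL at n = 259,
  heritability recovery on 100 replicates at n = 500 with 1,000 SNPs, and
  Haldane calibration on 10,000 gametes.
- This is an analysis package used from R: the exported functions and this
  vignette are the interface; no shell entry point is shipped.

## A worked call sequence

```{r example, eval = FALSE}
sim <- sim_germplasm(seed = 1)

fit <- fit_multiyear_blup(sim$phenotypes, "firmness")
glance(fit)

blups <- tidy(fit)
geno <- maf_filter(sim$genotypes[blups$id, ])
scan <- blink_scan(geno, blups$deviation)
autoplot(scan, sim$map)

qtl <- list(name = "qFirm-LG1.1m", linkage_group = 1L,
            peak_cm = sim$truth$qtl$pos_cm[3])
designate_primary_snp(scan, qtl, sim$blocks, sim$map)
```

## Known limitations

- The PBA engine itself (Bayesian MCMC QTL mapping) is consumed, not
  implemented; variance components arrive as a table.
- The recombinant-classification rule resolves *any* non-matching string
  by its PS allele, including multi-recombinant strings; with more than
  two candidate parental haplotypes sharing a PS allele the strand is
  left unassigned rather than guessed.
- Imputation in tracking is unique-completion only; likelihood-based IBD
  inference is out of scope.
- The stability and naming rules are reverse-engineered codifications of
  published practice; they reproduce the published table they were
  checked against but are not guaranteed to match other groups' naming.
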