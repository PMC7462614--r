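---
title: "Methods: pooled population genomics with poolpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled population genomics with poolpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

poolpopgen implements the inference chain used to ask whether wild
populations with small effective size accumulate slightly deleterious
variation — the relaxed-selection signature studied in short-lived
killifish: pooled-sequencing diversity (π, Watterson's θ, N~e~),
pairwise F~ST~ with an outlier scan, outgroup-polarized
McDonald–Kreitman statistics (asymptotic α, DoS), site-frequency-spectrum
projection with a gamma model of the distribution of fitness effects
(DFE), and a forward Wright–Fisher simulator that generates complete
synthetic study systems with known truth. This vignette documents the
models, the defaults and why they are what they are, the numerical
choices, and what the synthetic data can and cannot tell you about real
data.

## Diversity estimators for pooled reads

A pool of `n` haploid genomes sequenced to depth `M` at a site gives read
counts `c_A..c_T`. Per-site heterozygosity uses the unbiased read-pair
form

π̂ = M/(M−1) · (1 − Σ~a~ (c~a~/M)²),

which is exactly the probability that two reads drawn without
replacement differ (`site_pi()`, tested against an exhaustive pair
oracle). Windowed estimates (`window_stats()`, default 50 kb,
non-overlapping) average π̂ over covered sites and compute

θ̂~W~ = S / (a~n~ · covered sites),  a~n~ = Σ~i=1~^n−1^ 1/i,

where S counts SNPs whose minor allele has at least `min_count` reads
(default 2) and `n` is the *haploid pool size*, not the read depth: the
pool bounds the number of distinct lineages sampled. Windows covered
below 30% are dropped; sites outside the per-population coverage band
(default half to twice the mean depth, overridable) do not count as
covered. Within windows, alleles below the minimum count are masked
before computing π̂ and SNP status — this is the behaviour of the
standard pool-seq windowing tools, and without it a per-base error rate
ε inflates every site's π̂ by ≈2ε. Two residual biases of the naive
estimators are documented and accepted: read sampling with replacement
from the pool shrinks π̂ by (n−1)/n, and the min-count filter loses a
small fraction of true singletons at moderate depth; both are ≪ the
Monte-Carlo error at the depths used in the checks (≥80×).

N~e~ comes from the compound parameter θ = 2·p·N~e~·μ (`estimate_ne()`),
with a default mutation rate of 2.6321e-9 per bp per generation (one
generation per year in annual killifish).

## Differentiation

`fst_from_counts()` uses the classical π-based estimator
F~ST~ = (π~total~ − π~within~)/π~total~ with π~within~ the mean of the
two pool diversities and π~total~ computed on summed counts; negative
values are clamped to 0. Windows (`window_fst()`, min count 4, min
coverage 20) aggregate the per-site π sums over SNPs; genes are
single-span windows (`gene_fst()`), the "one huge window per gene" device. Per pair of populations, window F~ST~ values are
Z-transformed and the 0.5% tails flagged (`zfst_outliers()`, type-7
empirical quantiles, per-pair as the comparisons are independent).
Candidate genes (`candidate_genes()`) must satisfy all three criteria:
an outlier window, a gene F~ST~ above the 99.5th percentile, and at
least one SNP significant in a two-sided Fisher exact test after
Benjamini–Hochberg correction (adjusted p < 0.001; `snp_fisher_bh()`
via `fisher.test`/`p.adjust`). The genome-wide pairwise F~ST~ matrix
feeds `ape::nj()` (`nj_tree()`); negative branch lengths are reported
as-is.

## Polarization and site classes

`classify_degeneracy()` assigns every CDS position a degeneracy class
under the standard genetic code: four-fold (any substitution is
synonymous; the neutral proxy), zero-fold (any substitution is
non-synonymous; the selected proxy) or other. Two-/three-fold sites are
excluded from all MK/DFE computations. `polarize()` calls the derived
allele as the allele not carried by the outgroup pseudogenome and
applies the filter stack: outgroup base must be A/C/G/T; coverage within
per-population bounds; at most two alleles with real (≥2 reads) support;
a minor allele with a single supporting read makes the site monomorphic;
DAF above 0.95 makes it a fixed difference, below 0.05 effectively
monomorphic for the ancestral allele; biallelic sites where the outgroup
matches neither allele are excluded (cross-species triallelic; excluding them is the conservative choice). Ties in
the pseudogenome major-allele rule (`call_major_allele()`) are masked as
N, again conservatively. The role usually played by an
external Bayesian pooled SNP caller is filled by a self-contained three-state posterior
(`segregation_filter()`): monomorphic-reference, monomorphic-alternative
(minor reads explained by a 1% error rate) or segregating with a uniform
frequency prior, equal prior weights; polymorphic calls need posterior
> 0.9. It discards low-confidence SNPs without external dependencies.

## McDonald–Kreitman statistics

Per gene, `mk_counts()` tallies fixed differences versus the outgroup
(Dn, Ds: divergent monomorphic sites plus nearly fixed SNPs with
DAF > 0.95) and polymorphisms (Pn, Ps: DAF in [0.05, 0.95]), with
polymorphic counts binned by DAF. α(x) = 1 − (Ds/Dn)·(Pn(x)/Ps(x)) per
bin (`alpha_x()`; nine equal bins over [0.05, 0.95] — the bin count is a
free choice, nine gives ≥4 informative bins even for sparse data while
still resolving the low-frequency tail). The asymptotic estimate fits
α(x) = a + b·exp(−c·x) by Levenberg–Marquardt least squares and reports
α(1) (`fit_asymptotic_alpha()`); if the exponential is degenerate (flat
curves make c unidentifiable) a linear extrapolation to x = 1 is
reported and flagged. Confidence intervals bootstrap over genes
(default 200 replicates). DoS = Dn/(Dn+Ds) − Pn/(Pn+Ps) per gene
(`dos()`), undefined without at least one substituted and one
polymorphic site; gene sets are the 2.5%/97.5% tails (`dos_gene_sets()`).
DoS and the pooled α always agree in sign, which the suite checks.

## SFS and the DFE

`build_sfs()` places polymorphic sites at derived count round(DAF·n) and
`project_sfs()` downsamples by the exact hypergeometric expectation to
n = 10 (the default used throughout), recording the mass that projection
pushes into the monomorphic classes. `expected_sfs()` evaluates the
Poisson-random-field expectation

E[F~i~] = θ~L~ · C(n,i) ∫₀¹ H(x;S) x^i (1−x)^{n−i} dx,
H(x;S) = (1−e^{−S(1−x)})/(x(1−x)(1−e^{−S})),

with S = 4N~e~s, the neutral limit H = 1/x (giving θ~L~/i), the ratio
computed in the overflow-safe form (e^{Sx}−e^S)/(1−e^S), adaptive
quadrature at rel. tol. 1e-9, and the boundary-layer asymptotic
C(n,i)(i−1)!/|S|^i below S = −500. `fit_gamma_dfe()` maximizes the
Poisson composite likelihood of the non-synonymous spectrum under a
gamma distribution of −S (quantile-discretized into 64 classes;
expected spectra interpolated from a 140-node spline over log|S| built
once per sample size, exact at the nodes), with the synonymous spectrum
fitted as neutral and both mutation-supply parameters profiled out
analytically. Model variants — deleterious-only (the default: purifying selection is the
dominant regime in the systems this package targets) and deleterious
plus a neutral point mass — are compared by AIC (`compare_models_aic()`). The
fit deliberately omits ancestral-misidentification and demographic
nuisance parameters. Optimization is bounded (shape in [1e-3, 100],
mean of −S in [1e-2, 1e5]): sparse spectra can leave the likelihood
flat in one direction, and an unbounded optimizer then wanders to
astronomically large, meaningless parameter values; estimates at a
bound raise a warning. From a 9-class projected spectrum the gamma *shape*
is well identified (recovered to ±0.1 in the checks); the gamma *mean*
of 4N~e~s is weakly identified without divergence information, and its
estimate should be read as order-of-magnitude only. Parametric (Poisson)
bootstrap gives CIs; estimates pinned to the numerical boundary trigger
a warning.

## The forward simulator

`simulate_forward()` is a diploid Wright–Fisher simulator with
selection, written in C++ (as the field's simulators are): fitness is
multiplicative across sites (heterozygote 1 + hs, homozygote 1 + s, no
epistasis), parents are sampled proportional to fitness, gametes
recombine by Poisson crossovers on a linear genome (no gene conversion),
and mutations follow the infinite-sites model restricted to coding
positions — neutral at third-codon-slot-like positions (~1/3), gamma
deleterious at the rest. Defaults are the rescaled study conditions: an
ancestral population of 10,000 diploids, 1500 CDS of 500 bp, μ =
5.468928e-8 and r = 6.604764e-6 per bp per generation, a reflected gamma
DFE with mean −2.5, shape 0.35 and dominance 0.1, and a 50,000-generation
burn-in (5N; burn-in scales proportionally under `rescale_sim_config()`,
and convergence is not monitored dynamically). The gamma mean is read on the *s* scale; because a mean of
−2.5 on that scale is unusually strong, the interpretation is a config
switch (`scale = "2Ns"` divides by 2N). Demography plans (`build_demography()`) cover the
four standard scenarios: instant size change versus exponential growth,
split at burn-in end versus later; exponential growth rates are solved
so the target size is hit exactly at the final generation. Daughter
sizes default to a 1:10 small:large ratio at desk scale — illustrative,
since the full-scale values were inferred from coalescent analyses and
never printed. One master seed per replicate drives every draw; same
seed, same bytes.

`write_sim_fixtures()` emits a complete study system: a reference genome
whose CDS are built from the six four-fold codon families (GCN, GGN,
GTN, ACN, CCN, TCN — third positions exactly four-fold, first and second
zero-fold, no stops, so the annotation-based degeneracy map coincides
with the simulator's site classes), a GTF, an outgroup diverged by
Jukes–Cantor substitution with divergence at selected sites reduced by a
factor 0.25 (purifying selection on the outgroup lineage; with uniform
divergence Dn/Ds would be ~1 and α meaninglessly high), pooled read
counts (Poisson depth, multinomial base errors) in sync format, and
truth tables. `sim_mk_tables()` computes MK tables straight from the
truth, optionally adding Poisson outgroup-lineage divergence per gene —
at desk scale the populations' own fixations are too few for per-gene
statistics, whereas in real data interspecies divergence dominates D.

`sim_mk_tables()` computes the per-gene divergence noise from one
outgroup branch: all daughter populations of a replicate are compared
against the same outgroup, so `draw_outgroup_mk_divergence()` is drawn
once per replicate and shared — drawing it independently per population
would inject spurious between-population variance into paired
comparisons.

One emergent property worth knowing: at high mutation supply the
strongly deleterious influx (mean s = −2.5 makes most selected
mutations severely deleterious) causes substantial background
selection — in the desk-scale paired experiment linked purging
depresses neutral diversity several-fold below 4Nμ. This is real
population genetics, not an artefact, but it means θ contrasts between
populations are draft-noisy at high μ; the three-population
demonstration therefore uses a gentler mutation supply (μ = 2e-6,
deleterious mutation rate U ≈ 0.3 per diploid per generation) at which
the size-driven ordering θ(small) < θ(mid) < θ(large) is robust, while
the paired DoS/DFE experiment keeps the higher supply that per-gene MK
statistics need (its tested quantities are count ratios, which draft
does not bias differentially).

### What the synthetic data do and do not show

The generator reproduces the features the estimators rely on: pool-read
sampling noise, sequencing error, coverage variation (Poisson), codon
structure, outgroup divergence with polarization errors at shared
polymorphic sites, linked selection within a linear genome, and
population size contrasts. It does not emulate mapping artefacts,
indels, base-quality variation, GC or CpG mutation-rate heterogeneity,
gene conversion, migration, or reference bias. Passing checks therefore
validate the estimator chain and its filters, not the upstream read
processing of real data.

### Desk-scale test conditions

The paired small-N/large-N experiment used by the test suite runs 25
replicates of: ancestral N = 500 splitting immediately after a 2500-
generation (5N) burn-in into daughters of 50 and 500, 250 further
generations, 40 CDS of 3000 bp, μ = 1e-5, r = 1.3e-5, 30 diploids
sampled. Gene length and mutation supply are set so that a gene carries
several polymorphic sites, matching the information content of
full-scale data (under strict 1/N rescaling genes would hold ~1 SNP and
per-gene statistics would be degenerate); recombination is not fully
up-scaled because linkage does not enter the tested quantities. The
neutral-recovery check uses N = 1000, a 1 Mb neutral genome, μ = 1e-7,
r = 1e-7 (non-zero so that 50 kb windows decorrelate and a window
bootstrap SE is meaningful), 10N generations, pooled at 500×. The
split-time series uses N = 300 pairs at three post-split ages. These
problem sizes are the package's reference desk scale; all scale up
through the config objects.

## Numerical and degenerate-input choices

Empirical quantiles are type 7 throughout. Negative window F~ST~ is
clamped to 0 before Z-transformation. Zero-variance window sets,
distance matrices that are asymmetric or too small, θ on empty windows,
pool sizes < 2, thresholds outside (0,1) and Dn = 0 curves raise errors
rather than propagate NaN. Fisher tables with a zero margin return
p = 1. The simulator guards against extinction (reports the generation)
and against runaway mutation counts (configurable cap). Projection to
the native sample size is the identity; projected mass on the
monomorphic classes is reported, not silently dropped.
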