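---
title: "Models and methods behind hybridscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hybridscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridscape)
```

hybridscape studies how hybridization shapes speciation in small species
complexes — its motivating system is an alpine butterfly complex with two
parental species, two taxa of hybrid origin, and a handful of contact
zones — from reduced-representation (ddRAD-style) SNP panels of around a
thousand loci.  This vignette explains the models the package implements,
the choices made where a method leaves latitude, and what the synthetic
data used by the test suite can and cannot demonstrate.

## Genotype data and filtering

Genotypes are diploid counts of the alternate allele (0, 1, 2, or
missing) over biallelic SNPs, each SNP optionally attached to the RAD tag
it was called on.  `filter_loci()` applies the retention rules typical of
ddRAD panels, in a fixed order: the SNP's tag must be genotyped in at
least 3 species; the SNP must be genotyped in more than 40% of all
individuals (a global rule, not per species); its minor-allele frequency
over genotyped individuals must be at least 1% (boundary inclusive, so
tests can be exact); and one SNP is kept per tag.  The one-per-tag
tie-break — fewest missing calls, then smallest within-tag position, then
lexicographic id — is a package choice made for determinism; any rule
that keeps one SNP would do scientifically, and it maximizes retained
data.

## Joint allele-frequency spectra

A two- or three-population joint allele-frequency spectrum (JAFS) counts
SNPs by their derived-allele count in each population.  The monomorphic
corners carry no information about polymorphism and are always masked.
Missing genotypes are absorbed by per-site hypergeometric projection:
a site genotyped in $m$ chromosomes contributes, at target size $n$, the
expected counts of a draw of $n$ chromosomes without replacement, so
projected spectra have fractional entries.  Projection is exact
expectation, not resampling — the test suite checks it against 10,000
explicit subsamplings.

Ref/alt polarization is used as a stand-in for ancestral/derived
orientation.  Because no outgroup polarization is attempted, two
mitigations exist: spectra can be folded onto minor-allele counts, or the
unfolded analysis can estimate an orientation parameter $O$ — the
probability a SNP is correctly oriented — under the mixture
$S' = O\,S + (1-O)\,\mathrm{rev}(S)$, where $\mathrm{rev}$ swaps derived
and ancestral states.  The mixture form is this package's explicit
definition; $O$ is estimated only in the heterogeneous-migration models,
where the parameter count then matches the published model table's
AIC arithmetic.

## Demographic scenarios and the coalescent engine

Scenarios use diffusion-style units: deme sizes $\nu$ relative to an
ancestral reference size $N_{ref}$, times in units of $2N_{ref}$
generations, scaled migration rates $M$ such that a lineage jumps
backward between demes at rate $M/2$ per unit time, and a free scale
parameter $\theta$ profiled out of the likelihood (expected spectra are
computed per unit $\theta$).  Under these dynamics the symmetric
two-deme island model has Nei-type $F_{st} = 1/(1+4M)$, which the test
suite uses as a closed-form oracle.

The two-population model space is the standard divergence family: strict
isolation (SI), isolation with migration (IM), ancient migration (AM,
gene flow confined to the interval of length $T_{am}$ adjacent to the
split, the two lineages isolated ever since), and secondary
contact (SC, gene flow only during the most recent $T_{sc}$).  A `G`
suffix lets each daughter deme grow exponentially from the ancestral
size to its present size; this parameterization adds no free parameters,
so a growth model competes with its base model on fit alone.  A `2m`
suffix adds genomic heterogeneity of gene flow: a fraction $P$ of loci
belong to a restricted class whose migration rates $me_{12}, me_{21}$
replace $M_{12}, M_{21}$, modelling barrier loci that resist
introgression; the expected spectrum is the $(1-P, P)$ mixture of the
two classes.

The three-population space contrasts hybrid speciation with secondary
gene flow.  In HS models the third deme is founded at time $T_h$ by an
admixture pulse drawing each lineage from parent 1 with probability $f$;
HSp1/HSp2/HS2p add continuous gene flow between the hybrid and one or
both parents.  In SGF models the third deme splits from one parent
(SGF1: parent 1; SGF2: parent 2) and then exchanges genes with both.
The parental demes themselves do not exchange migrants within the
three-population models; the triplet analysis targets hybrid–parent
gene flow, and parental gene flow is the two-population models' job.
These epoch structures are the package's explicit reading of the
scenario space; nested limits (HS2p with zero migration equals HS, HS
with $f = 1$ equals a split from parent 1) are enforced exactly, seed
for seed.

Expected spectra come from a structured-coalescent Monte Carlo rather
than a diffusion solver: for each replicate genealogy, every branch
contributes its length to the JAFS cell indexed by its descendant-leaf
counts per deme (mutations arise at rate $\theta/2$ per unit branch
length, so branch-length weighting gives the expected SNP count per unit
$\theta$ directly, with far less variance than sampling mutations).
Migration never changes a branch's descendant set, so a branch's whole
lifespan belongs to one cell — the engine therefore only touches the
spectrum at coalescence events, making single-population runs of 50,000
replicates sub-second.  Exponential growth is handled by discretizing an
epoch into 16 piecewise-constant steps of the exponential trajectory; at
the engine's Monte-Carlo resolution this is indistinguishable from exact
time rescaling.  All randomness flows through R's RNG, so results are
bit-reproducible given a seed, with one independent stream per locus
class.

## Fitting and model selection

Fitting maximizes the Poisson composite log-likelihood over unmasked
cells, with $\hat\theta$ the ratio of observed to model mass (its
analytical optimum).  Model cells below $10^{-12}$ are floored there so
a finite Monte-Carlo model spectrum cannot produce an infinite
likelihood.  Optimization is Nelder–Mead on transformed coordinates —
log for positive parameters, logit for proportions, and the AM/SC phase
durations and the hybrid-origin time as logit fractions of the split
time, which enforces chronology without constrained optimization.
Nelder–Mead is used instead of a gradient method because the objective
is a Monte-Carlo estimate: within a restart the simulation seed is fixed
(common random numbers), making the objective deterministic but jagged,
which derivative-free search tolerates.  Ten independent restarts from
log-uniformly perturbed starts (factors up to 3) are the default, and
only the best is kept.

Two practical points matter for accuracy.  First, fits are run on
spectra projected to modest sample sizes (16 chromosomes per deme in
the tests): with ~1,000–2,000 SNPs spread over a 31×31 grid most cells
hold almost no mass, and the relative Monte-Carlo error of the model in
those cells dominates the likelihood; projection concentrates mass and
makes recovery reliable.  Projecting down to roughly 15 individuals per
species is also how analysts of such panels usually absorb missing
genotypes while keeping resolution, so the default mirrors field
practice; the projection size is a plain argument, not a constant, and
whether "15 individuals" should mean 15 or 30 chromosomes per axis is
left to the caller.  Second,
the replicate budget per objective evaluation (20,000 in the recovery
tests) trades time against the displacement of the noisy optimum; the
suite's problem sizes — 2,000 loci, 2–3 restarts, a few hundred
Nelder–Mead iterations — were chosen as the smallest ones at which
recovery within 20% is comfortable.

Model selection follows standard AIC practice on the composite
likelihood (no small-sample correction): $AIC = 2k - 2\ln L$ with $k$
the free-parameter count from `model_params()` (e.g. 9 for IM2m, 10 for
AM2m — $\theta$ is profiled and not counted); $\Delta AIC < 10$ retains
a model; the model score $(\Delta_{max} - \Delta AIC_i)/\Delta_{max}$
maps the best model to 1 and the worst to 0; and Akaike weights
normalize $e^{-\Delta AIC_i/2}$.  When every model ties, scores are
defined as 1 with a warning.  Composite-likelihood AICs compare fit, not
calibrated probability; the weights should be read comparatively.

## Hybrid index and interspecific heterozygosity

For contact zones, each individual's hybrid index $h$ is the proportion
of its gene copies inherited from reference species B.  The likelihood
treats the two copies at a locus as independent draws from a mixture of
the parental allele pools: a copy carries the alternate allele with
probability $q(h) = (1-h)p_A + h p_B$ and the genotype is
$\mathrm{Binomial}(2, q(h))$.  This closed-form likelihood is the
package's own explicit definition of the maximum-likelihood hybrid
index; numeric identity with other implementations is not claimed, but
the boundary behaviour (pure individuals at 0 and 1, F1s at 0.5 with
diagnostic markers) is exact.  The maximum is located on a $10^{-3}$
grid and refined by golden-section search; the support interval collects
all $h$ within 2 log-likelihood units of the maximum (roughly 95%).

Interspecific heterozygosity is the proportion of loci whose two copies
descend one from each parental species, computed per locus as the
posterior probability of the mixed ancestry configuration under the
prior $((1-h)^2,\; 2h(1-h),\; h^2)$ and averaged over loci.  Recent
hybrids (F1, F2, fresh backcrosses) combine intermediate $h$ with
elevated interspecific heterozygosity, whereas long-standing admixed
zones show intermediate $h$ with low heterozygosity; `classify_recent_hybrids()`
flags individuals inside an $h$ window (default $[0.2, 0.8]$) whose
heterozygosity exceeds the 90th percentile of the individuals outside
the window.  The window and quantile are configurable because the
field's practice is a visual call on the triangle plot; with no
outside-window individuals a zone provides no background and nothing is
flagged, which is the desired answer for a stable hybrid zone.

## Fst and niche overlap

`nei_fst()` fixes one specific estimator among the family of Nei-style
measures: per locus, $H_s$ is the unweighted mean of the two group
expected heterozygosities $2p(1-p)$ from sample frequencies and $H_t =
2\bar p(1-\bar p)$ with $\bar p$ the unweighted mean frequency; the
multilocus value is $1 - \sum H_s / \sum H_t$ (ratio of sums), with no
sample-size correction.  Uncorrected sample heterozygosities bias the
estimator slightly upward at small samples (order $1/n$), which is well
inside the tolerances used here.

Niche overlap standardizes five climate variables over the pooled
occurrences, projects onto the two leading principal axes, smooths each
species onto a shared 100×100 grid with a Gaussian kernel (Scott's-rule
bandwidth, $\mathrm{sd} \cdot n^{-1/6}$ per axis), and reports
Schoener's $D = 1 - \frac12\sum|z_1 - z_2|$ on the normalized densities.
No correction for the availability of background climate is applied —
densities are smoothed in environment space only — which is a
simplification of the full niche-comparison framework and will inflate
overlap slightly where occupancy tracks availability.

## The synthetic-data generator

Every pipeline input can be generated with known truth.
`gen_species_complex()` simulates one genealogy per RAD tag under any
compiled scenario and drops Poisson mutations on it (infinite sites), so
SNPs on a tag are linked through their shared tree while tags are
independent — matching the data type the filters expect.  A four-taxon
fixture (`complex4_params()`) emulates the study design at reduced
scale: 15 individuals per taxon and 1,000 tags with a per-tag
$\theta_{tag} = 0.5$ and 5% uniformly random missingness, a widespread
lowland parent, heterogeneous parental gene flow ($P = 0.3$ of loci
restricted), a hybrid lineage founded at half the divergence time with
$f = 0.5$, and a recent daughter split.  `gen_contact_zone()` builds
zone samples from Mendelian ancestry classes under free recombination,
and `gen_occurrences()` draws Gaussian niches.

What passing tests on these data show — and what they do not: the
generator realizes exactly the model family the fitter searches, so
recovery tests validate the estimation machinery, not the realism of
the models; real ddRAD data add linkage beyond the tag, non-uniform
missingness correlated with coverage, genotyping error, and
paralog-collapse artifacts that no test here exercises.  Likewise the
generator's missingness is uniform because the real mechanism is
unknown.

## Numerical choices, edge cases, limitations

- Masked cells are excluded from every likelihood sum; observed and
  model masks are OR-combined.
- A model cell of exactly zero with a positive observation would be an
  infinite penalty; the $10^{-12}$ floor makes it a large finite one.
- Folding halves the self-conjugate ridge cells so mass is conserved
  exactly; folding twice is an error rather than a no-op.
- The engine refuses demographies with no common root (isolated demes
  under the oldest epoch) instead of hanging.
- Degenerate hybrid-index inputs (no usable loci; parents identical at
  every locus) error or warn explicitly; the flat-likelihood case
  returns `h = NA` with the full interval.
- Growth models reuse their base model's $k$; if a study wants
  present-size-vs-ancestral-size freedom, that is a different
  parameterization and would change the AIC arithmetic.
- Parameter uncertainty (bootstrap or Godambe corrections) is out of
  scope; only point estimates and AIC comparisons are provided.
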