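---
title: "Inferring demographic history from SNPs by approximate Bayesian computation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring demographic history from SNPs by approximate Bayesian computation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpabc)
```

## The inference problem

A set of diploid individuals, genotyped at unlinked biallelic SNPs and
assigned to five genetic groups (SOUTHERN, LOWER-CENTRAL, UPPER-CENTRAL,
EASTERN, NORTHERN), carries information about the order and timing of the
population splits — and possible admixture events — that produced those
groups. The likelihood of a full demographic model for such data is
intractable, so the package implements approximate Bayesian computation
(ABC): candidate histories are simulated under parameter values drawn from
priors, each simulated dataset is reduced to a vector of summary
statistics, and inference proceeds by comparing the observed statistics
with the simulated ones.

The pipeline has five stages, each an exported module surface:

1. **Scenarios and priors** (`builtin_scenarios()`, `prior_spec()`,
   `sample_prior()`) — a declarative event language for
   divergence/admixture histories.
2. **Coalescent simulation** (`simulate_dataset()`) — Hudson-style
   backward-in-time simulation of independent SNP loci.
3. **Summary statistics** (`compute_sumstats()`) — the 26-component
   statistic vector.
4. **Quality control** (`run_cascade()`) — the SNP filter cascade applied
   to raw genotype matrices before analysis.
5. **ABC proper** (`build_reference_table()`, `direct_pp()`,
   `logistic_pp()`, `prior_error_rate()`, `estimate_parameters()`,
   `model_check()`, `recalibrate_time()`).

## The demographic model family

Each scenario is an ordered list of instantaneous events over five
sampled demes plus one ancestor. A *merge* at time $t$ (backward in time)
moves every lineage of a source deme into a destination deme — forward in
time, the source population splits off from the destination. An
*admixture* routes each lineage of the admixed deme to parent 1 with
probability $r_a$, else to parent 2. Times are in generations; population
sizes are numbers of diploid individuals.

The built-in registry holds eight models in two blocks. In scenarios 1–4
the UPPER-CENTRAL deme is the trunk from which the other groups split; in
5–8 the LOWER-CENTRAL deme is. Within each block the two clean-split
models differ in whether the EASTERN or the NORTHERN split is older, and
the remaining two repeat that pair with the non-trunk central deme founded
by admixture between the trunk and the SOUTHERN deme. Scenario 1 — the
reference model — reads, forward in time: the ancestor (size `NA`) splits
at `t4` into SOUTHERN (`N1`) and the central trunk; EASTERN (`N4`) splits
at `t3`; NORTHERN (`N5`) at `t2`; finally LOWER-CENTRAL (`N2`) and
UPPER-CENTRAL (`N3`) separate at `t1`, with `t1 < t2 < t3 < t4`.

Only the two reference topologies (1 and 2) are fixed by the source
analysis; the topologies of 3–8 are **provisional defaults** chosen to
complete a plausible model family with the full eleven-parameter union
(`NA`, `N1`–`N5`, `t1`–`t4`, `ra`). They can be replaced without code
changes through `read_scenario_config()`, which round-trips scenario sets
and priors through JSON.

```{r scenarios}
scs <- builtin_scenarios()
scs[[1]]
sort(unique(unlist(lapply(scs, scenario_params))))
```

## Priors

All priors are uniform: effective sizes on $[10, 6 \times 10^5]$
diploids, event times on $[10, 10^3]$ generations with the strict chain
$t_1 < t_2 < t_3 < t_4$, and the admixture rate on $[10^{-3}, 0.999]$.
The ordering is enforced by joint rejection — all four times are redrawn
together until the chain holds — which leaves the draw exactly uniform on
the order polytope.

One internal inconsistency of the source analysis had to be resolved: its
reported posterior mean for the oldest split is $1.26 \times 10^3$
generations, *above* the reported common time-prior bound of $10^3$ (a
posterior mean cannot exceed the prior's support; the per-parameter prior
table of the original supplement is not available). `estimation_priors()`
therefore widens the time bound to $2 \times 10^3$ generations so that
the reference truth lies inside prior support, and the shipped recovery
analyses use it. `prior_spec()` defaults keep the narrow published bound.

## The coalescent simulator

Within a deme of constant diploid size $N$, each pair of lineages
coalesces at rate $1/(2N)$ per generation; waiting times are exponential
and piecewise-constant between events (the continuous-time approximation
to the Wright–Fisher model, standard at these sizes and time scales). At
a merge all lineages of the source move to the destination; at an
admixture each lineage of the admixed deme flips an $r_a$-coin. The core
is compiled (Rcpp) with a pure-R reference engine (`engine = "r"`)
implementing the identical algorithm; the two are cross-checked
distributionally in the test suite.

**Mutation model.** Each locus receives exactly one mutation at a point
drawn uniformly over the genealogy's total branch length (the root
carries no branch), so every simulated locus is polymorphic in the pooled
sample, mirroring SNP ascertainment. No further frequency rejection is
applied by default (`min_maf = 0` — a sensitivity knob exists).

A consequence worth stating precisely: under this *per-tree* placement
the probability that the derived allele has $i$ copies is
$\mathbb{E}[\ell_i/L]$ (singleton branch fraction), which is **not** the
classical conditional site-frequency spectrum
$\mathbb{E}[\ell_i]/\mathbb{E}[L] = (1/i)/H_{n-1}$ that arises from
Poisson mutations conditioned on segregating. For $n = 10$ gene copies
the singleton probability is $\approx 0.376$ versus $1/H_9 = 0.3535$.
Exact sampling of the Poisson-conditional (length-biased) law for
event-structured histories has no efficient algorithm, and reference
table and observed data share the same law, so all ABC comparisons remain
internally consistent; the test suite verifies both that the genealogy's
*branch-length proportions* match the analytic $1/i$ spectrum and that
the mutation placement matches its own documented law. Statistics are all
frequency-based and invariant to allele polarity, so unpolarized observed
data are handled identically.

Gene copies are paired into diploids in sampling order; by
exchangeability this is equivalent to random pairing.

## The summary-statistic vector

With five groups and one three-sample configuration the vector has 26
components, in fixed order:

* **5** per-group mean gene diversities, $H = \frac{n}{n-1}(1 - \sum_a
  p_a^2)$, averaged over the *complete* locus distribution (monomorphic
  loci contribute 0);
* **10** pairwise Weir–Cockerham $\hat\theta$ (1984 variance components
  $a/(a+b+c)$, observed heterozygote frequencies, sample-size weighted),
  averaged over loci whose value is defined and non-zero;
* **10** pairwise Nei (1972) standard distances $D = -\ln(J_{xy} /
  \sqrt{J_x J_y})$, same non-zero rule;
* **1** three-sample admixture estimate $\hat f = (p_A - p_2)/(p_1 -
  p_2)$, unclipped, same rule. The default trio takes LOWER-CENTRAL as
  admixed with UPPER-CENTRAL and SOUTHERN as parents — a configurable
  choice, since the original statistic set is not recoverable in full.

"Non-zero" is evaluated with a $10^{-12}$ tolerance so that membership in
the mean is stable under allele relabelling; negative $\hat\theta$ values
are retained (they are non-zero). Undefined values (monomorphic pair,
disjoint alleles, equal parental frequencies) are excluded as `NA`, never
silently zero, and an empty contributing set raises an error.

## The QC cascade

`run_cascade()` applies, in order: biallelic-only, individual
missingness $< 30\%$, pooled MAF $> 5\%$, exact Hardy–Weinberg test
($p \le 0.01$ removed; Levene–Haldane enumeration, two-sided), global
multi-group $\hat\theta > 0.1$ outlier removal, and greedy all-pairs LD
pruning at $r^2 \ge 0.8$ on composite genotype correlations (GBS tags
have no genomic order, so no windowing). Complete-case selection is a
separate final step used to prepare the ABC input. Design points the
source leaves open, with our defaults: HWE is tested on the pooled sample
(per-group mode available; pooling can flag Wahlund-effect loci, which is
noted rather than hidden), and the $F_{ST} > 0.1$ parenthetical is read
as outlier *removal* — keeping only high-$F_{ST}$ loci would bias
demographic inference — with the direction configurable. LD tie-breaks:
remove the member with higher missingness, then lower MAF, then the later
locus; this makes survivor sets order-deterministic.

## ABC machinery

**Reference table.** For each scenario, draws from the prior are pushed
through the simulator and the statistic vector;
rows carry scenario id and the full parameter draw. Tables are buildable
in batches and concatenated with `combine_reference_tables()`; they
persist as a delimited body plus a JSON metadata sidecar.

**Scenario choice.** The *direct* approach standardizes every statistic
by its reference-table standard deviation (a MAD option exists), ranks
rows by Euclidean distance to the observed vector, and reports each
scenario's share of the $k$ nearest rows, with Clopper–Pearson 95%
intervals. The *logistic* approach takes the closest fraction, replaces
statistics by linear-discriminant scores fitted on that subset, and fits
a multinomial logistic regression of scenario on scores with Epanechnikov
weights (bandwidth = the subset's largest distance), evaluated at the
observed point; intervals come from the delta method on the regression's
asymptotic covariance. Both interval constructions are conventions of
this package, not reproductions of the original software's unspecified
method. Degenerate subsets (a single scenario) return probability one
with a warning; singular discriminant fits fall back to a
ridge-regularized projection.

**Prior error rate.** Fresh pseudo-observed datasets are simulated from
the prior under a designated true scenario (never resampled from the
table); the error rate is the fraction in which the true scenario fails
to attain the *strictly* highest posterior probability — ties count as
errors, the conservative reading.

**Parameter estimation.** Within the chosen scenario's rows, the closest
fraction is accepted; every parameter is mapped by
$\mathrm{logit}((\theta - a)/(b - a))$ against its prior bounds; a
weighted local-linear regression of transformed parameters on
standardized statistics (Epanechnikov weights) yields adjusted draws =
fitted value at the observed point + residuals, back-transformed and
summarized by kernel-weighted mean, median, mode (Gaussian KDE, Silverman
bandwidth) and quantiles. Fewer than 50 accepted rows is an error by
default. Two alternatives are available: `method = "ridge"` shrinks the
same fit with a GCV-selected penalty (for ill-conditioned statistic
sets), and `method = "rejection"` skips adjustment.

**Statistic split.** The shipped analyses estimate parameters on the
gene-diversity + $F_{ST}$ components (`estimation_stats()`) and run the
"less biased" goodness-of-fit check on the held-out Nei + admixture
components (`checking_stats()`), so fit quality is never judged by the
statistics that drove the fit. `model_check()` simulates from the
adjusted posterior, fits a PCA on the prior-predictive statistics, and
reports prior cloud, posterior cloud and observed point in PC space plus
per-statistic posterior-predictive tail probabilities.

**Time recalibration.** Posterior times in generations convert to years
by exact multiplication with the species' generation time, 8 years
(range 6–10): central $8t$, low $6t$, high $10t$ — applied to means and
quantiles alike.

## The synthetic-data generator

`make_observed()` simulates the registry's Scenario 1 at the reference
truth (`truth_parameters()`: `NA` $= 5.98\times10^5$, `N1` $= 3440$,
`N2` $= 2710$, `N3` $= 2600$, `N4` $= 681$, `N5` $= 365$; `t4` $= 1260$,
`t3` $= 629$, `t2` $= 351$, `t1` $= 261$ generations), with 693 loci and
124 individuals in groups of 28/41/27/14/14 — nine source populations of
12–15 individuals are emulated by sub-labels. Group sizes are package
defaults (the study's per-population table is not available) and
overridable. Because the truth equals the reference analysis's posterior
means, end-to-end recovery doubles as a plausibility check of that
analysis.

`make_raw()` produces the QC exercise matrix: hierarchical-frequency base
loci with weak structure, plus planted triallelic sites, low-MAF loci,
heterozygote-deficit (HWE-violating) loci, near-fixed high-$F_{ST}$
outliers, duplicated/correlated blocks, and beta-distributed per-genotype
missingness (mean $\approx 1\%$ for ordinary individuals — chosen so
roughly a third of loci are fully observed in a 124-individual matrix, as
in a typical GBS study — plus a few high-missingness individuals). Every
planted set is recorded so tests can assert exact survivor bookkeeping.
What the generator does **not** emulate: genotyping error, allele
dropout, depth-dependent missingness, linked loci, or selection — so
passing tests demonstrate correctness of the machinery under the model's
own assumptions, not robustness to those artefacts.

## Problem sizes and numerical choices

The shipped validation runs at desk scale: reference tables of 300 rows
per scenario (model choice, prior error) and 2,500 rows for the
single-scenario estimation table, 693 loci throughout, 30–40
pseudo-observed datasets, $k = 100$ nearest rows and a 5–6% acceptance
fraction. These sizes keep the full suite in the tens of minutes; the
original analysis used $8\times10^6$ simulations with $k = 500$ and a 1%
fraction, and all scale parameters are plain function arguments.

Numerical conventions: distances standardize by table SD with
zero-variance columns dropped (warning); nearest-neighbour ties break by
row order; weighted quantiles interpolate the weighted ECDF; KDE modes
use the unweighted-sample Silverman bandwidth; the logit transform clamps
at $10^{-12}$ from the bounds. A prior or posterior draw can, rarely,
produce a dataset in which some statistic has an empty non-zero
contributing set (for example, a pair of demes monomorphic at every
locus under an extreme size configuration); `compute_sumstats()` treats
that as an error by contract, and the long-running loops
(`build_reference_table()`, `prior_error_rate()`, `model_check()`)
resample such degenerate draws rather than aborting, reporting the count
in a warning.

## Known limitations

* **Desk-scale prior-tail geometry.** Under the wide uniform size prior,
  the reference truth (two groups of effective size a few hundred, an
  ancestor at $5.98\times10^5$) lies in a corner of prior-predictive
  space with joint mass $\sim10^{-6}$. Small reference tables therefore
  place the observed statistics far outside the simulated cloud; the
  local-linear adjustment is then an extrapolation, and the oldest
  split's time trades off against population sizes (high southern-branch
  $F_{ST}$ can be explained by a larger $t_4$ or a smaller $N_1$). In
  scaled recovery runs the ancestral-size posterior correctly
  concentrates at the top of its range, while $t_4$ is biased toward its
  upper bound. The reference analysis's own boundary-hugging estimates
  suggest the same regime. Conclusions about the *oldest* split time from
  tables of this size should lean on the model-choice and
  model-checking outputs, not the point estimate.
* **Mutation law**, as discussed above: per-tree placement, not the
  Poisson-conditional spectrum.
* No recombination, no linked loci, no within-deme substructure, no
  size changes between events (the model family uses none).
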