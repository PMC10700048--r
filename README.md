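# snpabc

Approximate Bayesian computation (ABC) for inferring the demographic
history of structured populations from unlinked biallelic SNPs.

The package is aimed at population geneticists and phylogeographers who
have a genotype matrix for individuals grouped into genetic units and
want to ask: *in what order did these groups split, were any of them
founded by admixture, when did the events happen, and how large were the
populations?* The likelihood of such models is intractable, so inference
is simulation-based:

1. Candidate histories (divergence/admixture **scenarios**) are written
   in a small declarative event language; eight built-in models cover a
   five-group system with either central group as the trunk lineage,
   with and without admixed origins.
2. Parameters are drawn from uniform priors — effective sizes
   *N* ∈ [10, 6×10⁵] diploids, split times *t* ∈ [10, 10³] generations
   with *t₁ < t₂ < t₃ < t₄*, admixture rate *ra* ∈ [10⁻³, 0.999] — and a
   Hudson-style coalescent (compiled core) simulates independent SNP
   loci: within a deme of size *N* lineage pairs coalesce at rate
   1/(2*N*); one mutation per locus, uniform on the genealogy's branches.
3. Every dataset is reduced to a 26-component summary vector: 5 mean
   gene diversities *H* = *n*/(*n*−1)(1−Σ*p*²), 10 pairwise
   Weir–Cockerham *θ̂* = *a*/(*a*+*b*+*c*), 10 pairwise Nei (1972)
   distances *D* = −ln(*J*ₓᵧ/√(*J*ₓ*J*ᵧ)), and a three-sample admixture
   estimate *f̂* = (*p*<sub>A</sub>−*p*₂)/(*p*₁−*p*₂); two- and
   three-sample means are taken over loci with non-zero values.
4. Scenario choice uses the share of the *k* reference rows nearest the
   observed statistics (direct approach) and a weighted multinomial
   logistic regression on linear-discriminant scores of the closest 1%
   (logistic approach); confidence in the winner is quantified by the
   prior error rate over fresh pseudo-observed datasets.
5. Parameters of the chosen scenario are estimated by logit-transformed
   local-linear regression on the closest fraction of its rows;
   posterior times in generations convert to years via the species'
   generation time, 8 (6–10) years. Goodness-of-fit is checked by
   posterior-predictive simulation in the PCA space of held-out
   statistics.

A quality-control module reproduces the standard SNP filter cascade
(biallelic → individual missingness < 30% → MAF > 5% → exact
Hardy–Weinberg *p* ≤ 0.01 → *θ̂* > 0.1 outliers → LD pruning at
*r*² = 0.8, plus complete-case selection for the ABC input), and a
synthetic-data module generates study-structured datasets with known
truth — including a 124-individual, five-group, 693-locus stand-in
"observed" dataset — so the whole pipeline is testable end to end.

## Worked example

```r
library(snpabc)
obs <- make_observed(seed = 7)   # scenario 1 at the reference truth
obs$geno
#> <geno_matrix> 124 individuals x 693 loci
#>   groups: SOUTHERN (28), LOWER-CENTRAL (41), UPPER-CENTRAL (27), EASTERN (14), NORTHERN (14)
#>   missing: 0.00%

s <- compute_sumstats(obs$geno)
round(s[c("HD.SOUTHERN", "FST.SOUTHERN~UPPER-CENTRAL",
          "FST.LOWER-CENTRAL~UPPER-CENTRAL", "NEI.EASTERN~NORTHERN")], 4)
#>                     HD.SOUTHERN      FST.SOUTHERN~UPPER-CENTRAL
#>                          0.2248                          0.1364
#> FST.LOWER-CENTRAL~UPPER-CENTRAL            NEI.EASTERN~NORTHERN
#>                          0.0374                          0.3170

recalibrate_time(1.26e3)         # oldest split, generations -> years
#>      years  years_low years_high
#>      10080       7560      12600
```

The numbers read as a demographic fingerprint: the SOUTHERN group, whose
split is the oldest (*t₄* = 1260 generations ≈ 10,080 years at 8
years/generation), is strongly differentiated from the trunk
(*θ̂* ≈ 0.14), while the two central groups, separated only at *t₁*, are
barely distinct (*θ̂* ≈ 0.04); the two small peripheral groups (EASTERN,
NORTHERN, effective sizes in the hundreds) show the largest genetic
distances because drift is fastest in small populations.

From here a full analysis is:

```r
ref  <- build_reference_table(builtin_scenarios(), estimation_priors(),
                              default_groups(), n_loci = 693,
                              n_per_scenario = 300, seed = 101)
direct_pp(ref, s, k = 100)            # scenario posterior probabilities
logistic_pp(ref, s, fraction = 0.05)
prior_error_rate(ref, true_scenario = 1, n_pods = 40,
                 method = "direct", k = 100, seed = 1)
post <- estimate_parameters(ref, s, scenario_id = 1, fraction = 0.06,
                            stat_subset = estimation_stats(colnames(ref$stats)))
model_check(ref, post, s,
            stat_subset = checking_stats(colnames(ref$stats)))
```

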