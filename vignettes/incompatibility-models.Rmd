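---
title: "Segregation distortion and Dobzhansky-Muller incompatibility models in F2 crosses"
author: "hybridDMI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segregation distortion and Dobzhansky-Muller incompatibility models in F2 crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridDMI)
```

# The biological setting

When two long-isolated populations are crossed, their F1 hybrids carry one
haploid genome from each parent and are often healthy, but the F2
generation recombines the two genomes and exposes Dobzhansky-Muller (DM)
incompatibilities: combinations of alleles that evolved separately and
function poorly together. In an F2 intercross every codominant marker is
expected to segregate 1:2:1 (parental-1 homozygote : heterozygote :
parental-2 homozygote). Viability selection against particular multi-locus
genotypes during development drags the genotyped cohort away from that
ratio, so *segregation distortion measured at a marker is a fitness
readout* for the chromosomal region around it.

hybridDMI implements the complete analysis chain for such experiments,
modeled on studies of intertidal copepod (*Tigriopus californicus*)
population crosses in which F2 offspring are sampled twice: as nauplii
(the first free-swimming larval stage, collected before most selection has
acted) and as adults (after the larval-to-adult selection episode).
Contrasting the two stages separates early-acting from developmental
selection, and contrasting two-locus tables across stages separates
physical linkage from epistatic viability selection.

# Single-locus statistics

For a marker with class counts $(n_{11}, n_{12}, n_{22})$ and
$N = n_{11}+n_{12}+n_{22}$ scored individuals:

* **Mendelian test.** Pearson $\chi^2$ against expectations
  $(N/4,\,N/2,\,N/4)$ on 2 df. No continuity correction is applied — the
  large statistics typical of these screens make it immaterial, and the
  uncorrected statistic is the one comparable across published tables — but
  a note is attached when any expected cell falls below 5.
* **Sex-homogeneity and reciprocal-cross tests.** A 2×3 contingency
  $\chi^2$ with rows = sexes (or reciprocal crosses) on 2 df. A genotype
  class empty in *both* rows is dropped and the df reduced; a group with
  no individuals is an error rather than a silent zero.
* **Haldane relative viability.** Distortion is quantified per homozygous
  class as $v = 2 n_{\text{hom}} / n_{\text{het}}$, i.e. the deviation
  from the 1:2 homozygote:heterozygote ratio with the heterozygote's
  viability fixed at 1. The reported standard error is the delta-method
  value $\mathrm{se}(v) = v \sqrt{1/n_{\text{hom}} + 1/n_{\text{het}}}$.
  The published figures this mirrors show error bars without stating a
  formula; the delta method was chosen as the standard first-order
  treatment of a count ratio, and an empty homozygote class is reported as
  $v = 0$, $\mathrm{se} = 0$ with an explicit `zero_count` flag rather
  than an undefined value.
* **Holm correction.** Families of tests are corrected with the
  sequential Bonferroni (Holm) step-down procedure. The family is always
  *the results table actually produced* — the threshold printed for a
  published table cannot be reconstructed without its exact test list, so
  the implementation derives thresholds from its own family size rather
  than hard-coding any value.

# The marginal-adjusted two-locus test

The central statistic is a test for deviations from *independence* of two
loci that is deliberately insensitive to each locus's own distortion. For
an ordered pair with observed 3×3 grid $O_{ij}$ over the
pairwise-complete individuals (missing at either locus excluded), the
expected numbers are

$$E_{ij} = \frac{O_{i\cdot}\, O_{\cdot j}}{N},$$

the product of the grid's *own* observed marginals. Single-locus viability
selection moves marginals; because the expectations are built from those
moved marginals, only genuine two-locus structure (linkage or epistatic
selection) contributes to

$$X^2 = \sum_{i,j} \frac{(O_{ij}-E_{ij})^2}{E_{ij}},$$

referred to $\chi^2$ on 4 df (9 cells − 1 − 2 − 2 estimated marginal
class frequencies). The construction conserves marginals exactly —
$\sum_j E_{ij} = O_{i\cdot}$ to machine precision — which the test suite
asserts at $10^{-12}$, and the null rejection rate stays at $\alpha$ even
under heavily distorted marginals (checked at
$(0.1, 0.5, 0.4)\otimes(0.25, 0.5, 0.25)$ with 2,000 replicates of
$N = 500$). Signed per-cell contributions
$\mathrm{sign}(O-E)\,(O-E)^2/E$ are retained so the geometry of a
deviation (which genotype combinations are missing or in excess) can be
read directly; their absolute values sum to the statistic. Expected cells
below 1 attach a warning note but do not abort the test, since grids with
near-lethal classes are exactly the interesting ones; an empty marginal
class, however, makes the test undefined and is an error.

## Linkage versus epistasis

Two loci can fail the independence test for two reasons with different
stage signatures:

* **Physical linkage** distorts nauplii and adults alike, and in a
  coupling-phase F2 the depleted cells are the recombinant-type
  (off-diagonal) combinations.
* **Epistatic viability selection** during development distorts adults
  but not nauplii.

`classifyPair()` codifies this verbal reasoning: `linkage_like` requires
both stages significant with the two most-depleted cells of each stage
off-diagonal and depleted at both stages; `epistasis_like` requires adults
significant and nauplii not; `none` neither; anything else is
`ambiguous`. The rule is a labeled heuristic — the source studies apply
this argument verbally, not algorithmically — and the identity of the
most-depleted cells is left as a *class* (recombinant-type cells) rather
than demanding the same two cells in both stages, which sampling noise
would violate even for genuinely linked loci. In `runScreen()` the
per-stage significance decisions come from the Holm family over the
two-locus table, so classification respects the same multiplicity control
as the flags.

# Exact incompatibility-model enumeration

`f2Frequencies()` enumerates all $3^L$ F2 genotype classes exactly. F1
parents are heterozygous at every locus in coupling phase (each F1 carries
one intact haploid genome from each source population), so gamete
haplotype probabilities follow the recombination fractions directly, with
independence across intervals (no crossover interference — a standard
simplification at the two- and three-locus scale used here). Unlinked loci
contribute independent $(1/4, 1/2, 1/4)$ factors; $r = 0.5$ reproduces the
unlinked table to $10^{-12}$.

A `FitnessScheme` maps derived-allele dosage $d_\ell \in \{0,1,2\}$ per
locus (plus optionally the cytotype, a fixed maternally inherited factor
set by cross direction) to a viability $w \in [0,1]$, as a set of clauses.
All named models are recessive-style in the focal locus:

| model | lethal/penalized combinations |
|---|---|
| `pairwise_hom_hom` | $d_f = 2 \wedge d_p = 2$ |
| `pairwise_one_way` | $d_f = 2 \wedge d_p \ge 1$ |
| `complex_conspecific` | all listed loci $d = 2$ |
| `independent_one_way` | one one-way clause per partner |
| `independent_two_way` | one-way clauses plus $d_f = 1 \wedge d_p = 2$ per partner |
| `cytonuclear` | $d_f = 2 \wedge$ foreign cytotype |

Fitness composes *multiplicatively* across simultaneously satisfied
clauses, treating multiple incompatibilities as independent survival
hazards; at the default $w = 0$ (complete inviability) the choice of
composition rule is inconsequential because any satisfied clause is
already lethal. $w = 0$ is the default because it yields the models'
sharp analytic bounds on the focal derived homozygote's relative
viability, which the package reproduces exactly by enumeration:

* `pairwise_hom_hom`: $v = 0.75$ — a hom×hom interaction can remove at
  most a quarter of the focal homozygotes;
* `pairwise_one_way`: $v = 0.25$ — three quarters of focal derived
  homozygotes are inviable;
* `independent_one_way`, two partners: $v = 1/16 = 0.0625$;
* `independent_two_way`, two partners: $v = 1/9$, with the partner's
  derived homozygote dropping to $0.4$ and its ancestral homozygote
  rising to $1.1$;
* `complex_conspecific`, three loci: $v = 0.9375$ — requiring joint
  homozygosity at three loci *dilutes* the marginal effect at any single
  locus.

These numbers frame the interpretation of observed viabilities: a
single-locus relative viability around 0.1 is below the two-locus
one-way floor of 0.25, so it requires either multiple independent
incompatibilities sharing the focal region or a cytoplasmic interaction
(which reciprocal crosses can exclude, since the cytotype changes while
the skew persists).

`estimateFitness()` inverts the engine by maximum likelihood: for a
single-free-parameter scheme family it maximizes the multinomial
log-likelihood of observed class counts over $w \in [0,1]$ and reports a
profile-likelihood interval at the $\chi^2_1$ cutoff of 1.92
log-likelihood units. A likelihood flat to within $10^{-6}$ across the
whole parameter range (e.g. counts at a locus the scheme never touches)
is flagged non-identifiable instead of returning an arbitrary optimum.

# The forward simulator

`simulateCohort()` is the package's test bed: it generates data with the
structure of a real two-stage F2 experiment without any downloaded input.

1. Each of `nOffspring` zygotes is the union of two coupling-phase
   gametes drawn per linkage group (Markov chain over loci with flip
   probability $r$).
2. Sex is assigned male/female with probability 1/2, independent of
   genotype.
3. Episode 1 (`embryo_to_nauplius`) survival is Bernoulli with the
   scheme's fitness; the nauplius sample is then drawn *destructively*
   (sampled larvae are genotyped, not returned to the dish), matching how
   larval samples are actually collected.
4. An optional genotype-independent `baselineMortality` thins the
   remainder (default 0: stage-to-stage background attrition is not
   reported in the motivating studies, so it is exposed only as a
   nuisance parameter).
5. Episode 2 (`nauplius_to_adult`) selection acts, and the adult sample
   is drawn — either a total count or per-sex counts, so cohorts can be
   sampled at realistic genotyped sizes (e.g. 241 males, 411 females and
   174 nauplii, the scale of the motivating experiment).
6. Nauplii are reported with sex `"unknown"`, since larvae cannot be
   sexed morphologically.

Sex differences are modeled as *intensity* scaling only: females survive
with probability $w^{1+\texttt{sexEffect}}$, males with $w$. This
reproduces the empirical pattern that sexes differ in the magnitude but
not the direction of deviations, and it makes genotype independent of sex
by construction when $w \equiv 1$. A single seeded generator with a
documented stream order (gametes by linkage group, sex, episode-1
survival, nauplius sample, baseline mortality, episode-2 survival, adult
sample) makes every table byte-reproducible from its `SimConfig`.

What the generator deliberately does **not** emulate: fecundity variation
among F1 females, inbreeding, genotyping error, multi-generation
dynamics, and environmental (e.g. temperature) modulation beyond running
separate fitness schemes per scenario. Tests passing on simulated data
therefore validate the statistical machinery under the stated sampling
model, not the field realism of any particular dataset.

# Numerical and design choices

* Genotype codes are population-anchored (`P1`/`H`/`P2`), not
  allele-letter, so reciprocal crosses share one vocabulary; which
  parental allele is "derived" is a per-locus annotation
  (`derived_parent`), since it must be inferred per cross and cannot be
  read from the data.
* Missing genotypes are dropped per test (pairwise deletion for
  two-locus grids), never imputed; per-marker totals may therefore differ
  across markers, as in the published tables.
* p-values are kept at full precision internally; `formatPValue()`
  truncates to `"<0.00001"` only for display.
* The enumeration engine and the simulator are held together by a
  total-variation check (TV < 0.01 between the enumerated joint table and
  a 200,000-adult simulated cohort) and the estimator by parameter
  recovery at $N = 10{,}000$ ($\hat w$ within 0.05 of truth for
  $w \in \{0, 0.5\}$).
* Simulation-study sizes in the test suite (e.g. 500 neutral cohorts of
  1,000 offspring for the Mendelian size check, 100-replicate power runs
  at the 660-adult scale of a real cross) were chosen as the smallest
  runs whose Monte-Carlo error is comfortably inside the asserted bands.

# Limitations

* Only F2 intercross designs are supported — no F1/backcross, no
  multi-allelic markers, no genotype likelihoods.
* The two-locus test is asymptotic Pearson; no exact or log-linear
  alternatives are provided, and three-way interactions enter only
  through model predictions, not observed-data tests.
* `classifyPair()` is a heuristic summary of a stage contrast, not an
  inference about recombination fraction; tightly linked loci under
  strong epistatic selection can genuinely be `ambiguous`.
* The fitness estimator assumes a single free $w$ shared by all clauses
  of the family; schemes with per-clause fitnesses must be composed
  manually.
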