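---
title: "Fine-mapping HLA association signals: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping HLA association signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlafinemap)
```

## The problem

Immune-mediated diseases map overwhelmingly to the MHC, but the region's
long-range linkage disequilibrium means a significant classical allele may
be causal, may tag a causal variant elsewhere on its haplotype, or may owe
its signal entirely to a partner allele. `hlafinemap` implements the
standard dissection toolkit for case-control cohorts whose genotypes
arrive as classical HLA allele calls: association testing at the allele
and amino-acid level, conditional and stepwise modelling, haplotype
frequency estimation, carrier-level exact inference, and regulatory-variant
imputation. This vignette records the models, their assumptions, and the
choices we made where conventions genuinely differ.

## Data model

A cohort is one row per subject: phenotype (case/control), sex, cohort
label, ancestry principal-component scores, and exactly two allele calls
per locus (A, B, C, DQA1, DQB1, DRB1), each either missing or a
WHO-nomenclature name at two-digit (`C*06`) or four-digit (`C*06:02`)
resolution. Four-digit resolution determines the protein sequence, which
is why residue-level analyses require it. Two-digit analyses are separate
runs over calls truncated at the first colon (`collapse_two_digit()`).

**Missing calls.** How half-typed genotypes enter frequency denominators
is a genuine convention choice. We compute allele frequencies over
non-missing chromosomes only and log the excluded count. Additive dosage
columns are set missing for a subject with *any* missing call at that
locus, because a dosage over a half-observed genotype systematically
undercounts. Carrier (dominant-model) predicates instead work over the
observed alleles — one observed Bw4-80I allele proves carriage regardless
of the partner — so carrier analyses and dosage analyses can legitimately
have different denominators on the same cohort.

**Frequency filter.** Only alleles (and residues) with frequency strictly
greater than 1% *in the control group* are analysed by default. Using
controls only keeps the filter independent of the case sample; the
boundary case (exactly 1%) is excluded.

## Association model

All single-marker tests are additive logistic regressions

$$\operatorname{logit} P(\text{case}) = \beta_0 + \beta x + \gamma' z,$$

with $x \in \{0,1,2\}$ the dosage, $z$ the covariates (sex, cohort
indicator columns, ancestry PCs — the number of PCs is a configuration
value since scree-based choices differ per cohort), and conditioning
implemented by adding the conditioned dosages to $z$. Single terms are
reported with Wald statistics, matching the output conventions of the
standard GWAS toolchain; the multi-residue omnibus test is a
likelihood-ratio test because its null spans several coefficients.

Numerical conventions: iteratively reweighted least squares to a relative
log-likelihood change below 1e-10 with at most 100 iterations;
rank-deficient designs are pivoted so aliased columns get `NA`
coefficients — an aliased *focal* term produces a warning and no p-value,
never a spurious one; any fitted $|\beta| > 15$ (log-odds) flags the
result unstable, the practical symptom of perfect separation.

**Amino-acid expansion.** Four-digit alleles are mapped to residues via a
positional alignment in 1-based mature-protein coordinates; the alignment
file's header row fixes the numbering convention and is the single source
of truth. Gap (`-`) and undetermined (`?`) symbols are treated as missing
at that position rather than as an extra residue level, so omnibus degrees
of freedom never count a gap state. The packaged alignment is a
**synthetic** stand-in covering the ~70 alleles used in tests and
examples: the position-80 Bw4-80I/Bw4-80T/Bw6 assignments and the
116Y allele set follow published serology, while residues at other
positions are realistic but illustrative. Real analyses should supply a
full reference alignment in the same TSV format. Residue columns with
identical dosage vectors (alleles identical over the covered positions)
can optionally be merged (`dedupe = TRUE`), since they are exact aliases
in any regression.

**Omnibus position test.** For a position with $k$ residues we drop one
reference residue (the most frequent, by default — the statistic is
invariant to this choice, which the tests verify) and compare the model
with the remaining $k-1$ dosages against the covariates-only null:
$\text{LRT} \sim \chi^2_{k-1}$.

## Stepwise selection

Forward selection from an empty model (optionally seeded with a forced
first term, e.g. the locus-wide top allele): at each step every remaining
candidate is tested conditional on all selected terms, the smallest
conditional Wald p enters if it clears the threshold, and selection stops
otherwise. There is no backward elimination. Entry thresholds ship as the
0.05 Bonferroni bounds for the standard candidate counts (88 class I + II
alleles → 0.0006; 52 class I alleles → 0.00096; 480 residues → 0.0001).
Ties are broken by larger $|\beta|$, then lexicographic term name, purely
so selection is deterministic and testable. Reported effects come in two
flavours, matching standard practice: the at-entry (stepwise-univariate)
statistics and a final joint refit (multivariate). Covariates are held
fixed throughout a run. A caution inherent to the method: with dense LD
the selected set depends on the starting term, and a functional residue
can be displaced by a tagging partner — selection identifies independent
*signals*, not necessarily causal residues.

## Haplotype estimation

`em_haplotypes()` is the standard genotype EM under within-group
Hardy-Weinberg equilibrium: the E-step distributes each ambiguous
multi-locus genotype over its compatible haplotype pairs proportionally to
the current frequency products, the M-step re-estimates frequencies from
expected counts. The log-likelihood is asserted non-decreasing at every
iteration. Convergence: maximum absolute frequency change below 1e-8 or
10,000 iterations; 5 restarts from Dirichlet-perturbed uniform starts
(fixed default seed 17) guard against local maxima; haplotypes below 1e-6
are pruned. EM runs separately within cases and within controls: under
case-control ascertainment a joint fit would violate HWE exactly when an
association exists, biasing the estimates the test then consumes.

Case-control haplotype tests convert estimated frequencies to counts
(frequency × 2N, rounded half-up) and test the 2×2 of this haplotype
versus all others — chi-squared by default, switching to the exact test
whenever any expected cell is below 5 (the choice of switch rule is ours;
results are insensitive for the common haplotypes of interest). Treating
EM point estimates as counts ignores phase uncertainty; we note this
rather than correct it, matching standard practice for this analysis. LD
statistics use the closed forms $D = p_{AB} - p_A p_B$,
$D' = D/D_{\max}$, $r^2 = D^2/(p_A p_a p_B p_b)$.

## Carrier-level exact inference

Dominant-model analyses reduce to 2×2 tables (exposed/unexposed ×
case/control). The odds ratio is the cross product with a Woolf interval
$\exp(\log \text{OR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$; a zero cell takes
the Haldane 0.5 correction with a warning. CI conventions for 2×2 tables
differ across tools (Woolf, exact conditional, mid-p); we use Woolf and
flag it as convention-dependent. The two-sided Fisher test uses the
probability-mass rule — the sum of hypergeometric probabilities of all
tables with the observed margins no more probable than the observed one —
with a 1e-12 relative slack so analytically tied tables that differ only
in floating point are included. Two-sided definitions for this test vary
(doubling the one-sided p is the main alternative); the probability-mass
rule is the dominant convention and the one implemented.

The KIR3DS1 × Bw4-80I compound genotype is the joint carrier status of an
activating NK-cell receptor (KIR3DS1, chromosome 19, segregating
independently of the MHC) and its putative ligand (any HLA-B allele with
isoleucine at position 80). `compound_status()` requires complete KIR and
HLA-B information for a call — `incomplete` is a value, not an error —
while the single-marker Bw4-80I predicate counts carriage over observed
alleles; this is why the five standard carrier analyses can have three
different denominators on one cohort.

## Deletion imputation

rs67384697 (HLA-C 3′UTR G/del, disrupting the hsa-miR-148 site; the del
allele marks high HLA-C surface expression) is assigned from four-digit
HLA-C alleles through a lookup table, exploiting the strong allele-indel
LD (complete for C*06:02). The shipped default table covers common
European alleles and is explicitly replaceable; alleles absent from the
table impute as missing and are counted. The conditional machinery then
asks the substantive question: a deletion that merely tags a causal allele
attenuates toward OR 1 once that allele is conditioned on, while a
deletion with its own effect retains conditional significance — both
behaviours are exercised in the test suite with planted truth.

## Heterogeneity

Per-cohort effects are pooled by fixed-effect inverse variance;
$Q = \sum_i w_i(\beta_i - \bar\beta)^2$ with $w_i = 1/\text{se}_i^2$, and
$I^2 = \max(0, (Q - \text{df})/Q) \times 100$ is the percentage of
variation attributable to between-cohort heterogeneity (≈25 low, ≈50
moderate, ≈75 high). At least two cohorts are required (df = 0
otherwise).

## The synthetic cohort generator

`generate_cohort()` draws two haplotypes per subject from a configurable
pool under HWE, covariates from the covariate model, KIR3DS1 carriage
independently (an unlinked locus), and disease by the logistic model on
additive dosages plus covariates and the dominant×dominant KIR×Bw4-80I
interaction. Cases and controls are ascertained by rejection sampling
from a base population with configurable prevalence (default 2%) — odds
ratios, not absolute risks, are the estimands, and conditional ORs are
preserved under outcome-dependent sampling. Missingness is applied last,
completely at random per subject-locus. The truth record keeps the phased
haplotypes, the KIR states and every planted effect, which is what lets
the test suite verify EM against direct phase counting, stepwise recovery
against planted effects, and attenuation patterns against known
mediation.

Defaults represent a large European-ancestry psoriasis-style study: 1,727
cases and 3,581 controls; a 28-haplotype B-C pool with strong LD including
a B*57:01–C*06:02 haplotype at base frequency 0.034; a leading HLA-C
risk allele (OR 3) with additional class I effects; KIR3DS1 carrier
frequency 0.33 with a compound-genotype interaction (OR ≈ 3.9); and mild
cohort/ancestry confounding (cohort effect log 1.2, PC shifts of 0.5 SD
with PC effects of 0.1). Where the emulated study design fixes a value we
use it; remaining choices (covariate effect sizes, prevalence) are set
once at field-realistic magnitudes and documented here.

What the generator does *not* emulate: genuine MHC recombination maps and
population demography, imputation error in the allele calls, and
non-random missingness. Passing tests therefore demonstrate correctness
of the statistical machinery under the stated model, not robustness to
imputation artefacts or cryptic structure in real data.

`table6_fixture()` is different in kind: a deterministic 679-subject
cohort engineered so the five KIR3DS1/Bw4-80I carrier analyses reproduce
a published table cell-for-cell, including its three distinct
denominators, which arise naturally from the missingness conventions
described above (KIR typed in all 397/282; ≥1 HLA-B call in 339/247;
complete HLA-B in 331/245). Its construction is assertion-checked at
build time.

## Problem sizes used in validation

The shipped validation suite runs at desk scale, chosen to make each
check sharp while remaining quick: exhaustive Fisher enumeration over all
2×2 tables with n ≤ 60 against an independent `lchoose`-based oracle; EM
against a brute-force one-parameter likelihood grid on the classic
50/50/10 two-locus instance and against phased truth over 50 seeded
cohorts of 2,000 subjects; stepwise null calibration with 88 candidates
and 100 phenotype permutations against the analytic
$1-(1-0.0006)^{88}$ rate, and power with two planted unlinked effects
(OR 3.5 and 1.8) at n = 4,000 over 50 replicates; omnibus type-I error
over 1,000 null simulations. The paper-scale covariate-adjusted cohort
results themselves are not reproducible without the original genotypes;
the property-based checks above are the designed substitute.

## Known limitations

* Wald p-values are anti-conservative under separation; such fits are
  flagged, not silently dropped.
* The EM treats allele calls as known; posterior-probability dosages from
  imputation are not propagated.
* The packaged alignment and deletion map are test-scale defaults, not
  reference data; both loaders accept full externally supplied tables.
* Haplotype tests on EM counts understate uncertainty for rare
  haplotypes; prefer the exact-test path (automatic below expected count
  5) and treat borderline rare-haplotype p-values with caution.
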