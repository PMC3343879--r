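# hlafinemap

Fine-mapping of HLA association signals in case-control cohorts.

The MHC is the strongest association locus for many immune-mediated
diseases, but its dense linkage disequilibrium makes the signal hard to
localise. Starting from classical HLA allele calls (typed or imputed, WHO
nomenclature such as `B*57:01`), `hlafinemap` re-expresses and dissects the
association at every level a fine-mapping analysis needs:

* **Alleles** — covariate-adjusted additive logistic regression per allele,
  with the control-group MAF > 1% filter, conditional tests, and results
  ranked by p-value.
* **Amino acids** — each four-digit allele determines its protein sequence,
  so allele calls translate into per-position residue dosages; single
  residues get Wald tests and multi-residue positions a joint
  likelihood-ratio (omnibus) test on k − 1 degrees of freedom.
* **Independent effects** — forward stepwise selection with Bonferroni
  stopping thresholds (0.0006 for 88 class I + II allele candidates,
  0.00096 for 52 class I candidates, 0.0001 for 480 residue candidates),
  entry by conditional Wald p, final effects from a joint refit.
* **Haplotypes** — EM estimation of multi-locus haplotype frequencies from
  unphased genotypes under Hardy–Weinberg equilibrium, cross-checked by
  direct counting of phased data, with chi-squared/exact case-control tests
  and pairwise LD statistics (D′, r²).
* **Carrier-level (dominant) 2×2 analyses** — odds ratios with Woolf
  intervals and a probability-mass two-sided Fisher's exact test, including
  the KIR3DS1 × HLA-B Bw4-80I compound genotype (Bw4-80I = isoleucine at
  mature-protein position 80 of HLA-B; Bw6 = asparagine).
* **rs67384697** — imputation of the HLA-C 3′UTR G/del polymorphism from
  four-digit HLA-C alleles via a configurable LD lookup, with conditional
  association tests.
* **Cross-cohort heterogeneity** — fixed-effect pooling with Cochran's Q
  and I² = max(0, (Q − df)/Q) × 100.
* **Synthetic cohorts** — a generator that draws haplotypes under HWE,
  applies a logistic disease model with allele/residue/interaction effects
  and covariate confounding, ascertains cases and controls by rejection
  sampling, and retains full ground truth (including phase) so every stage
  can be validated.

The core model throughout is additive logistic regression

&nbsp;&nbsp;logit P(case) = β₀ + β·dosage + γ′·covariates,

with dosage ∈ {0, 1, 2} copies of an allele or residue, covariates
comprising sex, cohort indicators and ancestry principal components, and
conditioning implemented by adding the conditioned dosages to the
covariate set. OR = exp(β).

## Worked example

```r
library(hlafinemap)

## simulate a cohort with known structure, then scan it
ch <- generate_cohort(simulation_spec(n_cases = 500, n_controls = 1000,
                                      seed = 42))
y <- phenotype_vector(ch)
X <- allele_dosage_matrix(ch, maf_filter_cohort(ch))   # MAF > 1% in controls
head(assoc_scan(y, X, covariates = covariate_matrix(ch)), 5)
#>      term    or ci_lo ci_hi        p
#> 1 C*06:02 4.915 3.918 6.165 3.87e-43
#> 2 B*57:01 6.682 4.696 9.508 4.84e-26
#> 3 B*50:01 3.251 2.226 4.748 1.06e-09
#> 4 B*13:02 2.664 1.847 3.843 1.59e-07
#> 5 C*04:01 0.414 0.295 0.583 3.93e-07
```

The generator plants a risk effect on `C*06:02`; the other significant
alleles are hitchhikers riding the B–C haplotype structure (`B*57:01`
shares a haplotype with `C*06:02`), which is exactly the confounding the
conditional and haplotype machinery untangles:

```r
est_ca <- em_haplotypes(ch, c("B", "C"), group = "cases")
est_co <- em_haplotypes(ch, c("B", "C"), group = "controls")
haplotype_case_control_test(est_ca, est_co, c("B*57:01", "C*06:02"))
#> B*57:01-C*06:02: freq cases 0.137, controls 0.024, OR 6.60, p 2.63e-34
```

A deterministic KIR3DS1 × Bw4-80I demonstration cohort ships with the
package:

```r
aln <- read_alignment()
compound_genotype_table(table6_fixture(aln), aln)
#>          genetic_variable freq_cases_pct freq_controls_pct        p    or
#> 1 KIR3DS1_without_Bw4-80I           23.9              25.7 6.26e-01 0.906
#> 2 Bw4-80I_without_KIR3DS1           23.0              16.3 5.84e-02 1.527
#> 3         KIR3DS1+Bw4-80I           22.7               6.9 1.54e-07 3.929
#> 4                 KIR3DS1           46.6              32.6 2.68e-04 1.802
#> 5                 Bw4-80I           45.4              23.5 3.76e-08 2.713
```

The compound genotype — an activating NK-cell receptor together with its
putative HLA-B ligand — carries the risk; either factor alone does not.

`run_pipeline(run_config(cohort, out_dir))` chains all stages and writes
diffable TSV tables plus a JSON manifest; `inst/cli/hlafinemap.R` is a thin
command-line wrapper over the same functions.

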