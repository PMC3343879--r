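# In-code fixture builders shared across test files.

# Minimal subject frame: two-locus (A, B) cohort from explicit calls.
make_subjects <- function(phenotype, ..., kir3ds1 = NULL) {
  calls <- list(...)
  n <- length(phenotype)
  df <- data.frame(
    id = sprintf("s%04d", seq_len(n)),
    phenotype = phenotype,
    sex = rep(c("F", "M"), length.out = n),
    cohort = "c1",
    stringsAsFactors = FALSE
  )
  for (nm in names(calls)) df[[nm]] <- calls[[nm]]
  if (!is.null(kir3ds1)) df$kir3ds1 <- kir3ds1
  df
}

# Tiny in-code protein alignment written to a tempfile and loaded through
# the package reader (so the reader itself is exercised).
make_alignment <- function(alleles, positions, residues) {
  stopifnot(nrow(residues) == length(alleles),
            ncol(residues) == length(positions))
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(allele = alleles, residues, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("allele", positions)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  read_alignment(path)
}

# Cohort drawn from two independent biallelic-ish loci with no LD, so the
# planted effects are genuinely unlinked.
unlinked_spec <- function(beta_c = log(3.5), beta_b = log(1.8),
                          n_cases = 2000, n_controls = 2000, seed = 1) {
  bf <- c("B*57:01" = 0.15, "B*07:02" = 0.35, "B*08:01" = 0.50)
  cf <- c("C*06:02" = 0.20, "C*07:01" = 0.50, "C*07:02" = 0.30)
  pool <- expand.grid(B = names(bf), C = names(cf),
                      stringsAsFactors = FALSE)
  pool$freq <- bf[pool$B] * cf[pool$C]
  simulation_spec(
    loci = c("B", "C"), haplotypes = pool,
    allele_effects = c("C*06:02" = beta_c, "B*57:01" = beta_b),
    kir_bw4_beta = 0, cohort_beta = 0, pc_beta = numeric(0),
    cohort_pc_shift = 0, sex_beta = 0,
    n_cases = n_cases, n_controls = n_controls, seed = seed
  )
}
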