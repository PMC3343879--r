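#' Read an HLA-C allele to rs67384697 state mapping
#'
#' rs67384697 is a G/deletion polymorphism in the HLA-C 3'UTR; the
#' deletion disrupts the hsa-miR-148 binding site and marks high HLA-C
#' surface expression. Because four-digit HLA-C alleles are in strong LD
#' with the indel (complete for C*06:02), genotypes can be assigned from
#' the classical alleles through a lookup. The file is a two-column TSV
#' (`allele`, `state` of `G`/`del`/`unknown`); the package ships a curated
#' default covering common European alleles, which a user-supplied full
#' table replaces.
#'
#' @param path Path to the mapping TSV; default: the packaged default.
#' @return Object of class `deletion_map`: named character vector
#'   allele -> state, with a `"source"` attribute.
#' @export
read_deletion_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rs67384697_map_default.tsv",
                        package = "hlafinemap", mustWork = TRUE)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "#",
                          quote = "")
  if (!all(c("allele", "state") %in% names(df))) {
    stop_fm("deletion map needs columns 'allele' and 'state'")
  }
  if (!all(df$state %in% c("G", "del", "unknown"))) {
    stop_fm("deletion map states must be G, del or unknown")
  }
  parse_allele(df$allele, locus = "C")  # validates
  map <- df$state
  names(map) <- df$allele
  structure(map, class = "deletion_map", source = path)
}

#' Impute rs67384697 deletion dosage from HLA-C alleles
#'
#' Per subject, the deletion dosage is the number of HLA-C alleles
#' mapping to `del` (0/1/2). If either call is missing, or maps to
#' `unknown`, or is absent from the map, the genotype is missing; the
#' number of such subjects is logged. The imputation is a pure function
#' of the HLA-C calls and the map.
#'
#' @param cohort A [cohort_table()] with four-digit HLA-C calls.
#' @param map A `deletion_map` (default: the packaged mapping).
#' @return Numeric vector of del dosages named by subject id (`NA` =
#'   missing).
#' @export
impute_deletion <- function(cohort, map = read_deletion_map()) {
  if (!length(map)) stop_fm("deletion map is empty")
  if (!"C" %in% cohort$loci) stop_fm("cohort has no HLA-C calls")
  sub <- cohort$subjects
  state <- function(al) {
    out <- unname(unclass(map)[al])
    out[is.na(al)] <- NA
    out
  }
  s1 <- state(sub$C_1)
  s2 <- state(sub$C_2)
  known <- !is.na(s1) & !is.na(s2) & s1 != "unknown" & s2 != "unknown"
  dose <- rep(NA_real_, nrow(sub))
  dose[known] <- (s1[known] == "del") + (s2[known] == "del")
  if (any(!known)) {
    fm_log(sum(!known), " subject(s) with unmapped or missing HLA-C ",
           "alleles; rs67384697 genotype set missing")
  }
  names(dose) <- sub$id
  dose
}

#' Association of the imputed rs67384697 deletion with phenotype
#'
#' Fits the del dosage in the standard covariate-adjusted logistic model,
#' optionally conditioning on classical-allele dosage terms (e.g. to ask
#' whether the deletion signal survives conditioning on C*06:02).
#'
#' @param cohort A [cohort_table()].
#' @param map A `deletion_map`.
#' @param covariates Optional covariate matrix.
#' @param condition Optional conditioning dosage matrix/vector.
#' @return An `hla_assoc` result for term `"rs67384697_del"`.
#' @export
deletion_association <- function(cohort, map = read_deletion_map(),
                                 covariates = NULL, condition = NULL) {
  dose <- impute_deletion(cohort, map)
  fit_logistic(phenotype_vector(cohort), dose, covariates = covariates,
               condition = condition, term = "rs67384697_del")
}
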